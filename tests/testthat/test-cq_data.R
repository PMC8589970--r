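test_that("long Cq tables round-trip through read and write", {
  f <- withr::local_tempfile(fileext = ".tsv")
  long_cq_file(f, genes = c("g1", "g2"), samples = c("s1", "s2"), n_rep = 3)
  res <- read_cq_table(f, layout = "long")
  expect_s3_class(res$cq, "cq_matrix")
  expect_equal(nrow(res$cq$technical), 12)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(res$cq, f2)
  res2 <- read_cq_table(f2, layout = "long")
  expect_identical(res2$cq$technical$cq, res$cq$technical$cq)
  expect_identical(res2$cq$technical$gene, res$cq$technical$gene)
})

test_that("invalid tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,gene_name,cq", "s1,g1,20"), f)
  expect_error(read_cq_table(f, layout = "long"), "gene")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,gene,cq", "s1,g1,20", "s2,g1,notanumber"), f2)
  expect_error(read_cq_table(f2, layout = "long"), "row 2")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g1", "s1,20,21"), f3)
  expect_error(read_cq_table(f3, layout = "wide"), "duplicated gene")

  expect_error(cq_matrix(matrix(c(20, 50), 1, 2,
                                dimnames = list("g", c("a", "b")))),
               "invalid Cq")
})

test_that("technical replicates aggregate by mean with spread QC flags", {
  tech <- data.frame(
    gene = rep("g1", 3), sample_id = rep("s1", 3),
    technical_replicate = 1:3, cq = c(20.0, 20.1, 24.0))
  m <- aggregate_technical_replicates(cq_matrix(technical = tech),
                                      max_spread = 1.0)
  expect_equal(unname(m$values["g1", "s1"]), mean(c(20, 20.1, 24)))
  qc <- attr(m, "qc")
  expect_true(qc$flagged[qc$gene == "g1" & qc$sample == "s1"])
  expect_equal(qc$spread[1], 4.0)

  # constant replicates: exact value, no flag
  tech2 <- data.frame(gene = "g1", sample_id = "s1",
                      technical_replicate = 1:3, cq = rep(20, 3))
  m2 <- aggregate_technical_replicates(cq_matrix(technical = tech2))
  expect_equal(unname(m2$values[1, 1]), 20)
  expect_false(attr(m2, "qc")$flagged[1])

  # (20, 21, 22) -> 21
  tech3 <- data.frame(gene = "g1", sample_id = "s1",
                      technical_replicate = 1:3, cq = c(20, 21, 22))
  expect_equal(unname(aggregate_technical_replicates(cq_matrix(technical = tech3),
                                                     max_spread = 5)$values[1, 1]),
               21)

  # a missing cell errors with the cell identity
  m4 <- cq_matrix(technical = rbind(
    data.frame(gene = c("g1", "g2"), sample_id = "s1",
               technical_replicate = 1, cq = c(20, 21)),
    data.frame(gene = "g1", sample_id = "s2",
               technical_replicate = 1, cq = 20)))
  expect_error(aggregate_technical_replicates(m4), "g2.*s2|s2.*g2")
})

test_that("dataset splitting partitions samples by resistance class", {
  samples <- paste0("s", 1:16)
  classes <- rep(c("susceptible", "resistant"), each = 8)
  x <- matrix(20 + seq_len(3 * 16) / 10, 3, 16,
              dimnames = list(c("g1", "g2", "g3"), samples))
  ann <- tiny_annotations(samples, classes)
  sp <- split_datasets(cq_matrix(x), ann)
  expect_equal(ncol(sp$all$values), 16)
  expect_equal(ncol(sp$susceptible$values), 8)
  expect_equal(ncol(sp$resistant$values), 8)
  expect_length(intersect(colnames(sp$susceptible$values),
                          colnames(sp$resistant$values)), 0)
  expect_identical(rownames(sp$resistant$values), rownames(x))

  # one-class data: the other subset is absent, with a warning
  ann1 <- tiny_annotations(samples, rep("susceptible", 16))
  expect_warning(sp1 <- split_datasets(cq_matrix(x), ann1), "resistant")
  expect_null(sp1$resistant)

  # unannotated sample errors
  expect_error(split_datasets(cq_matrix(x), ann[-1, ]), "s1")
})

test_that("the full factorial design yields 64 samples, 32 per class", {
  cfg <- simulation_config(seed = 11)
  sim <- simulate_cq_dataset(cfg)
  expect_equal(nrow(sim$annotations), 2 * 2 * 2 * 2 * 4)
  m <- aggregate_technical_replicates(sim$cq)
  sp <- split_datasets(m, sim$annotations)
  expect_equal(ncol(sp$all$values), 64)
  expect_equal(ncol(sp$susceptible$values), 32)
  expect_equal(ncol(sp$resistant$values), 32)
})

test_that("aggregation commutes with dataset splitting", {
  cfg <- simulation_config(seed = 5, n_populations = 1, n_bioreps = 2)
  sim <- simulate_cq_dataset(cfg)
  agg_then_split <- split_datasets(aggregate_technical_replicates(sim$cq),
                                   sim$annotations)
  # split the technical layer first, then aggregate each part
  for (ds in c("susceptible", "resistant")) {
    keep <- sim$annotations$sample_id[
      sim$annotations$population_class == ds]
    tech <- sim$cq$technical[sim$cq$technical$sample_id %in% keep, ]
    split_then_agg <- aggregate_technical_replicates(
      cq_matrix(technical = tech))
    expect_equal(
      split_then_agg$values[, colnames(agg_then_split[[ds]]$values)],
      agg_then_split[[ds]]$values)
  }
})

test_that("Cq summaries are correct and sample-order invariant", {
  x <- rbind(g1 = c(18, 20, 22), g2 = c(20, 20, 20))
  colnames(x) <- paste0("s", 1:3)
  s <- summarize_cq(cq_matrix(x))
  expect_equal(s$mean, c(20, 20))
  expect_equal(s$range, c(4, 0))
  # range 0 iff constant
  expect_true(s$range[2] == 0)
  expect_true(s$range[1] > 0)
  perm <- summarize_cq(cq_matrix(x[, c(3, 1, 2)]))
  expect_equal(perm[, -1], s[, -1])
})
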