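test_that("normalization factors follow efficiency-weighted relative quantities", {
  # single reference with constant Cq: NF = 1 everywhere
  x <- rbind(ref = rep(20, 4), tgt = c(20, 19, 18, 20))
  colnames(x) <- paste0("s", 1:4)
  m <- cq_matrix(x)
  assays <- assay_info(c("ref", "tgt"), c(1, 1))
  nf <- normalization_factor(m, "ref", assays)
  expect_equal(unname(nf), rep(1, 4))

  # one cycle below the gene mean at E = 1 doubles the quantity
  y <- rbind(ref = c(19, 21), tgt = c(20, 20))
  colnames(y) <- c("s1", "s2")
  nf2 <- normalization_factor(cq_matrix(y), "ref",
                              assay_info(c("ref", "tgt"), c(1, 1)))
  expect_equal(unname(nf2["s1"]), 2)
  expect_equal(unname(nf2["s2"]), 0.5)

  # two references: geometric mean of their RQs (RQ 2 and 8 -> NF 4)
  z <- rbind(r1 = c(19, 21), r2 = c(17, 23), tgt = c(20, 20))
  colnames(z) <- c("s1", "s2")
  nf3 <- normalization_factor(cq_matrix(z), c("r1", "r2"),
                              assay_info(c("r1", "r2", "tgt"), c(1, 1, 1)))
  expect_equal(unname(nf3["s1"]), sqrt(2 * 8))

  # single-reference NF equals that reference's RQ
  nf_single <- normalization_factor(cq_matrix(z), "r2",
                                    assay_info(c("r1", "r2", "tgt"),
                                               c(1, 1, 1)))
  expect_equal(unname(nf_single["s1"]), 8)

  expect_error(normalization_factor(m, "missing", assays), "absent")
})

test_that("relative expression reduces to 2^(-ddCq) at unit efficiency", {
  set.seed(21)
  samples <- paste0("s", 1:12)
  ref1 <- 20 + rnorm(12, 0, 0.5)
  ref2 <- 22 + rnorm(12, 0, 0.5)
  tgt <- 25 + rnorm(12, 0, 1)
  names(tgt) <- samples
  x <- rbind(r1 = ref1, r2 = ref2, t = tgt)
  colnames(x) <- samples
  m <- cq_matrix(x)
  assays <- assay_info(c("r1", "r2", "t"), c(1, 1, 1))
  cal <- samples[1:4]
  nf <- normalization_factor(m, c("r1", "r2"), assays)
  re <- relative_expression(tgt, nf, 1, cal)
  oracle <- oracle_ddcq(tgt, list(ref1, ref2), seq_len(4))
  expect_equal(re$fold, unname(oracle), tolerance = 1e-12)
  # calibrator condition mean is exactly 1
  expect_equal(mean(re$fold[re$sample_id %in% cal]), 1.0)
})

test_that("a target two cycles below the calibrator shows fold 4 at E = 1", {
  samples <- c("cal", "hot")
  tgt <- c(cal = 22, hot = 20)
  nf <- setNames(c(1, 1), samples)
  re <- relative_expression(tgt, nf, 1, "cal")
  expect_equal(re$fold[re$sample_id == "hot"], 4.0)
  # all-identical samples: every fold 1
  re2 <- relative_expression(setNames(c(20, 20), samples),
                             nf, 1, "cal")
  expect_equal(re2$fold, c(1, 1))
  expect_error(relative_expression(tgt, nf, 1, character(0)), "calibrator")
})

test_that("shared loading shifts cancel only when applied to target too", {
  set.seed(8)
  samples <- paste0("s", 1:8)
  base_ref <- 20 + rnorm(8, 0, 0.2)
  base_tgt <- 24 + rnorm(8, 0, 0.3)
  shift <- rnorm(8, 0, 1)
  mk_re <- function(ref, tgt) {
    x <- rbind(ref = ref, t = tgt)
    colnames(x) <- samples
    names(tgt) <- samples
    nf <- normalization_factor(cq_matrix(x), "ref",
                               assay_info(c("ref", "t"), c(1, 1)))
    relative_expression(tgt, nf, 1, samples[1:2])
  }
  re0 <- mk_re(base_ref, base_tgt)
  re_both <- mk_re(base_ref + shift, base_tgt + shift)
  re_ref_only <- mk_re(base_ref + shift, base_tgt)
  expect_equal(re_both$fold, re0$fold, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(re_ref_only$fold, re0$fold)))
})

test_that("condition summaries give mean, SD, SE and normal 95% CI", {
  re <- structure(
    data.frame(sample_id = c("a1", "a2", "b1", "b2", "b3", "b4"),
               fold = c(2, 4, 1, 1, 1, 1), stringsAsFactors = FALSE),
    class = c("relative_expression", "data.frame"), calibrator = "b1")
  conds <- setNames(c("A", "A", "B", "B", "B", "B"), re$sample_id)
  s <- condition_summary(re, conds)
  a <- s[s$condition == "A", ]
  expect_equal(a$mean, 3)
  expect_equal(a$sd, sqrt(2), tolerance = 1e-9)
  expect_equal(a$se, 1.0, tolerance = 1e-9)
  expect_equal(a$ci_low, 3 - qnorm(0.975), tolerance = 1e-9)
  b <- s[s$condition == "B", ]
  expect_equal(b$mean, 1)
  expect_equal(b$sd, 0)

  # reorder invariance
  re2 <- re[c(3, 1, 5, 2, 6, 4), ]
  class(re2) <- class(re)
  s2 <- condition_summary(re2, conds)
  expect_equal(s2[order(s2$condition), -1], s[order(s$condition), -1],
               ignore_attr = TRUE)

  # singleton condition flagged with NA SD
  conds3 <- setNames(c("A", "C", "B", "B", "B", "B"), re$sample_id)
  s3 <- condition_summary(re, conds3)
  expect_true(s3$flagged[s3$condition == "C"])
  expect_true(is.na(s3$sd[s3$condition == "C"]))
})

test_that("normalizer discordance flags direction flips", {
  mk <- function(folds, ids) {
    structure(data.frame(sample_id = ids, fold = folds,
                         stringsAsFactors = FALSE),
              class = c("relative_expression", "data.frame"),
              calibrator = ids[1])
  }
  ids <- paste0("s", 1:4)
  conds <- setNames(c("c1", "c1", "c2", "c2"), ids)
  a <- mk(c(1.4, 1.6, 1.4, 1.6), ids)  # both conditions up
  b <- mk(c(1.4, 1.6, 0.5, 0.7), ids)  # c2 down under the other normalizer
  d <- normalizer_discordance(a, b, conds)
  expect_false(d$direction_flip[d$condition == "c1"])
  expect_true(d$direction_flip[d$condition == "c2"])
  expect_equal(d$ratio[d$condition == "c2"], 1.5 / 0.6, tolerance = 1e-9)

  # identical inputs: ratios 1, no flips
  d0 <- normalizer_discordance(a, a, conds)
  expect_equal(d0$ratio, c(1, 1))
  expect_false(any(d0$direction_flip))
})
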