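test_that("geNorm reproduces hand-derived M and pairwise variation", {
  m <- cq_matrix(toy_matrix())
  g <- genorm(m)
  expect_equal(unname(g$stability[c("A", "B", "C")]),
               c(0.6455, 0.6455, 1.2910), tolerance = 1e-4)
  expect_identical(g$exclusion_order, "C")
  expect_setequal(g$final_pair, c("A", "B"))
  expect_equal(unname(g$pairwise_variation["V2/3"]), 0.4303,
               tolerance = 1e-4)
  # the final pair share the SD of their log-ratio as exclusion-round M
  expect_equal(unname(g$m_at_exclusion["A"]),
               sd(toy_matrix()["B", ] - toy_matrix()["A", ]))
  expect_equal(g$m_at_exclusion[["A"]], g$m_at_exclusion[["B"]])
})

test_that("genes at a constant offset have zero geNorm M and DeltaCt SD", {
  x <- rbind(A = c(20, 21, 22), B = c(25, 26, 27), C = c(18, 23, 20))
  colnames(x) <- paste0("s", 1:3)
  g <- genorm(cq_matrix(x))
  # A and B track each other exactly: V_AB = 0
  expect_equal(unname(g$m_at_exclusion[["A"]]), 0)
  d <- delta_ct(cq_matrix(x))
  expect_equal(unname(d$pairwise_sd["A", "B"]), 0)
})

test_that("delta-Ct reproduces the hand-derived toy and its invariances", {
  m <- cq_matrix(toy_matrix())
  d <- delta_ct(m)
  expect_equal(unname(d$stability[c("A", "B", "C")]),
               c(0.6455, 0.6455, 1.2910), tolerance = 1e-4)
  # adding a per-sample constant to every gene cancels in the differences
  x <- toy_matrix()
  shifted <- sweep(x, 2, c(1.5, -2, 0.7, 3))
  d2 <- delta_ct(cq_matrix(shifted))
  expect_equal(d2$stability, d$stability)
  g2 <- genorm(cq_matrix(shifted))
  expect_equal(g2$stability, genorm(m)$stability)
})

test_that("BestKeeper descriptive statistics match hand computation", {
  x <- rbind(g1 = c(20, 21, 22, 23), g2 = c(24, 24, 24, 24) + c(0, 1, 0, 1))
  colnames(x) <- paste0("s", 1:4)
  bk <- bestkeeper(cq_matrix(x))
  expect_equal(bk$stats$ar_mean[1], 21.5)
  expect_equal(bk$stats$sd[1], 1.0)              # MAD convention
  expect_equal(bk$stats$cv[1], 100 * 1.0 / 21.5)
  bk_sd <- bestkeeper(cq_matrix(x), sd_type = "sd")
  expect_equal(bk_sd$stats$sd[1], sd(c(20, 21, 22, 23)))
  expect_equal(bk_sd$stats$sd[1], 1.2910, tolerance = 1e-4)

  # constant gene: zero SD and CV, undefined correlation reported as NA
  y <- rbind(g1 = c(20, 20, 20), g2 = c(19, 21, 23))
  colnames(y) <- paste0("s", 1:3)
  bk2 <- bestkeeper(cq_matrix(y))
  expect_equal(bk2$stats$sd[1], 0)
  expect_equal(bk2$stats$cv[1], 0)
  expect_true(is.na(bk2$stats$r[1]))

  # identical genes: all correlations 1, all SD equal
  z <- rbind(g1 = c(19, 21, 23), g2 = c(19, 21, 23))
  colnames(z) <- paste0("s", 1:3)
  bk3 <- bestkeeper(cq_matrix(z))
  expect_equal(bk3$stats$r, c(1, 1))
  expect_equal(bk3$stats$sd[1], bk3$stats$sd[2])
})

test_that("NormFinder flags the group-shifted gene as least stable", {
  set.seed(42)
  samples <- paste0("s", 1:8)
  groups <- setNames(rep(c("a", "b"), each = 4), samples)
  x <- matrix(20 + rnorm(4 * 8, 0, 0.05), 4, 8,
              dimnames = list(paste0("g", 1:4), samples))
  x["g4", groups == "b"] <- x["g4", groups == "b"] + 1
  nf <- normfinder(cq_matrix(x), groups)
  expect_identical(names(which.max(abs(nf$intergroup_d[, "a"]))), "g4")
  expect_identical(names(which.max(nf$stability)), "g4")

  # permuting samples within groups leaves rho unchanged
  perm <- c(4, 2, 3, 1, 8, 6, 7, 5)
  nf2 <- normfinder(cq_matrix(x[, perm]), groups)
  expect_equal(nf2$stability, nf$stability)
})

test_that("a gene perfectly tracking the global average has minimal rho", {
  # g1..g3 constant; any sample loading is shared, so all centered values 0
  x <- rbind(g1 = c(20, 21, 20, 22), g2 = c(22, 23, 22, 24),
             g3 = c(25, 26, 25, 27))
  colnames(x) <- paste0("s", 1:4)
  groups <- setNames(rep(c("a", "b"), each = 2), colnames(x))
  nf <- normfinder(cq_matrix(x), groups)
  expect_equal(unname(nf$stability), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(nf$intragroup_var), matrix(0, 3, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("all four methods are invariant under sample reordering", {
  m <- random_cq(5, 8, seed = 3)
  perm <- sample(seq_len(8))
  mp <- cq_matrix(m$values[, perm])
  groups <- setNames(rep(c("a", "b"), each = 4), colnames(m$values))
  expect_equal(genorm(mp)$stability, genorm(m)$stability)
  expect_equal(delta_ct(mp)$stability, delta_ct(m)$stability)
  expect_equal(bestkeeper(mp)$stability, bestkeeper(m)$stability)
  expect_equal(normfinder(mp, groups)$stability,
               normfinder(m, groups)$stability)
})

test_that("each method matches its independent literal transcription", {
  for (seed in 1:100) {
    m <- random_cq(4, 6, seed = seed)
    x <- m$values
    groups <- setNames(rep(c("a", "b"), each = 3), colnames(x))
    expect_equal(genorm(m)$stability, oracle_genorm_m(x), tolerance = 1e-9)
    expect_equal(delta_ct(m)$stability, oracle_delta_ct(x),
                 tolerance = 1e-9)
    bk <- bestkeeper(m)
    ob <- oracle_bestkeeper(x)
    expect_equal(bk$stability, ob$sd, tolerance = 1e-9)
    expect_equal(bk$stats$r, ob$r, tolerance = 1e-9)
    expect_equal(unname(bk$index), ob$index, tolerance = 1e-9)
    expect_equal(normfinder(m, groups)$stability,
                 oracle_normfinder(x, groups), tolerance = 1e-9)
    expect_equal(normfinder(m)$stability,
                 oracle_normfinder(x, setNames(rep("one", 6), colnames(x))),
                 tolerance = 1e-9)
  }
})

test_that("delta-Ct and geNorm agree on the worst gene when one gene is noisy", {
  set.seed(9)
  for (rep in 1:5) {
    samples <- paste0("s", 1:10)
    x <- rbind(
      g1 = 20 + rnorm(10, 0, 0.02),
      g2 = 22 + rnorm(10, 0, 0.02),
      g3 = 24 + rnorm(10, 0, 0.02),
      noisy = 23 + rnorm(10, 0, 1.5))
    colnames(x) <- samples
    m <- cq_matrix(x)
    expect_identical(names(which.max(genorm(m)$stability)), "noisy")
    expect_identical(names(which.max(delta_ct(m)$stability)), "noisy")
  }
})

test_that("geNorm breaks exclusion ties deterministically and messages", {
  # two identical unstable genes tie for the highest M
  x <- rbind(a = c(20, 21, 22, 23), b = c(21, 22, 23, 24),
             z1 = c(20, 24, 19, 26), z2 = c(21, 25, 20, 27))
  colnames(x) <- paste0("s", 1:4)
  expect_message(g <- genorm(cq_matrix(x)), "tie")
  expect_identical(g$exclusion_order[1], "z2")
})

test_that("stability preconditions are enforced", {
  x2 <- rbind(a = c(20, 21), b = c(22, 23))
  colnames(x2) <- c("s1", "s2")
  two <- cq_matrix(x2)
  expect_error(genorm(two), "3 genes")
  expect_error(normfinder(two), "3 genes")
  groups <- setNames(c("a", "a", "b"), paste0("s", 1:3))
  y <- matrix(21 + (1:9) / 10, 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_error(normfinder(cq_matrix(y), groups), "at least 2 samples")
})
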