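# Independent literal-formula transcriptions of the stability statistics,
# written as plain loops with a hand-rolled SD, used to cross-check the
# package implementations on random instances.

sd_oracle <- function(v) {
  m <- sum(v) / length(v)
  sqrt(sum((v - m)^2) / (length(v) - 1))
}

# geNorm M: mean over partners of the SD of the pairwise log2 ratio
# (on the Cq scale the log2 ratio of genes j and k is Cq_k - Cq_j)
oracle_genorm_m <- function(x) {
  g <- nrow(x)
  out <- numeric(g)
  names(out) <- rownames(x)
  for (j in seq_len(g)) {
    acc <- 0
    for (k in seq_len(g)) {
      if (k == j) next
      a_jk <- x[k, ] - x[j, ]
      acc <- acc + sd_oracle(a_jk)
    }
    out[j] <- acc / (g - 1)
  }
  out
}

# delta-Ct: mean over partners of the SD of the per-sample Cq difference
oracle_delta_ct <- function(x) {
  g <- nrow(x)
  out <- numeric(g)
  names(out) <- rownames(x)
  for (i in seq_len(g)) {
    sds <- c()
    for (j in seq_len(g)) {
      if (j == i) next
      sds <- c(sds, sd_oracle(x[i, ] - x[j, ]))
    }
    out[i] <- mean(sds)
  }
  out
}

# BestKeeper: descriptive stats, geometric-mean index, Pearson r vs index
oracle_bestkeeper <- function(x, sd_type = "mad") {
  g <- nrow(x)
  n <- ncol(x)
  index <- numeric(n)
  for (s in seq_len(n)) index[s] <- prod(x[, s])^(1 / g)
  out <- list(sd = numeric(g), cv = numeric(g), r = numeric(g),
              ar_mean = numeric(g), geo_mean = numeric(g), index = index)
  for (i in seq_len(g)) {
    v <- x[i, ]
    am <- sum(v) / n
    out$ar_mean[i] <- am
    out$geo_mean[i] <- prod(v)^(1 / n)
    out$sd[i] <- if (sd_type == "mad") sum(abs(v - am)) / n else sd_oracle(v)
    out$cv[i] <- 100 * out$sd[i] / am
    out$r[i] <- if (sd_oracle(v) == 0) NA_real_ else
      stats::cor(v, index, method = "pearson")
  }
  names(out$sd) <- rownames(x)
  out
}

# NormFinder: literal transcription of the documented model-based
# estimator (sample centering on -Cq, bias-corrected intragroup variance,
# empirical-Bayes shrinkage of intergroup differences)
oracle_normfinder <- function(x, groups) {
  k <- nrow(x)
  genes <- rownames(x)
  glev <- unique(groups[colnames(x)])
  z <- matrix(NA_real_, k, ncol(x), dimnames = dimnames(x))
  for (s in seq_len(ncol(x))) {
    ga <- mean(-x[, s])
    for (i in seq_len(k)) z[i, s] <- -x[i, s] - ga
  }
  zbar <- sig2 <- matrix(NA_real_, k, length(glev),
                         dimnames = list(genes, glev))
  ng <- numeric(length(glev))
  for (gi in seq_along(glev)) {
    cols <- which(groups[colnames(x)] == glev[gi])
    ng[gi] <- length(cols)
    s2 <- numeric(k)
    for (i in seq_len(k)) {
      zi <- z[i, cols]
      zbar[i, gi] <- mean(zi)
      s2[i] <- sd_oracle(zi)^2
    }
    for (i in seq_len(k)) {
      sig2[i, gi] <- max(0, (s2[i] - mean(s2) / (k - 1)) * k / (k - 2))
    }
  }
  if (length(glev) == 1) return(sqrt(sig2[, 1]))
  dhat <- zbar
  for (i in seq_len(k)) dhat[i, ] <- zbar[i, ] - mean(zbar[i, ])
  sampvar <- sig2
  for (gi in seq_along(glev)) sampvar[, gi] <- sig2[, gi] / ng[gi]
  tau2 <- max(0, mean(dhat^2) - mean(sampvar))
  rho_ig <- matrix(NA_real_, k, length(glev))
  for (i in seq_len(k)) {
    for (gi in seq_along(glev)) {
      w <- if (tau2 + sampvar[i, gi] > 0) tau2 / (tau2 + sampvar[i, gi])
           else 0
      dtilde <- dhat[i, gi] * w
      rho_ig[i, gi] <- abs(dtilde) + sqrt(sampvar[i, gi])
    }
  }
  out <- rowMeans(rho_ig)
  names(out) <- genes
  out
}

# direct 2^(-ddCq) relative quantification (used as the E = 1 oracle)
oracle_ddcq <- function(target_cq, ref_cq_list, calibrator) {
  n <- length(target_cq)
  ref_mean <- rep(0, n)
  for (r in ref_cq_list) ref_mean <- ref_mean + r / length(ref_cq_list)
  dcq <- target_cq - ref_mean
  fold <- 2^(-dcq)
  fold / mean(fold[calibrator])
}
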