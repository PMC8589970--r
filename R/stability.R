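#' @keywords internal
stability_input <- function(m, min_genes = 2, min_samples = 2) {
  stopifnot(inherits(m, "cq_matrix"))
  if (is.null(m$values)) stop("aggregate technical replicates first",
                              call. = FALSE)
  x <- m$values
  if (anyNA(x)) stop("stability analysis requires a complete Cq matrix",
                     call. = FALSE)
  if (nrow(x) < min_genes) {
    stop("need at least ", min_genes, " genes", call. = FALSE)
  }
  if (ncol(x) < min_samples) {
    stop("need at least ", min_samples, " samples", call. = FALSE)
  }
  x
}

# M values for one gene set: M_j = mean over k != j of
# sd over samples of the pairwise log2-ratio A_jk = Cq_k - Cq_j
# (Cq is -log2 quantity, so Cq_k - Cq_j is the log2 expression ratio j/k).
genorm_m <- function(x) {
  g <- nrow(x)
  v <- matrix(0, g, g, dimnames = list(rownames(x), rownames(x)))
  for (j in seq_len(g - 1)) {
    for (k in (j + 1):g) {
      s <- stats::sd(x[k, ] - x[j, ])
      v[j, k] <- s
      v[k, j] <- s
    }
  }
  rowSums(v) / (g - 1)
}

#' geNorm expression-stability analysis
#'
#' Computes each gene's average expression-stability value M -- the mean,
#' over all other genes, of the standard deviation across samples of the
#' pairwise log2 expression ratio -- then performs the stepwise exclusion of
#' the least stable gene (highest M; ties broken by excluding the
#' lexicographically last gene, logged via a message) until two genes
#' remain. Also computes the pairwise variation V_n/n+1 between sequential
#' normalization factors NF_n (geometric mean of the n top-ranked genes'
#' relative quantities), used to decide how many reference genes are needed.
#'
#' The per-gene `$stability` values are the full-set M values (what is
#' typically tabulated); the stepwise trace in `$m_at_exclusion` records
#' each gene's M in the round it was excluded, with the final pair sharing
#' the standard deviation of their log-ratio.
#'
#' @param m An aggregated, complete [cq_matrix] with >= 3 genes and
#'   >= 2 samples.
#' @return Object of class `genorm_result`: list with `stability` (named,
#'   full-set M), `m_at_exclusion`, `exclusion_order` (least stable first),
#'   `final_pair`, `ranking` (most stable first, from the stepwise
#'   procedure), and `pairwise_variation` (named V_2/3 ... V_(G-1)/G).
#' @export
genorm <- function(m) {
  x <- stability_input(m, min_genes = 3, min_samples = 2)
  full_m <- genorm_m(x)
  cur <- x
  excl <- character(0)
  m_at_excl <- numeric(0)
  while (nrow(cur) > 2) {
    mm <- genorm_m(cur)
    worst <- max(mm)
    cand <- names(mm)[mm == worst]
    if (length(cand) > 1) {
      message("geNorm tie at M = ", format(worst),
              " between ", paste(cand, collapse = ", "),
              "; excluding ", sort(cand)[length(cand)])
    }
    drop <- sort(cand)[length(cand)]
    excl <- c(excl, drop)
    m_at_excl[drop] <- mm[drop]
    cur <- cur[setdiff(rownames(cur), drop), , drop = FALSE]
  }
  final_pair <- rownames(cur)
  m_final <- stats::sd(cur[2, ] - cur[1, ])
  m_at_excl[final_pair] <- m_final
  # most stable first: the final pair (ordered by full-set M, then name),
  # then the excluded genes in reverse order of exclusion
  pair_sorted <- final_pair[order(full_m[final_pair], final_pair)]
  ranking <- c(pair_sorted, rev(excl))
  v <- genorm_pairwise_variation(x, ranking)
  structure(list(
    stability = full_m,
    m_at_exclusion = m_at_excl[names(full_m)],
    exclusion_order = excl,
    final_pair = final_pair,
    ranking = ranking,
    pairwise_variation = v
  ), class = "genorm_result")
}

# V_n/n+1 = sd over samples of log2(NF_n / NF_{n+1}); on the -Cq log2 scale
# the per-sample log2 NF_n is the mean of -Cq over the n top-ranked genes.
genorm_pairwise_variation <- function(x, ranking) {
  g <- length(ranking)
  if (g < 3) return(numeric(0))
  v <- numeric(g - 2)
  nms <- character(g - 2)
  for (n in 2:(g - 1)) {
    nf_n <- colMeans(-x[ranking[1:n], , drop = FALSE])
    nf_n1 <- colMeans(-x[ranking[1:(n + 1)], , drop = FALSE])
    v[n - 1] <- stats::sd(nf_n - nf_n1)
    nms[n - 1] <- sprintf("V%d/%d", n, n + 1)
  }
  names(v) <- nms
  v
}

#' BestKeeper descriptive-statistics analysis
#'
#' Per-gene descriptive statistics of the Cq values plus the correlation of
#' each gene with the BestKeeper index (the per-sample geometric mean of Cq
#' across all candidate genes). The gene with the lowest SD is the most
#' stable. Following the original tool's convention, "SD" defaults to the
#' mean absolute deviation from the arithmetic mean; the sample standard
#' deviation (n-1) is available via `sd_type = "sd"`.
#'
#' @param m An aggregated, complete [cq_matrix] with >= 2 genes and
#'   >= 3 samples.
#' @param sd_type `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @return Object of class `bestkeeper_result`: list with `stats` (data
#'   frame: gene, n, geo_mean, ar_mean, min, max, sd, cv, r), `index`
#'   (per-sample geometric mean of Cq), `stability` (named SD vector), and
#'   `sd_type`. For a zero-variance gene the correlation is undefined and
#'   reported as `NA` (its SD of 0 is retained).
#' @export
bestkeeper <- function(m, sd_type = c("mad", "sd")) {
  sd_type <- match.arg(sd_type)
  x <- stability_input(m, min_genes = 2, min_samples = 3)
  ar_mean <- rowMeans(x)
  sd_val <- switch(sd_type,
    mad = rowMeans(abs(x - ar_mean)),
    sd  = apply(x, 1, stats::sd)
  )
  index <- exp(colMeans(log(x)))
  r <- vapply(seq_len(nrow(x)), function(i) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(index) == 0) NA_real_
    else stats::cor(x[i, ], index)
  }, numeric(1))
  stats_df <- data.frame(
    gene = rownames(x),
    n = ncol(x),
    geo_mean = exp(rowMeans(log(x))),
    ar_mean = ar_mean,
    min = apply(x, 1, min),
    max = apply(x, 1, max),
    sd = sd_val,
    cv = 100 * sd_val / ar_mean,
    r = r,
    stringsAsFactors = FALSE, row.names = NULL
  )
  stability <- sd_val
  names(stability) <- rownames(x)
  structure(list(stats = stats_df, index = index, stability = stability,
                 sd_type = sd_type),
            class = "bestkeeper_result")
}

#' NormFinder model-based stability analysis
#'
#' Model-based decomposition of expression variation into intragroup and
#' intergroup components, computed on the log2 expression scale (-Cq) after
#' centering each sample by its across-gene mean (the "global average
#' expression"). Per gene and group, the intragroup variance is estimated
#' with a bias correction that subtracts the shared variance contributed by
#' the across-gene centering; the intergroup difference d of each gene is
#' shrunk toward zero in proportion to its sampling variance (empirical
#' Bayes). The stability value rho of a gene combines the magnitude of its
#' shrunken intergroup difference with its intragroup standard error; lower
#' rho means more stable. With a single group, rho reduces to the
#' intragroup standard deviation.
#'
#' Negative intragroup variance estimates are floored at zero (reported in
#' `$floored`).
#'
#' @param m An aggregated, complete [cq_matrix] with >= 3 genes.
#' @param groups Named character vector mapping each sample to its group
#'   label, or `NULL` for the single-group variant. With >= 2 groups every
#'   group needs >= 2 samples.
#' @return Object of class `normfinder_result`: list with `stability`
#'   (named rho), `intergroup_d` (gene x group matrix of shrunken d, or
#'   `NULL`), `intragroup_var` (gene x group matrix), `tau2` (between-gene
#'   variance of the true intergroup differences), `groups`, `floored`.
#' @export
normfinder <- function(m, groups = NULL) {
  x <- stability_input(m, min_genes = 3, min_samples = 2)
  k <- nrow(x)
  genes <- rownames(x)
  # log2 expression, sample-centered by the global average expression
  z <- -x
  z <- sweep(z, 2, colMeans(z))
  if (is.null(groups)) {
    grp <- rep("all", ncol(x))
    names(grp) <- colnames(x)
  } else {
    miss <- setdiff(colnames(x), names(groups))
    if (length(miss) > 0) {
      stop("no group label for sample(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    grp <- as.character(groups[colnames(x)])
    names(grp) <- colnames(x)
  }
  glev <- unique(grp)
  ng <- table(factor(grp, glev))
  if (length(glev) > 1 && any(ng < 2)) {
    stop("every group needs at least 2 samples (offending: ",
         paste(names(ng)[ng < 2], collapse = ", "), ")", call. = FALSE)
  }
  if (k < 3) stop("need at least 3 genes", call. = FALSE)
  floored <- character(0)
  zbar <- matrix(NA_real_, k, length(glev), dimnames = list(genes, glev))
  sig2 <- matrix(NA_real_, k, length(glev), dimnames = list(genes, glev))
  for (g in glev) {
    zg <- z[, grp == g, drop = FALSE]
    n <- ncol(zg)
    zbar[, g] <- rowMeans(zg)
    s2 <- if (n >= 2) apply(zg, 1, stats::var) else rep(0, k)
    # centering by the across-gene mean leaks 1/k of every gene's variance
    # into each z; remove the shared term and rescale (unbiased for k >= 3)
    est <- (s2 - mean(s2) / (k - 1)) * k / (k - 2)
    if (any(est < 0)) floored <- union(floored, genes[est < 0])
    sig2[, g] <- pmax(est, 0)
  }
  if (length(glev) == 1) {
    rho <- sqrt(sig2[, 1])
    res <- list(stability = rho, intergroup_d = NULL,
                intragroup_var = sig2, tau2 = NA_real_,
                groups = grp, floored = floored)
    return(structure(res, class = "normfinder_result"))
  }
  # intergroup difference of gene i in group g, centered over groups
  d_hat <- zbar - rowMeans(zbar)
  samp_var <- sweep(sig2, 2, as.numeric(ng), "/")  # var of d_hat, per cell
  tau2 <- max(0, mean(d_hat^2) - mean(samp_var))
  denom <- tau2 + samp_var
  shrink <- ifelse(denom > 0, tau2 / denom, 0)  # degenerate: no signal at all
  d_tilde <- d_hat * shrink
  rho_ig <- abs(d_tilde) + sqrt(samp_var)
  rho <- rowMeans(rho_ig)
  structure(list(stability = rho, intergroup_d = d_tilde,
                 intragroup_var = sig2, tau2 = tau2,
                 groups = grp, floored = floored),
            class = "normfinder_result")
}

#' Pairwise delta-Ct stability analysis
#'
#' For every pair of genes the per-sample Cq difference is formed and its
#' standard deviation across samples (n-1) computed; each gene's stability
#' value is the arithmetic mean of these SDs over all partner genes. A gene
#' that fluctuates independently of the others inflates every one of its
#' pairwise SDs and ranks last.
#'
#' @param m An aggregated, complete [cq_matrix] with >= 2 genes and
#'   >= 2 samples.
#' @return Object of class `delta_ct_result`: list with `stability` (named
#'   mean SD per gene) and `pairwise_sd` (symmetric gene x gene matrix,
#'   zero diagonal).
#' @export
delta_ct <- function(m) {
  x <- stability_input(m, min_genes = 2, min_samples = 2)
  g <- nrow(x)
  sd_mat <- matrix(0, g, g, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      s <- stats::sd(x[i, ] - x[j, ])
      sd_mat[i, j] <- s
      sd_mat[j, i] <- s
    }
  }
  stability <- rowSums(sd_mat) / (g - 1)
  structure(list(stability = stability, pairwise_sd = sd_mat),
            class = "delta_ct_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("<genorm_result>\n  ranking (most stable first): ",
      paste(x$ranking, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  ord <- order(x$stability)
  cat("<bestkeeper_result> (", x$sd_type, ")\n  ranking: ",
      paste(names(x$stability)[ord], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.normfinder_result <- function(x, ...) {
  ord <- order(x$stability)
  cat("<normfinder_result>\n  ranking: ",
      paste(names(x$stability)[ord], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.delta_ct_result <- function(x, ...) {
  ord <- order(x$stability)
  cat("<delta_ct_result>\n  ranking: ",
      paste(names(x$stability)[ord], collapse = ", "), "\n", sep = "")
  invisible(x)
}
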