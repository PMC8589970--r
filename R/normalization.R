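#' Multi-reference normalization factor
#'
#' Per sample, each reference gene's relative quantity is computed
#' Pfaffl-style with its own amplification efficiency,
#' RQ = (1 + E)^(mean Cq - Cq), where the gene's mean Cq over all samples
#' serves as the internal calibration point; the normalization factor is
#' the geometric mean of the references' RQ values. With a single reference
#' the NF equals that gene's RQ.
#'
#' @param m An aggregated [cq_matrix] containing the reference genes.
#' @param refs Character vector of reference gene symbols (>= 1).
#' @param assays An [assay_info] table covering `refs`.
#' @return Named numeric vector of per-sample normalization factors.
#' @export
normalization_factor <- function(m, refs, assays) {
  stopifnot(inherits(m, "cq_matrix"), inherits(assays, "assay_info"))
  if (is.null(m$values)) stop("aggregate technical replicates first",
                              call. = FALSE)
  if (length(refs) < 1) stop("need at least one reference gene", call. = FALSE)
  miss <- setdiff(refs, rownames(m$values))
  if (length(miss) > 0) {
    stop("reference gene(s) absent from the Cq matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  miss_a <- setdiff(refs, assays$gene)
  if (length(miss_a) > 0) {
    stop("no assay metadata for reference gene(s): ",
         paste(miss_a, collapse = ", "), call. = FALSE)
  }
  log_rq <- sapply(refs, function(g) {
    e <- assays$efficiency[match(g, assays$gene)]
    cq <- m$values[g, ]
    (mean(cq) - cq) * log(1 + e)
  })
  # samples x refs matrix of log RQ; geometric mean across references
  if (is.null(dim(log_rq))) log_rq <- matrix(log_rq, ncol = length(refs))
  nf <- exp(rowMeans(log_rq))
  names(nf) <- colnames(m$values)
  nf
}

#' Relative expression of a target gene
#'
#' Efficiency-weighted relative quantification of a target gene against a
#' per-sample normalization factor: expression =
#' (1 + E_target)^(mean Cq - Cq) / NF, rescaled so that the mean of the
#' calibrator samples is exactly 1.0 (the condition mean, not each
#' replicate, is set to 1, following the usual figure convention). With all
#' efficiencies equal to 1 this reduces exactly to the 2^(-ddCq) method.
#'
#' @param target_cq Named numeric vector of the target gene's Cq per sample.
#' @param nf Named per-sample normalization factor (see
#'   [normalization_factor]); names must cover those of `target_cq`.
#' @param efficiency Target assay amplification efficiency (fraction).
#' @param calibrator Character vector of sample ids forming the calibrator
#'   condition (>= 1 sample, all present in `target_cq`).
#' @return Object of class `relative_expression`: data frame with columns
#'   `sample_id`, `fold`, and attribute `calibrator`.
#' @export
relative_expression <- function(target_cq, nf, efficiency, calibrator) {
  if (is.null(names(target_cq))) stop("target_cq must be named by sample",
                                      call. = FALSE)
  miss <- setdiff(names(target_cq), names(nf))
  if (length(miss) > 0) {
    stop("normalization factor missing for sample(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(calibrator) == 0 ||
      !all(calibrator %in% names(target_cq))) {
    stop("calibrator must select at least one sample present in target_cq",
         call. = FALSE)
  }
  if (!is.finite(efficiency) || efficiency <= 0) {
    stop("efficiency must be a positive fraction", call. = FALSE)
  }
  rq <- (1 + efficiency)^(mean(target_cq) - target_cq)
  expr <- rq / nf[names(target_cq)]
  fold <- expr / mean(expr[calibrator])
  structure(
    data.frame(sample_id = names(target_cq), fold = unname(fold),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("relative_expression", "data.frame"),
    calibrator = calibrator
  )
}

#' Per-condition summary of relative expression
#'
#' Descriptive statistics of fold changes per experimental condition: mean,
#' sample SD, standard error, and a 95% confidence interval
#' (normal approximation mean +/- 1.96 SE by default; a t-quantile variant
#' is available, relevant at the usual n = 4 biological replicates).
#' Conditions with fewer than 2 replicates get `NA` SD and are flagged.
#'
#' @param re A [relative_expression] result.
#' @param conditions Named character vector mapping sample ids to condition
#'   labels.
#' @param conf Confidence level (default 0.95).
#' @param ci `"normal"` (default) or `"t"`.
#' @return Data frame with columns `condition`, `n`, `mean`, `sd`, `se`,
#'   `ci_low`, `ci_high`, `flagged`.
#' @export
condition_summary <- function(re, conditions, conf = 0.95,
                              ci = c("normal", "t")) {
  ci <- match.arg(ci)
  stopifnot(inherits(re, "relative_expression"))
  miss <- setdiff(re$sample_id, names(conditions))
  if (length(miss) > 0) {
    stop("no condition label for sample(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cond <- as.character(conditions[re$sample_id])
  levs <- unique(cond)
  out <- lapply(levs, function(cl) {
    v <- re$fold[cond == cl]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    se <- if (n >= 2) s / sqrt(n) else NA_real_
    q <- if (ci == "normal") stats::qnorm(1 - (1 - conf) / 2)
         else stats::qt(1 - (1 - conf) / 2, df = n - 1)
    data.frame(condition = cl, n = n, mean = mean(v), sd = s, se = se,
               ci_low = mean(v) - q * se, ci_high = mean(v) + q * se,
               flagged = n < 2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Discordance between two normalizer choices
#'
#' Compares the relative expression of the same target computed with two
#' different reference-gene sets (e.g. the most stable vs the least stable
#' pair). Per condition it reports the ratio of condition means, each set's
#' SD, and a direction-flip flag: the biologically serious case where one
#' normalizer set calls the condition up-regulated (mean > 1) and the other
#' calls it down-regulated (mean < 1).
#'
#' @param a,b [relative_expression] results for the same target, samples
#'   and calibrator, computed with different normalizer sets.
#' @param conditions Named character vector mapping sample ids to condition
#'   labels.
#' @return Data frame with columns `condition`, `mean_a`, `mean_b`,
#'   `ratio`, `sd_a`, `sd_b`, `direction_flip`.
#' @export
normalizer_discordance <- function(a, b, conditions) {
  stopifnot(inherits(a, "relative_expression"),
            inherits(b, "relative_expression"))
  if (!identical(sort(a$sample_id), sort(b$sample_id))) {
    stop("the two expression sets cover different samples", call. = FALSE)
  }
  sa <- condition_summary(a, conditions)
  sb <- condition_summary(b, conditions)
  if (!identical(sort(sa$condition), sort(sb$condition))) {
    stop("mismatched conditions", call. = FALSE)
  }
  sb <- sb[match(sa$condition, sb$condition), ]
  data.frame(
    condition = sa$condition,
    mean_a = sa$mean,
    mean_b = sb$mean,
    ratio = sa$mean / sb$mean,
    sd_a = sa$sd,
    sd_b = sb$sd,
    direction_flip = (sa$mean > 1 & sb$mean < 1) |
                     (sa$mean < 1 & sb$mean > 1),
    stringsAsFactors = FALSE
  )
}
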