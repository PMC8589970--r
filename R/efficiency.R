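#' Construct per-assay primer metadata
#'
#' Holds the standard-curve metadata of each qPCR assay: amplification
#' efficiency E (fraction; 1.0 means perfect doubling per cycle),
#' standard-curve R-squared, amplicon length and annealing temperature.
#' Efficiencies outside [0.8, 1.2] trigger a warning; values outside
#' (0, 1.5] are rejected.
#'
#' @param gene Character vector of gene symbols.
#' @param efficiency Numeric vector of efficiencies as fractions
#'   (e.g. 0.882 for 88.2%).
#' @param r_squared Standard-curve R-squared values in (0, 1].
#' @param amplicon_length Optional amplicon lengths (bp).
#' @param annealing_temp Optional annealing temperatures (degrees C).
#' @return Data frame of class `assay_info`.
#' @export
assay_info <- function(gene, efficiency, r_squared = NA_real_,
                       amplicon_length = NA_integer_,
                       annealing_temp = NA_real_) {
  check_ids(gene, "gene")
  if (any(!is.finite(efficiency) | efficiency <= 0 | efficiency > 1.5)) {
    stop("efficiency must be a fraction in (0, 1.5]", call. = FALSE)
  }
  if (any(efficiency < 0.8 | efficiency > 1.2)) {
    warning("assay efficiency outside [0.8, 1.2] for: ",
            paste(gene[efficiency < 0.8 | efficiency > 1.2], collapse = ", "),
            call. = FALSE)
  }
  if (any(!is.na(r_squared) & (r_squared <= 0 | r_squared > 1))) {
    stop("r_squared must lie in (0, 1]", call. = FALSE)
  }
  structure(
    data.frame(gene = gene, efficiency = efficiency, r_squared = r_squared,
               amplicon_length = amplicon_length,
               annealing_temp = annealing_temp,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("assay_info", "data.frame")
  )
}

#' Read assay metadata from a delimited file
#'
#' Expects columns `gene`, `efficiency_percent`, and optionally `r_squared`,
#' `amplicon_length`, `annealing_temp` (comma for `.csv`, tab otherwise).
#' Percent efficiencies are converted to fractions on input.
#'
#' @param path Path to the file.
#' @return An [assay_info] data frame.
#' @export
read_assay_table <- function(path) {
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("gene", "efficiency_percent") %in% names(df))) {
    stop("assay table needs columns gene, efficiency_percent", call. = FALSE)
  }
  assay_info(
    gene = df$gene,
    efficiency = df$efficiency_percent / 100,
    r_squared = if ("r_squared" %in% names(df)) df$r_squared else NA_real_,
    amplicon_length = if ("amplicon_length" %in% names(df))
      df$amplicon_length else NA_integer_,
    annealing_temp = if ("annealing_temp" %in% names(df))
      df$annealing_temp else NA_real_
  )
}

#' Fit a dilution-series standard curve
#'
#' Ordinary least-squares fit of Cq against log10 relative template
#' concentration. The amplification efficiency follows from the slope as
#' E = 10^(-1/slope) - 1; a 10-fold series with perfect doubling has slope
#' -1/log10(2) = -3.3219 and E = 1.
#'
#' @param log10_conc Numeric vector of log10 relative concentrations
#'   (at least 3 distinct values).
#' @param cq Numeric vector of measured Cq, same length.
#' @return Object of class `standard_curve`: list with `slope`, `intercept`,
#'   `r_squared`, `efficiency`, and the input `points`.
#' @export
fit_standard_curve <- function(log10_conc, cq) {
  if (length(log10_conc) != length(cq)) {
    stop("log10_conc and cq must have equal length", call. = FALSE)
  }
  if (length(unique(log10_conc)) < 3) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10_conc)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("non-negative slope: invalid dilution series ",
         "(Cq must increase as template is diluted)", call. = FALSE)
  }
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((cq - mean(cq))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    efficiency = 10^(-1 / slope) - 1,
    points = data.frame(log10_conc = log10_conc, cq = cq)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope %.4f, intercept %.3f, E = %.1f%%, r^2 = %.4f\n",
    x$slope, x$intercept, 100 * x$efficiency, x$r_squared))
  invisible(x)
}

#' Efficiency-correct a Cq matrix
#'
#' Rescales each gene's raw Cq onto the ideal-doubling cycle scale:
#' Cq' = Cq x log2(1 + E). A cycle measured with per-cycle gain (1 + E)
#' corresponds to log2(1 + E) ideal cycles, so after correction 2^(-Cq')
#' tracks the true relative template quantity for every assay regardless of
#' its efficiency. The correction is the identity at E = 1.
#'
#' @param m A [cq_matrix] on the raw scale.
#' @param assays An [assay_info] table covering every gene in `m`.
#' @return A new [cq_matrix] with `scale = "efficiency_corrected"`; the
#'   input is not modified.
#' @export
correct_cq <- function(m, assays) {
  stopifnot(inherits(m, "cq_matrix"), inherits(assays, "assay_info"))
  if (m$scale != "raw") {
    stop("matrix is already on the efficiency-corrected scale", call. = FALSE)
  }
  genes <- if (!is.null(m$values)) rownames(m$values) else unique(m$technical$gene)
  miss <- setdiff(genes, assays$gene)
  if (length(miss) > 0) {
    stop("no assay metadata for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  eff <- assays$efficiency[match(genes, assays$gene)]
  names(eff) <- genes
  factor_g <- log2(1 + eff)
  vals <- NULL
  if (!is.null(m$values)) {
    vals <- m$values * factor_g[rownames(m$values)]
  }
  tech <- NULL
  if (!is.null(m$technical)) {
    tech <- m$technical
    tech$cq <- tech$cq * factor_g[tech$gene]
  }
  cq_matrix(values = vals, scale = "efficiency_corrected", technical = tech)
}

#' Assays with extreme amplification efficiency
#'
#' @param assays An [assay_info] table (non-empty).
#' @return List with elements `min` and `max`, each an [assay_info] subset
#'   holding every assay attaining the extreme (ties are all reported).
#' @export
efficiency_range <- function(assays) {
  stopifnot(inherits(assays, "assay_info"))
  if (nrow(assays) == 0) stop("empty assay table", call. = FALSE)
  list(
    min = assays[assays$efficiency == min(assays$efficiency), , drop = FALSE],
    max = assays[assays$efficiency == max(assays$efficiency), , drop = FALSE]
  )
}
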