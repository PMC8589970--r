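methods_on <- function(m, groups_for_normfinder, bestkeeper_sd) {
  list(
    geNorm = genorm(m),
    BestKeeper = bestkeeper(m, sd_type = bestkeeper_sd),
    NormFinder = normfinder(m, groups = groups_for_normfinder),
    DeltaCt = delta_ct(m)
  )
}

#' Run the full reference-gene stability analysis
#'
#' Orchestrates the complete workflow on one experiment: technical-replicate
#' aggregation (when a replicate layer is present), optional efficiency
#' correction, splitting into the three analysis datasets (all samples,
#' susceptible, resistant), the four stability methods, the geometric-mean
#' consensus, the pairwise-variation decision on how many reference genes
#' are needed, and -- when both scales are analysed -- the positional
#' comparison of raw versus efficiency-corrected rankings per method.
#'
#' NormFinder grouping defaults to the resistance class for the pooled
#' dataset and to treatment within each class-specific dataset (the design
#' factors; configurable via `normfinder_grouping`).
#'
#' @param cq A [cq_matrix] on the raw scale (aggregated or with technical
#'   replicates).
#' @param annotations Sample annotation data frame (see
#'   [validate_annotations]).
#' @param assays [assay_info] covering the candidate genes; required when
#'   `scale` includes the corrected analysis.
#' @param scale `"both"` (default), `"raw"`, or `"efficiency_corrected"`.
#' @param max_spread Technical-replicate QC threshold in cycles.
#' @param v_threshold Pairwise-variation cut-off (default 0.15).
#' @param bestkeeper_sd `"mad"` or `"sd"` (see [bestkeeper]).
#' @param normfinder_grouping `"auto"` (class for pooled, treatment within
#'   class), `"population_class"`, `"treatment"`, `"timepoint"`, or
#'   `"none"`.
#' @return Object of class `stability_analysis`: list with `results`
#'   (per scale, per dataset: the four method objects), `rankings` (per
#'   scale, per dataset: the four [rank_genes] rankings plus `Consensus`),
#'   `pairwise_variation` and `reference_count` (per scale, per dataset),
#'   `rank_changes` (per method incl. consensus, when both scales were
#'   analysed), `qc`, and `config` (echo of the choices).
#' @export
run_stability <- function(cq, annotations, assays = NULL,
                          scale = c("both", "raw", "efficiency_corrected"),
                          max_spread = 0.5, v_threshold = 0.15,
                          bestkeeper_sd = c("mad", "sd"),
                          normfinder_grouping = "auto") {
  scale <- match.arg(scale)
  bestkeeper_sd <- match.arg(bestkeeper_sd)
  ann <- validate_annotations(annotations)
  qc <- NULL
  if (!is.null(cq$technical)) {
    cq <- aggregate_technical_replicates(cq, max_spread = max_spread)
    qc <- attr(cq, "qc")
  }
  if (cq$scale != "raw") {
    stop("run_stability expects raw-scale input", call. = FALSE)
  }
  scales <- switch(scale,
                   both = c("raw", "efficiency_corrected"),
                   raw = "raw",
                   efficiency_corrected = "efficiency_corrected")
  if ("efficiency_corrected" %in% scales && is.null(assays)) {
    stop("efficiency-corrected analysis needs `assays`", call. = FALSE)
  }
  matrices <- list(raw = cq)
  if ("efficiency_corrected" %in% scales) {
    matrices$efficiency_corrected <- correct_cq(cq, assays)
  }
  results <- rankings <- pv <- refcount <- list()
  for (sc in scales) {
    splits <- split_datasets(matrices[[sc]], ann)
    for (ds in names(splits)) {
      m <- splits[[ds]]
      grouping <- normfinder_groups(normfinder_grouping, ds, ann,
                                    colnames(m$values))
      res <- methods_on(m, grouping, bestkeeper_sd)
      rk <- lapply(names(res), function(nm) {
        rank_genes(res[[nm]], method = nm, dataset = ds, scale = sc)
      })
      names(rk) <- names(res)
      rk$Consensus <- consensus_geomean(rk[c("geNorm", "BestKeeper",
                                             "NormFinder", "DeltaCt")],
                                        dataset = ds, scale = sc)
      results[[sc]][[ds]] <- res
      rankings[[sc]][[ds]] <- rk
      pv[[sc]][[ds]] <- res$geNorm$pairwise_variation
      refcount[[sc]][[ds]] <- optimal_reference_count(
        res$geNorm$pairwise_variation, threshold = v_threshold)
    }
  }
  rank_changes <- NULL
  if (length(scales) == 2) {
    datasets <- names(rankings$raw)
    rank_changes <- lapply(
      c("geNorm", "BestKeeper", "NormFinder", "DeltaCt", "Consensus"),
      function(meth) {
        a <- lapply(rankings$raw, `[[`, meth)
        b <- lapply(rankings$efficiency_corrected, `[[`, meth)
        names(a) <- names(b) <- datasets
        count_rank_changes(a, b, method = meth)
      })
    names(rank_changes) <- c("geNorm", "BestKeeper", "NormFinder",
                             "DeltaCt", "Consensus")
  }
  structure(list(
    results = results, rankings = rankings, pairwise_variation = pv,
    reference_count = refcount, rank_changes = rank_changes, qc = qc,
    config = list(scale = scale, max_spread = max_spread,
                  v_threshold = v_threshold, bestkeeper_sd = bestkeeper_sd,
                  normfinder_grouping = normfinder_grouping)
  ), class = "stability_analysis")
}

normfinder_groups <- function(choice, dataset, ann, samples) {
  pick <- function(col) {
    stats::setNames(as.character(ann[[col]][match(samples, ann$sample_id)]),
                    samples)
  }
  if (choice == "none") return(NULL)
  if (choice == "auto") {
    if (dataset == "all") return(pick("population_class"))
    return(pick("treatment"))
  }
  if (!choice %in% c("population_class", "treatment", "timepoint")) {
    stop("unknown normfinder grouping: ", choice, call. = FALSE)
  }
  g <- pick(choice)
  if (length(unique(g)) < 2) NULL else g
}

#' @export
print.stability_analysis <- function(x, ...) {
  cat("<stability_analysis>\n")
  for (sc in names(x$rankings)) {
    cons <- x$rankings[[sc]]$all$Consensus
    cat("  ", sc, " consensus (all samples): ",
        paste(utils::head(cons$gene, 3), collapse = ", "), ", ...\n",
        sep = "")
  }
  if (!is.null(x$rank_changes)) {
    for (rc in x$rank_changes) {
      cat(sprintf("  %s: %d/%d positions changed (%d%%)\n", rc$method,
                  rc$pooled, rc$denominator, rc$percentage))
    }
  }
  invisible(x)
}

#' Condition labels from annotations
#'
#' @param annotations Annotation data frame.
#' @return Named character vector, sample id -> condition label
#'   (`class.treatment.timepoint`).
#' @export
condition_labels <- function(annotations) {
  ann <- validate_annotations(annotations)
  stats::setNames(paste(ann$population_class, ann$treatment, ann$timepoint,
                        sep = "."),
                  ann$sample_id)
}

#' Validate target-gene normalization with chosen reference sets
#'
#' For each target gene and each normalizer set, computes the per-sample
#' normalization factor, the calibrator-scaled relative expression, and the
#' per-condition summary; with two or more sets it also reports the
#' pairwise discordance (ratios of condition means and direction flips)
#' against the first set.
#'
#' @param cq An aggregated [cq_matrix] containing targets and references.
#' @param annotations Sample annotation data frame.
#' @param assays [assay_info] covering targets and references.
#' @param targets Character vector of target gene symbols.
#' @param normalizer_sets Named list of character vectors of reference
#'   genes (e.g. `list(best = c("TBP", "GAPC"), worst = c("EF1A", "UBQ"))`).
#' @param calibrator Either a character vector of sample ids or a named
#'   list of annotation filters (e.g. `list(population_class =
#'   "susceptible", treatment = "untreated", timepoint = "1h")`).
#' @return Object of class `validation_analysis`: per target, per set:
#'   `expression` ([relative_expression]) and `summary`
#'   ([condition_summary] table); plus `discordance` per target (or `NULL`
#'   with a single set).
#' @export
run_validation <- function(cq, annotations, assays, targets,
                           normalizer_sets, calibrator) {
  stopifnot(inherits(cq, "cq_matrix"))
  if (!is.null(cq$technical)) {
    cq <- aggregate_technical_replicates(cq)
  }
  ann <- validate_annotations(annotations)
  for (nm in names(normalizer_sets)) {
    clash <- intersect(targets, normalizer_sets[[nm]])
    if (length(clash) > 0) {
      stop("target gene(s) listed among references in set '", nm, "': ",
           paste(clash, collapse = ", "), call. = FALSE)
    }
  }
  cal_samples <- resolve_calibrator(calibrator, ann)
  conds <- condition_labels(ann)
  out <- list()
  for (tg in targets) {
    if (!tg %in% rownames(cq$values)) {
      stop("target gene absent from the Cq matrix: ", tg, call. = FALSE)
    }
    e_t <- assays$efficiency[match(tg, assays$gene)]
    if (is.na(e_t)) stop("no assay metadata for target ", tg, call. = FALSE)
    per_set <- list()
    for (nm in names(normalizer_sets)) {
      nf <- normalization_factor(cq, normalizer_sets[[nm]], assays)
      re <- relative_expression(cq$values[tg, ], nf, e_t, cal_samples)
      per_set[[nm]] <- list(expression = re,
                            summary = condition_summary(re, conds))
    }
    disc <- NULL
    if (length(per_set) >= 2) {
      first <- names(per_set)[1]
      disc <- lapply(names(per_set)[-1], function(nm) {
        normalizer_discordance(per_set[[first]]$expression,
                               per_set[[nm]]$expression, conds)
      })
      names(disc) <- paste(first, "vs", names(per_set)[-1])
    }
    out[[tg]] <- list(sets = per_set, discordance = disc)
  }
  structure(list(targets = out, calibrator = cal_samples,
                 normalizer_sets = normalizer_sets),
            class = "validation_analysis")
}

resolve_calibrator <- function(calibrator, ann) {
  if (is.character(calibrator)) {
    miss <- setdiff(calibrator, ann$sample_id)
    if (length(miss) > 0) {
      stop("calibrator sample(s) not annotated: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    return(calibrator)
  }
  if (!is.list(calibrator)) {
    stop("calibrator must be sample ids or a list of annotation filters",
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(ann))
  for (col in names(calibrator)) {
    if (!col %in% names(ann)) {
      stop("unknown calibrator filter column: ", col, call. = FALSE)
    }
    keep <- keep & ann[[col]] %in% calibrator[[col]]
  }
  sel <- ann$sample_id[keep]
  if (length(sel) == 0) stop("calibrator selects no samples", call. = FALSE)
  sel
}

#' Write the analysis outputs as delimited text
#'
#' Writes one ranking table per method and dataset and scale, the
#' pairwise-variation series, the rank-change report (when present), the
#' replicate QC report (when present), and a small manifest listing every
#' file written.
#'
#' @param x A `stability_analysis`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
write_stability_tables <- function(x, dir) {
  stopifnot(inherits(x, "stability_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (sc in names(x$rankings)) {
    for (ds in names(x$rankings[[sc]])) {
      for (meth in names(x$rankings[[sc]][[ds]])) {
        f <- file.path(dir, sprintf("ranking_%s_%s_%s.tsv", meth, ds, sc))
        write_ranking(x$rankings[[sc]][[ds]][[meth]], f)
        written <- c(written, f)
      }
      v <- x$pairwise_variation[[sc]][[ds]]
      f <- file.path(dir, sprintf("pairwise_variation_%s_%s.tsv", ds, sc))
      utils::write.table(
        data.frame(pair = names(v), v = unname(v)), f, sep = "\t",
        row.names = FALSE, quote = FALSE)
      written <- c(written, f)
    }
  }
  if (!is.null(x$rank_changes)) {
    rows <- do.call(rbind, lapply(x$rank_changes, function(rc) {
      data.frame(method = rc$method, pooled = rc$pooled,
                 denominator = rc$denominator, percentage = rc$percentage)
    }))
    f <- file.path(dir, "rank_changes.tsv")
    utils::write.table(rows, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  if (!is.null(x$qc)) {
    f <- file.path(dir, "replicate_qc.tsv")
    utils::write.table(x$qc, f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }
  manifest <- file.path(dir, "MANIFEST.txt")
  writeLines(c("qpcrstab stability analysis outputs", basename(written)),
             manifest)
  invisible(c(written, manifest))
}
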