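#' Construct a Cq matrix
#'
#' A `cq_matrix` holds quantification-cycle (Cq) values for a set of genes
#' (rows) measured across samples (columns), together with the scale of the
#' values (`"raw"` or `"efficiency_corrected"`) and, optionally, the
#' per-reaction technical-replicate layer from which the aggregated matrix
#' is computed.
#'
#' Cq values must be finite and lie in (0, 45]; gene and sample identifiers
#' must be unique and non-empty. A `cq_matrix` may carry either an aggregated
#' `values` matrix, a technical-replicate layer, or both (after aggregation
#' the replicate layer is dropped).
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   complete dimnames. May be `NULL` when only a technical layer is supplied.
#' @param scale One of `"raw"` or `"efficiency_corrected"`.
#' @param technical Optional long-format data frame of per-reaction values
#'   with columns `gene`, `sample_id`, `technical_replicate`, `cq`.
#' @return An object of class `cq_matrix`.
#' @export
cq_matrix <- function(values = NULL, scale = c("raw", "efficiency_corrected"),
                      technical = NULL) {
  scale <- match.arg(scale)
  if (is.null(values) && is.null(technical)) {
    stop("a cq_matrix needs `values`, a `technical` layer, or both",
         call. = FALSE)
  }
  if (!is.null(values)) {
    if (!is.matrix(values) || !is.numeric(values)) {
      stop("`values` must be a numeric matrix (genes x samples)", call. = FALSE)
    }
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      stop("`values` must have gene rownames and sample colnames", call. = FALSE)
    }
    check_ids(rownames(values), "gene")
    check_ids(colnames(values), "sample")
    check_cq_range(values, "values")
  }
  if (!is.null(technical)) {
    technical <- as.data.frame(technical)
    req <- c("gene", "sample_id", "technical_replicate", "cq")
    miss <- setdiff(req, names(technical))
    if (length(miss) > 0) {
      stop("technical layer lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    check_cq_range(technical$cq, "technical cq")
  }
  structure(list(values = values, scale = scale, technical = technical),
            class = "cq_matrix")
}

check_ids <- function(x, what) {
  if (length(x) == 0 || anyNA(x) || any(!nzchar(x))) {
    stop(what, " identifiers must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(x)) {
    stop("duplicated ", what, " identifier(s): ",
         paste(unique(x[duplicated(x)]), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

check_cq_range <- function(x, what) {
  bad <- which(!is.finite(x) | x <= 0 | x > 45)
  if (length(bad) > 0) {
    stop("invalid Cq in ", what, " (must be finite, in (0, 45]) at index ",
         bad[1], call. = FALSE)
  }
  invisible(x)
}

#' @export
print.cq_matrix <- function(x, ...) {
  g <- if (!is.null(x$values)) nrow(x$values) else length(unique(x$technical$gene))
  s <- if (!is.null(x$values)) ncol(x$values) else length(unique(x$technical$sample_id))
  cat(sprintf("<cq_matrix> %d gene(s) x %d sample(s), scale = %s%s\n",
              g, s, x$scale,
              if (!is.null(x$technical)) ", with technical replicates" else ""))
  invisible(x)
}

#' @export
dim.cq_matrix <- function(x) {
  if (!is.null(x$values)) dim(x$values)
  else c(length(unique(x$technical$gene)), length(unique(x$technical$sample_id)))
}

annotation_enums <- list(
  population_class = c("susceptible", "resistant"),
  treatment        = c("treated", "untreated"),
  timepoint        = c("1h", "24h")
)

#' Validate sample annotations
#'
#' Sample annotations describe the experimental design: resistance class of
#' the source population, population identity, herbicide treatment, harvest
#' time point and biological replicate.
#'
#' @param ann Data frame with columns `sample_id`, `population_class`
#'   (`susceptible`/`resistant`), `population_id`, `treatment`
#'   (`treated`/`untreated`), `timepoint` (`1h`/`24h`),
#'   `biological_replicate` (positive integer).
#' @return The validated data frame (invisibly usable downstream).
#' @export
validate_annotations <- function(ann) {
  ann <- as.data.frame(ann)
  req <- c("sample_id", "population_class", "population_id", "treatment",
           "timepoint", "biological_replicate")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0) {
    stop("annotation column(s) missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_ids(as.character(ann$sample_id), "sample")
  for (col in names(annotation_enums)) {
    bad <- setdiff(unique(as.character(ann[[col]])), annotation_enums[[col]])
    if (length(bad) > 0) {
      stop("invalid ", col, " value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(annotation_enums[[col]], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  br <- ann$biological_replicate
  if (anyNA(br) || any(br != as.integer(br)) || any(br < 1)) {
    stop("biological_replicate must be a positive integer", call. = FALSE)
  }
  ann
}

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a delimited Cq table
#'
#' Reads Cq measurements plus sample annotations from a delimited text file
#' (comma for `.csv`, tab otherwise; header row required; UTF-8).
#'
#' In `long` layout each row is one reaction (or one aggregated well), with
#' required columns `sample_id`, `gene`, `cq` (case-insensitive) and an
#' optional `technical_replicate` column; annotation columns present in the
#' file are parsed into the annotation table. In `wide` layout each row is a
#' sample and each gene is a column; annotation columns are recognised by
#' name and all remaining columns are taken as genes.
#'
#' @param path Path to the file.
#' @param layout `"long"` (canonical interchange) or `"wide"`.
#' @return A list with elements `cq` (a [cq_matrix]; the technical layer is
#'   populated when a `technical_replicate` column is present) and
#'   `annotations` (data frame, or `NULL` when the file carries none).
#' @export
read_cq_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  df <- utils::read.table(path, sep = delim_for(path), header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  names(df) <- ifelse(tolower(names(df)) %in%
                        c("cq", "sample_id", "gene", "technical_replicate"),
                      tolower(names(df)), names(df))
  ann_cols <- c("population_class", "population_id", "treatment", "timepoint",
                "biological_replicate")
  if (layout == "long") {
    req <- c("sample_id", "gene", "cq")
    miss <- setdiff(req, names(df))
    if (length(miss) > 0) {
      stop("required column(s) missing: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    cqv <- suppressWarnings(as.numeric(df$cq))
    bad <- which(is.na(cqv) | !is.finite(cqv) | cqv <= 0 | cqv > 45)
    if (length(bad) > 0) {
      stop("non-numeric or out-of-range Cq at row ", bad[1], call. = FALSE)
    }
    df$cq <- cqv
    genes <- unique(df$gene)
    samples <- unique(df$sample_id)
    ann <- NULL
    present_ann <- intersect(ann_cols, names(df))
    if (length(present_ann) > 0) {
      ann <- unique(df[, c("sample_id", present_ann), drop = FALSE])
      if (anyDuplicated(ann$sample_id)) {
        stop("inconsistent annotations for sample ",
             ann$sample_id[duplicated(ann$sample_id)][1], call. = FALSE)
      }
      rownames(ann) <- NULL
    }
    if ("technical_replicate" %in% names(df)) {
      tech <- df[, c("gene", "sample_id", "technical_replicate", "cq")]
      m <- cq_matrix(technical = tech)
    } else {
      key <- paste(df$gene, df$sample_id, sep = "\r")
      if (anyDuplicated(key)) {
        stop("duplicated gene x sample rows without a technical_replicate ",
             "column", call. = FALSE)
      }
      vals <- matrix(NA_real_, length(genes), length(samples),
                     dimnames = list(genes, samples))
      vals[cbind(match(df$gene, genes), match(df$sample_id, samples))] <- df$cq
      if (anyNA(vals)) stop("incomplete gene x sample grid in long table",
                            call. = FALSE)
      m <- cq_matrix(values = vals)
    }
    list(cq = m, annotations = ann)
  } else {
    if (!"sample_id" %in% names(df)) {
      stop("required column(s) missing: sample_id", call. = FALSE)
    }
    check_ids(as.character(df$sample_id), "sample")
    gene_cols <- names(df)[!names(df) %in% c("sample_id", ann_cols)]
    if (length(gene_cols) == 0) stop("wide table has no gene columns",
                                     call. = FALSE)
    check_ids(gene_cols, "gene")
    vals <- t(as.matrix(df[, gene_cols, drop = FALSE]))
    colnames(vals) <- df$sample_id
    storage.mode(vals) <- "double"
    ann <- NULL
    present_ann <- intersect(ann_cols, names(df))
    if (length(present_ann) > 0) {
      ann <- df[, c("sample_id", present_ann), drop = FALSE]
      rownames(ann) <- NULL
    }
    list(cq = cq_matrix(values = vals), annotations = ann)
  }
}

#' Write a Cq table in canonical long layout
#'
#' @param m A [cq_matrix].
#' @param path Output path (`.csv` comma, otherwise tab).
#' @param annotations Optional annotation data frame, joined on `sample_id`.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(m, path, annotations = NULL) {
  stopifnot(inherits(m, "cq_matrix"))
  if (!is.null(m$technical)) {
    df <- m$technical[, c("sample_id", "gene", "technical_replicate", "cq")]
  } else {
    df <- data.frame(
      sample_id = rep(colnames(m$values), each = nrow(m$values)),
      gene = rep(rownames(m$values), times = ncol(m$values)),
      cq = as.vector(m$values),
      stringsAsFactors = FALSE
    )
  }
  if (!is.null(annotations)) {
    df <- merge(df, annotations, by = "sample_id", sort = FALSE)
  }
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Aggregate technical replicates
#'
#' Collapses the per-reaction technical-replicate layer to one Cq per
#' gene x sample (arithmetic mean by default, the usual qPCR convention;
#' median available). Replicate sets whose spread (max - min) exceeds
#' `max_spread` cycles are flagged in the attached QC report; nothing is
#' dropped silently.
#'
#' @param m A [cq_matrix] with a technical layer.
#' @param max_spread QC threshold on the within-cell replicate spread, in
#'   cycles (default 0.5).
#' @param method `"mean"` (default) or `"median"`.
#' @return An aggregated [cq_matrix] (no replicate layer) with the QC report
#'   as attribute `"qc"`: a data frame with columns `gene`, `sample`,
#'   `n_replicates`, `spread`, `flagged`.
#' @export
aggregate_technical_replicates <- function(m, max_spread = 0.5,
                                           method = c("mean", "median")) {
  stopifnot(inherits(m, "cq_matrix"))
  method <- match.arg(method)
  if (is.null(m$technical)) {
    stop("no technical-replicate layer to aggregate", call. = FALSE)
  }
  tech <- m$technical
  genes <- unique(tech$gene)
  samples <- unique(tech$sample_id)
  # every gene x sample cell must hold at least one reaction
  tab <- table(factor(tech$gene, genes), factor(tech$sample_id, samples))
  if (any(tab == 0)) {
    idx <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("no technical replicates for gene ", genes[idx[1]], ", sample ",
         samples[idx[2]], call. = FALSE)
  }
  key <- interaction(factor(tech$gene, genes), factor(tech$sample_id, samples),
                     drop = FALSE)
  agg_fun <- if (method == "mean") mean else stats::median
  vals_by_cell <- split(tech$cq, key)
  agg <- vapply(vals_by_cell, agg_fun, numeric(1))
  spread <- vapply(vals_by_cell, function(v) max(v) - min(v), numeric(1))
  nrep <- lengths(vals_by_cell)
  vals <- matrix(agg, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  qc <- data.frame(
    gene = rep(genes, times = length(samples)),
    sample = rep(samples, each = length(genes)),
    n_replicates = as.integer(nrep),
    spread = spread,
    flagged = spread > max_spread,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- cq_matrix(values = vals, scale = m$scale)
  attr(out, "qc") <- qc
  out
}

#' Write the replicate QC report
#'
#' @param m An aggregated [cq_matrix] carrying a `"qc"` attribute.
#' @param path Output path (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(m, path) {
  qc <- attr(m, "qc")
  if (is.null(qc)) stop("no QC report attached; aggregate first", call. = FALSE)
  utils::write.table(qc, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a Cq matrix into the three analysis datasets
#'
#' Stability analyses run on three datasets: all samples pooled, the
#' susceptible-population samples, and the resistant-population samples.
#'
#' @param m An aggregated [cq_matrix].
#' @param annotations Annotation data frame covering every sample in `m`.
#' @return Named list of [cq_matrix] objects: `all`, `susceptible`,
#'   `resistant` (gene order preserved). An empty class subset is retained
#'   as `NULL` with a warning.
#' @export
split_datasets <- function(m, annotations) {
  stopifnot(inherits(m, "cq_matrix"))
  if (is.null(m$values)) stop("aggregate technical replicates first",
                              call. = FALSE)
  ann <- validate_annotations(annotations)
  samples <- colnames(m$values)
  missing_ann <- setdiff(samples, ann$sample_id)
  if (length(missing_ann) > 0) {
    stop("sample(s) lacking class annotation: ",
         paste(missing_ann, collapse = ", "), call. = FALSE)
  }
  cls <- ann$population_class[match(samples, ann$sample_id)]
  out <- list(all = m)
  for (k in c("susceptible", "resistant")) {
    keep <- samples[cls == k]
    if (length(keep) == 0) {
      warning("no samples in class '", k, "'", call. = FALSE)
      out[[k]] <- NULL
    } else {
      out[[k]] <- cq_matrix(values = m$values[, keep, drop = FALSE],
                            scale = m$scale)
    }
  }
  out
}

#' Subset a Cq matrix to a set of genes
#'
#' @param m A [cq_matrix].
#' @param genes Character vector of gene symbols to keep (order preserved).
#' @return A [cq_matrix] restricted to `genes`.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "cq_matrix"))
  have <- if (!is.null(m$values)) rownames(m$values) else unique(m$technical$gene)
  miss <- setdiff(genes, have)
  if (length(miss) > 0) {
    stop("gene(s) absent from the Cq matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  vals <- if (!is.null(m$values)) m$values[genes, , drop = FALSE]
  tech <- if (!is.null(m$technical)) {
    t <- m$technical[m$technical$gene %in% genes, , drop = FALSE]
    rownames(t) <- NULL
    t
  }
  out <- cq_matrix(values = vals, scale = m$scale, technical = tech)
  attr(out, "qc") <- attr(m, "qc")
  out
}

#' Per-gene Cq summary statistics
#'
#' @param m An aggregated [cq_matrix].
#' @return Data frame with columns `gene`, `n`, `mean`, `min`, `max`,
#'   `range` (cycles).
#' @export
summarize_cq <- function(m) {
  stopifnot(inherits(m, "cq_matrix"))
  if (is.null(m$values)) stop("aggregate technical replicates first",
                              call. = FALSE)
  x <- m$values
  data.frame(
    gene = rownames(x),
    n = ncol(x),
    mean = rowMeans(x),
    min = apply(x, 1, min),
    max = apply(x, 1, max),
    range = apply(x, 1, max) - apply(x, 1, min),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
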