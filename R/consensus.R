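#' Rank genes by a stability statistic
#'
#' Orders genes by ascending stability value (lower = more stable). Exact
#' ties keep their order of first occurrence in the display order and are
#' flagged; the `rank` column carries tie-averaged ranks, which is what the
#' geometric-mean consensus consumes.
#'
#' @param x A method result (`genorm_result`, `bestkeeper_result`,
#'   `normfinder_result`, `delta_ct_result`) or a named numeric vector of
#'   stability values.
#' @param method,dataset,scale Optional labels stored as attributes
#'   (e.g. method `"geNorm"`, dataset `"all"`, scale `"raw"`).
#' @return Object of class `stability_ranking`: a data frame with columns
#'   `gene`, `value`, `rank`, most stable first, with attributes `method`,
#'   `dataset`, `scale` and `ties` (list of tied gene groups, possibly
#'   empty).
#' @export
rank_genes <- function(x, method = NULL, dataset = NULL, scale = NULL) {
  values <- if (is.numeric(x)) x else x$stability
  if (is.null(names(values))) stop("stability values must be named",
                                   call. = FALSE)
  if (is.null(method) && !is.numeric(x)) {
    method <- switch(class(x)[1],
                     genorm_result = "geNorm",
                     bestkeeper_result = "BestKeeper",
                     normfinder_result = "NormFinder",
                     delta_ct_result = "DeltaCt",
                     NULL)
  }
  ord <- order(values)  # stable sort: ties keep first-occurrence order
  df <- data.frame(gene = names(values)[ord],
                   value = unname(values[ord]),
                   rank = rank(values, ties.method = "average")[ord],
                   stringsAsFactors = FALSE, row.names = NULL)
  tie_groups <- unname(split(df$gene, match(df$value, unique(df$value))))
  tie_groups <- Filter(function(g) length(g) > 1, tie_groups)
  structure(df, class = c("stability_ranking", "data.frame"),
            method = method, dataset = dataset, scale = scale,
            ties = tie_groups)
}

ranking_order <- function(x) {
  if (inherits(x, "stability_ranking")) x$gene
  else if (is.character(x)) x
  else stop("expected a stability_ranking or a character gene order",
            call. = FALSE)
}

#' Geometric-mean consensus of method rankings
#'
#' Comprehensive ranking across stability methods: each gene's consensus
#' value is the geometric mean of its (tie-averaged) ranks across the
#' supplied rankings, as popularised by RefFinder. The result is invariant
#' to the order in which the methods are supplied.
#'
#' @param rankings List of [rank_genes] results (typically the four
#'   methods) covering the same gene set.
#' @param dataset,scale Optional labels stored as attributes.
#' @return A `stability_ranking` (method label `"Consensus"`) whose `value`
#'   column is the geometric mean of ranks, in \[1, G\].
#' @export
consensus_geomean <- function(rankings, dataset = NULL, scale = NULL) {
  if (length(rankings) < 2) stop("need at least two rankings", call. = FALSE)
  genes <- sort(rankings[[1]]$gene)
  for (r in rankings) {
    if (!identical(sort(r$gene), genes)) {
      stop("rankings do not cover the same gene set", call. = FALSE)
    }
  }
  logsum <- stats::setNames(numeric(length(genes)), genes)
  for (r in rankings) logsum[r$gene] <- logsum[r$gene] + log(r$rank)
  geo <- exp(logsum / length(rankings))
  rank_genes(geo, method = "Consensus", dataset = dataset, scale = scale)
}

#' Count positional ranking changes between two scales
#'
#' Compares, per dataset, the gene occupying each rank position in two
#' ranking sets of the same method (e.g. computed from raw versus
#' efficiency-corrected Cq) and counts positions where the genes differ.
#' Counts are pooled over the datasets and expressed as a percentage of the
#' pooled denominator (genes x datasets), rounded to the nearest integer.
#'
#' @param a,b Named lists (same dataset names) of rankings -- either
#'   `stability_ranking` objects or plain character vectors of genes, most
#'   stable first -- over identical gene sets.
#' @param method Optional method label for the report.
#' @return Object of class `rank_change_report`: list with `per_dataset`
#'   (data frame: dataset, changed, n_genes), `pooled`, `denominator`,
#'   `percentage`, `method`.
#' @export
count_rank_changes <- function(a, b, method = NULL) {
  if (!identical(sort(names(a)), sort(names(b)))) {
    stop("ranking sets cover different datasets", call. = FALSE)
  }
  datasets <- names(a)
  changed <- integer(length(datasets))
  n_genes <- integer(length(datasets))
  for (i in seq_along(datasets)) {
    oa <- ranking_order(a[[datasets[i]]])
    ob <- ranking_order(b[[datasets[i]]])
    if (!identical(sort(oa), sort(ob))) {
      stop("mismatched gene sets in dataset '", datasets[i], "'",
           call. = FALSE)
    }
    changed[i] <- sum(oa != ob)
    n_genes[i] <- length(oa)
  }
  pooled <- sum(changed)
  denom <- sum(n_genes)
  structure(list(
    per_dataset = data.frame(dataset = datasets, changed = changed,
                             n_genes = n_genes, stringsAsFactors = FALSE),
    pooled = pooled,
    denominator = denom,
    percentage = round(100 * pooled / denom),
    method = method
  ), class = "rank_change_report")
}

#' @export
print.rank_change_report <- function(x, ...) {
  cat(sprintf("<rank_change_report>%s %d/%d positions changed (%d%%)\n",
              if (!is.null(x$method)) paste0(" ", x$method, ":") else "",
              x$pooled, x$denominator, x$percentage))
  invisible(x)
}

#' Optimal number of reference genes from pairwise variation
#'
#' Scans the geNorm pairwise-variation series V_n/n+1 for the smallest n
#' whose value falls below the threshold (conventionally 0.15): below it,
#' adding the (n+1)-th reference gene no longer improves the normalization
#' factor. If no value satisfies the threshold, all G genes are recommended
#' and the result is flagged.
#'
#' @param v Named numeric vector `V2/3 ... V(G-1)/G` (as produced by
#'   [genorm]).
#' @param threshold Cut-off on V (default 0.15).
#' @return List with `n` (recommended gene count), `satisfied` (logical:
#'   did some V fall below the threshold), `threshold` and the input `v`.
#' @export
optimal_reference_count <- function(v, threshold = 0.15) {
  if (length(v) == 0) stop("empty pairwise-variation vector", call. = FALSE)
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  n_seq <- seq(2, length.out = length(v))
  below <- which(v < threshold)
  if (length(below) > 0) {
    list(n = n_seq[below[1]], satisfied = TRUE, threshold = threshold, v = v)
  } else {
    list(n = n_seq[length(v)] + 1, satisfied = FALSE, threshold = threshold,
         v = v)
  }
}

#' Write a ranking table as delimited text
#'
#' @param ranking A `stability_ranking`.
#' @param path Output path (`.csv` comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "stability_ranking"))
  df <- as.data.frame(ranking)
  df$method <- attr(ranking, "method") %||% NA_character_
  df$dataset <- attr(ranking, "dataset") %||% NA_character_
  df$scale <- attr(ranking, "scale") %||% NA_character_
  utils::write.table(df, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
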