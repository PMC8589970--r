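# deterministic per-stream seeding: a draw for one (gene, sample) pair never
# depends on how many other genes are simulated
stream_seed <- function(master, ...) {
  key <- paste(c(...), collapse = "\r")
  acc <- as.double(master) %% 2147483647
  for (code in utf8ToInt(key)) {
    acc <- (acc * 31 + code) %% 2147483647
  }
  as.integer(acc)
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration for synthetic Cq data
#'
#' Describes a synthetic RT-qPCR experiment with the variance components
#' that reference-gene stability analysis assumes: a per-gene baseline Cq,
#' a per-sample loading effect shared by all genes (the template-amount
#' variation that normalization is meant to remove), per-gene stability
#' noise, condition-specific shifts, and technical-replicate noise. The
#' default configuration mirrors a two-class herbicide-response design:
#' 2 susceptible + 2 resistant populations, treated/untreated, harvests at
#' 1 h and 24 h, 4 biological replicates per condition and technical
#' triplicates, with 11 candidate reference genes of heterogeneous
#' stability plus 2 treatment-responsive target genes.
#'
#' @param genes Character vector of gene symbols.
#' @param baseline Named numeric vector of baseline Cq per gene (cycles,
#'   in (10, 35)).
#' @param tau Named numeric vector of per-gene stability noise SD (cycles).
#' @param efficiency Named numeric vector of true assay efficiencies
#'   (fractions).
#' @param effects Data frame of condition shifts with columns `gene`,
#'   `factor` (one of `population_class`, `treatment`, `timepoint`),
#'   `level`, `shift` (cycles, added to Cq for samples at that level).
#' @param sigma_loading SD of the shared per-sample loading effect (cycles).
#' @param sigma_tech SD of the technical-replicate noise (cycles).
#' @param n_populations Populations per resistance class.
#' @param n_bioreps Biological replicates per condition.
#' @param n_techreps Technical replicates per reaction.
#' @param targets Character vector naming the validation target genes among
#'   `genes` (excluded from the candidate-reference set); defaults to
#'   `ABCC10`/`CYP89A2` for the default gene set, empty otherwise.
#' @param seed Master seed (integer).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(genes = NULL, baseline = NULL, tau = NULL,
                              efficiency = NULL, effects = NULL,
                              sigma_loading = 1.0, sigma_tech = 0.15,
                              n_populations = 2, n_bioreps = 4,
                              n_techreps = 3, targets = NULL, seed = 1L) {
  default_set <- is.null(genes)
  if (is.null(genes)) {
    genes <- c("TBP", "GAPC", "CYP28", "ACT", "ARF1", "SPS", "UBC", "RCA",
               "RPL23A", "UBQ", "EF1A", "ABCC10", "CYP89A2")
    baseline <- stats::setNames(
      c(24.5, 20.5, 23.0, 21.0, 27.2, 25.5, 22.5, 18.8,
        23.5, 21.5, 19.5, 28.0, 26.5), genes)
    tau <- stats::setNames(
      c(0.08, 0.12, 0.15, 0.18, 0.22, 0.26, 0.30, 0.35,
        0.45, 0.60, 0.90, 0.40, 0.40), genes)
    efficiency <- stats::setNames(
      c(0.905, 1.067, 0.999, 0.914, 0.948, 0.998, 0.926, 1.056,
        0.882, 0.986, 1.082, 1.134, 1.030), genes)
    effects <- data.frame(
      gene = c("EF1A", "UBQ", "RPL23A",
               "ABCC10", "ABCC10", "CYP89A2", "CYP89A2"),
      factor = c("population_class", "treatment", "timepoint",
                 "population_class", "treatment", "population_class",
                 "treatment"),
      level = c("resistant", "treated", "24h",
                "resistant", "treated", "resistant", "treated"),
      shift = c(0.5, 0.3, 0.25, -0.8, -1.0, -0.8, -1.5),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(baseline) || is.null(tau)) {
    stop("custom gene sets need explicit `baseline` and `tau`", call. = FALSE)
  }
  if (is.null(efficiency)) {
    efficiency <- stats::setNames(rep(1, length(genes)), genes)
  }
  if (is.null(effects)) {
    effects <- data.frame(gene = character(0), factor = character(0),
                          level = character(0), shift = numeric(0),
                          stringsAsFactors = FALSE)
  }
  check_ids(genes, "gene")
  for (nm in c("baseline", "tau", "efficiency")) {
    v <- get(nm)
    if (!all(genes %in% names(v))) {
      stop("`", nm, "` must be named and cover every gene", call. = FALSE)
    }
  }
  if (any(baseline[genes] <= 10 | baseline[genes] >= 35)) {
    stop("baseline Cq must lie in (10, 35)", call. = FALSE)
  }
  if (any(tau[genes] < 0) || sigma_loading < 0 || sigma_tech < 0) {
    stop("noise SDs must be non-negative", call. = FALSE)
  }
  if (n_populations < 1 || n_bioreps < 1 || n_techreps < 1) {
    stop("design counts must be >= 1", call. = FALSE)
  }
  if (is.null(targets)) {
    targets <- if (default_set) c("ABCC10", "CYP89A2") else character(0)
  }
  if (!all(targets %in% genes)) {
    stop("`targets` must be a subset of `genes`", call. = FALSE)
  }
  bad_f <- setdiff(effects$factor,
                   c("population_class", "treatment", "timepoint"))
  if (length(bad_f) > 0) {
    stop("unknown effect factor(s): ", paste(bad_f, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    genes = genes, baseline = baseline[genes], tau = tau[genes],
    efficiency = efficiency[genes], effects = effects,
    sigma_loading = sigma_loading, sigma_tech = sigma_tech,
    n_populations = n_populations, n_bioreps = n_bioreps,
    n_techreps = n_techreps, targets = targets,
    reference_genes = setdiff(genes, targets), seed = as.integer(seed)
  ), class = "simulation_config")
}

gene_effect_shift <- function(cfg, gene, ann_row) {
  ef <- cfg$effects[cfg$effects$gene == gene, , drop = FALSE]
  if (nrow(ef) == 0) return(0)
  sum(ef$shift[mapply(function(f, l) identical(as.character(ann_row[[f]]), l),
                      ef$factor, ef$level)])
}

#' Simulate a synthetic Cq dataset
#'
#' Draws Cq values under the additive model
#' Cq(g, s, rep) = B_g + L_s + delta_g(condition of s) + eps(g, s) + eta(rep),
#' with L_s ~ N(0, sigma_loading^2) shared across genes within a sample,
#' eps ~ N(0, tau_g^2) the gene's stability noise, and
#' eta ~ N(0, sigma_tech^2) per technical replicate. Random streams are
#' seeded per gene and sample from the master seed, so adding a gene to the
#' configuration does not perturb the draws of the others; identical seeds
#' give identical output.
#'
#' @param cfg A [simulation_config].
#' @return List with `cq` (a raw-scale [cq_matrix] carrying the
#'   technical-replicate layer), `annotations` (data frame, one row per
#'   sample), `assays` (an [assay_info] built from the configured true
#'   efficiencies), and `truth` (the config plus `true_order`, genes sorted
#'   by ascending instability burden tau_g + sum(|delta_g|)/2).
#' @export
simulate_cq_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  design <- expand.grid(
    biological_replicate = seq_len(cfg$n_bioreps),
    timepoint = c("1h", "24h"),
    treatment = c("untreated", "treated"),
    population = seq_len(cfg$n_populations),
    population_class = c("susceptible", "resistant"),
    stringsAsFactors = FALSE
  )
  design$population_id <- paste0(
    ifelse(design$population_class == "susceptible", "S", "R"),
    design$population)
  design$sample_id <- sprintf(
    "%s.%s.%s.b%d", design$population_id, design$treatment,
    design$timepoint, design$biological_replicate)
  ann <- data.frame(
    sample_id = design$sample_id,
    population_class = design$population_class,
    population_id = design$population_id,
    treatment = design$treatment,
    timepoint = design$timepoint,
    biological_replicate = as.integer(design$biological_replicate),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(ann)
  loading <- vapply(ann$sample_id, function(s) {
    with_seed(stream_seed(cfg$seed, "loading", s),
              stats::rnorm(1, 0, cfg$sigma_loading))
  }, numeric(1))
  rows <- vector("list", length(cfg$genes) * n_s)
  idx <- 1L
  for (g in cfg$genes) {
    for (si in seq_len(n_s)) {
      s <- ann$sample_id[si]
      shift <- gene_effect_shift(cfg, g, ann[si, ])
      draws <- with_seed(stream_seed(cfg$seed, "cell", g, s), {
        eps <- stats::rnorm(1, 0, cfg$tau[g])
        eta <- stats::rnorm(cfg$n_techreps, 0, cfg$sigma_tech)
        cfg$baseline[g] + loading[si] + shift + eps + eta
      })
      rows[[idx]] <- data.frame(
        gene = g, sample_id = s,
        technical_replicate = seq_len(cfg$n_techreps),
        cq = draws, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  tech <- do.call(rbind, rows)
  burden <- vapply(cfg$genes, function(g) {
    cfg$tau[g] + sum(abs(cfg$effects$shift[cfg$effects$gene == g])) / 2
  }, numeric(1))
  refs <- cfg$reference_genes
  truth <- list(config = cfg,
                burden = burden,
                true_order = cfg$genes[order(burden)],
                reference_order = refs[order(burden[refs])])
  list(
    cq = cq_matrix(technical = tech, scale = "raw"),
    annotations = ann,
    assays = assay_info(gene = cfg$genes,
                        efficiency = unname(cfg$efficiency)),
    truth = truth
  )
}

#' Simulate a dilution-series standard curve
#'
#' Generates Cq measurements along a 10-fold dilution series under a known
#' amplification efficiency: Cq = intercept - x / log10(1 + E) + noise at
#' log10 relative concentration x = 0, -1, ....
#'
#' @param efficiency True amplification efficiency (fraction, > 0).
#' @param intercept Cq at relative concentration 1 (cycles).
#' @param n_points Number of dilution points (>= 3).
#' @param noise_sd SD of measurement noise on Cq (cycles).
#' @param seed Optional seed for the noise draws.
#' @return Data frame with columns `log10_conc`, `cq`, suitable for
#'   [fit_standard_curve].
#' @export
simulate_dilution_series <- function(efficiency, intercept = 20,
                                     n_points = 5, noise_sd = 0,
                                     seed = NULL) {
  if (!is.finite(efficiency) || efficiency <= 0) {
    stop("efficiency must be a positive fraction", call. = FALSE)
  }
  if (n_points < 3) stop("need at least 3 dilution points", call. = FALSE)
  x <- -(seq_len(n_points) - 1)
  noise <- if (noise_sd > 0) {
    if (!is.null(seed)) with_seed(seed, stats::rnorm(n_points, 0, noise_sd))
    else stats::rnorm(n_points, 0, noise_sd)
  } else rep(0, n_points)
  data.frame(log10_conc = x,
             cq = intercept - x / log10(1 + efficiency) + noise)
}

#' Load the packaged published ranking and assay fixtures
#'
#' Returns the published expression-stability rankings (five methods, three
#' datasets, raw and efficiency-corrected scales, with the printed
#' stability values) and the published per-assay primer metadata, packaged
#' as plain-text resources. These fixtures feed the ranking-comparison
#' operations; the stability values themselves are carried for table
#' reproduction only.
#'
#' @return List with `assays` (the 11 reference-gene assays as
#'   [assay_info]), `validation_assays` (the 2 target-gene assays), and
#'   `rankings` (data frame with columns `method`, `dataset`, `scale`,
#'   `rank`, `gene`, `value`).
#' @export
load_paper_fixtures <- function() {
  adir <- system.file("extdata", package = "qpcrstab")
  apath <- file.path(adir, "assay_metadata.tsv")
  rpath <- file.path(adir, "stability_rankings.tsv")
  if (!file.exists(apath) || !file.exists(rpath)) {
    stop("packaged fixture files not found", call. = FALSE)
  }
  adf <- utils::read.table(apath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("gene", "role", "efficiency_percent", "r_squared",
            "amplicon_length", "annealing_temp")
  if (!all(need %in% names(adf))) stop("corrupted assay fixture",
                                       call. = FALSE)
  mk <- function(d) assay_info(d$gene, d$efficiency_percent / 100,
                               d$r_squared, d$amplicon_length,
                               d$annealing_temp)
  rdf <- utils::read.table(rpath, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("method", "dataset", "scale", "rank", "gene", "value") %in%
           names(rdf))) {
    stop("corrupted ranking fixture", call. = FALSE)
  }
  list(
    assays = mk(adf[adf$role == "reference", , drop = FALSE]),
    validation_assays = mk(adf[adf$role == "validation", , drop = FALSE]),
    rankings = rdf
  )
}

#' Extract one published ranking from the fixture bundle
#'
#' @param fixtures Result of [load_paper_fixtures].
#' @param method One of `geNorm`, `BestKeeper`, `NormFinder`, `DeltaCt`,
#'   `Consensus`.
#' @param dataset One of `all`, `susceptible`, `resistant`.
#' @param scale `raw` or `efficiency_corrected`.
#' @return Data frame ordered most stable first with columns `rank`,
#'   `gene`, `value`.
#' @export
fixture_ranking <- function(fixtures, method, dataset, scale) {
  r <- fixtures$rankings
  sel <- r[r$method == method & r$dataset == dataset & r$scale == scale, ,
           drop = FALSE]
  if (nrow(sel) == 0) {
    stop("no fixture ranking for ", method, " / ", dataset, " / ", scale,
         call. = FALSE)
  }
  sel <- sel[order(sel$rank), c("rank", "gene", "value")]
  rownames(sel) <- NULL
  sel
}
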