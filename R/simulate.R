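#' Simulation design for the two-cohort study
#'
#' Defines the conditions of the synthetic study: a blood (PBMC-like)
#' cohort sampled at five ordered clinical stages, and a collection of
#' heterogeneous tissue (glomerular-like) case/control datasets on
#' distinct probe universes. Defaults mirror the published cohort scale:
#' stage sizes HC/D1/D2/D3/ESRD = 10/11/7/5/7 for the blood cohort, and
#' three tissue datasets totalling 25 cases vs 26 controls.
#'
#' @param n_genes Number of genes in the shared universe (default 5000).
#' @param stage_sizes Named ordered vector of per-stage sample counts.
#' @param n_trend_genes Genes planted with a monotone stage trend
#'   (default 50).
#' @param trend_step_delta Mean shift per stage step for trend genes, in
#'   units of the residual noise SD (default 0.5).
#' @param trend_stages Ordered stages over which the trend rises; stages
#'   before/after the set sit at its first/last level. Default: the full
#'   clinical ordering, since disease severity spans the whole cohort.
#' @param n_datasets Number of tissue datasets (default 3).
#' @param n_case,n_control Per-dataset case/control counts, recycled to
#'   `n_datasets`. Defaults (8, 8, 9) vs (9, 9, 8): 25 cases, 26 controls
#'   in total.
#' @param n_de_genes Genes planted as differentially expressed in tissue
#'   (default 100).
#' @param de_effect Case-minus-control mean shift in noise-SD units
#'   (default 2).
#' @param n_overlap_genes Genes planted in BOTH cohorts with consistent
#'   (increasing/up) direction (default 30); must not exceed
#'   `min(n_trend_genes, n_de_genes)`.
#' @param probe_multiplicity Mean probes per gene on each tissue platform
#'   (Poisson-distributed, at least 1; default 2).
#' @param noise_sd Residual SD of the log2 expression noise (default 1).
#' @param baseline_mean,baseline_sd Per-gene baseline log2 level
#'   distribution (defaults 7 and 1.5).
#' @param platform_sd SD of the per-gene additive platform offset drawn
#'   once per tissue dataset (default 0.5).
#' @param probe_offset_sd,probe_noise_sd Probe-level additive offset and
#'   independent probe noise SDs (defaults 0.3 and 0.3).
#' @param gene_coverage Fraction of the gene universe measured by each
#'   tissue platform (default 1).
#' @param seed Default seed for the generators.
#' @return List of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 5000L,
                              stage_sizes = c(HC = 10L, D1 = 11L, D2 = 7L,
                                              D3 = 5L, ESRD = 7L),
                              n_trend_genes = 50L,
                              trend_step_delta = 0.5,
                              trend_stages = names(stage_sizes),
                              n_datasets = 3L,
                              n_case = c(8L, 8L, 9L),
                              n_control = c(9L, 9L, 8L),
                              n_de_genes = 100L,
                              de_effect = 2,
                              n_overlap_genes = 30L,
                              probe_multiplicity = 2,
                              noise_sd = 1,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              platform_sd = 0.5,
                              probe_offset_sd = 0.3,
                              probe_noise_sd = 0.3,
                              gene_coverage = 1,
                              seed = 1L) {
  stopifnot(n_genes >= 1, n_trend_genes >= 0, n_de_genes >= 0,
            n_overlap_genes >= 0, n_datasets >= 1,
            probe_multiplicity >= 1, noise_sd > 0,
            gene_coverage > 0, gene_coverage <= 1)
  if (is.null(names(stage_sizes))) stop("stage_sizes must be named (ordered)")
  if (any(stage_sizes < 2L)) stop("design error: every stage needs >= 2 samples")
  if (!all(trend_stages %in% names(stage_sizes))) {
    stop("trend_stages must be a subset of the stage ordering")
  }
  n_case <- rep_len(as.integer(n_case), n_datasets)
  n_control <- rep_len(as.integer(n_control), n_datasets)
  if (any(n_case < 2L) || any(n_control < 2L)) {
    stop("design error: every dataset needs >= 2 cases and >= 2 controls")
  }
  if (n_overlap_genes > min(n_trend_genes, n_de_genes)) {
    stop("n_overlap_genes cannot exceed min(n_trend_genes, n_de_genes)")
  }
  if (n_trend_genes + n_de_genes - n_overlap_genes > n_genes) {
    stop("more signal genes than genes in the universe")
  }
  structure(list(n_genes = as.integer(n_genes), stage_sizes = stage_sizes,
                 n_trend_genes = as.integer(n_trend_genes),
                 trend_step_delta = trend_step_delta,
                 trend_stages = trend_stages,
                 n_datasets = as.integer(n_datasets),
                 n_case = n_case, n_control = n_control,
                 n_de_genes = as.integer(n_de_genes), de_effect = de_effect,
                 n_overlap_genes = as.integer(n_overlap_genes),
                 probe_multiplicity = probe_multiplicity,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, platform_sd = platform_sd,
                 probe_offset_sd = probe_offset_sd,
                 probe_noise_sd = probe_noise_sd,
                 gene_coverage = gene_coverage,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

gene_ids <- function(n) sprintf("G%05d", seq_len(n))

# per-sample trend level: position within trend_stages, clamped at its ends
stage_trend_index <- function(stage, stage_order, trend_stages) {
  pos <- match(as.character(stage), stage_order)
  lo <- match(trend_stages[1L], stage_order)
  hi <- match(trend_stages[length(trend_stages)], stage_order)
  pmin(pmax(pos, lo), hi) - lo
}

#' Simulate a PBMC-like ordered-stage cohort
#'
#' Gene g in sample s is `Normal(mu_g + s_g * delta * noise_sd * t_s,
#' noise_sd^2)` where `t_s` is the sample's trend index (stage steps
#' within `design$trend_stages`) and `s_g` is +1/-1 for planted trend
#' genes and 0 otherwise. The ground truth records every planted gene.
#'
#' @param design A [simulation_design()].
#' @param seed Seed (defaults to `design$seed`).
#' @param signal_genes,signal_signs Optional predetermined trend gene ids
#'   and signs (used by [simulate_overlap_study()]); default random.
#' @return List with `expr` (matrix genes x samples), `annotation`, and
#'   `truth` (class `ground_truth`).
#' @export
simulate_pbmc_cohort <- function(design, seed = design$seed,
                                 signal_genes = NULL, signal_signs = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  genes <- gene_ids(design$n_genes)
  stages <- names(design$stage_sizes)
  stage_vec <- rep(stages, design$stage_sizes)
  sample_id <- unlist(lapply(stages, function(s) {
    sprintf("%s_%02d", s, seq_len(design$stage_sizes[[s]]))
  }))
  if (is.null(signal_genes)) {
    signal_genes <- sample(genes, design$n_trend_genes)
    signal_signs <- sample(c(1, -1), design$n_trend_genes, replace = TRUE)
  }
  stopifnot(length(signal_genes) == length(signal_signs),
            all(signal_genes %in% genes))

  tindex <- stage_trend_index(stage_vec, stages, design$trend_stages)
  mu <- stats::rnorm(design$n_genes, design$baseline_mean, design$baseline_sd)
  slope <- numeric(design$n_genes)
  slope[match(signal_genes, genes)] <-
    signal_signs * design$trend_step_delta * design$noise_sd
  x <- mu + outer(slope, tindex) +
    matrix(stats::rnorm(design$n_genes * length(sample_id), 0, design$noise_sd),
           design$n_genes)
  dimnames(x) <- list(genes, sample_id)
  attr(x, "feature_kind") <- "gene"

  annotation <- make_sample_annotation(
    data.frame(sample_id = sample_id, stage = stage_vec,
               stringsAsFactors = FALSE),
    stage_levels = stages)
  truth <- structure(list(trend_genes = signal_genes,
                          trend_signs = stats::setNames(signal_signs, signal_genes),
                          trend_step_delta = design$trend_step_delta,
                          trend_stages = design$trend_stages,
                          seed = seed),
                     class = "ground_truth")
  list(expr = x, annotation = annotation, truth = truth)
}

#' Simulate a heterogeneous collection of tissue case/control datasets
#'
#' Every dataset has its own probe universe (about `probe_multiplicity`
#' probes per gene, Poisson-distributed and at least 1), its own per-gene
#' additive platform offset, and the shared planted DE genes shifted by
#' `de_effect` noise-SD units in cases. Probe values are the gene-level
#' value plus a fixed probe offset and independent probe noise.
#'
#' @param design A [simulation_design()].
#' @param seed Seed (defaults to `design$seed`).
#' @param signal_genes,signal_signs Optional predetermined DE gene ids and
#'   signs; default random.
#' @return List with `datasets` (list of [case_control_dataset()]) and
#'   `truth`.
#' @export
simulate_glomerular_collection <- function(design, seed = design$seed,
                                           signal_genes = NULL,
                                           signal_signs = NULL) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  genes <- gene_ids(design$n_genes)
  if (is.null(signal_genes)) {
    signal_genes <- sample(genes, design$n_de_genes)
    signal_signs <- sample(c(1, -1), design$n_de_genes, replace = TRUE)
  }
  stopifnot(length(signal_genes) == length(signal_signs),
            all(signal_genes %in% genes))
  mu <- stats::rnorm(design$n_genes, design$baseline_mean, design$baseline_sd)
  shift <- numeric(design$n_genes)
  shift[match(signal_genes, genes)] <-
    signal_signs * design$de_effect * design$noise_sd

  datasets <- vector("list", design$n_datasets)
  for (d in seq_len(design$n_datasets)) {
    ds_id <- sprintf("DS%d", d)
    covered <- if (design$gene_coverage < 1) {
      sort(sample(design$n_genes, round(design$gene_coverage * design$n_genes)))
    } else {
      seq_len(design$n_genes)
    }
    n_probes_per_gene <- 1L + stats::rpois(length(covered),
                                           design$probe_multiplicity - 1)
    gene_idx <- rep(covered, n_probes_per_gene)
    probe_id <- sprintf("%s_P%06d", ds_id, seq_along(gene_idx))
    map <- make_probe_gene_map(
      data.frame(probe_id = probe_id, gene_id = genes[gene_idx],
                 stringsAsFactors = FALSE))

    nc <- design$n_case[d]
    nt <- design$n_control[d]
    sample_id <- c(sprintf("%s_case_%02d", ds_id, seq_len(nc)),
                   sprintf("%s_ctrl_%02d", ds_id, seq_len(nt)))
    group <- c(rep("case", nc), rep("control", nt))
    platform <- stats::rnorm(design$n_genes, 0, design$platform_sd)
    gene_level <- mu + platform +
      outer(shift, as.numeric(group == "case")) +
      matrix(stats::rnorm(design$n_genes * (nc + nt), 0, design$noise_sd),
             design$n_genes)
    probe_offset <- stats::rnorm(length(gene_idx), 0, design$probe_offset_sd)
    probes <- gene_level[gene_idx, , drop = FALSE] + probe_offset +
      matrix(stats::rnorm(length(gene_idx) * (nc + nt), 0,
                          design$probe_noise_sd),
             length(gene_idx))
    dimnames(probes) <- list(probe_id, sample_id)
    attr(probes, "feature_kind") <- "probe"
    annotation <- make_sample_annotation(
      data.frame(sample_id = sample_id, group = group,
                 stringsAsFactors = FALSE))
    datasets[[d]] <- case_control_dataset(probes, annotation, map, ds_id)
  }
  truth <- structure(list(de_genes = signal_genes,
                          de_signs = stats::setNames(signal_signs, signal_genes),
                          de_effect = design$de_effect,
                          seed = seed),
                     class = "ground_truth")
  list(datasets = datasets, truth = truth)
}

#' Simulate the full two-cohort overlap study
#'
#' Plants `n_overlap_genes` genes as increasing trend genes in the blood
#' cohort AND up-regulated DE genes in every tissue dataset (consistent
#' positive sign, mirroring a shared up/up disease signature); the
#' remaining trend and DE genes are disjoint with random signs.
#'
#' @param design A [simulation_design()].
#' @param seed Seed (defaults to `design$seed`); sub-seeds for the two
#'   cohorts are derived from it.
#' @return List with `pbmc` (see [simulate_pbmc_cohort()]), `glomerular`
#'   (see [simulate_glomerular_collection()]) and a combined `truth`
#'   carrying `overlap_genes`.
#' @export
simulate_overlap_study <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "simulation_design"))
  set.seed(seed)
  genes <- gene_ids(design$n_genes)
  overlap <- sort(sample(genes, design$n_overlap_genes))
  pool <- setdiff(genes, overlap)
  extra_trend <- sample(pool, design$n_trend_genes - design$n_overlap_genes)
  pool <- setdiff(pool, extra_trend)
  extra_de <- sample(pool, design$n_de_genes - design$n_overlap_genes)

  trend_genes <- c(overlap, extra_trend)
  trend_signs <- c(rep(1, length(overlap)),
                   sample(c(1, -1), length(extra_trend), replace = TRUE))
  de_genes <- c(overlap, extra_de)
  de_signs <- c(rep(1, length(overlap)),
                sample(c(1, -1), length(extra_de), replace = TRUE))

  sub_seed <- function(off) as.integer((as.numeric(seed) + off) %% 2147483647)
  pbmc <- simulate_pbmc_cohort(design, seed = sub_seed(1),
                               signal_genes = trend_genes,
                               signal_signs = trend_signs)
  glom <- simulate_glomerular_collection(design, seed = sub_seed(2),
                                         signal_genes = de_genes,
                                         signal_signs = de_signs)

  truth <- structure(list(overlap_genes = overlap,
                          trend_genes = trend_genes,
                          trend_signs = stats::setNames(trend_signs, trend_genes),
                          de_genes = de_genes,
                          de_signs = stats::setNames(de_signs, de_genes),
                          trend_step_delta = design$trend_step_delta,
                          de_effect = design$de_effect,
                          seed = seed),
                     class = "ground_truth")
  list(pbmc = pbmc, glomerular = glom, truth = truth)
}

#' Serialize a ground-truth record as JSON
#' @param truth A `ground_truth` object.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  # named vectors -> JSON objects, so names survive the round trip
  prep <- lapply(unclass(truth), function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(prep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read back a ground-truth record
#' @param path Path to the JSON file.
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- lapply(x, function(el) {
    if (is.list(el) && length(el) && all(lengths(el) == 1L)) unlist(el) else el
  })
  structure(x, class = "ground_truth")
}
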