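#' Run the full two-cohort discovery pipeline
#'
#' Convenience wrapper chaining the blood trend screen, the tissue
#' weighted-Z meta-analysis and the cross-cohort hypergeometric overlap.
#' The overlap universe is the set of genes testable in BOTH cohorts:
#' blood matrix genes intersected with the genes any tissue platform maps
#' to. By default the up-in-blood list is intersected with the
#' up-in-tissue list (the headline-table convention); `direction` selects
#' other combinations, and `"both"` unions up/up with down/down.
#'
#' @param pbmc List with `expr` and `annotation` (as from
#'   [simulate_pbmc_cohort()], or assembled from files).
#' @param datasets List of [case_control_dataset()] objects.
#' @param config An [analysis_config()].
#' @param stage_set Stages for the trend screen; `NULL` uses every stage
#'   present (see [trend_screen()]). The config's `trend_stage_set` is
#'   used when `stage_set = "config"`.
#' @param direction `"up"` (up/up, default), `"down"` (down/down) or
#'   `"both"`.
#' @return List with `trend`, `meta`, `overlap` and `universe`.
#' @export
run_overlap_pipeline <- function(pbmc, datasets, config = analysis_config(),
                                 stage_set = NULL, direction = c("up", "down", "both")) {
  direction <- match.arg(direction)
  if (identical(stage_set, "config")) stage_set <- config$trend_stage_set
  trend <- trend_screen(pbmc$expr, pbmc$annotation, stage_set = stage_set,
                        alpha = config$alpha_trend)
  meta <- egwas_screen(datasets, z_threshold = config$z_threshold,
                       weight_scheme = config$weight_scheme,
                       collapse_rule = config$probe_collapse_rule)
  tissue_genes <- unique(unlist(lapply(datasets, function(d) {
    unique(d$map$gene_id[!is.na(d$map$gene_id)])
  })))
  universe <- intersect(rownames(pbmc$expr), tissue_genes)

  pick <- function(blood, tissue) {
    intersect_and_score(intersect(blood, universe), intersect(tissue, universe),
                        universe, trend_table = trend$table,
                        meta_table = meta$table)
  }
  overlap <- switch(direction,
    up = pick(trend$up, meta$up),
    down = pick(trend$down, meta$down),
    both = pick(union(trend$up, trend$down), union(meta$up, meta$down))
  )
  list(trend = trend, meta = meta, overlap = overlap, universe = universe,
       config = config)
}
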