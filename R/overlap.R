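#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` marked items when `n` items are
#' drawn without replacement from a universe of `N` containing `m` marked
#' ones: `p = sum_{j = k}^{min(m, n)} C(m, j) C(N - m, n - j) / C(N, n)`.
#' The sum is accumulated in log space for numerical stability.
#'
#' @param k Observed overlap (`p = 1` exactly when `k <= 0`).
#' @param m Number of marked items in the universe.
#' @param n Number drawn.
#' @param N Universe size.
#' @return The upper-tail probability, in (0, 1].
#' @export
hypergeometric_p <- function(k, m, n, N) {
  stopifnot(length(k) == 1L, length(m) == 1L, length(n) == 1L, length(N) == 1L)
  if (m > N || n > N) stop("marked (m) and drawn (n) counts cannot exceed the universe (N)")
  if (k > min(m, n)) stop("overlap k cannot exceed min(m, n)")
  if (k <= 0) return(1)
  j <- k:min(m, n)
  lg <- lchoose(m, j) + lchoose(N - m, n - j) - lchoose(N, n)
  mx <- max(lg)
  p <- exp(mx + log(sum(exp(lg - mx))))
  min(p, 1)
}

#' Intersect two cohort gene lists and score the overlap
#'
#' The blood (trend-screen) and tissue (meta-analysis) gene lists are
#' intersected inside a shared universe and the overlap size is scored
#' with the upper-tail hypergeometric test. The ranked records are sorted
#' by the trend p ascending, ties broken by the meta p ascending (the
#' headline-table ordering).
#'
#' @param blood_list Character vector of genes from the blood screen.
#' @param tissue_list Character vector of genes from the tissue
#'   meta-analysis.
#' @param universe Character vector of genes testable in BOTH cohorts;
#'   must contain both lists.
#' @param trend_table Optional trend-screen table (from [trend_screen()])
#'   used to attach `p_trend` to the ranked records.
#' @param meta_table Optional meta-analysis table (from [egwas_screen()])
#'   used to attach `p_meta` and `z_meta`.
#' @return List of class `overlap_result`: `intersection`, `k`, `m`, `n`,
#'   `N`, `p`, and `records` (gene, p_meta, p_trend, z_meta, ranked).
#' @export
intersect_and_score <- function(blood_list, tissue_list, universe,
                                trend_table = NULL, meta_table = NULL) {
  universe <- unique(universe)
  if (length(blood_list) && length(tissue_list) &&
      !length(intersect(universe, c(blood_list, tissue_list)))) {
    stop("gene id harmonization error: lists share no ids with the universe")
  }
  if (!all(blood_list %in% universe) || !all(tissue_list %in% universe)) {
    stop("universe must contain every listed gene")
  }
  A <- unique(blood_list)
  B <- unique(tissue_list)
  inter <- intersect(A, B)
  k <- length(inter)
  p <- hypergeometric_p(k, length(A), length(B), length(universe))

  records <- data.frame(gene = inter, stringsAsFactors = FALSE)
  records$p_trend <- if (!is.null(trend_table)) {
    i <- match(inter, trend_table$gene)
    pmin(trend_table$p_increasing[i], trend_table$p_decreasing[i])
  } else rep(NA_real_, k)
  if (!is.null(meta_table)) {
    i <- match(inter, meta_table$gene)
    records$p_meta <- meta_table$p_meta[i]
    records$z_meta <- meta_table$z_meta[i]
  } else {
    records$p_meta <- rep(NA_real_, k)
    records$z_meta <- rep(NA_real_, k)
  }
  records <- records[order(records$p_trend, records$p_meta, records$gene), ,
                     drop = FALSE]
  rownames(records) <- NULL

  structure(list(intersection = inter, k = k, m = length(A), n = length(B),
                 N = length(universe), p = p, records = records),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Cross-cohort overlap: k = %d of |blood| = %d, |tissue| = %d, N = %d\n",
              x$k, x$m, x$n, x$N))
  cat(sprintf("  hypergeometric p = %.4g\n", x$p))
  invisible(x)
}

#' Over-representation analysis against a gene-set collection
#'
#' Each set is intersected with the universe, scored with the upper-tail
#' hypergeometric test against the query list, and the p-values are
#' adjusted across sets by Benjamini-Hochberg (`"bonferroni"` available).
#' A set passes when its adjusted q is at or below `fdr_limit`.
#'
#' @param gene_list Character vector of query genes (subset of universe).
#' @param gene_sets A collection from [read_gmt()] or a named list of
#'   character vectors.
#' @param universe Character vector of testable genes.
#' @param fdr_limit Pass threshold on q (default 0.05).
#' @param adjust `"BH"` (default) or `"bonferroni"`.
#' @return Data frame sorted by q then p: `set_name`, `overlap`,
#'   `set_size`, `list_size`, `universe_size`, `p`, `q`, `pass`.
#' @export
ora <- function(gene_list, gene_sets, universe, fdr_limit = 0.05,
                adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% universe)) stop("gene_list must be a subset of the universe")
  gene_sets <- as_gene_set_collection(gene_sets)

  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]$genes), universe)
    if (!length(members)) return(NULL)
    k <- length(intersect(members, gene_list))
    data.frame(set_name = nm, overlap = k, set_size = length(members),
               list_size = length(gene_list), universe_size = length(universe),
               p = hypergeometric_p(k, length(members), length(gene_list),
                                    length(universe)),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped) tm_log("ora: skipped %d set(s) with no members in the universe", skipped)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(set_name = character(0), overlap = integer(0),
                      set_size = integer(0), list_size = integer(0),
                      universe_size = integer(0), p = numeric(0),
                      q = numeric(0), pass = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = if (adjust == "BH") "BH" else "bonferroni")
  out$pass <- out$q <= fdr_limit
  out <- out[order(out$q, out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the cross-cohort report files
#'
#' Emits the ranked overlap table (headline-table schema, via
#' [write_results_table()]), the enrichment table, and a JSON run summary
#' with the record counts of every stage.
#'
#' @param overlap An [intersect_and_score()] result.
#' @param enrichments Optional [ora()] table.
#' @param out_dir Output directory (created if needed).
#' @param counts Optional named list of extra stage counts for the summary.
#' @return Invisibly, the paths written.
#' @export
build_overlap_report <- function(overlap, enrichments = NULL, out_dir = ".",
                                 counts = list()) {
  stopifnot(inherits(overlap, "overlap_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(out_dir, "overlap_genes.tsv")
  rec <- overlap$records
  write_results_table(
    data.frame(gene = rec$gene, p_egwas = rec$p_meta, p_jt = rec$p_trend,
               z_meta = rec$z_meta,
               direction = ifelse(is.na(rec$z_meta), NA,
                                  ifelse(rec$z_meta > 0, "up", "down")),
               stringsAsFactors = FALSE),
    tab_path)
  paths <- tab_path
  if (!is.null(enrichments)) {
    enr_path <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(enrichments, enr_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, enr_path)
  }
  summary_path <- file.path(out_dir, "run_summary.json")
  summary <- c(list(blood_genes = overlap$m, tissue_genes = overlap$n,
                    universe = overlap$N, overlap_k = overlap$k,
                    overlap_p = overlap$p,
                    enriched_sets = if (is.null(enrichments)) 0L else sum(enrichments$pass)),
               counts)
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, summary_path))
}
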