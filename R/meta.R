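#' Bundle one case/control dataset
#'
#' One platform's probe-level matrix, its case/control labels and its
#' probe-to-gene map, as consumed by [egwas_screen()].
#'
#' @param expr Probe-level expression matrix (probes x samples).
#' @param annotation Annotation with `sample_id` and `group`
#'   (`case`/`control`).
#' @param map Probe-to-gene map from [make_probe_gene_map()].
#' @param dataset_id Short identifier for the dataset/platform.
#' @return List of class `case_control_dataset`.
#' @export
case_control_dataset <- function(expr, annotation, map, dataset_id) {
  validate_expression_matrix(expr)
  if (!all(c("sample_id", "group") %in% names(annotation))) {
    stop("annotation must carry 'sample_id' and 'group'")
  }
  ann <- annotation[match(colnames(expr), annotation$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop("every sample must be labeled case or control")
  n_case <- sum(ann$group == "case")
  n_control <- sum(ann$group == "control")
  if (n_case < 2L || n_control < 2L) stop("need >= 2 cases and >= 2 controls")
  structure(list(expr = expr, annotation = ann, map = map,
                 dataset_id = dataset_id,
                 n_case = n_case, n_control = n_control),
            class = "case_control_dataset")
}

# row-wise group summary with NA support
row_group_stats <- function(x, idx) {
  xs <- x[, idx, drop = FALSE]
  n <- rowSums(!is.na(xs))
  m <- rowMeans(xs, na.rm = TRUE)
  v <- rowSums((xs - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = m, var = v)
}

#' Per-probe signed Z-scores from a one-tailed t-test
#'
#' For each probe, a case-vs-control t-test (Welch by default) gives the
#' upper one-tailed p `P(T > t)`, which is converted to a signed Z by the
#' standard-normal quantile: `z = qnorm(1 - p)`. Cases above controls give
#' z > 0, below give z < 0, so direction is encoded without a separate
#' sign step and a null probe has z ~ N(0, 1).
#'
#' @param dataset A [case_control_dataset()].
#' @param t_variant `"welch"` (unequal variance, default) or `"pooled"`.
#' @param min_n Minimum finite observations per group (default 2); probes
#'   below it get `NA`.
#' @return Data frame: `probe_id`, `t`, `df`, `z`, `n_case`, `n_control`,
#'   `degenerate` (zero variance in both groups with equal means, z = 0).
#' @export
dataset_zscores <- function(dataset, t_variant = c("welch", "pooled"),
                            min_n = 2L) {
  t_variant <- match.arg(t_variant)
  stopifnot(inherits(dataset, "case_control_dataset"))
  x <- dataset$expr
  grp <- dataset$annotation$group
  cs <- row_group_stats(x, which(grp == "case"))
  ct <- row_group_stats(x, which(grp == "control"))
  usable <- cs$n >= min_n & ct$n >= min_n
  diff <- cs$mean - ct$mean

  tstat <- df <- rep(NA_real_, nrow(x))
  if (t_variant == "welch") {
    se2 <- cs$var / cs$n + ct$var / ct$n
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((cs$var / cs$n)^2 / (cs$n - 1) + (ct$var / ct$n)^2 / (ct$n - 1))
  } else {
    df <- cs$n + ct$n - 2
    sp2 <- ((cs$n - 1) * cs$var + (ct$n - 1) * ct$var) / df
    tstat <- diff / sqrt(sp2 * (1 / cs$n + 1 / ct$n))
  }

  degenerate <- usable & is.finite(diff) & cs$var == 0 & ct$var == 0 & diff == 0
  p_up <- stats::pt(tstat, df, lower.tail = FALSE)
  # keep z finite: clamp p away from 0/1 (sub-1e-300 tails are off any scale
  # a 2-digit-n microarray test can support)
  p_up <- pmin(pmax(p_up, 1e-300), 1 - 1e-16)
  z <- stats::qnorm(p_up, lower.tail = FALSE)
  z[degenerate] <- 0
  z[!usable] <- NA_real_
  n_low <- sum(!usable)
  if (n_low) tm_log("dataset_zscores[%s]: %d probe(s) below min-n, set NA",
                    dataset$dataset_id, n_low)
  data.frame(probe_id = rownames(x), t = tstat, df = df, z = z,
             n_case = cs$n, n_control = ct$n,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Collapse probe-level Z-scores to gene level
#'
#' Default rule `max_abs_z` keeps, per gene, the probe with the largest
#' absolute Z (best-probe summarization; ties broken by lexically smallest
#' probe id). `median_z` takes the per-gene median instead. Unmapped probes
#' are dropped with a logged count.
#'
#' @param probe_z Named numeric vector of probe Z-scores, or the data frame
#'   from [dataset_zscores()].
#' @param map Probe-to-gene map.
#' @param rule `"max_abs_z"` or `"median_z"`.
#' @return Named numeric vector of per-gene Z-scores.
#' @export
collapse_probes <- function(probe_z, map, rule = c("max_abs_z", "median_z")) {
  rule <- match.arg(rule)
  if (is.data.frame(probe_z)) {
    probe_z <- stats::setNames(probe_z$z, probe_z$probe_id)
  }
  if (!nrow(map)) stop("empty probe-to-gene map")
  gene <- map$gene_id[match(names(probe_z), map$probe_id)]
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    tm_log("collapse_probes: dropped %d unmapped probe(s)", sum(unmapped))
  }
  keep <- !unmapped & !is.na(probe_z)
  z <- probe_z[keep]
  gene <- gene[keep]
  if (!length(z)) return(stats::setNames(numeric(0), character(0)))
  if (rule == "median_z") {
    out <- vapply(split(z, gene), stats::median, numeric(1))
    return(out)
  }
  ord <- order(gene, -abs(z), names(z))
  z <- z[ord]
  gene <- gene[ord]
  first <- !duplicated(gene)
  stats::setNames(z[first], gene[first])
}

#' Combine Z-scores across datasets by the weighted Z-method
#'
#' `Z_meta = sum(w_i z_i) / sqrt(sum(w_i^2))` (Stouffer/Liptak). With any
#' positive weights, `Z_meta ~ N(0, 1)` under the null; the conventional
#' weight is the square root of each dataset's sample size.
#'
#' @param z Numeric vector of per-dataset Z-scores.
#' @param weights Positive weights, same length (default equal).
#' @return The combined Z.
#' @export
weighted_z_combine <- function(z, weights = rep(1, length(z))) {
  if (!length(z)) stop("need at least one Z-score")
  if (length(weights) != length(z)) stop("weights must match z in length")
  if (any(weights <= 0)) stop("weights must be positive")
  sum(weights * z) / sqrt(sum(weights^2))
}

#' Cross-dataset meta-analysis screen (eGWAS style)
#'
#' For each dataset: per-probe one-tailed-t signed Z-scores
#' ([dataset_zscores()]), collapsed to genes ([collapse_probes()]); then
#' per gene the weighted-Z combination over the datasets observing it.
#' Genes with `Z_meta` above the threshold are called up-regulated, below
#' the negated threshold down-regulated.
#'
#' @param datasets List of [case_control_dataset()] objects.
#' @param z_threshold Significance threshold on `|Z_meta|` (default 5).
#' @param weight_scheme `"sqrt_n"` (default) or `"equal"`.
#' @param collapse_rule Passed to [collapse_probes()].
#' @param t_variant Passed to [dataset_zscores()].
#' @return List with `up`, `down` (gene lists) and `table`, a MetaResult
#'   data frame: per-dataset z columns, `n_datasets_observed`, `z_meta`,
#'   one-sided `p_meta`, `significant`, `direction`.
#' @export
egwas_screen <- function(datasets, z_threshold = 5,
                         weight_scheme = c("sqrt_n", "equal"),
                         collapse_rule = c("max_abs_z", "median_z"),
                         t_variant = c("welch", "pooled")) {
  weight_scheme <- match.arg(weight_scheme)
  collapse_rule <- match.arg(collapse_rule)
  t_variant <- match.arg(t_variant)
  if (!length(datasets)) stop("need at least one dataset")
  stopifnot(z_threshold >= 0)

  gene_z <- lapply(datasets, function(ds) {
    collapse_probes(dataset_zscores(ds, t_variant = t_variant), ds$map,
                    rule = collapse_rule)
  })
  w <- vapply(datasets, function(ds) {
    if (weight_scheme == "sqrt_n") sqrt(ds$n_case + ds$n_control) else 1
  }, numeric(1))
  ids <- vapply(datasets, function(ds) ds$dataset_id, character(1))

  genes <- sort(unique(unlist(lapply(gene_z, names))))
  if (!length(genes)) stop("no gene observed in any dataset")
  zmat <- matrix(NA_real_, length(genes), length(datasets),
                 dimnames = list(genes, ids))
  for (d in seq_along(datasets)) zmat[names(gene_z[[d]]), d] <- gene_z[[d]]

  obs <- !is.na(zmat)
  wmat <- matrix(w, nrow(zmat), length(w), byrow = TRUE)
  wmat[!obs] <- 0
  z_meta <- rowSums(wmat * ifelse(obs, zmat, 0)) / sqrt(rowSums(wmat^2))
  p_meta <- stats::pnorm(abs(z_meta), lower.tail = FALSE)

  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (d in seq_along(ids)) tab[[paste0("z_", ids[d])]] <- zmat[, d]
  tab$n_datasets_observed <- rowSums(obs)
  tab$z_meta <- z_meta
  tab$p_meta <- p_meta
  tab$significant <- abs(z_meta) > z_threshold
  tab$direction <- ifelse(z_meta > 0, "up", "down")
  rownames(tab) <- NULL

  list(up = genes[z_meta > z_threshold],
       down = genes[z_meta < -z_threshold],
       table = tab, z_threshold = z_threshold,
       weights = stats::setNames(w, ids))
}

#' Manhattan-style plotting table for meta-analysis results
#'
#' Flattens a MetaResult table into gene / position / Z / -log10(p) /
#' significance columns, ready for any plotting tool. No plotting happens
#' in the package core.
#'
#' @param meta_table The `table` element of [egwas_screen()].
#' @param gene_order Optional character vector giving plotting order;
#'   default alphabetical.
#' @return Data frame with `gene`, `position`, `z_meta`, `neg_log10_p`,
#'   `significant`.
#' @export
manhattan_table <- function(meta_table, gene_order = NULL) {
  if (!nrow(meta_table)) stop("meta table is empty")
  if (is.null(gene_order) || !length(gene_order)) {
    gene_order <- sort(meta_table$gene)
  }
  idx <- match(meta_table$gene, gene_order)
  if (anyNA(idx)) stop("gene_order must cover every gene in the table")
  out <- data.frame(gene = meta_table$gene, position = idx,
                    z_meta = meta_table$z_meta,
                    neg_log10_p = -log10(meta_table$p_meta),
                    significant = meta_table$significant,
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}
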