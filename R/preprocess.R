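#' Construct a two-color array (M/A representation)
#'
#' Per-probe log2 ratio `M = log2(Cy5/Cy3)` and mean log2 intensity
#' `A = (log2(Cy5) + log2(Cy3)) / 2`, the standard representation for
#' within-array normalization of competitive two-dye hybridizations.
#'
#' @param probe_id Character vector of probe ids.
#' @param M Numeric log2 ratios.
#' @param A Numeric mean log2 intensities.
#' @return Data frame of class `two_color_array`.
#' @export
two_color_array <- function(probe_id, M, A) {
  if (length(probe_id) != length(M) || length(M) != length(A)) {
    stop("probe_id, M and A must have equal lengths")
  }
  if (any(is.infinite(M)) || any(is.infinite(A))) {
    stop("M and A must be finite where present")
  }
  structure(data.frame(probe_id = as.character(probe_id), M = M, A = A,
                       stringsAsFactors = FALSE),
            class = c("two_color_array", "data.frame"))
}

#' Within-array loess normalization
#'
#' Removes the intensity-dependent dye bias by subtracting a locally
#' weighted regression of M on A: `M' = M - fhat(A)`; A is unchanged.
#' After normalization the median of M' within any intensity decile is
#' close to zero.
#'
#' @param array A [two_color_array()].
#' @param span Loess span in (0, 1]; default 0.3, the conventional
#'   MA-normalization choice.
#' @return The array with normalized M.
#' @export
loess_normalize_within <- function(array, span = 0.3) {
  stopifnot(inherits(array, "two_color_array"))
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]")
  ok <- is.finite(array$M) & is.finite(array$A)
  if (sum(ok) < 50L) {
    stop("degenerate fit: need >= 50 probes with finite M and A")
  }
  if (stats::sd(array$A[ok]) == 0) {
    warning("constant A: falling back to global median-centering of M")
    array$M[ok] <- array$M[ok] - stats::median(array$M[ok])
    return(array)
  }
  fit <- limma::loessFit(y = array$M[ok], x = array$A[ok], span = span)
  array$M[ok] <- fit$residuals
  array
}

#' Between-array intensity quantile (aquantile) normalization
#'
#' Aligns the A-value distributions across arrays: each array's sorted A
#' is replaced by the across-array mean of the sorted A values (quantile
#' normalization, average-rank tie rule), leaving M untouched. All arrays
#' must share one probe universe.
#'
#' @param arrays List of [two_color_array()] objects (>= 2).
#' @return List of arrays with identical A-quantile functions.
#' @export
aquantile_normalize_between <- function(arrays) {
  if (length(arrays) < 2L) stop("need at least 2 arrays")
  ref <- arrays[[1L]]$probe_id
  for (i in seq_along(arrays)) {
    missing <- setdiff(ref, arrays[[i]]$probe_id)
    extra <- setdiff(arrays[[i]]$probe_id, ref)
    if (length(missing) || length(extra)) {
      stop("probe universes differ (array ", i, "): missing ",
           paste(utils::head(missing, 5L), collapse = ", "),
           if (length(extra)) paste0("; extra ", paste(utils::head(extra, 5L), collapse = ", ")))
    }
  }
  A <- vapply(arrays, function(a) a$A[match(ref, a$probe_id)],
              numeric(length(ref)))
  Anorm <- limma::normalizeQuantiles(A, ties = TRUE)
  for (i in seq_along(arrays)) {
    ord <- match(arrays[[i]]$probe_id, ref)
    arrays[[i]]$A <- Anorm[ord, i]
  }
  arrays
}

#' Flag outlier samples on the first two principal components
#'
#' Computes a sample PCA on centered and scaled genes, robustly
#' standardizes the (PC1, PC2) scores (median/MAD per axis) and flags
#' samples whose Euclidean distance from the robust centroid exceeds
#' `threshold_sd`. Flagging is reported, never applied: removal is a
#' separate, logged decision by the analyst.
#'
#' @param mat Expression matrix (genes x samples); missing values are
#'   mean-imputed per gene for the PCA only.
#' @param threshold_sd Distance threshold in robust SD units (default 4).
#' @return List of class `qc_report`: `pca` (sample scores), `flagged`
#'   (sample ids), `threshold_sd`, `dropped_genes` (zero variance).
#' @export
flag_outliers_pca <- function(mat, threshold_sd = 4) {
  validate_expression_matrix(mat)
  if (ncol(mat) < 4L) stop("need at least 4 samples for PCA outlier flagging")
  x <- mat
  if (anyNA(x)) {
    rm_ <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- rm_[idx[, 1L]]
  }
  v <- apply(x, 1L, stats::var)
  dropped <- rownames(x)[!is.finite(v) | v == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance gene(s) dropped before PCA")
    x <- x[is.finite(v) & v > 0, , drop = FALSE]
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = TRUE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  zs <- apply(sc, 2L, function(col) {
    s <- stats::mad(col)
    if (s == 0) s <- stats::sd(col)
    if (s == 0) return(rep(0, length(col)))
    (col - stats::median(col)) / s
  })
  d <- sqrt(rowSums(zs^2))
  flagged <- colnames(mat)[d > threshold_sd]
  structure(list(pca = data.frame(sample_id = colnames(mat),
                                  PC1 = sc[, 1L],
                                  PC2 = if (ncol(sc) > 1L) sc[, 2L] else 0,
                                  distance = d,
                                  stringsAsFactors = FALSE),
                 flagged = flagged, threshold_sd = threshold_sd,
                 dropped_genes = dropped),
            class = "qc_report")
}

#' One-way ANOVA gene filter
#'
#' Classical equal-variance one-way fixed-effects ANOVA per gene; genes
#' with `p < alpha` pass. Genes constant across all samples have an
#' undefined F and are excluded with a warning.
#'
#' @param mat Expression matrix (genes x samples).
#' @param groups Factor of group labels aligned to the columns (>= 2
#'   groups, each with >= 2 samples).
#' @param alpha Significance cut (default 0.05).
#' @return List with `pass` (character gene list) and `table` (gene, F,
#'   p).
#' @export
anova_filter <- function(mat, groups, alpha = 0.05) {
  validate_expression_matrix(mat)
  groups <- droplevels(as.factor(groups))
  if (length(groups) != ncol(mat)) stop("groups must match the sample columns")
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L)) stop("every group needs >= 2 samples")
  k <- length(sizes)
  N <- ncol(mat)

  gm <- rowMeans(mat)
  ss_tot <- rowSums((mat - gm)^2)
  ssb <- 0
  for (lv in levels(groups)) {
    idx <- groups == lv
    ssb <- ssb + sum(idx) * (rowMeans(mat[, idx, drop = FALSE]) - gm)^2
  }
  ssw <- ss_tot - ssb
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)

  constant <- ss_tot == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) excluded (undefined F)")
    Fstat[constant] <- NA_real_
    p[constant] <- NA_real_
  }
  tab <- data.frame(gene = rownames(mat), F = Fstat, p = p,
                    stringsAsFactors = FALSE)
  list(pass = tab$gene[!is.na(p) & p < alpha], table = tab, alpha = alpha)
}

#' Deterministic hierarchical clustering of samples
#'
#' Agglomerative clustering of samples on a gene subset. Samples are
#' ordered lexically by id before the distance computation so the tree
#' (including tie-breaks) does not depend on input column order.
#'
#' @param mat Expression matrix (genes x samples).
#' @param gene_subset Character vector of genes to cluster on (e.g. the
#'   ANOVA pass list); default all genes.
#' @param linkage hclust agglomeration method (default `"average"`).
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson).
#' @return An [stats::hclust] tree with merge heights.
#' @export
hierarchical_cluster <- function(mat, gene_subset = rownames(mat),
                                 linkage = "average",
                                 distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  validate_expression_matrix(mat)
  if (!length(gene_subset)) stop("gene subset is empty")
  miss <- setdiff(gene_subset, rownames(mat))
  if (length(miss)) stop("unknown gene(s) in subset: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  x <- mat[gene_subset, order(colnames(mat)), drop = FALSE]
  d <- if (distance == "euclidean") {
    stats::dist(t(x))
  } else {
    stats::as.dist(1 - stats::cor(x))
  }
  stats::hclust(d, method = linkage)
}
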