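#' Read an expression matrix from a delimited text file
#'
#' Reads a TSV/CSV matrix with one header row of sample identifiers and a
#' first column of feature identifiers (probes or gene symbols). Lines
#' beginning with `!` (the GEO series-matrix metadata dialect) are skipped,
#' so the table body of a series-matrix file parses identically to a plain
#' TSV. Values are log2-scale expression; empty cells, `NA` and `NaN` are
#' treated as missing.
#'
#' @param path Path to the file.
#' @param orientation `"features_rows"` (default, canonical storage) if rows
#'   are features, `"samples_rows"` if the file stores samples as rows; the
#'   returned matrix is always features x samples.
#' @param feature_kind `"gene"` or `"probe"`; recorded as an attribute.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return Numeric matrix, features as rows, samples as columns, with
#'   attribute `feature_kind`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_rows", "samples_rows"),
                                   feature_kind = c("gene", "probe"),
                                   sep = NULL) {
  orientation <- match.arg(orientation)
  feature_kind <- match.arg(feature_kind)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("malformed file '", path, "': need a header line and at least one data row")
  }
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(
    text = lines, sep = sep, header = TRUE, check.names = FALSE,
    stringsAsFactors = FALSE, quote = "\"", comment.char = "",
    colClasses = "character"
  )
  if (ncol(df) < 2L) stop("malformed header in '", path, "': fewer than 2 columns")
  col_ids <- colnames(df)[-1L]
  if (anyDuplicated(col_ids) || any(!nzchar(col_ids))) {
    stop("malformed header in '", path, "': column ids must be unique and non-empty")
  }
  row_ids <- df[[1L]]
  if (anyDuplicated(row_ids)) {
    dup <- unique(row_ids[duplicated(row_ids)])
    stop("duplicate feature id(s) in '", path, "': ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  missing_tok <- raw == "" | raw == "NA" | raw == "NaN" | is.na(raw)
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  num[raw == "NaN"] <- NA_real_
  bad <- which(!missing_tok & is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s' in '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]], row_ids[bad[1L, 1L]],
                 col_ids[bad[1L, 2L]], path))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "samples_rows") num <- t(num)
  validate_expression_matrix(num)
  attr(num, "feature_kind") <- feature_kind
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: feature ids in the first column
#' (`feature_id` header), one column per sample. `read(write(x))`
#' round-trips exactly at the written precision.
#'
#' @param x Numeric matrix, features x samples.
#' @param path Output path.
#' @param digits Significant digits written (default 10).
#' @export
write_expression_matrix <- function(x, path, digits = 10L) {
  validate_expression_matrix(x)
  df <- data.frame(feature_id = rownames(x),
                   signif(x, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 2L) stop("need at least 1 feature and 2 samples")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop("feature ids must be present and unique")
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop("sample ids must be present and unique")
  }
  if (any(is.infinite(x))) stop("values must be finite or missing (NA)")
  invisible(TRUE)
}

#' Read a sample annotation table
#'
#' TSV with a `sample_id` column and optionally `stage` (ordered clinical
#' stage) and/or `group` (`case`/`control`); any further columns are kept as
#' covariates. The stage ordering must be supplied explicitly and total.
#'
#' @param path Path to the TSV file.
#' @param stage_levels Ordered character vector of stage labels, least to
#'   most severe. Defaults to [dkd_stages].
#' @return `data.frame` with `stage` as an ordered factor when present.
#' @export
read_sample_annotation <- function(path, stage_levels = dkd_stages) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  make_sample_annotation(df, stage_levels)
}

#' Construct/validate a sample annotation data frame
#'
#' @param df Data frame with `sample_id` and optionally `stage`, `group`.
#' @param stage_levels Ordered stage labels (see [read_sample_annotation()]).
#' @export
make_sample_annotation <- function(df, stage_levels = dkd_stages) {
  if (!"sample_id" %in% names(df)) stop("annotation must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  if ("stage" %in% names(df)) {
    unknown <- setdiff(unique(as.character(df$stage)), stage_levels)
    if (length(unknown)) {
      stop("stage value(s) not in the declared ordering: ",
           paste(unknown, collapse = ", "))
    }
    df$stage <- factor(as.character(df$stage), levels = stage_levels, ordered = TRUE)
  }
  if ("group" %in% names(df)) {
    bad <- setdiff(unique(as.character(df$group)), c("case", "control"))
    if (length(bad)) stop("group must be 'case' or 'control'; saw: ",
                          paste(bad, collapse = ", "))
    df$group <- factor(as.character(df$group), levels = c("case", "control"))
  }
  df
}

#' Write a sample annotation table as TSV
#' @param annotation Data frame from [make_sample_annotation()].
#' @param path Output path.
#' @export
write_sample_annotation <- function(annotation, path) {
  out <- annotation
  for (cl in names(out)) if (is.factor(out[[cl]])) out[[cl]] <- as.character(out[[cl]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-gene map
#'
#' TSV with columns `probe_id` and `gene_id`. Many probes may map to one
#' gene; each probe maps to at most one gene. Probes with an empty/NA gene
#' are kept and flagged as unmapped.
#'
#' @param path Path to the TSV file.
#' @param namespace Label for the gene-id namespace (e.g. `"entrez"`,
#'   `"symbol"`); informational.
#' @export
read_probe_gene_map <- function(path, namespace = "symbol") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  make_probe_gene_map(df, namespace)
}

#' Construct/validate a probe-to-gene map
#' @param df Data frame with `probe_id`, `gene_id` columns.
#' @param namespace Gene-id namespace label.
#' @export
make_probe_gene_map <- function(df, namespace = "symbol") {
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    stop("probe map must have 'probe_id' and 'gene_id' columns")
  }
  if (anyDuplicated(df$probe_id)) {
    stop("each probe must map to at most one gene (duplicated probe_id)")
  }
  df$gene_id <- as.character(df$gene_id)
  df$gene_id[!nzchar(df$gene_id) | df$gene_id == "NA"] <- NA_character_
  n_unmapped <- sum(is.na(df$gene_id))
  if (n_unmapped) tm_log("probe map: %d unmapped probe(s)", n_unmapped)
  attr(df, "namespace") <- namespace
  df
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB member TAB
#' member ...`. Duplicated members within a set are collapsed with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return Named list; each element is `list(description=, genes=)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(list(), class = "gene_set_collection"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields", i))
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf("GMT set '%s': duplicated member(s) collapsed", f[[1L]]))
      members <- unique(members)
    }
    if (!length(members)) stop(sprintf("GMT set '%s' (line %d) has no members", f[[1L]], i))
    nms[i] <- f[[1L]]
    sets[[i]] <- list(description = f[[2L]], genes = members)
  }
  if (anyDuplicated(nms)) stop("GMT set names must be unique")
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets Collection from [read_gmt()] or a named list of character
#'   vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  sets <- as_gene_set_collection(sets)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# accept either the class or a plain named list of gene vectors
as_gene_set_collection <- function(sets) {
  if (inherits(sets, "gene_set_collection")) return(sets)
  if (!is.list(sets) || is.null(names(sets))) stop("gene sets must be a named list")
  out <- lapply(names(sets), function(nm) {
    el <- sets[[nm]]
    if (is.character(el)) list(description = "", genes = el) else el
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection")
}

#' Write a ranked results table (headline-table schema)
#'
#' Fixed column order `gene`, `description`, `p_egwas`, `p_jt`, `z_meta`,
#' `direction`; p-values rendered in scientific notation with 4 significant
#' digits (e.g. `3.345E-10`). `gene`, `p_egwas` and `p_jt` are mandatory;
#' the rest are filled with placeholders when absent.
#'
#' @param records Data frame with at least `gene`, `p_egwas`, `p_jt`.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  mandatory <- c("gene", "p_egwas", "p_jt")
  miss <- setdiff(mandatory, names(records))
  if (length(miss)) {
    stop("results schema error: missing mandatory field(s): ",
         paste(miss, collapse = ", "))
  }
  n <- nrow(records)
  out <- data.frame(
    gene = as.character(records$gene),
    description = if ("description" %in% names(records)) {
      as.character(records$description)
    } else rep("", n),
    p_egwas = format_pvalue(records$p_egwas),
    p_jt = format_pvalue(records$p_jt),
    z_meta = if ("z_meta" %in% names(records)) {
      sprintf("%.4f", records$z_meta)
    } else rep("NA", max(n, 0L)),
    direction = if ("direction" %in% names(records)) {
      as.character(records$direction)
    } else rep("NA", max(n, 0L)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

format_pvalue <- function(p) {
  out <- toupper(formatC(p, format = "e", digits = 3))
  out[!is.finite(p)] <- "NA"
  out
}

#' Read back a results table written by [write_results_table()]
#' @param path Path to the TSV file.
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in c("p_egwas", "p_jt", "z_meta")) {
    if (cl %in% names(df)) df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  }
  df
}

#' Write a machine-readable run log
#'
#' Records the configuration, seed, input-file checksums and per-stage
#' record counts of a pipeline run, so that any result file can be traced
#' back to its inputs and replayed.
#'
#' @param path Output JSON path.
#' @param config An [analysis_config()] (or any list).
#' @param inputs Character vector of input file paths (md5-checksummed).
#' @param counts Named list/vector of per-stage record counts.
#' @export
write_run_log <- function(path, config = list(), inputs = character(),
                          counts = list()) {
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = unclass(config), input_md5 = sums, counts = counts)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
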