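#' Analysis configuration
#'
#' Bundles the tunable thresholds of the pipeline with validation, so a run
#' is fully described by one serializable object.
#'
#' @param alpha_trend Per-gene screening alpha for the trend test (raw,
#'   unadjusted, as in the headline screen). Default 0.05.
#' @param z_threshold Meta-analysis significance threshold on the combined
#'   Z-score (genes with `|Z| >` this are called). Default 5.
#' @param weight_scheme `"sqrt_n"` (weight each dataset by the square root
#'   of its total sample size; standard weighted-Z choice) or `"equal"`.
#' @param probe_collapse_rule `"max_abs_z"` (best-probe summarization,
#'   default) or `"median_z"`.
#' @param trend_stage_set Ordered stages entering the trend ranking;
#'   default the albuminuria stages `D1 < D2 < D3`.
#' @param fdr_limit BH-FDR limit for over-representation analysis.
#'   Default 0.05.
#' @param seed Integer seed recorded in every output; `NULL` means the
#'   caller must supply one at run time.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(alpha_trend = 0.05,
                            z_threshold = 5,
                            weight_scheme = c("sqrt_n", "equal"),
                            probe_collapse_rule = c("max_abs_z", "median_z"),
                            trend_stage_set = c("D1", "D2", "D3"),
                            fdr_limit = 0.05,
                            seed = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  probe_collapse_rule <- match.arg(probe_collapse_rule)
  stopifnot(is.numeric(alpha_trend), length(alpha_trend) == 1L,
            alpha_trend > 0, alpha_trend < 1)
  stopifnot(is.numeric(z_threshold), length(z_threshold) == 1L, z_threshold > 0)
  stopifnot(is.numeric(fdr_limit), fdr_limit > 0, fdr_limit <= 1)
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(!is.na(seed))
  }
  structure(list(alpha_trend = alpha_trend, z_threshold = z_threshold,
                 weight_scheme = weight_scheme,
                 probe_collapse_rule = probe_collapse_rule,
                 trend_stage_set = trend_stage_set,
                 fdr_limit = fdr_limit, seed = seed),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' A flat key/value document; keys not present fall back to the
#' [analysis_config()] defaults, and `...` overrides file values (the CLI
#' passes its flags here).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   pure defaults.
#' @param ... Overrides applied after the file is read.
#' @export
read_config <- function(path = NULL, ...) {
  vals <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    vals <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
    vals <- vals[intersect(names(vals), known)]
  }
  do.call(analysis_config, vals)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = " < ")))
  }
  invisible(x)
}
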