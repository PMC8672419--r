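#' Jonckheere-Terpstra statistic
#'
#' Sum of pairwise Mann-Whitney counts over all ordered group pairs:
#' `J = sum_{i<j} sum_{x in group i, y in group j} [1(x < y) + 0.5 * 1(x == y)]`.
#' Large J means values tend to increase along the declared group ordering;
#' J is invariant to any strictly increasing transform of the values.
#'
#' @param values Numeric vector.
#' @param groups Ordered factor (or integer codes) of the same length;
#'   factor level order defines the hypothesized ordering.
#' @return The statistic J (multiples of 0.5 when ties are present).
#' @export
jt_statistic <- function(values, groups) {
  g <- as_group_codes(groups)
  k <- length(attr(g, "k_levels"))
  keep <- !is.na(values) & !is.na(g)
  n_drop <- sum(!keep)
  if (n_drop) tm_log("jt_statistic: dropped %d observation(s) with missing data", n_drop)
  values <- values[keep]
  g <- g[keep]
  sizes <- tabulate(g, nbins = k)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  if (k < 2L) stop("need at least 2 ordered groups")
  jt_core(values, g, k)
}

as_group_codes <- function(groups) {
  if (is.factor(groups)) {
    codes <- as.integer(groups)
    attr(codes, "k_levels") <- levels(groups)
  } else if (is.numeric(groups)) {
    u <- sort(unique(groups[!is.na(groups)]))
    codes <- match(groups, u)
    attr(codes, "k_levels") <- as.character(u)
  } else {
    stop("groups must be an (ordered) factor or integer codes")
  }
  codes
}

# J on clean data (no NA, groups coded 1..k, all present)
jt_core <- function(values, g, k) {
  J <- 0
  for (i in seq_len(k - 1L)) {
    xi <- values[g == i]
    yj <- values[g > i]
    # Mann-Whitney count of group i against all later groups at once
    J <- J + sum(vapply(xi, function(x) {
      sum(yj > x) + 0.5 * sum(yj == x)
    }, numeric(1)))
  }
  J
}

#' Null mean and (tie-corrected) variance of the JT statistic
#'
#' Under the permutation null `E[J] = (N^2 - sum n_i^2) / 4` and, without
#' ties, `Var[J] = (N^2 (2N + 3) - sum n_i^2 (2 n_i + 3)) / 72`. With ties
#' the exact permutation variance uses the tie-group multiplicities
#' (standard three-term correction); it equals the empirical moments of the
#' full enumeration.
#'
#' @param group_sizes Integer vector of group sizes (k >= 2).
#' @param tie_counts Multiplicities of tied value groups (defaults to no
#'   ties, i.e. all 1); must sum to `sum(group_sizes)`.
#' @return List with `E_J` and `Var_J`.
#' @export
jt_null_moments <- function(group_sizes, tie_counts = NULL) {
  n <- as.numeric(group_sizes)
  if (length(n) < 2L) stop("need at least 2 ordered groups")
  if (any(n < 1)) stop("all group sizes must be >= 1")
  N <- sum(n)
  if (is.null(tie_counts)) tie_counts <- rep(1, N)
  tc <- as.numeric(tie_counts)
  if (sum(tc) != N) stop("tie_counts must sum to the total sample size")
  E_J <- (N^2 - sum(n^2)) / 4
  t1 <- (N * (N - 1) * (2 * N + 5) -
           sum(n * (n - 1) * (2 * n + 5)) -
           sum(tc * (tc - 1) * (2 * tc + 5))) / 72
  num2 <- sum(n * (n - 1) * (n - 2)) * sum(tc * (tc - 1) * (tc - 2))
  t2 <- if (num2 == 0) 0 else num2 / (36 * N * (N - 1) * (N - 2))
  t3 <- sum(n * (n - 1)) * sum(tc * (tc - 1)) / (8 * N * (N - 1))
  Var_J <- t1 + t2 + t3
  if (Var_J < 0 && Var_J > -1e-9) Var_J <- 0
  list(E_J = E_J, Var_J = Var_J)
}

# multiplicities of tied values
tie_pattern <- function(values) as.numeric(table(values))

# enumerate J over all distinct assignments of `values` to ordered groups of
# the given sizes; returns the vector of J* (each equally likely under the
# permutation null). Cost is the multinomial coefficient.
jt_enumerate <- function(values, sizes) {
  N <- length(values)
  stopifnot(sum(sizes) == N)
  cmp <- outer(values, values, function(a, b) (a < b) + 0.5 * (a == b))
  total <- round(exp(log_multinomial(sizes)))
  res <- numeric(total)
  pos <- 0L
  recurse <- function(remaining, gi, j_acc, assigned) {
    if (gi == length(sizes)) {
      # last group is forced
      add <- if (length(assigned)) sum(cmp[assigned, remaining, drop = FALSE]) else 0
      pos <<- pos + 1L
      res[pos] <<- j_acc + add
      return(invisible(NULL))
    }
    picks <- utils::combn(length(remaining), sizes[gi], simplify = FALSE)
    for (p in picks) {
      sel <- remaining[p]
      add <- if (length(assigned)) sum(cmp[assigned, sel, drop = FALSE]) else 0
      recurse(remaining[-p], gi + 1L, j_acc + add, c(assigned, sel))
    }
  }
  recurse(seq_len(N), 1L, 0, integer(0))
  res[seq_len(pos)]
}

log_multinomial <- function(sizes) {
  lfactorial(sum(sizes)) - sum(lfactorial(sizes))
}

#' Jonckheere-Terpstra trend test
#'
#' One-sided test for a monotone shift in location along an ordered set of
#' groups. Three computation methods: `exact` (full enumeration of the
#' permutation null; allowed when the multinomial partition count is at
#' most 1e6), `montecarlo` (permutation with the add-one estimator
#' `(b + 1) / (n_perm + 1)`, so p is never 0), and `asymptotic` (normal
#' approximation with the tie-corrected variance, no continuity
#' correction). `method = "auto"` picks exact for tiny problems, Monte
#' Carlo when ties are heavy (> 20% tied values) in a small sample, and
#' asymptotic otherwise.
#'
#' @param values Numeric vector.
#' @param groups Ordered factor or integer codes (level order = hypothesis
#'   order).
#' @param direction `"increasing"` (large J extreme) or `"decreasing"`.
#' @param method `"asymptotic"`, `"exact"`, `"montecarlo"` or `"auto"`.
#' @param n_perm Number of Monte-Carlo permutations (default 10000).
#' @param seed Seed for the Monte-Carlo method.
#' @return List of class `jt_test`: `J`, `E_J`, `Var_J`, `z`, `p`,
#'   `direction`, `method`, `group_sizes`, `degenerate` and, for Monte
#'   Carlo, `n_perm`/`seed`. Degenerate cases (zero permutation variance,
#'   e.g. all values tied) are flagged with `p = 1`.
#' @export
jt_test <- function(values, groups,
                    direction = c("increasing", "decreasing"),
                    method = c("asymptotic", "exact", "montecarlo", "auto"),
                    n_perm = 10000L, seed = NULL) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  g <- as_group_codes(groups)
  keep <- !is.na(values) & !is.na(g)
  values <- values[keep]
  gk <- g[keep]
  k <- length(attr(g, "k_levels"))
  sizes <- tabulate(gk, nbins = k)
  if (any(sizes == 0L)) stop("every group must be non-empty")
  if (k < 2L) stop("need at least 2 ordered groups")
  N <- sum(sizes)

  J <- jt_core(values, gk, k)
  tc <- tie_pattern(values)
  mom <- jt_null_moments(sizes, tc)
  degenerate <- mom$Var_J <= 0

  if (method == "auto") {
    tie_frac <- 1 - length(tc) / N
    method <- if (log_multinomial(sizes) <= log(5000)) {
      "exact"
    } else if (tie_frac > 0.2 && N <= 25) {
      "montecarlo"
    } else {
      "asymptotic"
    }
  }

  z <- if (degenerate) NA_real_ else (J - mom$E_J) / sqrt(mom$Var_J)
  res <- list(J = J, E_J = mom$E_J, Var_J = mom$Var_J, z = z,
              direction = direction, method = method,
              group_sizes = sizes, degenerate = degenerate)

  if (degenerate) {
    res$p <- 1
    class(res) <- "jt_test"
    return(res)
  }

  if (method == "exact") {
    if (log_multinomial(sizes) > log(1e6)) {
      stop("exact enumeration over budget (> 1e6 partitions); use method = 'montecarlo'")
    }
    Jstar <- jt_enumerate(values, sizes)
    res$p <- if (direction == "increasing") {
      mean(Jstar >= J - 1e-9)
    } else {
      mean(Jstar <= J + 1e-9)
    }
  } else if (method == "montecarlo") {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (r in seq_len(n_perm)) {
      Jp <- jt_core(sample(values), gk, k)
      hit <- if (direction == "increasing") Jp >= J - 1e-9 else Jp <= J + 1e-9
      b <- b + hit
    }
    res$p <- (b + 1) / (n_perm + 1)
    res$n_perm <- n_perm
    res$seed <- seed
  } else {
    res$p <- if (direction == "increasing") {
      stats::pnorm(z, lower.tail = FALSE)
    } else {
      stats::pnorm(z, lower.tail = TRUE)
    }
    if (res$p <= 0) res$p <- .Machine$double.xmin
  }
  class(res) <- "jt_test"
  res
}

#' @export
print.jt_test <- function(x, ...) {
  cat(sprintf("Jonckheere-Terpstra trend test (%s, %s)\n", x$method, x$direction))
  cat(sprintf("  groups n = %s; J = %.1f, E[J] = %.2f, Var[J] = %.4f\n",
              paste(x$group_sizes, collapse = "/"), x$J, x$E_J, x$Var_J))
  cat(sprintf("  z = %.4f, p = %.4g%s\n", x$z, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Screen an expression matrix for ordered-stage trends
#'
#' Runs the JT test gene by gene across the declared clinical-stage
#' ordering and splits significant genes into an increasing ("up") and a
#' decreasing ("down") list. Each gene is assigned the direction with the
#' smaller one-sided p and then thresholded at `alpha`, so the two lists
#' are always disjoint. p-values are raw (the screen is a ranking, as in
#' the headline counts); BH-adjusted columns are included for information.
#'
#' @param mat Expression matrix (genes x samples).
#' @param annotation Sample annotation with `sample_id` and ordered `stage`.
#' @param stage_set Ordered character vector of stages to use; `NULL`
#'   (default) uses every stage level present in the annotation, in its
#'   declared order. The headline-table convention is `c("D1","D2","D3")`.
#' @param alpha Screening alpha on the one-sided p (default 0.05).
#' @param method JT method passed to [jt_test()] (default asymptotic).
#' @param n_perm,seed Monte-Carlo controls when `method = "montecarlo"`.
#' @return List with `up`, `down` (character gene lists), `table` (per-gene
#'   TrendResult data frame) and `skipped` (genes with insufficient data).
#' @export
trend_screen <- function(mat, annotation, stage_set = NULL, alpha = 0.05,
                         method = c("asymptotic", "exact", "montecarlo", "auto"),
                         n_perm = 10000L, seed = NULL) {
  method <- match.arg(method)
  validate_expression_matrix(mat)
  if (!all(c("sample_id", "stage") %in% names(annotation))) {
    stop("annotation must carry 'sample_id' and 'stage'")
  }
  ann <- annotation[match(colnames(mat), annotation$sample_id), , drop = FALSE]
  if (anyNA(ann$sample_id)) stop("every matrix sample must be annotated")
  lv <- levels(ann$stage)
  if (is.null(stage_set)) stage_set <- lv[lv %in% unique(as.character(ann$stage))]
  if (!all(stage_set %in% lv)) stop("stage_set contains unknown stages")
  use <- as.character(ann$stage) %in% stage_set
  if (length(unique(as.character(ann$stage)[use])) < 2L) {
    stop("need at least 2 stages present among the samples")
  }
  sub <- mat[, use, drop = FALSE]
  stage <- factor(as.character(ann$stage)[use], levels = stage_set, ordered = TRUE)
  g <- as.integer(stage)
  k <- length(stage_set)

  n_genes <- nrow(sub)
  J <- E_J <- Var_J <- z <- p_inc <- p_dec <- rep(NA_real_, n_genes)
  degen <- rep(FALSE, n_genes)
  skipped <- character(0)

  for (i in seq_len(n_genes)) {
    v <- sub[i, ]
    ok <- !is.na(v)
    gi <- g[ok]
    if (length(unique(gi)) < 2L) {
      skipped <- c(skipped, rownames(sub)[i])
      next
    }
    vi <- v[ok]
    sizes <- tabulate(gi, nbins = k)
    present <- sizes > 0L
    # re-code to consecutive groups if a stage lost all samples to NA
    gi2 <- match(gi, which(present))
    sizes <- sizes[present]
    Ji <- jt_core(vi, gi2, length(sizes))
    mom <- jt_null_moments(sizes, tie_pattern(vi))
    J[i] <- Ji; E_J[i] <- mom$E_J; Var_J[i] <- mom$Var_J
    if (mom$Var_J <= 0) {
      degen[i] <- TRUE
      p_inc[i] <- p_dec[i] <- 1
      next
    }
    if (method == "asymptotic") {
      z[i] <- (Ji - mom$E_J) / sqrt(mom$Var_J)
      p_inc[i] <- stats::pnorm(z[i], lower.tail = FALSE)
      p_dec[i] <- stats::pnorm(z[i], lower.tail = TRUE)
    } else {
      up <- jt_test(vi, gi2, "increasing", method, n_perm = n_perm, seed = seed)
      dn <- jt_test(vi, gi2, "decreasing", method, n_perm = n_perm, seed = seed)
      z[i] <- up$z
      p_inc[i] <- up$p
      p_dec[i] <- dn$p
    }
  }

  tested <- !is.na(p_inc)
  tab <- data.frame(
    gene = rownames(sub), J = J, E_J = E_J, Var_J = Var_J, z = z,
    p_increasing = p_inc, p_decreasing = p_dec,
    q_increasing = NA_real_, q_decreasing = NA_real_,
    direction = ifelse(p_inc <= p_dec, "increasing", "decreasing"),
    degenerate = degen, stringsAsFactors = FALSE
  )
  tab$q_increasing[tested] <- stats::p.adjust(p_inc[tested], method = "BH")
  tab$q_decreasing[tested] <- stats::p.adjust(p_dec[tested], method = "BH")
  tab$direction[degen | !tested] <- NA_character_

  callable <- tested & !degen
  up <- tab$gene[callable & tab$direction == "increasing" & tab$p_increasing < alpha]
  down <- tab$gene[callable & tab$direction == "decreasing" & tab$p_decreasing < alpha]
  if (length(skipped)) {
    tm_log("trend_screen: skipped %d gene(s) with < 2 informative stages", length(skipped))
  }
  list(up = up, down = down, table = tab, skipped = skipped,
       stage_set = stage_set, alpha = alpha, method = method)
}
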