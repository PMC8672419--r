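# Independent oracles used to freeze expected values. These deliberately
# share no code with the package implementations they check.

# JT statistic by direct double loop over sample pairs
oracle_jt_J <- function(values, labels) {
  J <- 0
  N <- length(values)
  for (a in seq_len(N)) {
    for (b in seq_len(N)) {
      if (labels[a] < labels[b]) {
        J <- J + (values[a] < values[b]) + 0.5 * (values[a] == values[b])
      }
    }
  }
  J
}

# all distinct permutations of a label multiset (rows of a matrix)
multiset_label_perms <- function(labels) {
  if (length(labels) <= 1L) return(matrix(labels, nrow = 1L))
  u <- unique(labels)
  do.call(rbind, lapply(u, function(v) {
    rest <- labels[-match(v, labels)]
    cbind(v, multiset_label_perms(rest))
  }))
}

# full-enumeration permutation null of J: one J* per equally likely
# assignment of the observed values to the ordered groups
oracle_jt_null <- function(values, sizes) {
  labels <- rep(seq_along(sizes), sizes)
  perms <- multiset_label_perms(labels)
  lt <- outer(values, values, function(a, b) (a < b) + 0.5 * (a == b))
  apply(perms, 1L, function(l) sum(lt * outer(l, l, "<")))
}

# survival function of the t distribution with 2 df, in closed form
oracle_t2_surv <- function(t) 0.5 * (1 - t / sqrt(t^2 + 2))

# upper-tail hypergeometric by direct combinatorial sum
oracle_hyper <- function(k, m, n, N) {
  if (k <= 0) return(1)
  j <- k:min(m, n)
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

# Benjamini-Hochberg step-up by hand
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# random small JT dataset (with or without ties), group sizes kept small
# enough that full enumeration is instant
random_jt_dataset <- function(with_ties) {
  k <- sample(2:3, 1L)
  repeat {
    sizes <- sample(1:4, k, replace = TRUE)
    if (sum(sizes) <= 8L && sum(sizes) >= 4L) break
  }
  N <- sum(sizes)
  values <- if (with_ties) sample(1:3, N, replace = TRUE) else rnorm(N)
  list(values = values, sizes = sizes,
       groups = factor(rep(seq_len(k), sizes), ordered = TRUE))
}

# small two-cohort annotation/matrix builders for pipeline tests
tiny_stage_cohort <- function(n_genes = 200, seed = 1) {
  design <- simulation_design(n_genes = n_genes, n_trend_genes = 20,
                              n_overlap_genes = 0, n_de_genes = 20,
                              seed = seed)
  simulate_pbmc_cohort(design)
}
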