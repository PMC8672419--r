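test_that("JT statistic matches its definition on anchored cases", {
  g <- factor(rep(1:3, each = 2), ordered = TRUE)
  expect_equal(jt_statistic(c(1, 2, 3, 4, 5, 6), g), 12)   # perfectly ordered
  expect_equal(jt_statistic(c(5, 6, 3, 4, 1, 2), g), 0)    # anti-ordered
  expect_equal(jt_statistic(rep(1, 6), g), 6)              # all half-ties = E[J]
  # random data agrees with the double-loop oracle
  withr::with_seed(1, {
    for (r in 1:25) {
      d <- random_jt_dataset(with_ties = r %% 2 == 0)
      expect_equal(jt_statistic(d$values, d$groups),
                   oracle_jt_J(d$values, as.integer(d$groups)))
    }
  })
})

test_that("JT statistic is invariant to strictly monotone transforms", {
  withr::with_seed(2, {
    for (r in 1:10) {
      d <- random_jt_dataset(with_ties = r %% 2 == 0)
      J <- jt_statistic(d$values, d$groups)
      expect_equal(jt_statistic(exp(d$values), d$groups), J)
      expect_equal(jt_statistic(2 * d$values + 5, d$groups), J)
      t1 <- jt_test(d$values, d$groups, "increasing", "asymptotic")
      t2 <- jt_test(exp(d$values), d$groups, "increasing", "asymptotic")
      expect_equal(t1$p, t2$p)
    }
  })
})

test_that("reversal symmetry: J(order) + J(reversed order) = sum n_i n_j", {
  withr::with_seed(3, {
    for (r in 1:10) {
      d <- random_jt_dataset(with_ties = r %% 2 == 0)
      k <- length(d$sizes)
      rev_groups <- factor(k + 1L - as.integer(d$groups), ordered = TRUE)
      total_pairs <- (sum(d$sizes)^2 - sum(d$sizes^2)) / 2
      expect_equal(jt_statistic(d$values, d$groups) +
                     jt_statistic(d$values, rev_groups),
                   total_pairs)
    }
  })
})

test_that("null moments match formulas and enumeration, ties included", {
  m <- jt_null_moments(c(2, 2, 2))
  expect_equal(m$E_J, 6)
  expect_equal(m$Var_J, 456 / 72)
  expect_error(jt_null_moments(5), "at least 2")
  # all values tied: zero permutation variance
  expect_equal(jt_null_moments(c(2, 2, 2), tie_counts = 6)$Var_J, 0)
  # tie-corrected variance equals the empirical enumeration moments
  withr::with_seed(4, {
    for (r in 1:15) {
      d <- random_jt_dataset(with_ties = TRUE)
      Jstar <- oracle_jt_null(d$values, d$sizes)
      m <- jt_null_moments(d$sizes, as.numeric(table(d$values)))
      expect_equal(m$E_J, mean(Jstar), tolerance = 1e-12)
      expect_equal(m$Var_J, mean((Jstar - mean(Jstar))^2), tolerance = 1e-10)
    }
  })
})

test_that("exact p equals full enumeration; worked example anchors hold", {
  g <- factor(rep(1:3, each = 2), ordered = TRUE)
  v <- c(1, 2, 3, 4, 5, 6)
  ex <- jt_test(v, g, "increasing", "exact")
  expect_equal(ex$J, 12)
  expect_equal(ex$E_J, 6)
  expect_equal(ex$Var_J, 6.3333333333, tolerance = 1e-9)
  expect_equal(ex$p, 1 / 90)
  as <- jt_test(v, g, "increasing", "asymptotic")
  expect_equal(as$z, 6 / sqrt(456 / 72), tolerance = 1e-9)
  expect_equal(as$z, 2.3842, tolerance = 1e-4)
  expect_equal(as$p, pnorm(2.38419, lower.tail = FALSE), tolerance = 1e-4)
  # random datasets: exact equals enumeration in both directions
  withr::with_seed(5, {
    for (r in 1:20) {
      d <- random_jt_dataset(with_ties = r %% 2 == 0)
      J <- jt_statistic(d$values, d$groups)
      Jstar <- oracle_jt_null(d$values, d$sizes)
      up <- jt_test(d$values, d$groups, "increasing", "exact")
      dn <- jt_test(d$values, d$groups, "decreasing", "exact")
      expect_equal(up$p, mean(Jstar >= J - 1e-9))
      expect_equal(dn$p, mean(Jstar <= J + 1e-9))
    }
  })
})

test_that("montecarlo p uses the add-one estimator and tracks exact", {
  withr::with_seed(6, {
    d <- random_jt_dataset(with_ties = TRUE)
    ex <- jt_test(d$values, d$groups, "increasing", "exact")
    mc <- jt_test(d$values, d$groups, "increasing", "montecarlo",
                  n_perm = 4000, seed = 42)
    expect_gt(mc$p, 0)
    expect_gte(mc$p, 1 / 4001)
    expect_lt(abs(mc$p - ex$p), 4 * sqrt(ex$p * (1 - ex$p) / 4000) + 1e-3)
    # reproducible under the recorded seed
    mc2 <- jt_test(d$values, d$groups, "increasing", "montecarlo",
                   n_perm = 4000, seed = 42)
    expect_identical(mc$p, mc2$p)
  })
})

test_that("degenerate and invalid inputs are handled per contract", {
  g <- factor(rep(1:3, each = 2), ordered = TRUE)
  res <- jt_test(rep(2, 6), g, "increasing", "asymptotic")
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  expect_error(jt_statistic(1:4, factor(c(1, 1, 1, 2), levels = 1:3)),
               "non-empty")
  # NAs are dropped, not fatal
  expect_equal(jt_statistic(c(1, NA, 3, 4, 5, 6), g),
               jt_statistic(c(1, 3, 4, 5, 6), factor(c(1, 2, 2, 3, 3), ordered = TRUE)))
  # exact over budget refuses with advice
  big <- factor(rep(1:5, each = 6), ordered = TRUE)
  expect_error(jt_test(rnorm(30), big, method = "exact"), "montecarlo")
})

test_that("trend screen recovers planted genes and splits directions", {
  design <- simulation_design(n_genes = 600, n_trend_genes = 30,
                              trend_step_delta = 0.5, n_de_genes = 30,
                              n_overlap_genes = 0, seed = 7)
  co <- simulate_pbmc_cohort(design)
  scr <- trend_screen(co$expr, co$annotation, alpha = 0.05)
  planted_up <- names(co$truth$trend_signs)[co$truth$trend_signs > 0]
  planted_dn <- names(co$truth$trend_signs)[co$truth$trend_signs < 0]
  expect_gte(mean(planted_up %in% scr$up), 0.8)
  expect_gte(mean(planted_dn %in% scr$down), 0.8)
  expect_length(intersect(scr$up, scr$down), 0L)
  # null leakage is near alpha
  nulls <- setdiff(rownames(co$expr), co$truth$trend_genes)
  expect_lt(mean(nulls %in% c(scr$up, scr$down)), 0.2)
})

test_that("at alpha = 1 every testable gene lands in exactly one list", {
  co <- tiny_stage_cohort(n_genes = 100, seed = 8)
  scr <- trend_screen(co$expr, co$annotation, alpha = 1)
  expect_length(intersect(scr$up, scr$down), 0L)
  expect_setequal(c(scr$up, scr$down), rownames(co$expr))
})

test_that("trend screen restricts to the requested stage subset", {
  co <- tiny_stage_cohort(n_genes = 60, seed = 9)
  scr <- trend_screen(co$expr, co$annotation, stage_set = c("D1", "D2", "D3"))
  sizes <- scr$table$J <= (11 * 7 + 11 * 5 + 7 * 5)  # max J for 11/7/5
  expect_true(all(sizes))
  expect_identical(scr$stage_set, c("D1", "D2", "D3"))
  expect_error(trend_screen(co$expr, co$annotation, stage_set = c("D1", "XX")),
               "unknown")
  # genes with too few informative stages are skipped, not fatal
  x <- co$expr
  x[1, co$annotation$stage != "D1"] <- NA
  scr2 <- trend_screen(x, co$annotation)
  expect_identical(scr2$skipped, rownames(x)[1])
})
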