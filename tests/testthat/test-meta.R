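make_ds <- function(case_mat, control_mat, map = NULL, id = "DS1") {
  x <- cbind(case_mat, control_mat)
  rownames(x) <- if (is.null(rownames(x))) paste0("P", seq_len(nrow(x))) else rownames(x)
  colnames(x) <- paste0(id, "_s", seq_len(ncol(x)))
  ann <- data.frame(sample_id = colnames(x),
                    group = rep(c("case", "control"),
                                c(ncol(case_mat), ncol(control_mat))),
                    stringsAsFactors = FALSE)
  if (is.null(map)) {
    map <- make_probe_gene_map(data.frame(probe_id = rownames(x),
                                          gene_id = rownames(x),
                                          stringsAsFactors = FALSE))
  }
  case_control_dataset(x, ann, map, id)
}

test_that("signed Z from the one-tailed Welch t matches the closed form", {
  ds <- make_ds(matrix(c(2, 3), 1), matrix(c(0, 1), 1))
  zs <- dataset_zscores(ds)
  expect_equal(zs$t, 2.828427, tolerance = 1e-6)
  expect_equal(zs$df, 2, tolerance = 1e-9)
  p_up <- pt(zs$t, zs$df, lower.tail = FALSE)
  expect_equal(p_up, oracle_t2_surv(2.828427), tolerance = 1e-6)
  expect_equal(p_up, 0.052786, tolerance = 1e-4)
  expect_equal(zs$z, qnorm(1 - 0.052786), tolerance = 1e-5)
  expect_equal(zs$z, 1.6180, tolerance = 1e-3)
})

test_that("Z-scores are symmetric, antisymmetric and agree with t.test", {
  # identical groups: t = 0, z = 0
  ds0 <- make_ds(matrix(c(1, 2, 3), 1), matrix(c(1, 2, 3), 1))
  expect_equal(dataset_zscores(ds0)$z, 0)
  # swapped labels negate z exactly
  withr::with_seed(10, {
    a <- matrix(rnorm(50), 5)
    b <- matrix(rnorm(50), 5)
  })
  z1 <- dataset_zscores(make_ds(a, b))$z
  z2 <- dataset_zscores(make_ds(b, a))$z
  expect_equal(z1, -z2, tolerance = 1e-12)
  # Welch t agrees with stats::t.test per probe
  zz <- dataset_zscores(make_ds(a, b))
  for (i in 1:5) {
    tt <- t.test(a[i, ], b[i, ])
    expect_equal(zz$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(zz$df[i], unname(tt$parameter), tolerance = 1e-10)
  }
  # pooled variant agrees with var.equal = TRUE
  zp <- dataset_zscores(make_ds(a, b), t_variant = "pooled")
  tt <- t.test(a[2, ], b[2, ], var.equal = TRUE)
  expect_equal(zp$t[2], unname(tt$statistic), tolerance = 1e-10)
})

test_that("degenerate probes are flagged with z = 0", {
  ds <- make_ds(matrix(c(5, 5, 5), 1), matrix(c(5, 5), 1))
  zs <- dataset_zscores(ds)
  expect_true(zs$degenerate)
  expect_equal(zs$z, 0)
})

test_that("probe collapse follows the declared rules", {
  map <- make_probe_gene_map(data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    gene_id = c("GA", "GA", "GB", "GB", NA),
    stringsAsFactors = FALSE))
  z <- c(p1 = 1, p2 = 3, p3 = -4, p4 = 3, p5 = 9)
  out <- collapse_probes(z, map)
  expect_equal(out[["GA"]], 3)     # larger |z|
  expect_equal(out[["GB"]], -4)    # |-4| > |3|
  expect_false("p5" %in% names(out))  # unmapped dropped
  # single-probe gene passes through
  expect_equal(collapse_probes(c(p1 = 2.5), map)[["GA"]], 2.5)
  # |z| ties break to the lexically smallest probe id
  map2 <- make_probe_gene_map(data.frame(probe_id = c("pB", "pA"),
                                         gene_id = "G", stringsAsFactors = FALSE))
  expect_equal(collapse_probes(c(pB = -2, pA = 2), map2)[["G"]], 2)
  # median rule
  expect_equal(collapse_probes(z, map, rule = "median_z")[["GA"]], 2)
  expect_error(collapse_probes(z, map[0, ]), "empty")
})

test_that("weighted-Z combination matches closed forms", {
  expect_equal(weighted_z_combine(c(3, 4)), 7 / sqrt(2))
  expect_equal(weighted_z_combine(c(3, 4)), 4.949747, tolerance = 1e-6)
  expect_equal(weighted_z_combine(c(2, 3), c(4, 5)), 23 / sqrt(41))
  expect_equal(weighted_z_combine(c(2, 3), c(4, 5)), 3.59200, tolerance = 1e-5)
  expect_equal(weighted_z_combine(1.7, 12), 1.7)   # single study, any weight
  expect_error(weighted_z_combine(numeric(0)), "at least one")
  expect_error(weighted_z_combine(c(1, 2), c(1, -1)), "positive")
})

test_that("meta screen is antisymmetric under global label swap", {
  design <- simulation_design(n_genes = 120, n_de_genes = 20,
                              n_overlap_genes = 0, seed = 11)
  gl <- simulate_glomerular_collection(design)
  swapped <- lapply(gl$datasets, function(d) {
    ann <- d$annotation
    ann$group <- factor(ifelse(ann$group == "case", "control", "case"),
                        levels = c("case", "control"))
    case_control_dataset(d$expr, ann, d$map, d$dataset_id)
  })
  r1 <- egwas_screen(gl$datasets)
  r2 <- egwas_screen(swapped)
  expect_equal(r1$table$z_meta, -r2$table$z_meta, tolerance = 1e-10)
  expect_identical(r1$up, r2$down)
})

test_that("one dataset reproduces its own gene Z exactly; screens partition", {
  design <- simulation_design(n_genes = 80, n_de_genes = 10,
                              n_overlap_genes = 0, seed = 12)
  gl <- simulate_glomerular_collection(design)
  ds <- gl$datasets[[1]]
  direct <- collapse_probes(dataset_zscores(ds), ds$map)
  res <- egwas_screen(list(ds))
  expect_equal(res$table$z_meta, unname(direct[res$table$gene]), tolerance = 1e-12)
  # z_threshold = 0: every gene in exactly one list
  res0 <- egwas_screen(gl$datasets, z_threshold = 0)
  expect_length(intersect(res0$up, res0$down), 0L)
  expect_setequal(c(res0$up, res0$down), res0$table$gene)
})

test_that("planted DE genes are screened with concordant direction", {
  design <- simulation_design(n_genes = 400, n_de_genes = 40, de_effect = 2,
                              n_overlap_genes = 0, n_case = 13, n_control = 13,
                              seed = 13)
  gl <- simulate_glomerular_collection(design)
  res <- egwas_screen(gl$datasets, z_threshold = 5)
  signs <- gl$truth$de_signs
  hit_up <- names(signs)[signs > 0] %in% res$up
  hit_dn <- names(signs)[signs < 0] %in% res$down
  expect_gte(mean(c(hit_up, hit_dn)), 0.9)
  # no discordant calls
  expect_length(intersect(names(signs)[signs > 0], res$down), 0L)
})

test_that("genes missing from some platforms combine over observed datasets", {
  design <- simulation_design(n_genes = 150, n_de_genes = 0,
                              n_overlap_genes = 0, gene_coverage = 0.8,
                              seed = 14)
  gl <- simulate_glomerular_collection(design)
  res <- egwas_screen(gl$datasets)
  expect_true(any(res$table$n_datasets_observed < 3))
  expect_true(all(res$table$n_datasets_observed >= 1))
  expect_false(anyNA(res$table$z_meta))
  # a gene observed once must equal that dataset's z
  solo <- res$table[res$table$n_datasets_observed == 1, ]
  if (nrow(solo)) {
    zcols <- paste0("z_", c("DS1", "DS2", "DS3"))
    zo <- as.matrix(solo[, zcols])
    expect_equal(solo$z_meta, unname(rowSums(zo, na.rm = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("Manhattan table carries -log10 p and consistent flags", {
  design <- simulation_design(n_genes = 60, n_de_genes = 10, de_effect = 3,
                              n_overlap_genes = 0, n_case = 13, n_control = 13,
                              seed = 15)
  gl <- simulate_glomerular_collection(design)
  res <- egwas_screen(gl$datasets, z_threshold = 5)
  mt <- manhattan_table(res$table)
  expect_identical(mt$gene, sort(res$table$gene))
  expect_setequal(mt$gene[mt$significant],
                  union(res$up, res$down))
  # anchored: Z = 5 corresponds to -log10 p ~ 6.5427
  fake <- res$table[1, ]
  fake$z_meta <- 5
  fake$p_meta <- pnorm(5, lower.tail = FALSE)
  expect_equal(manhattan_table(fake)$neg_log10_p, 6.5427, tolerance = 1e-4)
  expect_equal(fake$p_meta, 2.866516e-7, tolerance = 1e-6)
  expect_error(manhattan_table(res$table[0, ]), "empty")
  expect_error(manhattan_table(res$table, gene_order = "nope"), "cover")
})
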