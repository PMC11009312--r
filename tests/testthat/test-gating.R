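test_that("Otsu separates a perfectly bimodal sample", {
  v <- c(rep(1, 50), rep(10, 50))
  thr <- otsu_threshold(v)
  expect_gt(thr, 1); expect_lt(thr, 10)
  expect_equal(sum(v > thr), 50)  # exactly the high group exceeds it
})

test_that("Otsu equals exhaustive between-class-variance search", {
  set.seed(101)
  for (i in 1:5) {
    v <- c(rlnorm(4500, log(100), 0.4), rlnorm(500, log(1000), 0.4))
    expect_equal(otsu_threshold(v), otsu_brute_force(v))
  }
  # and on a hard, overlapping mixture
  v <- c(rlnorm(3000, 4, 0.8), rlnorm(2000, 5, 0.8))
  expect_equal(otsu_threshold(v), otsu_brute_force(v))
})

test_that("Otsu is scale-equivariant and rejects degenerate input", {
  set.seed(102)
  v <- c(rlnorm(500, log(100), 0.3), rlnorm(60, log(1000), 0.3))
  thr <- otsu_threshold(v)
  expect_identical(otsu_threshold(v * 2), thr * 2)  # powers of two are exact
  expect_identical((v * 2) > otsu_threshold(v * 2), v > thr)
  expect_error(otsu_threshold(rep(3, 100)), "degenerate")
  expect_error(otsu_threshold(5), "degenerate")
})

test_that("local thresholds scale with per-run gains", {
  cfg <- tiny_config(compositions = default_compositions()["CT26"],
                     n_runs = 2, n_replicates = 2, gain_range = c(1, 1))
  study <- simulate_precision_study(cfg, seed = 31)
  # manufacture a pure gain contrast: run 2 holds the same cells as run 1
  # with every channel doubled, so Otsu's scale equivariance pins the ratio
  sec <- study$sections
  for (j in unique(sec$replicate_index)) {
    from <- sec$section_id[sec$run_id == "1" & sec$replicate_index == j]
    to <- sec$section_id[sec$run_id == "2" & sec$replicate_index == j]
    src <- study$cells[study$cells$section_id == from, ]
    src$section_id <- to
    src$cell_id <- paste0("r2", src$cell_id)
    for (m in cfg$markers) src[[m]] <- src[[m]] * 2
    study$cells <- dplyr::bind_rows(
      study$cells[study$cells$section_id != to, ], src)
  }
  pol <- fit_local_thresholds(study)
  th <- pol$thresholds
  for (m in cfg$markers) {
    r1 <- th$threshold[th$scope == "1" & th$marker == m]
    r2 <- th$threshold[th$scope == "2" & th$marker == m]
    expect_equal(r2 / r1, 2, tolerance = 1e-9)
  }
  # one-run study -> single scope
  one <- tiny_config(compositions = default_compositions()["CT26"],
                     n_runs = 1, n_replicates = 2)
  pol1 <- fit_local_thresholds(simulate_precision_study(one, seed = 32))
  expect_equal(unique(pol1$thresholds$scope), "1")
})

test_that("local Otsu gating is invariant under per-run multiplicative gains", {
  cfg0 <- tiny_config(compositions = default_compositions()["CT26"],
                      n_runs = 3, n_replicates = 2, gain_range = c(1, 1))
  cfg1 <- tiny_config(compositions = default_compositions()["CT26"],
                      n_runs = 3, n_replicates = 2, gain_range = c(0.5, 2))
  base <- simulate_precision_study(cfg0, seed = 33)
  pert <- simulate_precision_study(cfg1, seed = 33)
  # same seed: identical cells up to the per-run channel gains
  expect_identical(base$cells$true_class, pert$cells$true_class)
  g_base <- gate_study(base, fit_local_thresholds(base))
  g_pert <- gate_study(pert, fit_local_thresholds(pert))
  for (m in cfg0$markers)
    expect_identical(g_base$cells[[paste0("pos_", m)]],
                     g_pert$cells[[paste0("pos_", m)]])
  expect_identical(g_base$cells$phenotype, g_pert$cells$phenotype)
  # under one global threshold the same gains do change the labels
  gp <- global_policy(default_global_thresholds(cfg0$intensity))
  expect_false(identical(apply_thresholds(base, gp)$cells$pos_CD3e,
                         apply_thresholds(pert, gp)$cells$pos_CD3e))
})

test_that("threshold application: strict inequality, coverage, monotonicity", {
  gated <- build_section(c("CD3e" = 10, "CD3e+CD8a" = 5, "negative" = 20))
  # build_section gates at threshold 100: intensities are 10 or 1000
  expect_equal(sum(gated$cells$pos_CD3e), 15)

  markers <- gated$markers
  study <- new_study(gated$sections, markers,
                     gated$cells[!grepl("^pos_|^phenotype$", names(gated$cells))])
  # intensity exactly at the threshold is negative
  eq <- apply_thresholds(study, global_policy(setNames(rep(1000, 4), markers)))
  expect_equal(sum(eq$cells$pos_CD3e), 0)
  # all-zero thresholds: every cell positive (intensities > 0)
  z <- apply_thresholds(study, global_policy(setNames(rep(0, 4), markers)))
  expect_true(all(as.matrix(z$cells[paste0("pos_", markers)])))
  # raising one marker's threshold never increases its positive count
  n_prev <- Inf
  for (t in c(5, 500, 5000)) {
    th <- setNames(rep(100, 4), markers); th["CD3e"] <- t
    n_t <- sum(apply_thresholds(study, global_policy(th))$cells$pos_CD3e)
    expect_lte(n_t, n_prev); n_prev <- n_t
  }
  # missing threshold names the scope and marker
  part <- threshold_policy(
    tibble::tibble(scope = "*", marker = markers[-1], threshold = 100), "global")
  expect_error(apply_thresholds(study, part), "CD3e")
})

test_that("degenerate channels fall back to the floor threshold with a warning", {
  cfg <- tiny_config(compositions = default_compositions()["CT26"],
                     n_runs = 1, n_replicates = 2)
  study <- simulate_precision_study(cfg, seed = 34)
  study$cells$FoxP3 <- 7  # flat channel
  expect_warning(pol <- fit_local_thresholds(study), "degenerate")
  expect_true(is.na(pol$thresholds$threshold[pol$thresholds$marker == "FoxP3"]))
  suppressWarnings(
    pol2 <- fit_local_thresholds(study, floor = c(FoxP3 = 50)))
  expect_equal(pol2$thresholds$threshold[pol2$thresholds$marker == "FoxP3"], 50)
})

test_that("phenotype matching is priority-ordered and partitions the cells", {
  gated <- build_section(c(
    "CD3e+CD4+FoxP3" = 7,   # T_reg, even though it also satisfies T_helper
    "CD3e+CD4" = 11,        # T_helper
    "CD3e+CD8a" = 13,       # T_cyt
    "CD4" = 4, "negative" = 25))
  tab <- table(gated$cells$phenotype)
  expect_equal(unname(tab[c("T_reg", "T_helper", "T_cyt", "other")]),
               c(7, 11, 13, 29), ignore_attr = TRUE)
  expect_equal(sum(tab), nrow(gated$cells))  # partition
  combos <- attr(gated, "combination_counts")
  expect_equal(combos$n[combos$combo == "CD3e+CD4+FoxP3+"], 7)
  expect_equal(combos$n[combos$combo == "negative"], 25)
})

test_that("phenotype definitions are validated", {
  expect_error(phenotype_def("bad", character()), "non-empty")
  expect_error(phenotype_def("bad", "CD4", "CD4"), "overlap")
})
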