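test_that("cell counts follow the Poisson law of the density model", {
  cfg <- simulation_config()  # 4 mm^2 field, 2000 cells/mm^2 -> lambda 8000
  meta <- section_meta("S1", "CT26", 1, "1")
  n <- nrow(simulate_section(cfg, "CT26", meta,
                             setNames(rep(1, 4), cfg$markers), seed = 21))
  lambda <- 2000 * 4
  expect_lt(abs(n - lambda), 4 * sqrt(lambda))
})

test_that("ground-truth phenotype fractions are recovered by counting", {
  cfg <- simulation_config()
  meta <- section_meta("S1", "CT26", 1, "1")
  cells <- simulate_section(cfg, "CT26", meta,
                            setNames(rep(1, 4), cfg$markers), seed = 22)
  # jitter perturbs the per-section fraction; compare against a jitter-free
  # section for the clean binomial oracle
  cfg0 <- simulation_config(
    compositions = default_compositions(section_jitter_cv = 0))
  cells0 <- simulate_section(cfg0, "CT26", meta,
                             setNames(rep(1, 4), cfg0$markers), seed = 22)
  expect_within_3se(mean(cells0$true_class == "T_cyt"), 0.04, nrow(cells0))
  expect_within_3se(mean(cells0$true_class == "T_reg"), 0.015, nrow(cells0))
  # intensities are strictly positive and all markers present
  expect_true(all(as.matrix(cells[cfg$markers]) > 0))
})

test_that("gains rescale intensities exactly and leave ground truth untouched", {
  cfg <- tiny_config()
  meta <- section_meta("S1", "CT26", 1, "1")
  g1 <- setNames(rep(1, 4), cfg$markers)
  a <- simulate_section(cfg, "CT26", meta, g1, seed = 7)
  b <- simulate_section(cfg, "CT26", meta, g1 * 2, seed = 7)
  expect_identical(a$true_class, b$true_class)
  expect_identical(a$x_um, b$x_um)
  for (m in cfg$markers) expect_identical(a[[m]] * 2, b[[m]])
})

test_that("precision design shuffles serial sections across runs", {
  cfg <- tiny_config(compositions = default_compositions()["CT26"])
  study <- simulate_precision_study(cfg, seed = 1)
  sec <- study$sections
  expect_equal(nrow(sec), 15)
  expect_setequal(sec$serial_index[sec$run_id == "1"], c(1, 6, 11))
  expect_setequal(sec$serial_index[sec$run_id == "2"], c(2, 7, 12))
  expect_setequal(sec$serial_index, 1:15)  # no repeats across runs
  expect_true(all(sec$assay == "multiplex"))
})

test_that("sections of one run share a gain vector", {
  # with zero jitter and a fixed intensity model, per-run channel medians
  # estimate the shared gain; replicate sections of a run must agree while
  # runs differ
  cfg <- simulation_config(
    field_um = c(1500, 1500),
    compositions = default_compositions(section_jitter_cv = 0)["CT26"])
  study <- simulate_precision_study(cfg, seed = 2)
  med <- study$cells |>
    dplyr::left_join(study$sections, by = "section_id") |>
    dplyr::group_by(run_id, section_id) |>
    dplyr::summarise(m = median(CD3e), .groups = "drop_last") |>
    dplyr::summarise(spread = diff(range(m)), level = mean(m), .groups = "drop")
  # within-run spread is sampling noise (a few percent); between-run spread
  # reflects gains drawn log-uniformly from [0.5, 2]
  expect_true(all(med$spread / med$level < 0.15))
  expect_gt(diff(range(med$level)) / min(med$level), 0.2)
})

test_that("concordance design: one 4-plex section at serial position 3", {
  cfg <- tiny_config(compositions = default_compositions()["CT26"])
  study <- simulate_concordance_study(cfg, seed = 3)
  sec <- study$sections
  expect_equal(nrow(sec), 5)
  expect_equal(sec$serial_index[sec$assay == "multiplex"], 3)
  expect_setequal(sec$assay[sec$assay != "multiplex"],
                  paste0("singleplex:", cfg$markers))
})

test_that("singleplex sections emit other channels as background only", {
  cfg <- simulation_config(
    field_um = c(1500, 1500),
    compositions = default_compositions()["CT26"])
  study <- simulate_concordance_study(cfg, seed = 4)
  cd4_sec <- study$sections$section_id[study$sections$assay == "singleplex:CD4"]
  mx_sec <- study$sections$section_id[study$sections$assay == "multiplex"]
  sc <- study$cells[study$cells$section_id == cd4_sec, ]
  mx <- study$cells[study$cells$section_id == mx_sec, ]
  # the assayed CD4 channel keeps its signal population: the true CD4+
  # cells sit an order of magnitude above the channel median
  cd4_pos <- sc$true_class %in% c("T_helper", "T_reg", "CD4_only")
  expect_gt(median(sc$CD4[cd4_pos]), 5 * median(sc$CD4[!cd4_pos]))
  # the off-panel CD3e channel is background-only: even true T cells show
  # no elevated CD3e, unlike on the multiplex section (same shared gain)
  t_cells <- sc$true_class %in% c("T_cyt", "T_helper", "T_reg", "CD3e_only")
  t_cells_mx <- mx$true_class %in% c("T_cyt", "T_helper", "T_reg", "CD3e_only")
  expect_lt(median(sc$CD3e[t_cells]), 3 * median(sc$CD3e[!t_cells]))
  expect_gt(median(mx$CD3e[t_cells_mx]), 5 * median(mx$CD3e[!t_cells_mx]))
})

test_that("identical config and seed give byte-identical studies", {
  cfg <- tiny_config(compositions = default_compositions()["CT26"],
                     n_runs = 2, n_replicates = 2)
  a <- simulate_precision_study(cfg, seed = 77)
  b <- simulate_precision_study(cfg, seed = 77)
  expect_identical(a$cells, b$cells)
  expect_identical(a$sections, b$sections)
  c2 <- simulate_concordance_study(cfg, seed = 77)
  d2 <- simulate_concordance_study(cfg, seed = 77)
  expect_identical(c2$cells, d2$cells)
})

test_that("clustered mode keeps composition but concentrates positions", {
  cfg_p <- tiny_config(compositions = default_compositions()["CT26"])
  cfg_c <- tiny_config(compositions = default_compositions()["CT26"],
                       cluster = list(parents_per_mm2 = 10, sigma_um = 30))
  meta <- section_meta("S1", "CT26", 1, "1")
  g <- setNames(rep(1, 4), cfg_p$markers)
  a <- simulate_section(cfg_p, "CT26", meta, g, seed = 12)
  b <- simulate_section(cfg_c, "CT26", meta, g, seed = 12)
  expect_true(all(b$x_um >= 0 & b$x_um <= 1000))
  # clustered pattern has much smaller within-type NN distances
  nn_a <- nn_distances(a[1:500, ], a[1:500, ])
  nn_b <- nn_distances(b[1:500, ], b[1:500, ])
  expect_lt(mean(nn_b), mean(nn_a))
})
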