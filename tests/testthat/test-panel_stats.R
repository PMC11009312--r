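test_that("cv matches the hand formula and its degenerate conventions", {
  expect_equal(cv(c(5, 5, 5)), 0)
  expect_equal(cv(c(2, 4)), 100 * sqrt(2) / 3, tolerance = 1e-10)  # 47.1405 %
  set.seed(1); x <- rlnorm(20)
  expect_equal(cv(3.7 * x), cv(x))          # scale invariance
  expect_warning(expect_true(is.na(cv(7))), "fewer than 2")
  expect_warning(expect_true(is.na(cv(c(-1, 1)))), "mean is zero")
})

test_that("relative difference follows the symmetric Bland-Altman convention", {
  expect_equal(relative_difference(10, 10), 0)
  expect_equal(relative_difference(12, 10), 200 / 11, tolerance = 1e-10) # 18.1818 %
  expect_equal(relative_difference(10, 12), -relative_difference(12, 10))
  expect_equal(relative_difference(0, 0), 0)
  expect_error(relative_difference(-1, 2), "non-negative")
  # optional 1-plex denominator
  expect_equal(relative_difference(12, 10, denominator = "second"), 20)
})

test_that("section summaries compute percentages and intensity means", {
  gated <- build_section(c("CD3e" = 94, "negative" = 906))
  ss <- section_summaries(gated)
  r <- ss[ss$target == "CD3e", ]
  expect_equal(r$pct_positive, 9.4)
  expect_equal(r$n_total, 1000)
  expect_equal(r$mean_intensity_positive, 1000)
  expect_equal(r$mean_intensity_negative, 10)
  r4 <- ss[ss$target == "CD4", ]
  expect_equal(r4$pct_positive, 0)
  expect_true(is.na(r4$mean_intensity_positive))  # no positive cells
  # phenotype rows partition percentages consistently
  expect_true(all(ss$n_positive <= ss$n_total))
})

test_that("locally gated summaries recover ground-truth fractions", {
  cfg <- simulation_config(
    compositions = default_compositions(section_jitter_cv = 0)["CT26"],
    n_runs = 1, n_replicates = 2)
  study <- simulate_precision_study(cfg, seed = 51)
  g <- gate_study(study, fit_local_thresholds(study))
  ss <- section_summaries(g)
  for (sid in study$sections$section_id) {
    sc <- study$cells[study$cells$section_id == sid, ]
    truth <- mean(sc$true_class %in% c("T_cyt", "T_helper", "T_reg", "CD3e_only"))
    got <- ss$pct_positive[ss$section_id == sid & ss$target == "CD3e"] / 100
    expect_within_3se(got, truth, nrow(sc))
  }
})

test_that("an identical section used as both assays gives zero differences", {
  markers <- c("CD3e", "CD4", "CD8a", "FoxP3")
  set.seed(52)
  base <- tibble::tibble(
    cell_id = sprintf("c%04d", 1:400), section_id = "s3",
    x_um = runif(400, 0, 500), y_um = runif(400, 0, 500))
  for (m in markers)
    base[[m]] <- rlnorm(400, ifelse(runif(400) < 0.1, log(1000), log(100)), 0.3)
  assays <- c("singleplex:CD3e", "singleplex:CD4", "multiplex",
              "singleplex:CD8a", "singleplex:FoxP3")
  secs <- list(); cells <- list()
  for (i in 1:5) {
    sid <- paste0("s", i)
    secs[[i]] <- section_meta(sid, "M", i, "1", assay = assays[i])
    dup <- base; dup$section_id <- sid
    dup$cell_id <- sub("^c", paste0("s", i, "c"), dup$cell_id)
    cells[[i]] <- dup
  }
  study <- new_study(dplyr::bind_rows(secs), markers, dplyr::bind_rows(cells))
  g <- gate_study(study, global_policy(setNames(rep(300, 4), markers)))
  rep <- concordance_report(g)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$rel_diff_pct == 0))
  expect_true(all(rep$rel_diff_int == 0))
  expect_false(any(rep$flag_out_of_band))
})

test_that("concordance flags low-abundance markers and missing singleplex", {
  gated <- build_section(c("CD3e+CD8a" = 3, "CD3e" = 300, "negative" = 700))
  # make it a two-section concordance study: multiplex + CD8a singleplex
  cells <- gated$cells[!grepl("^pos_|^phenotype$", names(gated$cells))]
  one <- cells; one$section_id <- "S2"; one$cell_id <- paste0("b", one$cell_id)
  secs <- dplyr::bind_rows(
    section_meta("S1", "ctrl", 3, "1", assay = "multiplex"),
    section_meta("S2", "ctrl", 1, "1", assay = "singleplex:CD8a"))
  study <- new_study(secs, gated$markers, dplyr::bind_rows(cells, one))
  g <- gate_study(study, global_policy(setNames(rep(100, 4), gated$markers)))
  w <- testthat::capture_warnings(rep <- concordance_report(g))
  expect_match(w, "no singleplex section", all = FALSE)
  expect_equal(rep$marker, "CD8a")
  expect_true(rep$low_abundance)  # 3 positive cells < 50-cell floor
})

test_that("intensity histograms are normalised and separate signal from background", {
  cfg <- tiny_config(compositions = default_compositions()["CT26"])
  study <- simulate_precision_study(
    tiny_config(compositions = default_compositions()["CT26"],
                n_runs = 1, n_replicates = 1), seed = 53)
  g <- gate_study(study, global_policy(default_global_thresholds(cfg$intensity)))
  h <- intensity_histograms(g, study$sections$section_id[1], "CD3e")
  expect_equal(sum(h$density_positive), 1)
  expect_equal(sum(h$density_negative), 1)
  expect_lt(h$overlap, 0.05)  # well-separated populations
  # all cells positive -> negative histogram empty and flagged
  g2 <- g; g2$cells$pos_CD3e <- TRUE
  h2 <- intensity_histograms(g2, study$sections$section_id[1], "CD3e")
  expect_true(h2$empty_negative)
  expect_true(all(is.na(h2$density_negative)))
})

test_that("precision report: definitional consistency and degenerate runs", {
  # three identical replicate sections -> intra CV exactly 0
  markers <- c("CD3e", "CD4", "CD8a", "FoxP3")
  cells <- list(); secs <- list()
  for (i in 1:3) {
    g <- build_section(c("CD3e" = 50, "negative" = 450), section_id = paste0("S", i))
    cc <- g$cells[!grepl("^pos_|^phenotype$", names(g$cells))]
    cc$cell_id <- paste0(i, cc$cell_id)
    cells[[i]] <- cc
    secs[[i]] <- section_meta(paste0("S", i), "ctrl", i, "1", replicate_index = i)
  }
  study <- new_study(dplyr::bind_rows(secs), markers, dplyr::bind_rows(cells))
  g <- gate_study(study, global_policy(setNames(rep(100, 4), markers)))
  pr <- precision_report(g)
  cd3 <- pr$summary[pr$summary$target == "CD3e", ]
  expect_equal(cd3$intra_run_cv, 0)
  expect_equal(cd3$inter_run_cv, 0)

  # inter-run CV equals cv() of the pooled per-section vector
  cfg <- tiny_config(compositions = default_compositions()["CT26"],
                     n_runs = 2, n_replicates = 2)
  st <- simulate_precision_study(cfg, seed = 54)
  gg <- gate_study(st, fit_local_thresholds(st))
  pr2 <- precision_report(gg)
  ss <- section_summaries(gg)
  pooled <- ss$pct_positive[ss$target == "CD4"]
  expect_equal(pr2$summary$inter_run_cv[pr2$summary$target == "CD4"], cv(pooled))

  # single-replicate runs: intra CV missing, inter CV still defined
  cfg1 <- tiny_config(compositions = default_compositions()["CT26"],
                      n_runs = 3, n_replicates = 1)
  st1 <- simulate_precision_study(cfg1, seed = 55)
  pr1 <- precision_report(gate_study(st1, fit_local_thresholds(st1)))
  expect_true(all(is.na(pr1$summary$intra_run_cv)))
  expect_true(all(!is.na(pr1$summary$inter_run_cv)))
})
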