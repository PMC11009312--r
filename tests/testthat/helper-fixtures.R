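# Shared fixtures: all synthetic, built in code at test time.

# Small, fast simulation config: 1 mm^2 field (~2000 cells/section).
tiny_config <- function(..., field_um = c(1000, 1000)) {
  simulation_config(field_um = field_um, ...)
}

# A hand-built multiplex section: `combos` is a named vector giving the
# number of cells per marker-combination, e.g.
# c("CD3e+CD8a" = 50, "negative" = 200), where "negative" means positive for
# nothing. Positive markers get intensity 1000, negative cells 10; gated with
# threshold 100 everywhere.
build_section <- function(combos, markers = c("CD3e", "CD4", "CD8a", "FoxP3"),
                          section_id = "S1", specimen = "ctrl",
                          phenotypes = default_phenotypes()) {
  n <- sum(combos)
  cells <- tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    section_id = section_id,
    x_um = seq_len(n) * 10, y_um = rep(5, n)
  )
  for (m in markers) cells[[m]] <- 10
  at <- 0L
  for (i in seq_along(combos)) {
    idx <- at + seq_len(combos[i]); at <- at + combos[i]
    pos_markers <- strsplit(names(combos)[i], "+", fixed = TRUE)[[1]]
    pos_markers <- setdiff(pos_markers, "negative")
    for (m in pos_markers) cells[[m]][idx] <- 1000
  }
  meta <- section_meta(section_id, specimen, 1L, "1")
  study <- new_study(meta, markers, cells, phenotypes = phenotypes)
  gate_study(study, global_policy(setNames(rep(100, length(markers)), markers)))
}

# Independent Otsu oracle: exhaustive search over interior bin edges,
# computing the between-class variance for each split directly from the
# bin-midpoint representation of the data (loop, no cumulative sums).
otsu_brute_force <- function(values, n_bins = 256L) {
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  rep_vals <- mids[bin]
  best <- -Inf; best_edge <- NA_real_
  for (k in seq_len(n_bins - 1L)) {
    left <- rep_vals[bin <= k]; right <- rep_vals[bin > k]
    w0 <- length(left) / length(values); w1 <- 1 - w0
    mu0 <- if (length(left)) mean(left) else 0
    mu1 <- if (length(right)) mean(right) else 0
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best + 1e-12) { best <- s; best_edge <- edges[k + 1L] }
  }
  best_edge
}

cells_at <- function(xy, prefix = "c") {
  tibble::tibble(cell_id = paste0(prefix, seq_len(nrow(xy))),
                 x_um = xy[, 1], y_um = xy[, 2])
}

# Brute-force directional nearest-neighbor oracle (double loop).
nn_brute_force <- function(ref, target) {
  vapply(seq_len(nrow(ref)), function(i) {
    d <- sqrt((target$x_um - ref$x_um[i])^2 + (target$y_um - ref$y_um[i])^2)
    d[target$cell_id == ref$cell_id[i]] <- Inf
    min(d)
  }, numeric(1))
}

expect_within_3se <- function(observed_frac, true_frac, n) {
  se <- sqrt(true_frac * (1 - true_frac) / n)
  expect_lt(abs(observed_frac - true_frac), 3 * se + 1e-12)
}
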