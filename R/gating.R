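#' Otsu threshold of a per-cell intensity distribution
#'
#' Histogram-based threshold maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`, computed on the raw (not log) intensities over
#' `n_bins` equal-width bins spanning the min-max range. The returned value
#' is the bin *edge* achieving the maximum (the lowest such edge on ties),
#' so rescaling all intensities by `c > 0` rescales the threshold by exactly
#' `c` and leaves the induced positive/negative labels unchanged — the
#' property that makes per-run local gating immune to multiplicative batch
#' effects.
#'
#' @param values numeric vector of per-cell intensities (>= 2 distinct
#'   values required).
#' @param n_bins number of histogram bins (default 256).
#' @return the threshold, a bin edge strictly inside the data range. Cells
#'   are called positive when intensity is strictly greater than it.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L || diff(range(values)) == 0)
    stop("degenerate input: need >= 2 distinct values for Otsu thresholding")
  lo <- min(values); hi <- max(values)
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(
    pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins),
    nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  n <- sum(counts)
  cum_n <- cumsum(counts)[-n_bins]
  cum_s <- cumsum(counts * mids)[-n_bins]
  w0 <- cum_n / n
  w1 <- 1 - w0
  total_mean <- sum(counts * mids) / n
  mu0 <- ifelse(cum_n > 0, cum_s / cum_n, 0)
  mu1 <- ifelse(w1 > 0, (total_mean - w0 * mu0) / w1, 0)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  edges[which.max(bcv) + 1L]  # which.max returns the first (lowest) maximum
}

#' Threshold policy (global or per-run local)
#'
#' Maps `(scope, marker)` to an intensity cutoff, where `scope` is `"*"` for
#' a global policy (one threshold per marker for every image of the study)
#' or a `run_id` for a local policy (a separate threshold per staining run,
#' the remedy for batch-to-batch intensity variation).
#'
#' @param thresholds tibble with columns `scope`, `marker`, `threshold`.
#' @param mode `"global"` or `"local"`.
#' @return object of class `threshold_policy`.
#' @export
threshold_policy <- function(thresholds, mode = c("global", "local")) {
  mode <- match.arg(mode)
  stopifnot(all(c("scope", "marker", "threshold") %in% names(thresholds)))
  if (any(thresholds$threshold < 0, na.rm = TRUE)) stop("thresholds must be >= 0")
  if (mode == "global" && !all(thresholds$scope == "*"))
    stop("global policy must use scope '*'")
  structure(list(mode = mode, thresholds = tibble::as_tibble(thresholds)),
            class = "threshold_policy")
}

#' Global threshold policy from a marker -> value map
#' @param thresholds named numeric vector, one fixed cutoff per marker.
#' @return a global `threshold_policy`.
#' @export
global_policy <- function(thresholds) {
  threshold_policy(
    tibble::tibble(scope = "*", marker = names(thresholds),
                   threshold = unname(thresholds)),
    mode = "global")
}

#' @export
print.threshold_policy <- function(x, ...) {
  cat("<threshold_policy> mode =", x$mode, "\n")
  print(x$thresholds, n = 20)
  invisible(x)
}

lookup_threshold <- function(policy, scope, marker) {
  th <- policy$thresholds
  key <- if (policy$mode == "global") "*" else scope
  hit <- th$threshold[th$scope == key & th$marker == marker]
  if (length(hit) != 1L || is.na(hit))
    stop("no threshold for (scope = '", key, "', marker = '", marker, "')")
  hit
}

#' Fit per-run (local) Otsu thresholds
#'
#' For each staining run and marker, pools the mean per-cell intensities
#' across **all** cells of all the run's sections and applies
#' [otsu_threshold()]. Singleplex sections contribute only their own
#' marker's channel. A degenerate channel within a run (all values equal)
#' is recorded as `NA` with a warning; downstream statistics for that
#' (run, marker) are reported as missing unless a `floor` fallback
#' threshold is supplied.
#'
#' @param study a `mif_study`.
#' @param n_bins histogram bins passed to [otsu_threshold()].
#' @param floor optional named numeric fallback threshold per marker used
#'   when a run's channel is degenerate.
#' @return a local `threshold_policy` with one scope per run.
#' @export
fit_local_thresholds <- function(study, n_bins = 256L, floor = NULL) {
  runs <- unique(study$sections$run_id)
  sm <- singleplex_marker(study$sections$assay)
  names(sm) <- study$sections$section_id
  rows <- list()
  for (r in runs) {
    sec_r <- study$sections$section_id[study$sections$run_id == r]
    cells_r <- study$cells[study$cells$section_id %in% sec_r, , drop = FALSE]
    for (m in study$markers) {
      # a singleplex section only carries meaningful signal in its own channel
      keep <- is.na(sm[cells_r$section_id]) | sm[cells_r$section_id] == m
      v <- cells_r[[m]][keep]
      thr <- tryCatch(otsu_threshold(v, n_bins = n_bins), error = function(e) {
        warning("degenerate channel for run '", r, "', marker '", m, "'",
                if (!is.null(floor[[m]])) " - using floor threshold" else
                  " - threshold missing", call. = FALSE)
        if (!is.null(floor[[m]])) floor[[m]] else NA_real_
      })
      rows[[length(rows) + 1L]] <-
        tibble::tibble(scope = r, marker = m, threshold = thr)
    }
  }
  threshold_policy(dplyr::bind_rows(rows), mode = "local")
}

#' Apply a threshold policy to a study
#'
#' Adds one logical positivity column `pos_<marker>` per marker to the
#' study's cells: positive iff intensity is **strictly greater** than the
#' threshold for the cell's scope (an intensity exactly equal to the
#' threshold is negative). On singleplex sections only the section's own
#' marker is gated; the other channels are `NA`.
#'
#' @param study a `mif_study`.
#' @param policy a `threshold_policy`.
#' @return the study with positivity columns added (class gains
#'   `mif_gated`); the policy is stored in `$policy`.
#' @export
apply_thresholds <- function(study, policy) {
  cells <- study$cells
  sec <- study$sections
  run_of <- setNames(sec$run_id, sec$section_id)
  sp_of <- setNames(singleplex_marker(sec$assay), sec$section_id)
  scopes <- if (policy$mode == "global") "*" else unique(sec$run_id)
  thr <- matrix(NA_real_, nrow = length(scopes), ncol = length(study$markers),
                dimnames = list(scopes, study$markers))
  for (s in scopes) for (m in study$markers)
    thr[s, m] <- lookup_threshold(policy, s, m)
  cell_scope <- if (policy$mode == "global") rep("*", nrow(cells))
                else run_of[cells$section_id]
  cell_sp <- sp_of[cells$section_id]
  for (m in study$markers) {
    pos <- cells[[m]] > thr[cell_scope, m]
    pos[!is.na(cell_sp) & cell_sp != m] <- NA
    cells[[paste0("pos_", m)]] <- pos
  }
  study$cells <- cells
  study$policy <- policy
  class(study) <- unique(c("mif_gated", class(study)))
  study
}

#' Phenotype definition
#'
#' A named boolean marker combination: a cell matches when it is positive
#' for every marker in `require_pos` and negative for every marker in
#' `require_neg`.
#'
#' @param name phenotype label (e.g. `"T_reg"`).
#' @param require_pos markers that must be positive (non-empty).
#' @param require_neg markers that must be negative.
#' @return object of class `phenotype_def`.
#' @export
phenotype_def <- function(name, require_pos, require_neg = character()) {
  require_pos <- as.character(require_pos %||% character())
  require_neg <- as.character(require_neg %||% character())
  if (!length(require_pos)) stop("phenotype '", name, "': require_pos must be non-empty")
  if (length(intersect(require_pos, require_neg)))
    stop("phenotype '", name, "': require_pos and require_neg overlap")
  structure(list(name = name, require_pos = require_pos,
                 require_neg = require_neg), class = "phenotype_def")
}

#' Default T-cell phenotype definitions (murine panel)
#'
#' Priority-ordered, most specific first, so that matching is exclusive:
#' a CD3e+CD4+FoxP3+ cell is a T_reg, not a T_helper. T_helper explicitly
#' requires FoxP3-negative for the same reason.
#'
#' * `T_reg`: CD3e+ CD4+ FoxP3+
#' * `T_helper`: CD3e+ CD4+ FoxP3-
#' * `T_cyt`: CD3e+ CD8a+
#'
#' @return named list of [phenotype_def()]s.
#' @export
default_phenotypes <- function() {
  defs <- list(
    phenotype_def("T_reg", c("CD3e", "CD4", "FoxP3")),
    phenotype_def("T_helper", c("CD3e", "CD4"), "FoxP3"),
    phenotype_def("T_cyt", c("CD3e", "CD8a"))
  )
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Assign phenotype labels to gated cells
#'
#' Each cell receives the first definition (in priority order) whose
#' `require_pos` markers are all positive and `require_neg` markers all
#' negative; unmatched cells are labeled `"other"`. Cells with `NA`
#' positivity for a required marker (e.g. ungated channels of singleplex
#' sections) never match. Raw marker-combination counts are attached as
#' attribute `"combination_counts"` so unusual combinations (cell-cell
#' doublets showing up as e.g. CD3+PanCK+) can be surfaced.
#'
#' @param gated a gated study ([apply_thresholds()]).
#' @param defs priority-ordered list of [phenotype_def()]s (defaults to the
#'   study's own).
#' @return the study with a `phenotype` column added to its cells.
#' @export
assign_phenotypes <- function(gated, defs = NULL) {
  defs <- defs %||% gated$phenotypes
  if (!length(defs)) stop("no phenotype definitions supplied")
  pos <- as.matrix(gated$cells[paste0("pos_", gated$markers)])
  colnames(pos) <- gated$markers
  lab <- rep("other", nrow(pos))
  unset <- rep(TRUE, nrow(pos))
  for (d in defs) {
    ok <- unset
    for (m in d$require_pos) ok <- ok & !is.na(pos[, m]) & pos[, m]
    for (m in d$require_neg) ok <- ok & !is.na(pos[, m]) & !pos[, m]
    lab[ok] <- d$name
    unset <- unset & !ok
  }
  gated$cells$phenotype <- lab
  gated$phenotypes <- defs
  combo <- rep("", nrow(pos))
  any_na <- rep(FALSE, nrow(pos))
  for (m in colnames(pos)) {
    any_na <- any_na | is.na(pos[, m])
    combo <- paste0(combo, ifelse(!is.na(pos[, m]) & pos[, m], paste0(m, "+"), ""))
  }
  combo[combo == ""] <- "negative"
  combo[any_na] <- NA_character_
  tb <- table(combo, useNA = "no")
  attr(gated, "combination_counts") <-
    tibble::tibble(combo = names(tb), n = as.integer(tb)) |>
    dplyr::arrange(dplyr::desc(.data$n))
  gated
}

#' Gate a study and assign phenotypes in one step
#'
#' @param study a `mif_study`.
#' @param policy a `threshold_policy`.
#' @param defs phenotype definitions (defaults to the study's).
#' @return gated study with positivity columns and phenotype labels.
#' @export
gate_study <- function(study, policy, defs = NULL) {
  assign_phenotypes(apply_thresholds(study, policy), defs)
}
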