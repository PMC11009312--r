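#' Multiplex labeling efficiency configuration
#'
#' For each marker, the list of *qualifying* phenotypes: the valid
#' multi-marker combinations that include the marker of interest. The MLE
#' for a marker is the percentage of marker-positive cells that fall into
#' one of its qualifying phenotypes. Validation requires every qualifying
#' phenotype's `require_pos` to contain the marker, and the numerator is
#' a union over definitions, so each cell is counted at most once and the
#' MLE cannot exceed 100%.
#'
#' The default encodes the murine T-cell panel:
#' * CD3e: T_cyt + T_helper + T_reg over total CD3e+ cells
#' * CD4: T_helper + T_reg over total CD4+ cells
#' * CD8a: T_cyt over total CD8a+ cells
#' * FoxP3: T_reg over total FoxP3+ cells
#'
#' with T_helper counted as CD3e+CD4+FoxP3- (exclusive of T_reg) so the
#' CD3e and CD4 numerators do not double-count regulatory T cells.
#'
#' @param qualifying named list: marker -> character vector of phenotype
#'   names.
#' @param band flag band half-width in MLE percentage points (default 10).
#' @return object of class `mle_config`.
#' @export
mle_config <- function(qualifying = list(
                         CD3e = c("T_cyt", "T_helper", "T_reg"),
                         CD4 = c("T_helper", "T_reg"),
                         CD8a = "T_cyt",
                         FoxP3 = "T_reg"),
                       band = 10) {
  stopifnot(is.list(qualifying), !is.null(names(qualifying)), band > 0)
  structure(list(qualifying = qualifying, band = band), class = "mle_config")
}

validate_mle_config <- function(config, phenotypes, markers) {
  for (m in names(config$qualifying)) {
    if (!m %in% markers) stop("MLE config references unknown marker '", m, "'")
    for (p in config$qualifying[[m]]) {
      def <- phenotypes[[p]]
      if (is.null(def))
        stop("MLE config references unknown phenotype '", p, "'")
      if (!m %in% def$require_pos)
        stop("phenotype '", p, "' does not require marker '", m,
             "' positive; it cannot qualify for MLE(", m, ")")
    }
  }
  invisible(config)
}

#' Multiplex labeling efficiency of one marker in one section
#'
#' `100 * (marker-positive cells matching at least one qualifying
#' phenotype) / (total marker-positive cells)`. The numerator is counted
#' as the **union** of the qualifying phenotype definitions evaluated
#' directly on the gated positivity matrix, so each cell contributes at
#' most once even if a user supplies overlapping qualifying definitions,
#' and the efficiency of one marker depends only on the thresholds of the
#' markers its qualifying definitions mention (e.g. MLE(CD8a), qualified
#' by T_cyt alone, is untouched by CD4 or FoxP3 regating).
#'
#' Undefined (`NA` with a warning) when the section has no marker-positive
#' cells — never reported as 0, which would mean something else entirely.
#'
#' @param section_cells gated cells of one section.
#' @param marker marker of interest.
#' @param config an [mle_config()].
#' @param phenotypes named list of [phenotype_def()]s resolving the
#'   qualifying phenotype names (default [default_phenotypes()]).
#' @return list with `mle` (percent), `numerator`, `denominator`.
#' @export
mle_for_marker <- function(section_cells, marker, config = mle_config(),
                           phenotypes = default_phenotypes()) {
  pos <- section_cells[[paste0("pos_", marker)]]
  if (is.null(pos)) stop("marker '", marker, "' is not gated in this section")
  den <- sum(pos, na.rm = TRUE)
  qualifies <- rep(FALSE, nrow(section_cells))
  for (p in config$qualifying[[marker]]) {
    def <- phenotypes[[p]]
    if (is.null(def)) stop("unknown qualifying phenotype '", p, "'")
    ok <- rep(TRUE, nrow(section_cells))
    for (m in def$require_pos) {
      pm <- section_cells[[paste0("pos_", m)]]
      ok <- ok & !is.na(pm) & pm
    }
    for (m in def$require_neg) {
      pm <- section_cells[[paste0("pos_", m)]]
      ok <- ok & !is.na(pm) & !pm
    }
    qualifies <- qualifies | ok
  }
  num <- sum(qualifies)
  if (den == 0) {
    warning("MLE(", marker, ") undefined: no ", marker, "-positive cells")
    return(list(mle = NA_real_, numerator = num, denominator = 0L))
  }
  if (num > den)
    stop("MLE(", marker, ") numerator exceeds denominator; a qualifying ",
         "phenotype does not require the marker positive")
  list(mle = 100 * num / den, numerator = num, denominator = den)
}

#' MLE report across a gated study
#'
#' Per-section MLE for every configured marker, per-run means, and the
#' cross-section CV of the MLE per marker. A section is flagged when its
#' MLE deviates from the study-wide per-marker median by more than the
#' configured band (default +/- 10 percentage points, the suggested cutoff
#' for flagging a multiplex run); a run is flagged when its mean MLE does.
#' No flags are possible in a single-section study (no reference median
#' beyond the section itself).
#'
#' In routine use the MLE should be tracked on a positive/run control
#' specimen rather than on study samples whose biology may shift; pass
#' `control_specimen` to restrict the report accordingly.
#'
#' @param gated a gated, phenotyped study.
#' @param config an [mle_config()].
#' @param control_specimen optional specimen name to restrict to.
#' @return list of class `mif_mle`: `$sections` (per section x marker),
#'   `$runs` (per run x marker mean + flag), `$markers` (per marker median,
#'   CV across sections).
#' @export
mle_report <- function(gated, config = mle_config(), control_specimen = NULL) {
  stopifnot(inherits(gated, "mif_gated"), "phenotype" %in% names(gated$cells))
  validate_mle_config(config, gated$phenotypes, gated$markers)
  sec <- gated$sections
  if (!is.null(control_specimen)) {
    if (!control_specimen %in% sec$specimen)
      stop("control specimen '", control_specimen, "' not in study")
    sec <- sec[sec$specimen == control_specimen, , drop = FALSE]
  }
  sec <- sec[sec$assay == "multiplex", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sec))) {
    sc <- gated$cells[gated$cells$section_id == sec$section_id[i], , drop = FALSE]
    for (m in names(config$qualifying)) {
      r <- withCallingHandlers(
        mle_for_marker(sc, m, config, gated$phenotypes),
        warning = function(w) invokeRestart("muffleWarning"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        section_id = sec$section_id[i], specimen = sec$specimen[i],
        run_id = sec$run_id[i], marker = m, mle = r$mle,
        numerator = r$numerator, denominator = r$denominator)
    }
  }
  per_section <- dplyr::bind_rows(rows)
  markers_tab <- per_section |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(
      median_mle = median(.data$mle, na.rm = TRUE),
      cv_mle = if (sum(!is.na(.data$mle)) >= 2) cv(.data$mle) else NA_real_,
      n_sections = dplyr::n(), .groups = "drop")
  flaggable <- nrow(sec) > 1L
  per_section <- per_section |>
    dplyr::left_join(markers_tab[c("marker", "median_mle")], by = "marker") |>
    dplyr::mutate(flag = flaggable & !is.na(.data$mle) &
                    abs(.data$mle - .data$median_mle) > config$band)
  runs_tab <- per_section |>
    dplyr::group_by(.data$run_id, .data$marker) |>
    dplyr::summarise(mean_mle = mean(.data$mle, na.rm = TRUE),
                     median_mle = .data$median_mle[1], .groups = "drop") |>
    dplyr::mutate(flag = flaggable & !is.na(.data$mean_mle) &
                    abs(.data$mean_mle - .data$median_mle) > config$band)
  structure(list(sections = per_section, runs = runs_tab, markers = markers_tab,
                 band = config$band), class = "mif_mle")
}

#' @export
print.mif_mle <- function(x, ...) {
  cat("<mif_mle> band +/-", x$band, "pp\n")
  print(x$markers)
  if (any(x$runs$flag)) {
    cat("flagged runs:\n")
    print(x$runs[x$runs$flag, ])
  } else cat("no flagged runs\n")
  invisible(x)
}
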