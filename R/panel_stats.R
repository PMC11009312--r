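#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation —
#' appropriate for the small replicate counts of serial-section designs.
#' Undefined (returned as `NA` with a warning) for fewer than two values
#' or a zero mean.
#'
#' @param values numeric vector.
#' @return percent CV, or `NA_real_` when undefined.
#' @export
cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    warning("CV undefined: fewer than 2 values")
    return(NA_real_)
  }
  m <- mean(values)
  if (m == 0) {
    warning("CV undefined: mean is zero")
    return(NA_real_)
  }
  100 * sd(values) / m
}

#' Bland-Altman relative difference, in percent
#'
#' `100 * (a - b) / ((a + b) / 2)`: the symmetric convention with the mean
#' of the two measurements in the denominator, antisymmetric under swapping
#' the assays. By convention `a = b = 0` gives 0. Set
#' `denominator = "second"` to divide by `b` instead (e.g. to normalise by
#' the 1-plex value).
#'
#' @param a first measurement (e.g. 4-plex % positive), >= 0.
#' @param b second measurement (e.g. 1-plex % positive), same units, >= 0.
#' @param denominator `"mean"` (default) or `"second"`.
#' @return percent relative difference (vectorised).
#' @export
relative_difference <- function(a, b, denominator = c("mean", "second")) {
  denominator <- match.arg(denominator)
  if (any(a < 0 | b < 0, na.rm = TRUE))
    stop("relative_difference requires non-negative inputs")
  den <- if (denominator == "mean") (a + b) / 2 else b
  out <- 100 * (a - b) / den
  out[!is.na(a) & !is.na(b) & a == 0 & b == 0] <- 0
  out
}

#' Per-section summaries of positivity and intensity
#'
#' For every section, one row per single marker and one per phenotype:
#' total cells, positive cells, % positive, and (markers only) the mean
#' per-cell intensity over positive and over negative cells separately.
#' On singleplex sections only the assayed marker is summarised and
#' phenotypes are skipped (multi-marker calls need all channels).
#'
#' @param gated a gated, phenotyped study ([gate_study()]).
#' @return tibble with columns `section_id`, `specimen`, `run_id`,
#'   `replicate_index`, `assay`, `target`, `type` (`"marker"` or
#'   `"phenotype"`), `n_total`, `n_positive`, `pct_positive`,
#'   `mean_intensity_positive`, `mean_intensity_negative`.
#' @export
section_summaries <- function(gated) {
  stopifnot(inherits(gated, "mif_gated"))
  has_phen <- "phenotype" %in% names(gated$cells)
  out <- list()
  for (i in seq_len(nrow(gated$sections))) {
    meta <- gated$sections[i, ]
    sc <- gated$cells[gated$cells$section_id == meta$section_id, , drop = FALSE]
    n <- nrow(sc)
    sp <- singleplex_marker(meta$assay)
    for (m in gated$markers) {
      if (!is.na(sp) && sp != m) next
      pos <- sc[[paste0("pos_", m)]]
      npos <- sum(pos, na.rm = TRUE)
      out[[length(out) + 1L]] <- tibble::tibble(
        section_id = meta$section_id, specimen = meta$specimen,
        run_id = meta$run_id, replicate_index = meta$replicate_index,
        assay = meta$assay, target = m, type = "marker",
        n_total = n, n_positive = npos,
        pct_positive = if (n > 0) 100 * npos / n else NA_real_,
        mean_intensity_positive = if (npos > 0) mean(sc[[m]][pos %in% TRUE]) else NA_real_,
        mean_intensity_negative = if (n - npos > 0) mean(sc[[m]][pos %in% FALSE]) else NA_real_
      )
    }
    if (has_phen && is.na(sp)) {
      for (p in names(gated$phenotypes)) {
        npos <- sum(sc$phenotype == p)
        out[[length(out) + 1L]] <- tibble::tibble(
          section_id = meta$section_id, specimen = meta$specimen,
          run_id = meta$run_id, replicate_index = meta$replicate_index,
          assay = meta$assay, target = p, type = "phenotype",
          n_total = n, n_positive = npos,
          pct_positive = if (n > 0) 100 * npos / n else NA_real_,
          mean_intensity_positive = NA_real_, mean_intensity_negative = NA_real_
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Concordance report: 1-plex vs 4-plex agreement
#'
#' Pairs each marker's singleplex section with the specimen's multiplex
#' section and reports Bland-Altman relative differences
#' ([relative_difference()], 4-plex minus 1-plex) in % positive cells and
#' in mean intensity of positive cells. Entries with |relative difference|
#' above `band` are flagged; markers whose positive-cell count falls below
#' `low_abundance_floor` in either section are annotated as
#' expected-high-variance (low-abundance markers in cold tumors dominate
#' the large excursions).
#'
#' @param gated a gated concordance study.
#' @param band flag band in percent (default 20).
#' @param low_abundance_floor minimum positive cells per section (default 50).
#' @param denominator passed to [relative_difference()].
#' @return tibble, one row per (specimen, marker) pair present.
#' @export
concordance_report <- function(gated, band = 20, low_abundance_floor = 50,
                               denominator = "mean") {
  ss <- section_summaries(gated)
  ss <- ss[ss$type == "marker", , drop = FALSE]
  out <- list()
  for (sp in unique(gated$sections$specimen)) {
    sec_sp <- gated$sections[gated$sections$specimen == sp, ]
    mx_ids <- sec_sp$section_id[sec_sp$assay == "multiplex"]
    if (length(mx_ids) != 1L)
      stop("concordance design needs exactly one multiplex section per specimen (",
           sp, " has ", length(mx_ids), ")")
    for (m in gated$markers) {
      one_ids <- sec_sp$section_id[sec_sp$assay == paste0("singleplex:", m)]
      if (!length(one_ids)) {
        warning("specimen '", sp, "': no singleplex section for marker '", m,
                "'; skipped")
        next
      }
      s4 <- ss[ss$section_id == mx_ids & ss$target == m, ]
      for (oid in one_ids) {
        s1 <- ss[ss$section_id == oid & ss$target == m, ]
        rd_pct <- relative_difference(s4$pct_positive, s1$pct_positive,
                                      denominator = denominator)
        rd_int <- relative_difference(s4$mean_intensity_positive,
                                      s1$mean_intensity_positive,
                                      denominator = denominator)
        out[[length(out) + 1L]] <- tibble::tibble(
          specimen = sp, marker = m,
          section_1plex = oid, section_4plex = mx_ids,
          pct_positive_1plex = s1$pct_positive,
          pct_positive_4plex = s4$pct_positive,
          rel_diff_pct = rd_pct,
          mean_int_1plex = s1$mean_intensity_positive,
          mean_int_4plex = s4$mean_intensity_positive,
          rel_diff_int = rd_int,
          flag_out_of_band = !is.na(rd_pct) && abs(rd_pct) > band,
          low_abundance = min(s1$n_positive, s4$n_positive) < low_abundance_floor
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Paired intensity histograms of positive and negative cells
#'
#' Normalised histograms of the per-cell mean intensity of `marker` in
#' marker-positive and marker-negative cells of one section, on a shared
#' equal-width bin grid. Their overlap coefficient (sum of bin-wise minima)
#' quantifies signal-to-background delineation: well below 0.05 for a
#' well-separated channel.
#'
#' @param gated a gated study.
#' @param section_id section to summarise.
#' @param marker marker channel.
#' @param n_bins histogram bins (default 50).
#' @return list with `breaks`, `density_positive`, `density_negative`
#'   (each summing to 1; all-`NA` and flagged when a class is empty) and
#'   `overlap`.
#' @export
intensity_histograms <- function(gated, section_id, marker, n_bins = 50L) {
  sc <- gated$cells[gated$cells$section_id == section_id, , drop = FALSE]
  if (!nrow(sc)) stop("no cells for section '", section_id, "'")
  pos <- sc[[paste0("pos_", marker)]]
  v <- sc[[marker]]
  breaks <- seq(min(v), max(v), length.out = n_bins + 1L)
  breaks[1] <- breaks[1] - 1e-9
  count_norm <- function(x) {
    if (!length(x)) return(rep(NA_real_, n_bins))
    h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), nbins = n_bins)
    h / sum(h)
  }
  dp <- count_norm(v[pos %in% TRUE])
  dn <- count_norm(v[pos %in% FALSE])
  list(breaks = breaks, density_positive = dp, density_negative = dn,
       empty_positive = all(is.na(dp)), empty_negative = all(is.na(dn)),
       overlap = if (anyNA(dp) || anyNA(dn)) NA_real_ else sum(pmin(dp, dn)))
}

#' Precision report: intra-run and inter-run CV of % positive cells
#'
#' Per specimen and target (single marker or phenotype): the intra-run CV
#' — [cv()] of % positive across the replicate sections of each run — and
#' the inter-run CV — [cv()] of % positive over **all** sections across all
#' runs, the convention that treats every assay of the study as one
#' measurement series. Runs with a single replicate get a missing intra-run
#' CV (the human-panel design). Targets whose mean positive-cell count per
#' section falls below `low_abundance_floor` are flagged: CV excursions for
#' very low-abundance phenotypes are expected.
#'
#' @param gated a gated, phenotyped precision study.
#' @param cv_cutoff annotation cutoff in percent (default 25).
#' @param low_abundance_floor mean positive cells per section (default 50).
#' @return list of class `mif_precision`: `$intra` (per specimen, target,
#'   run), `$summary` (per specimen, target: `intra_run_cv` = mean of run
#'   CVs, `inter_run_cv`, flags), and the input `cv_cutoff`.
#' @export
precision_report <- function(gated, cv_cutoff = 25, low_abundance_floor = 50) {
  ss <- section_summaries(gated)
  ss <- ss[ss$assay == "multiplex", , drop = FALSE]
  intra <- ss |>
    dplyr::group_by(.data$specimen, .data$target, .data$type, .data$run_id) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      mean_pct = mean(.data$pct_positive),
      cv_pct = if (dplyr::n() >= 2 && mean(.data$pct_positive) > 0)
        cv(.data$pct_positive) else NA_real_,
      .groups = "drop")
  summary <- ss |>
    dplyr::group_by(.data$specimen, .data$target, .data$type) |>
    dplyr::summarise(
      n_sections = dplyr::n(),
      mean_pct = mean(.data$pct_positive),
      mean_n_positive = mean(.data$n_positive),
      inter_run_cv = if (dplyr::n() >= 2 && mean(.data$pct_positive) > 0)
        cv(.data$pct_positive) else NA_real_,
      .groups = "drop")
  intra_means <- intra |>
    dplyr::group_by(.data$specimen, .data$target, .data$type) |>
    dplyr::summarise(intra_run_cv = if (all(is.na(.data$cv_pct))) NA_real_
                     else mean(.data$cv_pct, na.rm = TRUE),
                     .groups = "drop")
  summary <- summary |>
    dplyr::left_join(intra_means, by = c("specimen", "target", "type")) |>
    dplyr::mutate(
      low_abundance = .data$mean_n_positive < low_abundance_floor,
      flag_intra = !is.na(.data$intra_run_cv) & .data$intra_run_cv > cv_cutoff,
      flag_inter = !is.na(.data$inter_run_cv) & .data$inter_run_cv > cv_cutoff)
  structure(list(intra = intra, summary = summary, cv_cutoff = cv_cutoff),
            class = "mif_precision")
}

#' @export
print.mif_precision <- function(x, ...) {
  cat("<mif_precision> cutoff ", x$cv_cutoff, "% CV\n", sep = "")
  print(x$summary, n = 30)
  invisible(x)
}
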