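#' Directional nearest-neighbor distances between two cell sets
#'
#' For each *reference* cell, the Euclidean centroid-to-centroid distance
#' (in microns) to its nearest *target* cell: the "A to B" distance when A
#' is the reference. Directional and generally asymmetric — when B cells
#' are much rarer than A cells, the average A-to-B distance exceeds the
#' average B-to-A distance. A cell belonging to both sets is excluded from
#' the target set while it is the reference (zero self-distances are
#' segmentation artefacts, not biology).
#'
#' Distances are computed blockwise against the full target set, so results
#' equal the brute-force pairwise minimum exactly.
#'
#' @param ref tibble of reference cells (`cell_id`, `x_um`, `y_um`).
#' @param target tibble of target cells (same columns).
#' @return numeric vector, one distance per reference cell (in `ref` row
#'   order).
#' @export
nn_distances <- function(ref, target) {
  if (!nrow(ref) || !nrow(target))
    stop("nn_distances: both reference and target sets must be non-empty")
  tx <- target$x_um; ty <- target$y_um
  tid <- target$cell_id
  n <- nrow(ref)
  out <- numeric(n)
  block <- max(1L, floor(4e6 / length(tx)))
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(s + block - 1L, n)
    d2 <- outer(ref$x_um[idx], tx, "-")^2 + outer(ref$y_um[idx], ty, "-")^2
    same <- outer(ref$cell_id[idx], tid, "==")
    d2[same] <- Inf
    out[idx] <- sqrt(apply(d2, 1L, min))
  }
  if (any(!is.finite(out)))
    stop("nn_distances: a reference cell has no eligible target ",
         "(target set contains only itself)")
  out
}

phenotype_cells <- function(gated, section_id, phenotype) {
  sc <- gated$cells[gated$cells$section_id == section_id, , drop = FALSE]
  sc[sc$phenotype == phenotype, c("cell_id", "x_um", "y_um"), drop = FALSE]
}

#' Nearest-neighbor distance summaries and their reproducibility
#'
#' Per multiplex section, the mean and median nearest-neighbor distance in
#' both directions (`ref -> target` and `target -> ref`) between two
#' phenotypes, plus the cross-section CV of the per-section mean distance:
#' per specimen over all sections of all runs pooled (the headline
#' reproducibility number), with per-run CVs as a supplementary table.
#' Sections lacking either phenotype are skipped and listed in
#' `$skipped_sections`.
#'
#' No edge correction is applied for cells near the field border; with
#' field extents much larger than typical nearest-neighbor distances the
#' bias is small, but summaries from different field sizes are not directly
#' comparable.
#'
#' @param gated a gated, phenotyped study.
#' @param ref_phenotype,target_phenotype phenotype labels.
#' @return list of class `mif_distance`: `$sections` (per section x
#'   direction: n_ref, n_target, mean_nn, median_nn), `$cv` (per specimen x
#'   direction pooled CV), `$cv_by_run`, `$skipped_sections`, and
#'   `$distances` (named list of full per-section distance vectors,
#'   retained for downstream tests and pooled comparisons).
#' @export
distance_report <- function(gated, ref_phenotype, target_phenotype) {
  stopifnot("phenotype" %in% names(gated$cells))
  known <- c(names(gated$phenotypes), "other")
  if (!ref_phenotype %in% known || !target_phenotype %in% known)
    stop("unknown phenotype: ",
         setdiff(c(ref_phenotype, target_phenotype), known)[1])
  sec <- gated$sections[gated$sections$assay == "multiplex", , drop = FALSE]
  rows <- list(); dists <- list(); skipped <- character()
  for (i in seq_len(nrow(sec))) {
    sid <- sec$section_id[i]
    a <- phenotype_cells(gated, sid, ref_phenotype)
    b <- phenotype_cells(gated, sid, target_phenotype)
    if (!nrow(a) || !nrow(b)) {
      warning("section '", sid, "' lacks ", if (!nrow(a)) ref_phenotype
              else target_phenotype, " cells; skipped")
      skipped <- c(skipped, sid)
      next
    }
    for (dir in c("ref_to_target", "target_to_ref")) {
      fwd <- dir == "ref_to_target"
      from <- if (fwd) a else b
      to <- if (fwd) b else a
      rp <- if (fwd) ref_phenotype else target_phenotype
      tp <- if (fwd) target_phenotype else ref_phenotype
      d <- nn_distances(from, to)
      dists[[paste(sid, dir, sep = ".")]] <- d
      rows[[length(rows) + 1L]] <- tibble::tibble(
        section_id = sid, specimen = sec$specimen[i], run_id = sec$run_id[i],
        direction = dir, ref_phenotype = rp, target_phenotype = tp,
        n_ref = nrow(from), n_target = nrow(to),
        mean_nn = mean(d), median_nn = median(d))
    }
  }
  sections <- dplyr::bind_rows(rows)
  cv_tab <- sections |>
    dplyr::group_by(.data$specimen, .data$direction,
                    .data$ref_phenotype, .data$target_phenotype) |>
    dplyr::summarise(n_sections = dplyr::n(),
                     mean_of_means = mean(.data$mean_nn),
                     cv_mean_nn = if (dplyr::n() >= 2) cv(.data$mean_nn) else NA_real_,
                     .groups = "drop")
  cv_run <- sections |>
    dplyr::group_by(.data$specimen, .data$run_id, .data$direction) |>
    dplyr::summarise(n_sections = dplyr::n(),
                     cv_mean_nn = if (dplyr::n() >= 2) cv(.data$mean_nn) else NA_real_,
                     .groups = "drop")
  structure(list(sections = sections, cv = cv_tab, cv_by_run = cv_run,
                 skipped_sections = skipped, distances = dists),
            class = "mif_distance")
}

#' Compare the two directions of a nearest-neighbor distance
#'
#' Pools the per-cell `a -> b` and `b -> a` nearest-neighbor distances over
#' all sections of each specimen and compares the two directions with a
#' two-sided Mann-Whitney (Wilcoxon rank-sum) test. When phenotype `b` is
#' much rarer than `a`, the median `a -> b` distance is expected to exceed
#' the median `b -> a` distance.
#'
#' @param gated a gated, phenotyped study.
#' @param pheno_a,pheno_b phenotype labels (a is the reference of the
#'   first direction).
#' @return tibble, one row per specimen: pooled n and median per direction,
#'   Mann-Whitney `statistic` and `p_value` (NA when either direction has
#'   fewer than 2 distances).
#' @export
compare_directions <- function(gated, pheno_a, pheno_b) {
  rep <- distance_report(gated, pheno_a, pheno_b)
  out <- list()
  for (sp in unique(rep$sections$specimen)) {
    sec_ids <- rep$sections$section_id[rep$sections$specimen == sp]
    pool <- function(dir) unlist(
      rep$distances[paste(unique(sec_ids), dir, sep = ".")], use.names = FALSE)
    ab <- pool("ref_to_target"); ba <- pool("target_to_ref")
    if (length(ab) >= 2 && length(ba) >= 2) {
      if (length(unique(c(ab, ba))) == 1L) {
        # every distance tied across both directions: no evidence of any
        # difference (the normal approximation would return 0/0 here)
        stat <- length(ab) * length(ba) / 2; pval <- 1
      } else {
        wt <- wilcox.test(ab, ba, alternative = "two.sided", exact = FALSE)
        stat <- unname(wt$statistic); pval <- wt$p.value
      }
    } else {
      warning("specimen '", sp, "': too few distances for a direction test")
      stat <- NA_real_; pval <- NA_real_
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      specimen = sp, ref_a = pheno_a, ref_b = pheno_b,
      n_a_to_b = length(ab), n_b_to_a = length(ba),
      median_a_to_b = median(ab), median_b_to_a = median(ba),
      statistic = stat, p_value = pval)
  }
  dplyr::bind_rows(out)
}
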