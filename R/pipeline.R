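#' Pipeline configuration
#'
#' Bundles everything a full validation run needs: the simulation settings
#' (or a pre-existing study), the gating mode, report cutoffs and the
#' master seed. Validated up front — an unknown phenotype name fails here,
#' before any computation.
#'
#' @param sim a [simulation_config()].
#' @param gating_mode `"global"`, `"local"` or `"both"`.
#' @param global_thresholds named numeric vector of per-marker global
#'   cutoffs; default midway between the background and signal medians of
#'   the gain-free intensity model, the stringent fixed-threshold choice.
#' @param phenotypes priority-ordered list of [phenotype_def()]s.
#' @param mle an [mle_config()].
#' @param cv_cutoff CV annotation cutoff in percent (default 25).
#' @param rel_diff_band concordance flag band in percent (default 20).
#' @param spatial_pair character vector of two phenotype names for the
#'   distance analyses (default `c("T_cyt", "T_reg")`).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            gating_mode = c("both", "global", "local"),
                            global_thresholds = default_global_thresholds(sim$intensity),
                            phenotypes = default_phenotypes(),
                            mle = mle_config(),
                            cv_cutoff = 25, rel_diff_band = 20,
                            spatial_pair = c("T_cyt", "T_reg"),
                            seed = 1L) {
  gating_mode <- match.arg(gating_mode)
  stopifnot(cv_cutoff > 0, rel_diff_band > 0, length(spatial_pair) == 2)
  if (!all(names(global_thresholds) %in% sim$markers) ||
      !all(sim$markers %in% names(global_thresholds)))
    stop("global_thresholds must name every panel marker")
  pnames <- vapply(phenotypes, `[[`, "", "name")
  validate_mle_config(mle, setNames(phenotypes, pnames), sim$markers)
  unknown <- setdiff(spatial_pair, pnames)
  if (length(unknown))
    stop("spatial_pair references unknown phenotype '", unknown[1], "'")
  structure(list(sim = sim, gating_mode = gating_mode,
                 global_thresholds = global_thresholds,
                 phenotypes = setNames(phenotypes, pnames), mle = mle,
                 cv_cutoff = cv_cutoff, rel_diff_band = rel_diff_band,
                 spatial_pair = spatial_pair, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Default global thresholds from an intensity model
#'
#' One fixed cutoff per marker, midway between the background and signal
#' medians of the gain-free model — a stand-in for the analyst who fixes a
#' stringent threshold by inspecting images from several runs.
#'
#' @param intensity an [intensity_model()].
#' @return named numeric vector.
#' @export
default_global_thresholds <- function(intensity) {
  setNames((exp(intensity$mu_neg) + exp(intensity$mu_pos)) / 2,
           intensity$marker)
}

#' Run the full validation pipeline
#'
#' Simulates the concordance and precision study designs, gates them
#' (globally, locally, or both), and computes every report: section
#' summaries, 1-plex vs 4-plex concordance, intra-/inter-run precision,
#' MLE, and directional nearest-neighbor distance reproducibility.
#' Deterministic given the config's seed. When `out_dir` is given, writes
#' each report as CSV, a JSON verdict summarising the flags at the
#' configured cutoffs, and a snapshot of every threshold used (the
#' auditability requirement: global-vs-local differences must be
#' inspectable).
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return named list of report objects (invisible `out_dir` paths
#'   attached as attribute `"paths"` when written).
#' @export
run_validation_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  modes <- if (config$gating_mode == "both") c("global", "local") else config$gating_mode
  conc_study <- simulate_concordance_study(config$sim, seed = child_seed(config$seed, "concordance"))
  prec_study <- simulate_precision_study(config$sim, seed = child_seed(config$seed, "precision"))
  res <- list(config = config)
  for (mode in modes) {
    policy_of <- function(study) {
      if (mode == "global") global_policy(config$global_thresholds)
      else fit_local_thresholds(study, floor = config$global_thresholds)
    }
    conc_g <- gate_study(conc_study, policy_of(conc_study), config$phenotypes)
    prec_g <- gate_study(prec_study, policy_of(prec_study), config$phenotypes)
    res[[mode]] <- list(
      thresholds = policy_of(prec_study)$thresholds,
      concordance = concordance_report(conc_g, band = config$rel_diff_band),
      precision = precision_report(prec_g, cv_cutoff = config$cv_cutoff),
      mle = mle_report(prec_g, config$mle),
      spatial = distance_report(prec_g, config$spatial_pair[1], config$spatial_pair[2]),
      directions = compare_directions(prec_g, config$spatial_pair[1], config$spatial_pair[2]),
      summaries = section_summaries(prec_g)
    )
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    verdict <- list(seed = config$seed, cutoffs = list(
      cv = config$cv_cutoff, rel_diff = config$rel_diff_band,
      mle_band = config$mle$band))
    for (mode in modes) {
      r <- res[[mode]]
      pre <- file.path(out_dir, mode)
      write.csv(r$thresholds, paste0(pre, "_thresholds.csv"), row.names = FALSE)
      write.csv(r$concordance, paste0(pre, "_concordance.csv"), row.names = FALSE)
      write.csv(r$precision$summary, paste0(pre, "_precision.csv"), row.names = FALSE)
      write.csv(r$mle$sections, paste0(pre, "_mle.csv"), row.names = FALSE)
      write.csv(r$spatial$sections, paste0(pre, "_spatial.csv"), row.names = FALSE)
      write.csv(r$summaries, paste0(pre, "_section_summaries.csv"), row.names = FALSE)
      verdict[[mode]] <- list(
        n_concordance_flags = sum(r$concordance$flag_out_of_band),
        n_intra_cv_flags = sum(r$precision$summary$flag_intra, na.rm = TRUE),
        n_inter_cv_flags = sum(r$precision$summary$flag_inter, na.rm = TRUE),
        n_mle_run_flags = sum(r$mle$runs$flag, na.rm = TRUE),
        median_intra_cv = median(r$precision$summary$intra_run_cv, na.rm = TRUE),
        median_inter_cv = median(r$precision$summary$inter_run_cv, na.rm = TRUE))
    }
    jsonlite::write_json(verdict, file.path(out_dir, "verdict.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
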