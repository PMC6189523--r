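# Pipeline orchestration: runs any contiguous subset of
# simulate -> fit-mpm -> sample -> depth-stats -> age-map from a RunConfig,
# writing stage outputs and a manifest with seeds and checksums. All
# randomness flows from the config seed.

#' Run the MPM analysis pipeline
#'
#' Executes the configured stages in order. `simulate` builds the cortical
#' model and cohort and (optionally) writes each subject's weighted volumes;
#' `fit-mpm` estimates parameter maps; `sample` writes the tidy
#' depth-sampled and ROI-profile tables; `depth-stats` selects the depth
#' polynomial order per parameter by likelihood-ratio tests; `age-map` runs
#' the jackknifed vertex-wise age analysis. Because the volumetric stages
#' operate per subject in memory, `simulate`/`fit-mpm`/`sample` execute as
#' one fused pass when any of them is requested; stage subsets starting at
#' `depth-stats` or `age-map` reload the tidy tables written earlier.
#'
#' @param config a `run_config` (or list / path accepted by
#'   [run_config()] / [read_run_config()]).
#' @return a `run_manifest`: list with `config`, `config_hash`, `seeds`,
#'   `outputs` (file checksums), `warnings`, `version`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "run_config")) config <- run_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }
  stages <- config$stages
  volumetric <- any(c("simulate", "fit-mpm", "sample") %in% stages)
  files <- character(0)
  if (volumetric) {
    model <- make_cortical_model(
      n_vertices_per_hemisphere = config$n_vertices_per_hemisphere,
      folding_amplitude = config$folding_amplitude,
      n_regions = config$n_regions, seed = config$seed)
    spec <- .config_effect_spec(config)
    cohort <- make_cohort(config$n_subjects, spec = spec,
                          n_regions = config$n_regions,
                          seed = config$seed + 1L)
    files <- c(files, write_cortical_model(model,
                                           file.path(out_dir, "model")))
    subj_f <- file.path(out_dir, "subjects.tsv")
    utils::write.table(cohort$subjects, subj_f, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, subj_f)
    if (isTRUE(config$write_volumes)) {
      gt <- subject_ground_truth(cohort, 1, model)
      fields <- make_field_maps(model, seed = .subject_seed(config$seed, 1L, 1L))
      proto <- mpm_protocol(config$protocol_preset)
      vols <- simulate_weighted_volumes(gt, fields, proto,
                                        noise_sd = spec$noise_sd,
                                        seed = .subject_seed(config$seed, 1L, 2L))
      files <- c(files, write_weighted_volumes(
        vols, file.path(out_dir, "volumes", cohort$subjects$id[1])))
    }
    study <- run_study(model, cohort, fractions = config$depth_fractions,
                       seed = config$seed)
    if ("fit-mpm" %in% stages) {
      gt <- subject_ground_truth(cohort, 1, model)
      fields <- make_field_maps(model, seed = .subject_seed(config$seed, 1L, 1L))
      proto <- mpm_protocol(config$protocol_preset)
      vols <- simulate_weighted_volumes(gt, fields, proto,
                                        noise_sd = spec$noise_sd,
                                        seed = .subject_seed(config$seed, 1L, 2L))
      maps <- fit_all_maps(vols)
      files <- c(files, write_parameter_maps(
        maps, file.path(out_dir, "maps", cohort$subjects$id[1])))
    }
    if (any(c("sample", "depth-stats", "age-map") %in% stages)) {
      prof <- study_roi_profiles(study)
      prof_f <- file.path(out_dir, "roi_profiles.tsv")
      utils::write.table(prof, prof_f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, prof_f)
      k5 <- which.min(abs(config$depth_fractions - 0.5))
      mid <- study$values[, k5, , ]
      mid_f <- file.path(out_dir, "sampled_mid_depth.tsv")
      vt <- study$vertices
      long <- do.call(rbind, lapply(dimnames(study$values)[[3]], function(p) {
        do.call(rbind, lapply(seq_len(nrow(study$subjects)), function(i)
          data.frame(subject = study$subjects$id[i], hemi = vt$hemi,
                     vertex = vt$vertex, depth = study$fractions[k5],
                     parameter = p, value = mid[, p, i])))
      }))
      utils::write.table(long, mid_f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, mid_f)
    }
  } else {
    prof_f <- file.path(out_dir, "roi_profiles.tsv")
    subj_f <- file.path(out_dir, "subjects.tsv")
    if (!file.exists(prof_f) || !file.exists(subj_f))
      stop("stage subset needs previous outputs in ", out_dir)
    prof <- utils::read.table(prof_f, header = TRUE, sep = "\t")
    study <- NULL
  }
  subjects <- utils::read.table(file.path(out_dir, "subjects.tsv"),
                                header = TRUE, sep = "\t")
  if ("depth-stats" %in% stages) {
    sel_out <- list()
    for (p in unique(prof$parameter)) {
      pd <- prof[prof$parameter == p, ]
      sel <- if (identical(config$depth_order, "auto"))
        select_depth_order(pd, subjects)
      else list(order = as.integer(config$depth_order),
                tests = list(),
                fits = list(fit_multilevel_depth(
                  pd, subjects, as.integer(config$depth_order))))
      sel_out[[p]] <- list(
        order = sel$order,
        tests = lapply(sel$tests, function(t)
          list(statistic = t$statistic, df = t$df, p_value = t$p_value)),
        logLik = vapply(sel$fits, function(f) f$logLik, 0),
        converged = vapply(sel$fits, function(f) f$converged, TRUE))
    }
    ds_f <- file.path(out_dir, "depth_stats.json")
    jsonlite::write_json(sel_out, ds_f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, ds_f)
  }
  if ("age-map" %in% stages) {
    if (is.null(study))
      stop("age-map stage requires the volumetric stages in the same run")
    age <- age_effect_mapping(study, q_level = config$q_level)
    vt <- study$vertices
    for (p in age$params) {
      st <- age$stats[[p]]
      st$hemi <- vt$hemi
      st$vertex <- vt$vertex
      f <- file.path(out_dir, paste0("age_stats_", p, ".tsv"))
      utils::write.table(st, f, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    roi_f <- file.path(out_dir, "age_overlap_rois.json")
    jsonlite::write_json(
      lapply(seq_along(age$rois), function(j) list(
        hemi = age$rois[[j]]$hemi, size = age$rois[[j]]$size,
        vertices = age$rois[[j]]$vertices,
        slopes = lapply(age$slopes[[j]], function(s)
          list(intercept = s$intercept, slope = s$slope,
               slope_pct = s$slope_pct, ci = s$ci)))),
      roi_f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, roi_f)
  }
  cfg_f <- file.path(out_dir, "config.json")
  cfg_export <- unclass(config)
  jsonlite::write_json(cfg_export, cfg_f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, cfg_f)
  files <- unique(normalizePath(files))
  manifest <- list(
    version = as.character(utils::packageVersion("mpmcortex")),
    config = cfg_export,
    config_hash = unname(tools::md5sum(cfg_f)),
    seeds = list(master = config$seed),
    outputs = as.list(tools::md5sum(files)),
    warnings = warnings_log)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", length(x$outputs), "outputs, config",
      x$config_hash, "\n")
  invisible(x)
}
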