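# Plain-text surface model and tidy-table IO. Surfaces are written as the
# documented GIFTI fallback: per-hemisphere vertex tables (white and pial
# coordinates, normal, thickness, curvature, region), triangle tables, and
# a JSON metadata file describing the voxel grid and generator parameters.

#' Write a cortical model to a directory of plain-text tables
#'
#' Per hemisphere: `<hemi>_vertices.tsv` (white/pial coordinates, normals,
#' thickness, curvature, region) and `<hemi>_triangles.tsv`; the voxel grid
#' labels go to NIfTI files (`tissue.nii`, `region.nii`, `depth.nii`) and
#' everything else to `model.json`.
#'
#' @param model a `cortical_model`.
#' @param dir output directory.
#' @return files written.
#' @export
write_cortical_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(model$hemis)) {
    h <- model$hemis[[nm]]
    vt <- data.frame(
      white_x = h$white[, 1], white_y = h$white[, 2], white_z = h$white[, 3],
      pial_x = h$pial[, 1], pial_y = h$pial[, 2], pial_z = h$pial[, 3],
      normal_x = h$normals[, 1], normal_y = h$normals[, 2],
      normal_z = h$normals[, 3],
      thickness = h$thickness, curvature = h$curvature, region = h$region)
    f1 <- file.path(dir, paste0(nm, "_vertices.tsv"))
    utils::write.table(vt, f1, sep = "\t", row.names = FALSE, quote = FALSE)
    f2 <- file.path(dir, paste0(nm, "_triangles.tsv"))
    utils::write.table(as.data.frame(h$triangles), f2, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    files <- c(files, f1, f2)
  }
  g <- model$grid
  for (vol in c("tissue", "region", "depth", "hemi", "vidx")) {
    f <- file.path(dir, paste0("grid_", vol, ".nii"))
    write_nifti(g[[vol]] + 0, f, g$voxel_size, g$origin,
                description = paste("model grid:", vol))
    files <- c(files, f)
  }
  fj <- file.path(dir, "model.json")
  jsonlite::write_json(
    list(params = model$params,
         grid = list(dim = g$dim, origin = g$origin,
                     voxel_size = g$voxel_size),
         hemis = lapply(model$hemis, function(h)
           list(nx = h$nx, ny = h$ny, spacing = h$spacing,
                y_offset = h$y_offset))),
    fj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c(files, fj)
}

#' Read a cortical model written by [write_cortical_model()]
#'
#' @param dir directory to read.
#' @return a `cortical_model`.
#' @export
read_cortical_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  hemis <- list()
  for (nm in c("lh", "rh")) {
    vt <- utils::read.table(file.path(dir, paste0(nm, "_vertices.tsv")),
                            header = TRUE, sep = "\t")
    tr <- as.matrix(utils::read.table(
      file.path(dir, paste0(nm, "_triangles.tsv")), header = TRUE,
      sep = "\t"))
    colnames(tr) <- NULL
    nv <- nrow(vt)
    hemis[[nm]] <- list(
      white = as.matrix(vt[, c("white_x", "white_y", "white_z")]),
      pial = as.matrix(vt[, c("pial_x", "pial_y", "pial_z")]),
      normals = as.matrix(vt[, c("normal_x", "normal_y", "normal_z")]),
      thickness = vt$thickness, curvature = vt$curvature,
      region = vt$region, triangles = tr,
      nx = meta$hemis[[nm]]$nx, ny = meta$hemis[[nm]]$ny,
      spacing = meta$hemis[[nm]]$spacing,
      y_offset = meta$hemis[[nm]]$y_offset,
      adjacency = .adjacency_from_triangles(tr, nv), hemi = nm)
    dimnames(hemis[[nm]]$white) <- NULL
    dimnames(hemis[[nm]]$pial) <- NULL
    dimnames(hemis[[nm]]$normals) <- NULL
  }
  dm <- as.integer(meta$grid$dim)
  grid <- list(dim = dm, origin = as.numeric(meta$grid$origin),
               voxel_size = meta$grid$voxel_size)
  for (vol in c("tissue", "region", "depth", "hemi", "vidx")) {
    x <- read_nifti(file.path(dir, paste0("grid_", vol, ".nii")))$data
    grid[[vol]] <- if (vol == "depth") x else {
      y <- array(as.integer(round(x)), dm)
      y[is.na(x)] <- NA_integer_
      y
    }
  }
  structure(list(hemis = hemis, grid = grid, params = meta$params),
            class = "cortical_model")
}

#' Write depth-sampled vertex data as a tidy table
#'
#' One row per subject x hemisphere x vertex x depth x parameter - the
#' canonical tabular hand-off between the sampling, profile-statistics and
#' age-mapping stages.
#'
#' @param sampled `[vertex, depth, parameter]` array from
#'   [sample_parameter_maps()].
#' @param path output `.tsv` path.
#' @param subject subject id for the rows.
#' @return `path` invisibly.
#' @export
write_sampled_table <- function(sampled, path, subject = NA_character_) {
  vt <- attr(sampled, "vertices")
  fr <- attr(sampled, "fractions")
  params <- dimnames(sampled)[[3]]
  rows <- expand.grid(vrow = seq_len(nrow(vt)), depth_idx = seq_along(fr),
                      parameter = params, stringsAsFactors = FALSE)
  df <- data.frame(subject = subject, hemi = vt$hemi[rows$vrow],
                   vertex = vt$vertex[rows$vrow],
                   depth = fr[rows$depth_idx], parameter = rows$parameter,
                   value = sampled[cbind(rows$vrow, rows$depth_idx,
                                         match(rows$parameter, params))])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' JSON with fields: `stages` (subset of simulate/fit-mpm/sample/
#' depth-stats/age-map, contiguous), `out_dir`, `seed`, `protocol_preset`,
#' `n_subjects`, `n_vertices_per_hemisphere`, `n_regions`,
#' `folding_amplitude`, `depth_fractions`, `q_level`, `noise_sd`,
#' `write_volumes`, and `effect_spec` (a list of [effect_spec()] argument
#' overrides, or a path to a JSON file of them). Missing fields take
#' defaults.
#'
#' @param path JSON config file.
#' @return validated named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg named list of settings (see above).
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(
    stages = c("simulate", "fit-mpm", "sample", "depth-stats", "age-map"),
    out_dir = "mpmcortex-run", seed = 1L, protocol_preset = "cohort1",
    n_subjects = 8L, n_vertices_per_hemisphere = 512L, n_regions = 17L,
    folding_amplitude = 3, depth_fractions = seq(0.1, 0.9, by = 0.1),
    q_level = 0.05, noise_sd = NULL, write_volumes = FALSE,
    depth_order = "auto", effect_spec = NULL)
  cfg <- utils::modifyList(defaults, cfg[!vapply(cfg, is.null, TRUE)])
  all_stages <- defaults$stages
  idx <- match(cfg$stages, all_stages)
  if (anyNA(idx)) stop("unknown stage(s): ",
                       paste(cfg$stages[is.na(idx)], collapse = ", "))
  if (length(idx) > 1 && !all(diff(sort(idx)) == 1))
    stop("stages must form a contiguous subset of the pipeline")
  cfg$stages <- all_stages[sort(idx)]
  cfg$seed <- as.integer(cfg$seed)
  if (!cfg$protocol_preset %in% c("cohort1", "cohort2"))
    stop("protocol_preset must be 'cohort1' or 'cohort2'")
  stopifnot(all(diff(cfg$depth_fractions) > 0),
            all(cfg$depth_fractions > 0 & cfg$depth_fractions < 1),
            cfg$q_level > 0, cfg$q_level < 1)
  if (is.character(cfg$effect_spec)) # path to a JSON of effect_spec() args
    cfg$effect_spec <- jsonlite::read_json(cfg$effect_spec,
                                           simplifyVector = TRUE)
  class(cfg) <- "run_config"
  cfg
}

# build the generator spec from config overrides (NULL = package defaults)
.config_effect_spec <- function(cfg) {
  args <- cfg$effect_spec %||% list()
  spec <- do.call(effect_spec, args)
  if (!is.null(cfg$noise_sd)) spec$noise_sd <- cfg$noise_sd
  spec
}
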