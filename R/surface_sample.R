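# Cortical-depth sampling of volumetric maps, ROI x depth aggregation, and
# iterative surface smoothing.

# continuous (1-based) voxel coordinates of physical points
.to_voxel_coords <- function(points, grid_meta) {
  sweep(sweep(points, 2, grid_meta$origin), 2, grid_meta$voxel_size, "/") + 1
}

# Trilinear interpolation of a 3D array at continuous 1-based voxel
# coordinates. Returns NA when the point leaves the grid or any corner with
# nonzero weight is NA.
.trilinear <- function(vol, u) {
  dm <- dim(vol)
  i0 <- floor(u)
  f <- u - i0
  out <- rep(NA_real_, nrow(u))
  inside <- i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1 &
    i0[, 1] <= dm[1] - 1 & i0[, 2] <= dm[2] - 1 & i0[, 3] <= dm[3] - 1
  # points exactly on the upper face
  hi <- u[, 1] <= dm[1] & u[, 2] <= dm[2] & u[, 3] <= dm[3] &
    (i0[, 1] == dm[1] | i0[, 2] == dm[2] | i0[, 3] == dm[3]) &
    i0[, 1] >= 1 & i0[, 2] >= 1 & i0[, 3] >= 1
  if (any(hi)) {
    i0[hi, ] <- pmin(i0[hi, , drop = FALSE],
                     matrix(dm - 1L, sum(hi), 3, byrow = TRUE))
    f[hi, ] <- u[hi, , drop = FALSE] - i0[hi, , drop = FALSE]
  }
  ok <- inside | hi
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  acc <- numeric(nrow(i0))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    v <- vol[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
    acc <- acc + w * ifelse(w == 0 & is.na(v), 0, v)
  }
  out[ok] <- acc
  out
}

#' Sample a volume along vertex normals at cortical depth fractions
#'
#' For every vertex `v` and depth fraction `d`, the sample point is
#' `white_v + d (pial_v - white_v)` (the straight white-to-pial
#' correspondence, i.e. along the vertex normal), interpolated trilinearly
#' from the volume. Samples falling outside the volume, or touching invalid
#' (NA) voxels, are returned as missing and counted.
#'
#' @param volume 3D array in the model's physical space (NA = invalid
#'   voxel).
#' @param model a `cortical_model`.
#' @param fractions strictly increasing depth fractions in (0, 1); default
#'   0.1 to 0.9 in steps of 0.1.
#' @param grid_meta volume geometry (`dim`, `origin`, `voxel_size`);
#'   defaults to the model's own grid.
#' @param method `"trilinear"` or `"nearest"`.
#' @return matrix `[n_vertices_total, n_fractions]` of samples (rows ordered
#'   as [model_vertex_table()]), with attributes `fractions`, `vertices`
#'   (the vertex table) and `n_missing`.
#' @export
sample_depth <- function(volume, model, fractions = seq(0.1, 0.9, by = 0.1),
                         grid_meta = NULL, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(all(diff(fractions) > 0), all(fractions > 0 & fractions < 1))
  if (is.null(grid_meta))
    grid_meta <- list(dim = model$grid$dim, origin = model$grid$origin,
                      voxel_size = model$grid$voxel_size)
  if (!identical(dim(volume), as.integer(grid_meta$dim)) &&
      !identical(dim(volume), grid_meta$dim))
    stop("volume dimensions do not match the grid metadata")
  white <- do.call(rbind, lapply(model$hemis, function(h) h$white))
  pial <- do.call(rbind, lapply(model$hemis, function(h) h$pial))
  nv <- nrow(white)
  out <- matrix(NA_real_, nv, length(fractions))
  for (k in seq_along(fractions)) {
    pts <- white + fractions[k] * (pial - white)
    u <- .to_voxel_coords(pts, grid_meta)
    out[, k] <- if (method == "trilinear") .trilinear(volume, u)
    else {
      ui <- round(u)
      ok <- ui[, 1] >= 1 & ui[, 2] >= 1 & ui[, 3] >= 1 &
        ui[, 1] <= dim(volume)[1] & ui[, 2] <= dim(volume)[2] &
        ui[, 3] <= dim(volume)[3]
      val <- rep(NA_real_, nv)
      val[ok] <- volume[ui[ok, , drop = FALSE]]
      val
    }
  }
  attr(out, "fractions") <- fractions
  attr(out, "vertices") <- model_vertex_table(model)
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Sample all four parameter maps over depth fractions
#'
#' @param maps a `parameter_maps` object.
#' @param model a `cortical_model`.
#' @param fractions depth fractions (see [sample_depth()]).
#' @param params which maps to sample.
#' @return 3D array `[vertex, depth, parameter]` with the attributes of
#'   [sample_depth()].
#' @export
sample_parameter_maps <- function(maps, model,
                                  fractions = seq(0.1, 0.9, by = 0.1),
                                  params = c("R1", "R2star", "MTsat",
                                             "PDstar")) {
  stopifnot(inherits(maps, "parameter_maps"))
  sm <- lapply(params, function(p)
    sample_depth(maps[[p]], model, fractions, maps$grid_meta))
  out <- array(NA_real_, c(nrow(sm[[1]]), length(fractions), length(params)),
               dimnames = list(NULL, NULL, params))
  for (k in seq_along(params)) out[, , k] <- sm[[k]]
  attr(out, "fractions") <- fractions
  attr(out, "vertices") <- attr(sm[[1]], "vertices")
  out
}

#' ROI x depth mean profiles, averaged across hemispheres
#'
#' Means are taken over vertices within each ROI per hemisphere and the two
#' hemisphere means are then averaged unweighted (so unequal hemisphere
#' vertex counts do not bias the profile). An ROI empty in one hemisphere is
#' reported from the other with a warning.
#'
#' @param sampled output of [sample_parameter_maps()] (or a single
#'   [sample_depth()] matrix).
#' @param model the `cortical_model` used for sampling.
#' @param subject optional subject id attached to the rows.
#' @return tidy data.frame: `subject`, `region`, `depth`, `parameter`,
#'   `value`, `n_vertices` (summed over contributing hemispheres).
#' @export
roi_depth_means <- function(sampled, model, subject = NA_character_) {
  if (length(dim(sampled)) == 2) {
    sampled <- array(sampled, c(dim(sampled), 1),
                     dimnames = list(NULL, NULL, "value"))
  }
  fractions <- attr(sampled, "fractions")
  vt <- model_vertex_table(model)
  params <- dimnames(sampled)[[3]]
  res <- list()
  for (p in seq_along(params)) {
    for (k in seq_along(fractions)) {
      v <- sampled[, k, p]
      hm <- tapply(v, list(vt$region, vt$hemi), mean, na.rm = TRUE)
      cnt <- tapply(!is.na(v), list(vt$region, vt$hemi), sum)
      miss <- is.na(hm) | cnt == 0
      if (any(miss) && k == 1 && p == 1)
        warning("some ROIs are empty in one hemisphere; reporting the other")
      hm[cnt == 0] <- NA
      value <- rowMeans(hm, na.rm = TRUE)
      res[[length(res) + 1]] <- data.frame(
        subject = subject, region = as.integer(rownames(hm)),
        depth = fractions[k], parameter = params[p],
        value = as.numeric(value),
        n_vertices = as.integer(rowSums(cnt, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out[out$n_vertices > 0, , drop = FALSE]
}

#' Iterative nearest-neighbour surface smoothing
#'
#' `n_steps` iterations of replacing each vertex value by the mean of
#' itself and its mesh neighbours (missing values are excluded from each
#' neighbourhood mean). Ten steps approximate a 2D Gaussian kernel of about
#' 3 mm FWHM on a 1 mm mesh. Used for map display/export only - never
#' before statistics.
#'
#' @param values numeric vector of per-vertex scalars (NA = missing).
#' @param adjacency adjacency list (as in `model$hemis[[h]]$adjacency`).
#' @param n_steps number of smoothing iterations (0 = identity).
#' @return smoothed vector.
#' @export
surface_smooth <- function(values, adjacency, n_steps = 10) {
  stopifnot(n_steps >= 0, length(values) == length(adjacency))
  if (n_steps == 0) return(values)
  nbr <- lapply(seq_along(adjacency), function(i) c(i, adjacency[[i]]))
  idx <- unlist(nbr)
  grp <- rep(seq_along(nbr), lengths(nbr))
  for (s in seq_len(n_steps)) {
    x <- values[idx]
    ok <- !is.na(x)
    sums <- tapply(ifelse(ok, x, 0), grp, sum)
    cnts <- tapply(ok, grp, sum)
    values <- as.numeric(ifelse(cnts > 0, sums / cnts, NA))
  }
  values
}
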