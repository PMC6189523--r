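# Synthetic cortical geometry: a parametric corrugated ribbon standing in
# for a reconstructed cortical surface. Each hemisphere is a height-field
# sheet z = a * sin(2*pi*x/Lx + px) * cos(2*pi*y/Ly + py) over a regular
# vertex lattice, with analytic normals and mean curvature, a pial surface
# offset from the white surface along the vertex normal by a spatially
# varying thickness, contiguous region labels, and a voxel grid labelled
# with tissue class and cortical depth fraction.
#
# Curvature sign convention (used everywhere in the package): positive =
# concave (sulcal fundus), negative = convex (gyral crown). Gyral crowns are
# made thicker than sulcal depths, mirroring real cortex.

.run_seeded <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.hemi_sheet <- function(nx, ny, spacing, amplitude, wave_x, wave_y,
                        phase_x, phase_y, y_offset,
                        thickness_mid, thickness_gain, curvature_scale) {
  x <- (seq_len(nx) - 1) * spacing
  y <- (seq_len(ny) - 1) * spacing + y_offset
  X <- matrix(x, nx, ny)
  Y <- matrix(y, nx, ny, byrow = TRUE)
  kx <- 2 * pi / wave_x
  ky <- 2 * pi / wave_y
  sx <- sin(kx * X + phase_x); cx <- cos(kx * X + phase_x)
  sy <- sin(ky * (Y - y_offset) + phase_y); cy <- cos(ky * (Y - y_offset) + phase_y)
  Z <- amplitude * sx * cy
  fx <- amplitude * kx * cx * cy
  fy <- -amplitude * ky * sx * sy
  fxx <- -amplitude * kx^2 * sx * cy
  fyy <- -amplitude * ky^2 * sx * cy
  fxy <- -amplitude * kx * ky * cx * sy
  nrm <- sqrt(1 + fx^2 + fy^2)
  # mean curvature of z = f(x, y); with the upward (outward) normal this is
  # negative on crowns (convex) and positive in fundi (concave)
  H <- ((1 + fy^2) * fxx - 2 * fx * fy * fxy + (1 + fx^2) * fyy) /
    (2 * nrm^3)
  H <- -H # flip so crowns (local maxima, fxx<0) come out negative
  Hn <- if (curvature_scale > 0) pmin(pmax(H / curvature_scale, -1), 1) else H * 0
  thickness <- pmin(pmax(thickness_mid - thickness_gain * Hn, 1.5), 4)
  white <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  normals <- cbind(as.vector(-fx / nrm), as.vector(-fy / nrm),
                   as.vector(1 / nrm))
  tvec <- as.vector(thickness)
  pial <- white + normals * tvec
  # lattice triangulation
  i <- rep(seq_len(nx - 1), ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  a <- (j - 1) * nx + i
  b <- a + 1
  c_ <- a + nx
  d <- c_ + 1
  triangles <- rbind(cbind(a, b, c_), cbind(b, d, c_))
  colnames(triangles) <- NULL
  list(white = white, pial = pial, normals = normals,
       thickness = tvec, curvature = as.vector(H),
       triangles = triangles, nx = nx, ny = ny,
       x_range = range(x), y_range = range(y), spacing = spacing,
       phase_x = phase_x, phase_y = phase_y,
       amplitude = amplitude, wave_x = wave_x, wave_y = wave_y,
       y_offset = y_offset)
}

.adjacency_from_triangles <- function(triangles, n_vertices) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(1, 3)])
  e <- rbind(e, e[, 2:1])
  key <- (e[, 1] - 1) * n_vertices + e[, 2]
  e <- e[!duplicated(key), , drop = FALSE]
  adj <- split(e[, 2], factor(e[, 1], levels = seq_len(n_vertices)))
  lapply(adj, function(v) sort(unique(v)))
}

#' Generate a synthetic folded cortical model
#'
#' Builds two hemispheres, each a sinusoidally corrugated sheet over a
#' regular vertex lattice: a white surface, a pial surface offset along the
#' outward unit normal by a spatially varying thickness (1.5-4 mm, thicker
#' on convex gyral crowns, thinner in concave sulcal depths), analytic mean
#' curvature (positive = concave/sulcal, negative = convex/gyral),
#' contiguous region labels (bands along the long axis, shared between
#' hemispheres), a lattice triangulation with vertex adjacency, and a voxel
#' grid containing the ribbon in which every voxel is labelled as
#' background, white matter, grey matter (with region id, cortical depth
#' fraction and associated vertex) or CSF.
#'
#' @param n_vertices_per_hemisphere requested vertex count (>= 100); the
#'   realized count is the nearest `nx * ny` lattice (reported in the
#'   result).
#' @param folding_amplitude corrugation amplitude in mm; 0 gives a flat slab
#'   with zero curvature and constant thickness.
#' @param voxel_size isotropic voxel size of the label grid, mm.
#' @param n_regions number of contiguous regions per hemisphere (>= 2; the
#'   emulated parcellation uses 17).
#' @param seed integer seed controlling the hemisphere-specific corrugation
#'   phases.
#' @param thickness_mid,thickness_gain midpoint (mm) and curvature-coupled
#'   modulation (mm) of cortical thickness.
#' @param wm_depth,csf_depth thickness (mm) of the white-matter slab beneath
#'   the white surface and the CSF slab above the pial surface.
#' @return An object of class `cortical_model`.
#' @export
#' @examples
#' m <- make_cortical_model(200, folding_amplitude = 2, n_regions = 4, seed = 1)
#' range(m$hemis$lh$thickness)
make_cortical_model <- function(n_vertices_per_hemisphere = 2048,
                                folding_amplitude = 3,
                                voxel_size = 1,
                                n_regions = 17,
                                seed = 1,
                                thickness_mid = 2.75,
                                thickness_gain = 1.25,
                                wm_depth = 3,
                                csf_depth = 2) {
  stopifnot(n_vertices_per_hemisphere >= 100, n_regions >= 2,
            folding_amplitude >= 0, voxel_size > 0)
  spacing <- 1
  ny <- max(6L, round(sqrt(n_vertices_per_hemisphere / 2)))
  nx <- max(2L * n_regions, ceiling(n_vertices_per_hemisphere / ny))
  wave_x <- 20; wave_y <- 24
  kappa_max <- folding_amplitude *
    max((2 * pi / wave_x)^2, (2 * pi / wave_y)^2)
  phases <- .run_seeded(seed, stats::runif(4, 0, 2 * pi))
  gap <- 8
  Ly <- (ny - 1) * spacing
  hemis <- list(
    lh = .hemi_sheet(nx, ny, spacing, folding_amplitude, wave_x, wave_y,
                     phases[1], phases[2], 0,
                     thickness_mid, thickness_gain, kappa_max / 2),
    rh = .hemi_sheet(nx, ny, spacing, folding_amplitude, wave_x, wave_y,
                     phases[3], phases[4], Ly + gap,
                     thickness_mid, thickness_gain, kappa_max / 2)
  )
  # self-intersection diagnostic: offsetting a concave surface patch along
  # the normal fails once the offset reaches the radius of curvature; mean
  # curvature is halved relative to the max principal curvature, hence the
  # factor 2
  for (h in hemis) {
    concave <- pmax(h$curvature, 0)
    if (max(h$thickness * concave * 2) >= 0.95)
      stop("degenerate geometry: pial surface would self-intersect ",
           "(folding too strong for the requested thickness)")
  }
  region_of_col <- ceiling(seq_len(nx) / nx * n_regions)
  nv <- nx * ny
  for (nm in names(hemis)) {
    hemis[[nm]]$region <- rep(region_of_col, ny)
    hemis[[nm]]$adjacency <- .adjacency_from_triangles(hemis[[nm]]$triangles, nv)
    hemis[[nm]]$hemi <- nm
  }
  grid <- .voxelize_ribbon(hemis, voxel_size, wm_depth, csf_depth)
  structure(list(
    hemis = hemis, grid = grid,
    params = list(n_vertices_per_hemisphere = nv, n_regions = n_regions,
                  folding_amplitude = folding_amplitude,
                  voxel_size = voxel_size, seed = seed,
                  thickness_mid = thickness_mid,
                  thickness_gain = thickness_gain,
                  wm_depth = wm_depth, csf_depth = csf_depth)
  ), class = "cortical_model")
}

# Label every voxel of a grid containing both hemisphere ribbons. For each
# voxel center the nearest vertex normal line is found among a 3x3 lattice
# window; the signed distance along that normal gives the tissue class and
# (in GM) the depth fraction.
.voxelize_ribbon <- function(hemis, voxel_size, wm_depth, csf_depth) {
  margin <- 2
  allz <- unlist(lapply(hemis, function(h) c(h$white[, 3], h$pial[, 3])))
  x_lo <- min(sapply(hemis, function(h) h$x_range[1])) - margin
  x_hi <- max(sapply(hemis, function(h) h$x_range[2])) + margin
  y_lo <- min(sapply(hemis, function(h) h$y_range[1])) - margin
  y_hi <- max(sapply(hemis, function(h) h$y_range[2])) + margin
  z_lo <- min(allz) - wm_depth - margin
  z_hi <- max(allz) + csf_depth + margin
  dim <- as.integer(c(ceiling((x_hi - x_lo) / voxel_size),
                      ceiling((y_hi - y_lo) / voxel_size),
                      ceiling((z_hi - z_lo) / voxel_size)))
  origin <- c(x_lo, y_lo, z_lo) + voxel_size / 2 # center of voxel [1,1,1]
  nvox <- prod(dim)
  cx <- origin[1] + (seq_len(dim[1]) - 1) * voxel_size
  cy <- origin[2] + (seq_len(dim[2]) - 1) * voxel_size
  cz <- origin[3] + (seq_len(dim[3]) - 1) * voxel_size
  px <- rep(cx, times = dim[2] * dim[3])
  py <- rep(rep(cy, each = dim[1]), times = dim[3])
  pz <- rep(cz, each = dim[1] * dim[2])
  tissue <- integer(nvox) # 0 bg, 1 WM, 2 GM, 3 CSF
  region <- rep(NA_integer_, nvox)
  depth <- rep(NA_real_, nvox)
  hemi <- rep(NA_integer_, nvox)
  vidx <- rep(NA_integer_, nvox)
  # normal lines diverge above convex crowns (by 1 + dd * curvature), so
  # the lateral catchment must be wider than the lattice spacing or the
  # ribbon gets spurious background holes
  lat_tol <- 2 * max(voxel_size, hemis$lh$spacing)
  y_split <- (hemis$lh$y_range[2] + hemis$rh$y_range[1]) / 2
  for (hi in seq_along(hemis)) {
    h <- hemis[[hi]]
    sel <- if (hi == 1) py <= y_split else py > y_split
    sel <- which(sel)
    if (!length(sel)) next
    qx <- px[sel]; qy <- py[sel]; qz <- pz[sel]
    ix0 <- round((qx - h$x_range[1]) / h$spacing) + 1
    iy0 <- round((qy - h$y_range[1]) / h$spacing) + 1
    best_lat <- rep(Inf, length(sel))
    best_dd <- rep(NA_real_, length(sel))
    best_v <- rep(NA_integer_, length(sel))
    for (dx in -1:1) for (dy in -1:1) {
      ix <- pmin(pmax(ix0 + dx, 1L), h$nx)
      iy <- pmin(pmax(iy0 + dy, 1L), h$ny)
      v <- (iy - 1L) * h$nx + ix
      wx <- qx - h$white[v, 1]; wy <- qy - h$white[v, 2]; wz <- qz - h$white[v, 3]
      dd <- wx * h$normals[v, 1] + wy * h$normals[v, 2] + wz * h$normals[v, 3]
      lat2 <- (wx - dd * h$normals[v, 1])^2 + (wy - dd * h$normals[v, 2])^2 +
        (wz - dd * h$normals[v, 3])^2
      better <- lat2 < best_lat
      best_lat[better] <- lat2[better]
      best_dd[better] <- dd[better]
      best_v[better] <- v[better]
    }
    ok <- sqrt(best_lat) <= lat_tol
    tv <- h$thickness[best_v]
    dfrac <- best_dd / tv
    cls <- integer(length(sel))
    cls[ok & dfrac >= 0 & dfrac <= 1] <- 2L
    cls[ok & best_dd < 0 & best_dd >= -wm_depth] <- 1L
    cls[ok & best_dd > tv & best_dd <= tv + csf_depth] <- 3L
    idx <- sel[cls > 0L]
    tissue[idx] <- cls[cls > 0L]
    hemi[idx] <- hi
    vidx[idx] <- best_v[cls > 0L]
    gm <- cls == 2L
    region[sel[gm]] <- h$region[best_v[gm]]
    depth[sel[gm]] <- pmin(pmax(dfrac[gm], 0), 1)
  }
  list(dim = dim, origin = origin, voxel_size = voxel_size,
       tissue = array(tissue, dim), region = array(region, dim),
       depth = array(depth, dim), hemi = array(hemi, dim),
       vidx = array(vidx, dim))
}

#' @export
print.cortical_model <- function(x, ...) {
  g <- x$grid
  cat("<cortical_model>", x$params$n_vertices_per_hemisphere,
      "vertices/hemisphere,", x$params$n_regions, "regions\n")
  cat("  grid", paste(g$dim, collapse = " x "), "voxels at",
      g$voxel_size, "mm;",
      sum(g$tissue == 2), "GM,", sum(g$tissue == 1), "WM,",
      sum(g$tissue == 3), "CSF\n")
  invisible(x)
}

#' Vertex bookkeeping table for a cortical model
#'
#' @param model a `cortical_model`.
#' @return data.frame with one row per vertex across both hemispheres:
#'   `hemi` ("lh"/"rh"), `vertex` (within-hemisphere index), `region`,
#'   `thickness`, `curvature`.
#' @export
model_vertex_table <- function(model) {
  do.call(rbind, lapply(names(model$hemis), function(nm) {
    h <- model$hemis[[nm]]
    data.frame(hemi = nm, vertex = seq_len(nrow(h$white)),
               region = h$region, thickness = h$thickness,
               curvature = h$curvature, stringsAsFactors = FALSE)
  }))
}
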