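#' Smooth transmit- and receive-field maps
#'
#' Generates spatially smooth multiplicative field maps over a cortical
#' model's voxel grid: transmit efficiency `f_T` (actual flip angle =
#' `f_T` x nominal) and receive sensitivity `g_R`. Each field is
#' `1 + amplitude * sin(pi x / Lx + phase) * sin(pi y / Ly + phase')`, a
#' half-period modulation across the field of view, so gradients are bounded
#' by `amplitude * pi / L` per mm.
#'
#' @param model a `cortical_model`.
#' @param f_t_amplitude,g_r_amplitude peak deviation from unity.
#' @param seed integer seed for the field phases.
#' @return list of class `field_maps` with 3D arrays `f_T` and `g_R`.
#' @export
make_field_maps <- function(model, f_t_amplitude = 0.1, g_r_amplitude = 0.1,
                            seed = 1) {
  g <- model$grid
  stopifnot(f_t_amplitude >= 0, f_t_amplitude < 1,
            g_r_amplitude >= 0, g_r_amplitude < 1)
  ph <- .run_seeded(seed, stats::runif(4, 0, 2 * pi))
  cx <- (seq_len(g$dim[1]) - 1) * g$voxel_size
  cy <- (seq_len(g$dim[2]) - 1) * g$voxel_size
  Lx <- max(cx) + g$voxel_size
  Ly <- max(cy) + g$voxel_size
  field <- function(a, p1, p2) {
    fx <- sin(pi * cx / Lx + p1)
    fy <- sin(pi * cy / Ly + p2)
    plane <- outer(fx, fy)
    array(rep(1 + a * plane, g$dim[3]), g$dim)
  }
  structure(list(f_T = field(f_t_amplitude, ph[1], ph[2]),
                 g_R = field(g_r_amplitude, ph[3], ph[4]),
                 seed = seed),
            class = "field_maps")
}

#' Forward-simulate the three weighted multi-echo FLASH volume sets
#'
#' For every weighting `w` and echo `i`, the voxel signal in tissue is
#' `g_R * flash_signal(A, R1, R2*, delta * [w = MTw], f_T * alpha_w, TR_w,
#' TE_w[i])` plus noise; background voxels contain pure noise. Noise is
#' Gaussian by default (valid for magnitude data at the simulated SNR) and
#' independent across voxels, echoes and weightings; a Rician magnitude
#' option is available.
#'
#' @param ground_truth a `tissue_ground_truth` (see
#'   [subject_ground_truth()]), or any list of congruent arrays `R1`,
#'   `R2star`, `MTdelta`, `A`.
#' @param fields a `field_maps` object congruent with the ground truth.
#' @param protocol an `mpm_protocol`.
#' @param noise_sd Gaussian noise SD in signal units (0 for noiseless).
#' @param seed integer seed; recorded in the result.
#' @param forward_model `"ernst"` (exact steady state) or `"small_angle"`
#'   (the rational approximation; useful for exactness tests).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @return object of class `weighted_volumes`: `$signals` (list of 4D
#'   arrays, echo as 4th dimension), `$protocol`, `$fields`, `$tissue`
#'   (label array: 0 background, 1 WM, 2 GM, 3 CSF), `$grid_meta`,
#'   `$noise_sd`, `$forward_model`, `$seed`.
#' @export
simulate_weighted_volumes <- function(ground_truth, fields, protocol,
                                      noise_sd = NULL, seed = 1,
                                      forward_model = c("ernst", "small_angle"),
                                      noise_model = c("gaussian", "rician")) {
  forward_model <- match.arg(forward_model)
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(protocol, "mpm_protocol"))
  dm <- dim(ground_truth$A)
  if (!identical(dm, dim(fields$f_T)) || !identical(dm, dim(fields$g_R)))
    stop("ground truth and field maps are not congruent")
  if (is.null(noise_sd)) noise_sd <- 0
  tissue <- ground_truth$tissue %||% {
    t0 <- array(0L, dm)
    t0[ground_truth$A > 0] <- 2L
    t0
  }
  if (!is.null(ground_truth$grid_meta) &&
      !identical(ground_truth$grid_meta$dim, dm))
    stop("ground truth grid metadata does not match its arrays")
  mask <- which(ground_truth$A > 0)
  A <- ground_truth$A[mask]
  R1 <- ground_truth$R1[mask]
  R2s <- ground_truth$R2star[mask]
  delta <- ground_truth$MTdelta[mask]
  fT <- fields$f_T[mask]
  gR <- fields$g_R[mask]
  signals <- list()
  .run_seeded(seed, {
    for (nm in names(protocol$weightings)) {
      ww <- protocol$weightings[[nm]]
      nte <- length(ww$TE)
      sig <- array(0, c(dm, nte))
      nvox <- prod(dm)
      for (i in seq_len(nte)) {
        clean <- numeric(nvox)
        clean[mask] <- gR * flash_signal(
          A, R1, R2s, if (ww$mt_pulse) delta else 0,
          fT * ww$flip_rad, ww$TR, ww$TE[i], model = forward_model)
        if (noise_sd > 0) {
          if (noise_model == "gaussian") {
            clean <- clean + stats::rnorm(nvox, 0, noise_sd)
          } else {
            clean <- sqrt((clean + stats::rnorm(nvox, 0, noise_sd))^2 +
                            stats::rnorm(nvox, 0, noise_sd)^2)
          }
        }
        sig[(i - 1) * nvox + seq_len(nvox)] <- clean
      }
      signals[[nm]] <- sig
    }
  })
  meta <- ground_truth$grid_meta %||%
    list(dim = dm, origin = c(0, 0, 0), voxel_size = 1)
  structure(list(signals = signals, protocol = protocol, fields = fields,
                 tissue = tissue, grid_meta = meta, noise_sd = noise_sd,
                 forward_model = forward_model, noise_model = noise_model,
                 seed = seed),
            class = "weighted_volumes")
}

#' @export
print.weighted_volumes <- function(x, ...) {
  cat("<weighted_volumes> cohort", x$protocol$cohort_id, "preset,",
      paste(names(x$signals), collapse = "/"), "\n")
  cat("  grid", paste(x$grid_meta$dim, collapse = " x "),
      "; echoes:", paste(vapply(x$signals, function(s) dim(s)[4], 0L),
                         collapse = "/"),
      "; noise_sd", x$noise_sd, "(", x$noise_model, ")\n")
  invisible(x)
}
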