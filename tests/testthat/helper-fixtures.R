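# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

tiny_model <- function() fixture("tiny_model", function()
  make_cortical_model(n_vertices_per_hemisphere = 200, folding_amplitude = 2,
                      n_regions = 4, seed = 101))

tiny_cohort <- function() fixture("tiny_cohort", function()
  make_cohort(n_subjects = 4, spec = effect_spec(), n_regions = 4,
              seed = 102))

# noiseless small-angle-consistent simulation on the tiny phantom
tiny_volumes_small_angle <- function() fixture("tiny_vol_sa", function() {
  gt <- subject_ground_truth(tiny_cohort(), 1, tiny_model())
  fields <- make_field_maps(tiny_model(), seed = 103)
  simulate_weighted_volumes(gt, fields, mpm_protocol("cohort1"),
                            noise_sd = 0, seed = 104,
                            forward_model = "small_angle")
})

tiny_ground_truth <- function() fixture("tiny_gt", function()
  subject_ground_truth(tiny_cohort(), 1, tiny_model()))

# a single synthetic voxel's multi-echo signals for ESTATICS tests
voxel_signals <- function(A = c(PDw = 500, T1w = 700, MTw = 450),
                          R2star = 20, protocol = mpm_protocol("cohort1"),
                          noise_sd = 0, seed = 1) {
  set.seed(seed)
  out <- lapply(names(protocol$weightings), function(w) {
    te <- protocol$weightings[[w]]$TE
    A[[w]] * exp(-te / 1000 * R2star) + stats::rnorm(length(te), 0, noise_sd)
  })
  names(out) <- names(protocol$weightings)
  out
}

# wrap per-voxel signal vectors into a 1x1xN weighted_volumes-like object
as_weighted_volumes <- function(signal_list, protocol,
                                n_voxels = length(signal_list[[1]][[1]])) {
  # signal_list: list over weightings of matrices [echo, voxel]
  dm <- c(n_voxels, 1L, 1L)
  signals <- lapply(signal_list, function(sm) {
    sm <- as.matrix(sm)
    array(t(sm), c(dm, nrow(sm)))
  })
  structure(list(signals = signals, protocol = protocol,
                 fields = list(f_T = array(1, dm), g_R = array(1, dm)),
                 tissue = array(2L, dm),
                 grid_meta = list(dim = dm, origin = c(0, 0, 0),
                                  voxel_size = 1),
                 noise_sd = NA_real_, forward_model = "synthetic",
                 noise_model = "none", seed = NA_integer_),
            class = "weighted_volumes")
}
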