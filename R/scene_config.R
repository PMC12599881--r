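#' Scene configuration for the synthetic optic-nerve generator
#'
#' Bundles every tunable of the synthetic scene generator: nerve and axon
#' geometry, imaging parameters (single-plane time series at 1 Hz for 60
#' frames; z-scans at 1 um steps), the transport model (movement-state
#' fractions, anterograde/retrograde speed distributions), state-dependent
#' two-channel coupling, extra-axonal deposit fractions and their
#' surface-versus-parenchyma split, protrusion morphodynamics, PSF blur,
#' Poisson-Gaussian noise and frame drift.
#'
#' Defaults encode the baseline conditions the analysis is validated
#' against: roughly half of axonal organelles stationary and a quarter
#' moving each direction, mean speeds 0.63 (anterograde) and 0.78
#' (retrograde) um/s, co-localization coupling enriched in the stationary
#' pool, and noise calibrated so spot-peak SNR is about 5.
#'
#' @param nerve_diameter_um Nerve diameter (um).
#' @param axon_length_um Length of the imaged axon segment / field (um).
#' @param n_axons Number of parallel axon lanes across the nerve.
#' @param axon_diameter_um Axon diameter (um).
#' @param pixel_size_um Lateral pixel size (um).
#' @param frame_interval_s Time between frames (s).
#' @param n_frames Number of frames in a time series (>= 2).
#' @param z_step_um Axial step of z-scans (um).
#' @param n_particles Number of particles per simulated scene.
#' @param state_fractions Named or ordered length-3 vector
#'   (stationary, anterograde, retrograde); must sum to 1.
#' @param speed_mean_antero_um_s,speed_mean_retro_um_s Mean speeds of the
#'   moving pools (um/s, unsigned).
#' @param speed_sd_um_s SD of moving speeds (um/s).
#' @param min_moving_speed_um_s Lower truncation of drawn moving speeds, kept
#'   above the 0.1 um/s classification boundary so ground truth is
#'   unambiguous.
#' @param stationary_jitter_sd_um Per-frame positional jitter SD of
#'   stationary particles (um), applied as a Brownian bridge.
#' @param stationary_net_sd_um_s SD of the Gaussian net drift of stationary
#'   (docked) particles (um/s).
#' @param stationary_max_net_um_s Truncation of that drift; kept below
#'   0.09 um/s so ground-truth classes are unambiguous at the 0.1 um/s
#'   boundary.
#' @param coloc_coupling Named numeric: per-state probability that a
#'   channel-A particle carries channel-B signal
#'   (names stationary/anterograde/retrograde).
#' @param extra_axonal_fraction Target voxel-volume fraction of z-stack
#'   signal outside the axon mask, in [0, 1].
#' @param surface_share_of_outside Fraction of the extra-axonal signal
#'   deposited at the nerve surface (the remainder is parenchymal), in
#'   [0, 1].
#' @param n_signal_blobs Number of signal deposits rendered into a z-stack.
#' @param protrusion_density_per_100um Linear density of axolemmal
#'   protrusions (per 100 um of axon).
#' @param protrusion_mito_prob Probability a protrusion contains
#'   mitochondrial signal.
#' @param pinch_prob_per_interval Per-interval probability that an attached
#'   protrusion pinches off during an event series.
#' @param psf_sigma_um Gaussian PSF sigma (um).
#' @param spot_amplitude Peak intensity of a rendered spot (arbitrary units).
#' @param noise_model List with `gaussian_sd` (additive read noise SD) and
#'   `poisson_scale` (photon scaling; 0 disables shot noise).
#' @param drift_per_frame_px Length-2 numeric (dy, dx): rigid drift per frame
#'   in pixels.
#' @param seed Integer master seed for scene-level wrappers.
#'
#' @return A `scene_config` object (a validated named list).
#' @examples
#' cfg <- scene_config(n_particles = 50, seed = 1)
#' cfg$state_fractions
#' @export
scene_config <- function(nerve_diameter_um = 30,
                         axon_length_um = 100,
                         n_axons = 40,
                         axon_diameter_um = 0.8,
                         pixel_size_um = 0.25,
                         frame_interval_s = 1,
                         n_frames = 60,
                         z_step_um = 1,
                         n_particles = 200,
                         state_fractions = c(stationary = 0.5,
                                             anterograde = 0.25,
                                             retrograde = 0.25),
                         speed_mean_antero_um_s = 0.63,
                         speed_mean_retro_um_s = 0.78,
                         speed_sd_um_s = 0.15,
                         min_moving_speed_um_s = 0.15,
                         stationary_jitter_sd_um = 0.05,
                         stationary_net_sd_um_s = 0.02,
                         stationary_max_net_um_s = 0.05,
                         coloc_coupling = c(stationary = 0.6,
                                            anterograde = 0.2,
                                            retrograde = 0.2),
                         extra_axonal_fraction = 0.15,
                         surface_share_of_outside = 0.239,
                         n_signal_blobs = 60,
                         protrusion_density_per_100um = 0.47,
                         protrusion_mito_prob = 0.603,
                         pinch_prob_per_interval = 0.1,
                         psf_sigma_um = 0.25,
                         spot_amplitude = 30,
                         noise_model = list(gaussian_sd = 2, poisson_scale = 1),
                         drift_per_frame_px = c(0, 0),
                         seed = NULL) {
  cfg <- structure(as.list(environment()), class = "scene_config")
  cfg$state_fractions <- name_states(state_fractions)
  cfg$coloc_coupling <- name_states(coloc_coupling)
  validate_scene_config(cfg)
}

name_states <- function(x) {
  states <- c("stationary", "anterograde", "retrograde")
  if (is.null(names(x)) || !all(states %in% names(x))) {
    if (length(x) != 3) {
      abort("state-indexed vectors must have length 3 or names stationary/anterograde/retrograde")
    }
    names(x) <- states
  }
  x[states]
}

#' Validate a scene configuration
#'
#' Checks the generator invariants: state fractions sum to 1 (within 1e-12),
#' lengths/rates non-negative, probabilities in \[0, 1\], `n_frames >= 2`.
#'
#' @param cfg A `scene_config`.
#' @return `cfg`, invisibly unchanged, or an error describing the violation.
#' @export
validate_scene_config <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (abs(sum(cfg$state_fractions) - 1) > 1e-12) {
    abort("state_fractions must sum to 1")
  }
  if (any(cfg$state_fractions < 0)) abort("state_fractions must be non-negative")
  lens <- c(cfg$nerve_diameter_um, cfg$axon_length_um, cfg$axon_diameter_um,
            cfg$pixel_size_um, cfg$frame_interval_s, cfg$z_step_um,
            cfg$psf_sigma_um, cfg$speed_sd_um_s, cfg$stationary_jitter_sd_um,
            cfg$protrusion_density_per_100um)
  if (any(lens < 0)) abort("lengths, times and rates must be non-negative")
  probs <- c(cfg$coloc_coupling, cfg$extra_axonal_fraction,
             cfg$surface_share_of_outside, cfg$protrusion_mito_prob,
             cfg$pinch_prob_per_interval)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (cfg$n_frames < 2) abort("n_frames must be at least 2")
  if (length(cfg$drift_per_frame_px) != 2) {
    abort("drift_per_frame_px must be a length-2 (dy, dx) vector")
  }
  cfg
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  nerve %g um, %d axons x %g um, field %g um\n",
              x$nerve_diameter_um, x$n_axons, x$axon_diameter_um,
              x$axon_length_um))
  cat(sprintf("  %d particles, fractions (%.2f, %.2f, %.2f), speeds (%.2f, %.2f) um/s\n",
              x$n_particles, x$state_fractions[1], x$state_fractions[2],
              x$state_fractions[3], x$speed_mean_antero_um_s,
              x$speed_mean_retro_um_s))
  cat(sprintf("  %d frames @ %g s, pixel %g um, z step %g um\n",
              x$n_frames, x$frame_interval_s, x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Read / write a scene configuration as YAML
#'
#' @param path File path.
#' @return `read_scene_config()` returns a `scene_config`;
#'   `write_scene_config()` returns `path` invisibly.
#' @export
read_scene_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$state_fractions <- unlist(vals$state_fractions)
  vals$coloc_coupling <- unlist(vals$coloc_coupling)
  vals$drift_per_frame_px <- unlist(vals$drift_per_frame_px)
  do.call(scene_config, vals)
}

#' @rdname read_scene_config
#' @param cfg A `scene_config`.
#' @export
write_scene_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(v) {
    if (is.numeric(v) && !is.null(names(v))) as.list(v) else v
  }), path)
  invisible(path)
}
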