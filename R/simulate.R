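#' Simulate ground-truth particle trajectories
#'
#' Draws `cfg$n_particles` organelle trajectories along parallel axon lanes.
#' Each particle is assigned a movement state from `cfg$state_fractions`;
#' moving particles get a constant signed velocity drawn from a truncated
#' normal (anterograde positive, retrograde negative, means
#' `speed_mean_antero_um_s` / `speed_mean_retro_um_s`), while stationary
#' particles jitter as a Brownian bridge around a drift kept strictly below
#' the 0.1 um/s classification boundary, so ground-truth class labels are
#' never ambiguous. Channel-B carriage is drawn per state from
#' `cfg$coloc_coupling`.
#'
#' @param cfg A [scene_config()].
#' @param seed Optional integer seed (defaults to `cfg$seed`).
#' @return A tibble with one row per particle: `particle_id`, `axon_id`,
#'   `axon_y_um` (transverse lane position), `state`, `speed_um_s` (signed
#'   net velocity), `carries_partner`, `compartment`, `inside_axon`, and a
#'   `positions` list-column of per-frame arclength positions (um,
#'   anterograde-positive).
#' @examples
#' tr <- simulate_trajectories(scene_config(n_particles = 20), seed = 1)
#' table(tr$state)
#' @export
simulate_trajectories <- function(cfg, seed = cfg$seed) {
  validate_scene_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_particles
  L <- cfg$axon_length_um
  nf <- cfg$n_frames
  tt <- (seq_len(nf) - 1) * cfg$frame_interval_s
  span <- tt[nf]

  lanes <- axon_lane_positions(cfg)
  # axons are not a perfect lattice: jitter lane positions slightly
  lanes <- lanes + runif(length(lanes), -0.3, 0.3) *
    cfg$nerve_diameter_um / cfg$n_axons
  axon_id <- sample.int(cfg$n_axons, n, replace = TRUE)
  state <- sample(names(cfg$state_fractions), n, replace = TRUE,
                  prob = cfg$state_fractions)

  speed <- numeric(n)
  positions <- vector("list", n)
  vmax <- (L - 2.5) / span # fastest speed whose full path fits the field
  for (i in seq_len(n)) {
    if (state[i] == "stationary") {
      # docked organelles: small Gaussian net drift, truncated well below
      # the 0.1 um/s classification boundary so truth is unambiguous
      v <- max(min(rnorm(1, 0, cfg$stationary_net_sd_um_s),
                   cfg$stationary_max_net_um_s), -cfg$stationary_max_net_um_s)
      x0 <- runif(1, 2, L - 2)
      jit <- rnorm(nf, 0, cfg$stationary_jitter_sd_um)
      # Brownian-bridge jitter: endpoints pinned so the net velocity is
      # exactly the drawn sub-boundary drift
      bridge <- jit - jit[1] - (seq_len(nf) - 1) / (nf - 1) * (jit[nf] - jit[1])
      positions[[i]] <- x0 + v * tt + bridge
    } else {
      mu <- if (state[i] == "anterograde") cfg$speed_mean_antero_um_s else
        cfg$speed_mean_retro_um_s
      sp <- draw_truncated_speed(mu, cfg$speed_sd_um_s,
                                 cfg$min_moving_speed_um_s, vmax)
      v <- if (state[i] == "anterograde") sp else -sp
      disp <- abs(v) * span
      x0 <- if (v > 0) runif(1, 1, L - 1 - disp) else runif(1, 1 + disp, L - 1)
      positions[[i]] <- x0 + v * tt
    }
    speed[i] <- v
  }
  carries <- runif(n) < cfg$coloc_coupling[state]

  out <- tibble(
    particle_id = seq_len(n),
    axon_id = axon_id,
    axon_y_um = lanes[axon_id],
    state = state,
    speed_um_s = speed,
    carries_partner = carries,
    compartment = "axon",
    inside_axon = TRUE,
    positions = positions
  )
  attr(out, "cfg") <- cfg
  out
}

draw_truncated_speed <- function(mu, sd, lo, hi) {
  if (sd == 0) return(min(max(mu, lo), hi))
  for (k in 1:100) {
    s <- rnorm(1, mu, sd)
    if (s >= lo && s <= hi) return(s)
  }
  min(max(mu, lo), hi)
}

axon_lane_positions <- function(cfg) {
  m <- field_margin_um(cfg)
  m + cfg$nerve_diameter_um * (seq_len(cfg$n_axons) - 0.5) / cfg$n_axons
}

field_margin_um <- function(cfg) 2.5

field_dims_px <- function(cfg) {
  m <- field_margin_um(cfg)
  c(ny = ceiling((cfg$nerve_diameter_um + 2 * m) / cfg$pixel_size_um),
    nx = ceiling((cfg$axon_length_um + 2 * m) / cfg$pixel_size_um))
}

#' Render a ground-truth trajectory set as a noisy time-lapse stack
#'
#' Stamps each particle as an isotropic Gaussian spot (sigma
#' `cfg$psf_sigma_um`) at its per-frame position. The `mito` channel carries
#' every particle, the `optn` channel only those with
#' `carries_partner = TRUE`, and the `membrane` channel is a static nerve
#' fill used for contour tracing and registration. Poisson shot noise and
#' additive Gaussian read noise follow `cfg$noise_model`.
#'
#' @param truth Trajectory tibble from [simulate_trajectories()].
#' @param cfg The [scene_config()] used to generate `truth`.
#' @param seed Optional seed for the noise realization.
#' @param noise If `FALSE`, return the noiseless rendering.
#' @return A [frame_stack()] with channels `mito`, `optn`, `membrane`.
#' @export
render_timelapse <- function(truth, cfg, seed = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  d <- field_dims_px(cfg)
  ny <- d[["ny"]]; nx <- d[["nx"]]
  px <- cfg$pixel_size_um
  nf <- cfg$n_frames
  m <- field_margin_um(cfg)
  sigma_px <- cfg$psf_sigma_um / px

  y_px <- truth$axon_y_um / px + 1
  pos_mat <- do.call(rbind, truth$positions) # particles x frames, um

  oob <- apply(pos_mat, 1, function(p) any(p < -m | p > cfg$axon_length_um + m))
  if (any(oob)) {
    warn(sprintf("%d particle(s) fall fully outside the field in some frames; skipped in rendering, kept in truth",
                 sum(oob)))
  }

  membrane_base <- matrix(0, ny, nx)
  nerve_rows <- abs((seq_len(ny) - 1) * px - (m + cfg$nerve_diameter_um / 2)) <
    cfg$nerve_diameter_um / 2
  membrane_base[nerve_rows, ] <- 15
  membrane_base <- matrix(cpp_smooth3d(as.numeric(membrane_base),
                                       c(ny, nx, 1L), 2, 2, 0), ny, nx)

  mito <- array(0, c(ny, nx, nf))
  optn <- array(0, c(ny, nx, nf))
  memb <- array(0, c(ny, nx, nf))
  carr <- truth$carries_partner
  for (t in seq_len(nf)) {
    x_px <- (pos_mat[, t] + m) / px + 1
    keep <- x_px > -4 * sigma_px & x_px < nx + 4 * sigma_px
    fr <- cpp_stamp_gaussians(matrix(0, ny, nx), y_px[keep], x_px[keep],
                              rep(cfg$spot_amplitude, sum(keep)), sigma_px)
    mito[, , t] <- if (noise) add_noise(fr, cfg$noise_model) else fr
    kb <- keep & carr
    fb <- cpp_stamp_gaussians(matrix(0, ny, nx), y_px[kb], x_px[kb],
                              rep(cfg$spot_amplitude, sum(kb)), sigma_px)
    optn[, , t] <- if (noise) add_noise(fb, cfg$noise_model) else fb
    memb[, , t] <- if (noise) add_noise(membrane_base, cfg$noise_model) else
      membrane_base
  }
  frame_stack(list(mito = mito, optn = optn, membrane = memb),
              pixel_size_um = px, frame_interval_s = cfg$frame_interval_s)
}

add_noise <- function(img, noise_model) {
  v <- as.numeric(img)
  sc <- noise_model$poisson_scale %||% 0
  if (sc > 0) v <- rpois(length(v), pmax(v, 0) * sc) / sc
  gs <- noise_model$gaussian_sd %||% 0
  if (gs > 0) v <- v + rnorm(length(v), 0, gs)
  out <- pmax(v, 0)
  if (is.matrix(img)) matrix(out, nrow(img), ncol(img)) else
    array(out, dim(img))
}

#' Apply a known rigid drift to a time-lapse stack
#'
#' Shifts frame `t` by `(t - 1) * drift_per_frame_px` (bilinear
#' interpolation for subpixel drifts), emulating the specimen drift that
#' rigid registration must remove. The true shift table is returned with the
#' stack so registration accuracy can be scored against it.
#'
#' @param stack A [frame_stack()].
#' @param drift_per_frame_px Length-2 numeric `(dy, dx)`, pixels per frame.
#' @return A list with `stack` (the drifted [frame_stack()]) and `shifts`
#'   (tibble `frame`, `dy`, `dx` of the injected per-frame offsets).
#' @export
inject_drift <- function(stack, drift_per_frame_px) {
  stopifnot(inherits(stack, "frame_stack"), length(drift_per_frame_px) == 2)
  d <- dim(stack$channels[[1]])
  nf <- d[3]
  cum <- (nf - 1) * abs(drift_per_frame_px)
  if (cum[1] > 0.25 * d[1] || cum[2] > 0.25 * d[2]) {
    abort("cumulative drift exceeds 25% of the field")
  }
  shifts <- tibble(frame = seq_len(nf),
                   dy = (seq_len(nf) - 1) * drift_per_frame_px[1],
                   dx = (seq_len(nf) - 1) * drift_per_frame_px[2])
  out <- stack
  if (any(drift_per_frame_px != 0)) {
    for (ch in names(out$channels)) {
      for (t in seq_len(nf)) {
        if (shifts$dy[t] == 0 && shifts$dx[t] == 0) next
        out$channels[[ch]][, , t] <-
          cpp_shift_bilinear(stack$channels[[ch]][, , t],
                             shifts$dy[t], shifts$dx[t])
      }
    }
  }
  list(stack = out, shifts = shifts)
}
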