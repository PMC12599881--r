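#' Generate a protrusion/evulsion event series with known dynamics
#'
#' Emits a repetitive z-scan series of a small sub-volume containing an axon
#' tube with a lateral bud, at 30-s intervals for 5 min or 2-min intervals
#' for 10 min. Four event kinds are modelled:
#' \describe{
#'   \item{swelling}{a symmetric bulge around the axon; bud-axon distance 0
#'     throughout, static intensities.}
#'   \item{loading}{an attached asymmetric bud whose signal rises while the
#'     axon signal directly beneath it falls, conserving the summed amount.}
#'   \item{pinching_off}{attached until `pinch_time_s`, then the bud detaches
#'     and drifts away; its signal concentrates further after separation.}
#'   \item{detached}{separate from the axon at every timepoint.}
#' }
#'
#' @param cfg A [scene_config()] (noise/PSF settings are taken from it).
#' @param kind Event kind (see above).
#' @param interval_s Sampling interval: 30 or 120 s.
#' @param duration_s Series duration; must be a multiple of `interval_s`
#'   (defaults: 300 s at 30-s intervals, 600 s at 2-min intervals).
#' @param pinch_time_s Last attached timepoint for `pinching_off` (default:
#'   mid-series).
#' @param noise Add Gaussian noise (SD 0.5; sub-volume ROIs are
#'   frame-averaged, hence low noise).
#' @param seed Optional seed.
#' @return A list: `volumes` (list of [volume_stack()]s with `membrane` and
#'   `optn` channels, one per timepoint), `axon_masks` (tube-only logical
#'   truth masks), `truth` (tibble `timepoint`, `t_s`, `min_distance_um`,
#'   `i_protrusion`, `i_axon_beneath`, normalized to the away-region
#'   baseline), `kind`, `pinch_time_s`, `interval_s`.
#' @export
make_protrusion_series <- function(cfg = scene_config(),
                                   kind = c("loading", "swelling",
                                            "pinching_off", "detached"),
                                   interval_s = 30, duration_s = NULL,
                                   pinch_time_s = NULL, noise = TRUE,
                                   seed = NULL) {
  kind <- match.arg(kind)
  if (!interval_s %in% c(30, 120)) {
    abort("interval_s must be 30 (5-min series) or 120 (10-min series)")
  }
  duration_s <- duration_s %||% if (interval_s == 30) 300 else 600
  if (duration_s %% interval_s != 0) {
    abort("duration_s must be a multiple of interval_s")
  }
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration_s, by = interval_s)
  nt <- length(times)
  if (kind == "pinching_off") {
    pinch_time_s <- pinch_time_s %||% times[ceiling(nt / 2)]
    if (!pinch_time_s %in% times) abort("pinch_time_s must be a sampled timepoint")
  } else {
    pinch_time_s <- NULL
  }

  # sub-volume geometry (um)
  py <- 0.25; pxs <- 0.25; pz <- 0.5
  ly <- 14; lx <- 20; lz <- 8
  ny <- ly / py; nx <- lx / pxs; nz <- lz / pz
  dims <- c(ny, nx, nz)
  yc <- ly / 2; zc <- lz / 2; bx <- lx / 2
  axon_r <- 1; bud_r <- 1.2
  attach_off <- axon_r + bud_r - 0.5
  base_amp <- 10

  ys <- (seq_len(ny) - 0.5) * py
  xs <- (seq_len(nx) - 0.5) * pxs
  zs <- (seq_len(nz) - 0.5) * pz
  tube_yz <- outer((ys - yc)^2, (zs - zc)^2, `+`) <= axon_r^2
  tube <- aperm(array(tube_yz, c(ny, nz, nx)), c(1, 3, 2))
  beneath <- tube & aperm(array(matrix(abs(xs - bx) <= bud_r + 1, nx, nz),
                                c(nx, nz, ny)), c(3, 1, 2))
  away <- tube & aperm(array(matrix(abs(xs - bx) >= 5, nx, nz),
                             c(nx, nz, ny)), c(3, 1, 2))

  sphere_mask <- function(y0, x0, z0, r) {
    dy2 <- (ys - y0)^2; dx2 <- (xs - x0)^2; dz2 <- (zs - z0)^2
    arr <- outer(dy2, dx2, `+`)
    out <- array(FALSE, dims)
    for (k in seq_len(nz)) out[, , k] <- arr + dz2[k] <= r^2
    out
  }

  v_bud0 <- NULL
  volumes <- vector("list", nt)
  masks <- vector("list", nt)
  truth <- tibble(timepoint = seq_len(nt), t_s = times,
                  min_distance_um = 0, i_protrusion = 1, i_axon_beneath = 1)

  for (i in seq_len(nt)) {
    t_s <- times[i]
    if (kind == "swelling") {
      bud <- sphere_mask(yc, bx, zc, 1.6) & !tube
      offset <- attach_off
      a_bud <- 15; a_ben <- base_amp
    } else {
      offset <- switch(kind,
        loading = attach_off,
        detached = axon_r + bud_r + 1,
        pinching_off = if (t_s <= pinch_time_s) attach_off else
          # detachment is acute: the bud clears the axon within one interval
          attach_off + 0.7 + 0.8 * (t_s - pinch_time_s) / interval_s)
      bud <- sphere_mask(yc + offset, bx, zc, bud_r) & !tube
      if (kind == "loading") {
        if (is.null(v_bud0)) {
          v_bud0 <- sum(bud); v_ben0 <- sum(beneath & !bud)
          a_tot <- 14 * v_bud0 + base_amp * v_ben0
        }
        a_bud <- 14 + 12 * (i - 1) / (nt - 1)
        a_ben <- (a_tot - a_bud * v_bud0) / v_ben0
      } else if (kind == "detached") {
        a_bud <- 18; a_ben <- base_amp
      } else {
        detached_now <- t_s > pinch_time_s
        a_bud <- if (detached_now) 22 else 18
        a_ben <- base_amp
      }
    }
    gap <- max(0, offset - (axon_r + bud_r))
    membrane <- array(0, dims)
    membrane[tube | bud] <- 20
    optn <- array(0, dims)
    optn[tube] <- base_amp
    optn[beneath & !bud] <- a_ben
    optn[bud] <- a_bud
    sm <- function(a) array(cpp_smooth3d(as.numeric(a), dims, 1, 1, 0.5), dims)
    membrane <- sm(membrane); optn <- sm(optn)
    if (noise) {
      membrane <- membrane + array(pmax(rnorm(prod(dims), 0, 0.5), -membrane),
                                   dims)
      optn <- optn + array(pmax(rnorm(prod(dims), 0, 0.5), -optn), dims)
    }
    volumes[[i]] <- volume_stack(list(membrane = membrane, optn = optn),
                                 pixel_size_um = py, z_step_um = pz)
    masks[[i]] <- tube
    truth$min_distance_um[i] <- gap
    truth$i_protrusion[i] <- a_bud / base_amp
    truth$i_axon_beneath[i] <- a_ben / base_amp
  }
  list(volumes = volumes, axon_masks = masks, truth = truth, kind = kind,
       pinch_time_s = pinch_time_s, interval_s = interval_s,
       bud_x_um = bx, voxel_um = c(py, pxs, pz))
}
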