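#' Segment 3D objects and measure volume, surface area and sphericity
#'
#' Connected components (6-connectivity) above a threshold. Volume is voxel
#' count times physical voxel volume; surface area is estimated by the
#' co-area formula — the summed gradient magnitude of a Gaussian-smoothed
#' indicator function — which converges to the true area as voxels shrink
#' (voxel-face counting would overestimate curved surfaces by ~50%).
#'
#' @param volume A [volume_stack()].
#' @param channel Channel role to segment.
#' @param threshold Raw threshold; `NULL` uses the background-referenced
#'   default ([signal_threshold_bg()]).
#' @param smooth_sigma_vox Smoothing sigma (voxels) for the area estimator.
#' @return Tibble `object_id`, `n_voxels`, `volume_um3`, `surface_area_um2`,
#'   `sphericity`, `centroid_y_um`, `centroid_x_um`, `centroid_z_um`; empty
#'   for a blank volume.
#' @export
segment_objects <- function(volume, channel = "mito", threshold = NULL,
                            smooth_sigma_vox = 1.5) {
  arr <- get_channel(volume, channel)
  dims <- dim(arr)
  if (max(arr) == 0) {
    return(tibble(object_id = integer(), n_voxels = integer(),
                  volume_um3 = numeric(), surface_area_um2 = numeric(),
                  sphericity = numeric(), centroid_y_um = numeric(),
                  centroid_x_um = numeric(), centroid_z_um = numeric()))
  }
  thr <- threshold %||% signal_threshold_bg(arr)
  sig <- arr > thr
  lab <- cpp_label3d(as.logical(sig), dims)
  nlab <- attr(lab, "n_labels")
  if (nlab == 0) {
    return(segment_objects(volume_stack(
      setNames(list(array(0, dims)), channel),
      volume$pixel_size_um, volume$z_step_um), channel))
  }
  sy <- volume$pixel_size_um; sx <- volume$pixel_size_um
  sz <- volume$z_step_um
  vox_vol <- sy * sx * sz
  idx <- which(lab > 0)
  co <- arrayInd(idx, dims)
  l <- lab[idx]
  out <- lapply(seq_len(nlab), function(k) {
    sel <- l == k
    n <- sum(sel)
    area <- mask_surface_area(lab == k, dims, c(sy, sx, sz), smooth_sigma_vox)
    V <- n * vox_vol
    tibble(object_id = k, n_voxels = n, volume_um3 = V,
           surface_area_um2 = area, sphericity = sphericity(V, area),
           centroid_y_um = mean(co[sel, 1]) * sy,
           centroid_x_um = mean(co[sel, 2]) * sx,
           centroid_z_um = mean(co[sel, 3]) * sz)
  })
  dplyr::bind_rows(out)
}

# co-area surface estimate: A = sum |grad u| dV for a smoothed indicator
mask_surface_area <- function(mask, dims, spacing, smooth_sigma_vox = 1.5) {
  # crop to bounding box with padding to keep it cheap
  idx <- which(mask)
  co <- arrayInd(idx, dims)
  pad <- ceiling(3 * smooth_sigma_vox) + 2
  lo <- pmax(apply(co, 2, min) - pad, 1)
  hi <- pmin(apply(co, 2, max) + pad, dims)
  sub <- array(0, hi - lo + 1)
  sub[cbind(co[, 1] - lo[1] + 1, co[, 2] - lo[2] + 1, co[, 3] - lo[3] + 1)] <- 1
  d <- dim(sub)
  # smooth isotropically in physical units: sigma in voxels per axis
  s_phys <- smooth_sigma_vox * min(spacing)
  u <- array(cpp_smooth3d(as.numeric(sub), d, s_phys / spacing[1],
                          s_phys / spacing[2], s_phys / spacing[3]), d)
  g2 <- array(0, d)
  for (ax in 1:3) {
    gp <- central_diff(u, ax) / spacing[ax]
    g2 <- g2 + gp^2
  }
  sum(sqrt(g2)) * prod(spacing)
}

central_diff <- function(u, axis) {
  d <- dim(u)
  n <- d[axis]
  if (n < 3) return(array(0, d))
  ip <- function(i) switch(axis,
                           u[i, , , drop = FALSE],
                           u[, i, , drop = FALSE],
                           u[, , i, drop = FALSE])
  g <- array(0, d)
  core <- 2:(n - 1)
  val <- (ip(core + 1) - ip(core - 1)) / 2
  if (axis == 1) g[core, , ] <- val
  if (axis == 2) g[, core, ] <- val
  if (axis == 3) g[, , core] <- val
  g
}

#' Wadell sphericity
#'
#' `psi = pi^(1/3) (6 V)^(2/3) / A`: the ratio of the surface area of a
#' sphere of the same volume to the actual surface area. Exactly 1 for a
#' sphere, `(pi/6)^(1/3) ~ 0.806` for a cube, lower for elongated solids.
#'
#' @param V Volume (um^3), positive.
#' @param A Surface area (um^2), positive.
#' @return Sphericity (unitless, vectorized).
#' @examples
#' sphericity(4 / 3 * pi, 4 * pi) # unit sphere -> 1
#' @export
sphericity <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) abort("V and A must be positive")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Detect asymmetric axolemmal protrusions along a sparse axon
#'
#' Measures the supra-threshold radial extent of the membrane signal on each
#' side of the axon centerline, and calls a protrusion where the one-sided
#' excursion above the tube radius exceeds `bump_min_height_um` over a
#' contiguous run at least `bump_min_width_um` wide **and** exceeds
#' `asymmetry_k` times the contralateral excursion (symmetric swellings are
#' rejected). Reports linear density per 100 um and the fraction of calls
#' containing mitochondrial signal.
#'
#' @param membrane Matrix (y by x) of the membrane/axon-fill channel.
#' @param mito Optional matrix of the mitochondria channel.
#' @param centerline_y_px Centerline row (pixels).
#' @param pixel_size_um Pixel size (um).
#' @param threshold Membrane threshold; `NULL` uses Otsu.
#' @param bump_min_height_um Minimum one-sided excursion above the tube
#'   radius (um).
#' @param bump_min_width_um Minimum along-axon width (um).
#' @param asymmetry_k A bump is asymmetric when its excursion exceeds `k`
#'   times the contralateral excursion.
#' @return A `protrusion_calls` list: `calls` tibble (`x_um`, `side`,
#'   `height_um`, `width_um`, `contains_mito`), `n_calls`,
#'   `density_per_100um`, `mito_fraction_pct`, `axon_length_um`.
#' @export
detect_protrusions <- function(membrane, mito = NULL, centerline_y_px,
                               pixel_size_um, threshold = NULL,
                               bump_min_height_um = 0.5,
                               bump_min_width_um = 0.6, asymmetry_k = 2) {
  px <- pixel_size_um
  nx <- ncol(membrane)
  length_um <- nx * px
  if (length_um < 10) {
    warn("axon shorter than 10 um: skipped")
    return(structure(list(calls = tibble(), n_calls = 0L,
                          density_per_100um = NA_real_,
                          mito_fraction_pct = NA_real_,
                          axon_length_um = length_um),
                     class = "protrusion_calls"))
  }
  thr <- threshold %||% otsu_threshold(membrane)
  bw <- membrane > thr
  ys <- seq_len(nrow(membrane))
  up_ext <- apply(bw, 2, function(col) {
    i <- which(col & ys >= centerline_y_px)
    if (length(i)) max(i) - centerline_y_px else 0
  }) * px
  dn_ext <- apply(bw, 2, function(col) {
    i <- which(col & ys <= centerline_y_px)
    if (length(i)) centerline_y_px - min(i) else 0
  }) * px
  tube_r <- min(median(up_ext), median(dn_ext))
  up_exc <- pmax(up_ext - tube_r, 0)
  dn_exc <- pmax(dn_ext - tube_r, 0)

  calls <- list()
  for (side in c("up", "down")) {
    exc <- if (side == "up") up_exc else dn_exc
    other <- if (side == "up") dn_exc else up_exc
    runs <- rle(exc >= bump_min_height_um)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      i0 <- starts[r]; i1 <- ends[r]
      w <- (i1 - i0 + 1) * px
      if (w < bump_min_width_um) next
      peak <- i0 - 1 + which.max(exc[i0:i1])
      if (exc[peak] < asymmetry_k * max(other[i0:i1], px / 2)) next
      has_mito <- FALSE
      if (!is.null(mito)) {
        m_thr <- max(mito) * 0.3
        has_mito <- max(mito[, i0:i1]) > m_thr && m_thr > 0
      }
      calls[[length(calls) + 1]] <- tibble(
        x_um = (peak - 0.5) * px, side = side, height_um = exc[peak],
        width_um = w, contains_mito = has_mito)
    }
  }
  calls <- dplyr::bind_rows(calls)
  n <- nrow(calls)
  structure(list(
    calls = calls, n_calls = n,
    density_per_100um = 100 * n / length_um,
    mito_fraction_pct = if (n > 0) 100 * sum(calls$contains_mito) / n else
      NA_real_,
    axon_length_um = length_um
  ), class = "protrusion_calls")
}

#' @export
print.protrusion_calls <- function(x, ...) {
  cat(sprintf("<protrusion_calls> %d calls over %.0f um (%.2f per 100 um), %.1f%% with mitochondria\n",
              x$n_calls, x$axon_length_um, x$density_per_100um,
              x$mito_fraction_pct))
  invisible(x)
}

#' Track a protrusion/evulsion event across a repetitive z-scan series
#'
#' For each timepoint, the protrusion is the supra-threshold signal
#' component outside the axon mask nearest the previous protrusion position;
#' the event records the minimum Euclidean 3D distance between protrusion
#' and axon boundaries (0 while they touch), and the mean signal intensity
#' in the protrusion and in the axon directly beneath it (within the
#' protrusion's along-axon footprint +/- 1 um), each normalized so the mean
#' of a same-axon away-region (>= 5 um from the event) equals 1. The event
#' kind is assigned from the distance/intensity dynamics: `detached`
#' (distance > 0 throughout), `pinching_off` (0 then > 0; `pinch_time_s` is
#' the first separated timepoint), `loading` (attached with rising
#' protrusion and falling beneath intensity), else `swelling`.
#'
#' @param volumes List of [volume_stack()]s (one per timepoint).
#' @param axon_masks List of logical arrays marking the axon at each
#'   timepoint.
#' @param times_s Acquisition times (s), equally spaced.
#' @param signal_channel Channel quantified (default `optn`).
#' @param threshold Signal threshold; `NULL` uses Otsu of the first volume.
#' @return A `dystrophy_event`: `timepoints` tibble (`t_s`,
#'   `min_distance_um`, `i_protrusion`, `i_axon_beneath`), `kind`,
#'   `pinch_time_s` (or `NA`), `censored_at_s` (or `NA`).
#' @export
track_event <- function(volumes, axon_masks, times_s,
                        signal_channel = "optn", threshold = NULL) {
  stopifnot(length(volumes) == length(axon_masks),
            length(volumes) == length(times_s))
  nt <- length(volumes)
  v1 <- volumes[[1]]
  sy <- v1$pixel_size_um; sx <- v1$pixel_size_um; sz <- v1$z_step_um
  thr <- threshold %||% otsu_threshold(get_channel(v1, signal_channel))
  rows <- vector("list", nt)
  censored_at <- NA_real_
  prev_centroid <- NULL
  for (i in seq_len(nt)) {
    arr <- get_channel(volumes[[i]], signal_channel)
    dims <- dim(arr)
    axon <- axon_masks[[i]]
    sig <- arr > thr
    out_sig <- sig & !axon
    lab <- cpp_label3d(as.logical(out_sig), dims)
    nlab <- attr(lab, "n_labels")
    if (nlab == 0) {
      censored_at <- times_s[max(i - 1, 1)]
      warn(sprintf("protrusion lost at t = %g s: event censored", times_s[i]))
      break
    }
    sizes <- tabulate(lab[lab > 0], nlab)
    cands <- which(sizes >= max(8, 0.05 * max(sizes)))
    if (!length(cands)) {
      censored_at <- times_s[max(i - 1, 1)]
      warn(sprintf("protrusion lost at t = %g s: event censored", times_s[i]))
      break
    }
    cents <- t(vapply(cands, function(k) {
      colMeans(arrayInd(which(lab == k), dims)) * c(sy, sx, sz)
    }, numeric(3)))
    pick <- if (is.null(prev_centroid)) cands[which.max(sizes[cands])] else
      cands[which.min(rowSums((cents - matrix(prev_centroid, nrow(cents), 3,
                                              byrow = TRUE))^2))]
    prot <- array(lab == pick, dims)
    prev_centroid <- colMeans(arrayInd(which(prot), dims)) * c(sy, sx, sz)

    d <- cpp_min_boundary_dist(as.logical(prot), as.logical(axon), dims,
                               sy, sx, sz)
    # footprint of the protrusion along the axon, +/- 1 um
    xr <- range(arrayInd(which(prot), dims)[, 2]) * sx
    x_um <- (seq_len(dims[2]) - 0.5) * sx
    in_fp <- x_um >= xr[1] - 1 & x_um <= xr[2] + 1
    away <- abs(x_um - mean(xr)) >= 5
    beneath_mask <- axon & aperm(array(matrix(in_fp, dims[2], dims[3]),
                                       c(dims[2], dims[3], dims[1])),
                                 c(3, 1, 2))
    away_mask <- axon & aperm(array(matrix(away, dims[2], dims[3]),
                                    c(dims[2], dims[3], dims[1])), c(3, 1, 2))
    base <- mean(arr[away_mask])
    rows[[i]] <- tibble(t_s = times_s[i], min_distance_um = d,
                        i_protrusion = mean(arr[prot]) / base,
                        i_axon_beneath = mean(arr[beneath_mask]) / base)
  }
  tp <- dplyr::bind_rows(rows)
  d <- tp$min_distance_um
  kind <- if (all(d > 0)) "detached"
  else if (any(d > 0) && min(which(d > 0)) > 1 &&
           all(d[seq_len(min(which(d > 0)) - 1)] == 0)) "pinching_off"
  else if (any(d > 0)) "detached"
  else {
    dp <- coef(lm(tp$i_protrusion ~ tp$t_s))[2]
    db <- coef(lm(tp$i_axon_beneath ~ tp$t_s))[2]
    rng <- diff(range(tp$i_protrusion))
    if (dp > 0 && db < 0 && rng > 0.2) "loading" else "swelling"
  }
  pinch <- if (kind == "pinching_off") tp$t_s[min(which(d > 0))] else NA_real_
  structure(list(timepoints = tp, kind = kind, pinch_time_s = pinch,
                 censored_at_s = censored_at, signal_channel = signal_channel),
            class = "dystrophy_event")
}

#' @export
print.dystrophy_event <- function(x, ...) {
  cat(sprintf("<dystrophy_event> kind = %s over %d timepoints", x$kind,
              nrow(x$timepoints)))
  if (!is.na(x$pinch_time_s)) cat(sprintf(", pinch at %g s", x$pinch_time_s))
  if (!is.na(x$censored_at_s)) cat(sprintf(", censored at %g s",
                                           x$censored_at_s))
  cat("\n")
  invisible(x)
}

#' @export
tidy.dystrophy_event <- function(x, ...) x$timepoints

#' @export
glance.dystrophy_event <- function(x, ...) {
  tibble(kind = x$kind, pinch_time_s = x$pinch_time_s,
         n_timepoints = nrow(x$timepoints), censored_at_s = x$censored_at_s)
}

#' Conservative lower bound on mean event persistence
#'
#' When `n_surviving` of `n_tracked` events are still present after an
#' observation span, survivors persisted at least the full span and
#' non-survivors at least 0, so the mean persistence is at least
#' `n_surviving * span / n_tracked`.
#'
#' @param n_tracked Number of events tracked (> 0).
#' @param n_surviving Number still present at the last timepoint.
#' @param span_min Observation span (minutes).
#' @return Lower bound on mean persistence (minutes).
#' @examples
#' persistence_bound(18, 13, 8) # 5.78 min, i.e. "more than 5 minutes"
#' @export
persistence_bound <- function(n_tracked, n_surviving, span_min) {
  if (n_tracked <= 0) abort("n_tracked must be positive")
  stopifnot(n_surviving >= 0, n_surviving <= n_tracked, span_min > 0)
  n_surviving * span_min / n_tracked
}
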