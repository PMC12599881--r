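#' Build the axon mask from the cytoplasmic LC3b channel
#'
#' Thresholds the axon-filling channel of a z-stack (Otsu by default),
#' removes connected components smaller than `min_object_voxels`, and
#' applies a morphological closing whose radius is interpreted in
#' micrometres (so the structuring element is ellipsoidal when voxels are
#' anisotropic).
#'
#' @param volume A [volume_stack()].
#' @param channel Channel role holding the axon-filling signal.
#' @param method `"otsu"` or `"quantile"`.
#' @param quantile_p Threshold quantile for `method = "quantile"`.
#' @param min_object_voxels Components smaller than this are removed.
#' @param closing_radius_um Closing radius (um); 0 disables.
#' @return An `axon_mask`: list with `mask` (logical array), `threshold`,
#'   `method`, `channel` and the physical voxel sizes.
#' @export
build_axon_mask <- function(volume, channel = "lc3b",
                            method = c("otsu", "quantile"), quantile_p = 0.99,
                            min_object_voxels = 27, closing_radius_um = 0) {
  method <- match.arg(method)
  arr <- get_channel(volume, channel)
  if (max(arr) == 0) abort("empty mask: channel is blank")
  thr <- if (method == "otsu") otsu_threshold(arr) else
    quantile(arr, quantile_p)
  m <- arr > thr
  if (!any(m)) abort("empty mask: nothing above threshold")
  dims <- dim(arr)
  if (min_object_voxels > 1) {
    lab <- cpp_label3d(as.logical(m), dims)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_object_voxels)
    m <- array(lab %in% keep, dims)
  }
  if (closing_radius_um > 0) {
    sy <- volume$pixel_size_um; sz <- volume$z_step_um
    m <- erode_mask_um(dilate_mask_um(array(m, dims), closing_radius_um,
                                      sy, sy, sz),
                       closing_radius_um, sy, sy, sz)
  }
  m <- array(m, dims)
  structure(list(mask = m, threshold = thr, method = method,
                 channel = channel, pixel_size_um = volume$pixel_size_um,
                 z_step_um = volume$z_step_um),
            class = "axon_mask")
}

as_mask_array <- function(mask) {
  if (inherits(mask, "axon_mask")) mask$mask else mask
}

#' Background-referenced signal threshold
#'
#' Default threshold for sparse punctate channels, where the signal occupies
#' well under a percent of the voxels and histogram-splitting methods (Otsu)
#' land inside the noise: the background statistics are estimated from the
#' voxels below the `bg_quantile` quantile and the threshold is
#' `mean + k x SD` of that pool.
#'
#' @param x Numeric array or vector of intensities.
#' @param bg_quantile Quantile bounding the background pool.
#' @param k Multiplier on the background SD.
#' @return Threshold in raw intensity units.
#' @export
signal_threshold_bg <- function(x, bg_quantile = 0.99, k = 5) {
  v <- as.numeric(x)
  bg <- v[v <= quantile(v, bg_quantile)]
  mean(bg) + k * sd(bg)
}

# supra-threshold mask with isolated noise voxels removed
clean_signal_mask <- function(arr, thr, min_component_voxels = 8) {
  sig <- arr > thr
  if (min_component_voxels > 1 && any(sig)) {
    dims <- dim(arr)
    lab <- cpp_label3d(as.logical(sig), dims)
    sizes <- tabulate(lab[lab > 0])
    sig <- array(sizes[ifelse(lab > 0, lab, NA)] >= min_component_voxels &
                   lab > 0, dims)
    sig[is.na(sig)] <- FALSE
  }
  sig
}

# EDT-backed Euclidean morphology on logical voxel arrays (radius in um)
dilate_mask_um <- function(mask, r_um, sy, sx, sz) {
  dims <- dim(mask)
  array(cpp_edt_sq(as.logical(mask), dims, sy, sx, sz) <= r_um^2 + 1e-9, dims)
}

erode_mask_um <- function(mask, r_um, sy, sx, sz) {
  dims <- dim(mask)
  array(cpp_edt_sq(as.logical(!mask), dims, sy, sx, sz) > r_um^2 + 1e-9, dims)
}

#' Percent of a channel's signal outside the axon mask
#'
#' `pct_outside = 100 x (supra-threshold signal voxels outside the mask) /
#' (all supra-threshold signal voxels)`, computed on voxel volumes. The
#' object-wise variant assigns each connected signal component wholly inside
#' or outside according to its centroid.
#'
#' @param volume A [volume_stack()].
#' @param channel Signal channel role.
#' @param mask An `axon_mask` or logical array of the same shape.
#' @param signal_threshold Raw threshold for "signal" voxels; `NULL` uses
#'   the background-referenced default ([signal_threshold_bg()]).
#' @param mode `"voxel"` (default) or `"object"`.
#' @param min_component_voxels Supra-threshold components smaller than this
#'   are treated as noise and ignored.
#' @return One-row tibble `channel`, `mode`, `n_signal_voxels`,
#'   `n_outside_voxels`, `pct_outside` (`NA` with a warning when the channel
#'   has no supra-threshold signal).
#' @export
pct_outside <- function(volume, channel, mask, signal_threshold = NULL,
                        mode = c("voxel", "object"),
                        min_component_voxels = 8) {
  mode <- match.arg(mode)
  arr <- get_channel(volume, channel)
  m <- as_mask_array(mask)
  stopifnot(identical(dim(arr), dim(m)))
  thr <- signal_threshold %||% signal_threshold_bg(arr)
  sig <- clean_signal_mask(arr, thr, min_component_voxels)
  if (!any(sig)) {
    warn(sprintf("channel '%s': no supra-threshold signal; fraction undefined",
                 channel))
    return(tibble(channel = channel, mode = mode, n_signal_voxels = 0L,
                  n_outside_voxels = 0L, pct_outside = NA_real_))
  }
  if (mode == "voxel") {
    n_tot <- sum(sig)
    n_out <- sum(sig & !m)
  } else {
    dims <- dim(arr)
    lab <- cpp_label3d(as.logical(sig), dims)
    nlab <- attr(lab, "n_labels")
    idx <- which(lab > 0)
    co <- arrayInd(idx, dims)
    l <- lab[idx]
    n_vox <- tabulate(l, nlab)
    # component centroid inside mask? nearest-voxel lookup
    cy <- round(tapply(co[, 1], l, mean))
    cx <- round(tapply(co[, 2], l, mean))
    cz <- round(tapply(co[, 3], l, mean))
    inside <- m[cbind(cy, cx, cz)]
    n_tot <- sum(n_vox)
    n_out <- sum(n_vox[!inside])
  }
  tibble(channel = channel, mode = mode, n_signal_voxels = as.integer(n_tot),
         n_outside_voxels = as.integer(n_out),
         pct_outside = 100 * n_out / n_tot)
}

#' Partition extra-axonal signal into nerve surface versus parenchyma
#'
#' Extra-axonal signal voxels within `d_um` of the nerve boundary are
#' labelled *surface*; the remainder is *parenchymal*. The surface shell is
#' built morphologically from the nerve mask (dilation minus erosion by
#' `d_um`), so it covers both sides of the boundary.
#'
#' @inheritParams pct_outside
#' @param nerve_mask Logical array marking the nerve interior (e.g. the
#'   generator's `nerve_mask` attribute, or a mask traced from a structural
#'   channel).
#' @param d_um Shell half-depth (um); must be positive.
#' @return One-row tibble: `channel`, `pct_outside` (of total signal),
#'   `pct_on_surface` and `pct_in_parenchyma` (of the **extra-axonal**
#'   signal, summing to 100), and `pct_total_on_surface` (of all signal).
#' @export
partition_surface <- function(volume, channel, mask, nerve_mask, d_um = 3,
                              signal_threshold = NULL) {
  if (d_um <= 0) abort("d_um must be positive")
  arr <- get_channel(volume, channel)
  m <- as_mask_array(mask)
  dims <- dim(arr)
  thr <- signal_threshold %||% signal_threshold_bg(arr)
  sig <- clean_signal_mask(arr, thr)
  out_sig <- sig & !m
  n_out <- sum(out_sig)
  sy <- volume$pixel_size_um; sz <- volume$z_step_um
  shell <- dilate_mask_um(array(nerve_mask, dims), d_um, sy, sy, sz) &
    !erode_mask_um(array(nerve_mask, dims), d_um, sy, sy, sz)
  n_surf <- sum(out_sig & shell)
  tibble(
    channel = channel,
    d_um = d_um,
    pct_outside = 100 * n_out / max(sum(sig), 1),
    pct_on_surface = if (n_out > 0) 100 * n_surf / n_out else NA_real_,
    pct_in_parenchyma = if (n_out > 0) 100 * (n_out - n_surf) / n_out else
      NA_real_,
    pct_total_on_surface = 100 * n_surf / max(sum(sig), 1)
  )
}

#' Trend of surface share versus total extra-axonal share across animals
#'
#' Ordinary least squares of per-animal (x = percent of signal outside the
#' axons, y = percent of signal on the nerve surface) pairs, as used to ask
#' whether nerves with more extra-axonal signal also show more of it at the
#' surface.
#'
#' @param pairs Data frame with columns `x` (total outside %) and `y`
#'   (surface %), one row per animal; at least 3 rows.
#' @return A `surface_trend`: list with `slope`, `intercept`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_surface_trend <- function(pairs) {
  stopifnot(all(c("x", "y") %in% names(pairs)))
  if (nrow(pairs) < 3) abort("at least 3 animals are required")
  fit <- lm(y ~ x, data = pairs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((pairs$y - mean(pairs$y))^2)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 0,
                 n = nrow(pairs), fit = fit, data = as_tibble(pairs)),
            class = "surface_trend")
}

#' @export
print.surface_trend <- function(x, ...) {
  cat(sprintf("<surface_trend> y = %.3f x + %.3f, R^2 = %.3f (n = %d animals)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' @export
tidy.surface_trend <- function(x, ...) {
  tibble(term = c("(Intercept)", "x"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.surface_trend <- function(x, ...) {
  tibble(r_squared = x$r_squared, n = x$n)
}
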