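#' Calibrated image-stack containers
#'
#' A `frame_stack` holds a multichannel single-plane time series: one
#' `[y, x, t]` array per channel, with the physical pixel size and frame
#' interval. A `volume_stack` holds a multichannel z-scan: one `[y, x, z]`
#' array per channel with pixel size and z step, optionally carrying a
#' per-voxel ground-truth compartment label (`0` background, `1` axon,
#' `2` parenchyma, `3` surface shell) when produced by the generator.
#'
#' @param channels Named list of numeric arrays (all the same shape,
#'   non-negative); names are channel roles such as `mito`, `optn`, `lc3b`,
#'   `membrane`.
#' @param pixel_size_um Lateral pixel size (um).
#' @param frame_interval_s Frame interval (s).
#' @return An object of class `frame_stack` or `volume_stack`.
#' @export
frame_stack <- function(channels, pixel_size_um, frame_interval_s) {
  check_channels(channels, 3L)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s,
                 channel_roles = names(channels)),
            class = "frame_stack")
}

#' @rdname frame_stack
#' @param z_step_um Axial step (um).
#' @param voxel_truth Optional integer array of per-voxel compartment labels.
#' @export
volume_stack <- function(channels, pixel_size_um, z_step_um,
                         voxel_truth = NULL) {
  check_channels(channels, 3L)
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel_roles = names(channels),
                 voxel_truth = voxel_truth),
            class = "volume_stack")
}

check_channels <- function(channels, ndim) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)))
  d <- dim(channels[[1]])
  if (length(d) != ndim) abort(sprintf("channels must be %d-dimensional arrays", ndim))
  for (ch in channels) {
    if (!identical(dim(ch), d)) abort("all channels must share one shape")
    if (min(ch) < 0) abort("intensities must be non-negative")
  }
  invisible(channels)
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<frame_stack> %d x %d px, %d frames @ %g s, pixel %g um\n",
              d[1], d[2], d[3], x$frame_interval_s, x$pixel_size_um))
  cat("  channels:", paste(x$channel_roles, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<volume_stack> %d x %d px x %d slices, pixel %g um, z step %g um\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  cat("  channels:", paste(x$channel_roles, collapse = ", "),
      if (!is.null(x$voxel_truth)) "(voxel truth attached)" else "", "\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$channels[[1]])[3]

get_channel <- function(stack, role) {
  if (!role %in% names(stack$channels)) {
    abort(sprintf("channel '%s' not present (have: %s)", role,
                  paste(names(stack$channels), collapse = ", ")))
  }
  stack$channels[[role]]
}
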