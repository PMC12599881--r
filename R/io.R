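#' Read and write calibrated stacks as multi-page TIFF + YAML sidecar
#'
#' Stacks are written as 32-bit float multi-page TIFF (pages ordered
#' channel-fastest), intensities scaled to \[0, 1\] per channel, with a YAML
#' sidecar (`<path>.yaml`) recording axis order, physical scales, channel
#' roles and the per-channel intensity scale, so a stack round-trips
#' losslessly up to float precision.
#'
#' @param stack A [frame_stack()] or [volume_stack()].
#' @param path Output TIFF path.
#' @return `write_*` return `path` invisibly; `read_*` return the stack.
#' @export
write_frame_stack <- function(stack, path) {
  write_stack_tiff(stack, path, type = "frame_stack",
                   meta = list(frame_interval_s = stack$frame_interval_s))
}

#' @rdname write_frame_stack
#' @export
write_volume_stack <- function(stack, path) {
  write_stack_tiff(stack, path, type = "volume_stack",
                   meta = list(z_step_um = stack$z_step_um))
}

write_stack_tiff <- function(stack, path, type, meta) {
  chs <- names(stack$channels)
  d <- dim(stack$channels[[1]])
  scales <- vapply(stack$channels, function(a) max(max(a), 1e-12), numeric(1))
  pages <- list()
  for (k in seq_len(d[3])) {
    for (ch in chs) {
      pages[[length(pages) + 1]] <- stack$channels[[ch]][, , k] / scales[ch]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(c(list(type = type, channels = chs,
                          n_planes = unname(d[3]),
                          ny = unname(d[1]), nx = unname(d[2]),
                          pixel_size_um = stack$pixel_size_um,
                          scales = as.list(scales)), meta),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  rs <- read_stack_tiff(path, "frame_stack")
  frame_stack(rs$channels, rs$meta$pixel_size_um, rs$meta$frame_interval_s)
}

#' @rdname write_frame_stack
#' @export
read_volume_stack <- function(path) {
  rs <- read_stack_tiff(path, "volume_stack")
  volume_stack(rs$channels, rs$meta$pixel_size_um, rs$meta$z_step_um)
}

read_stack_tiff <- function(path, type) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  if (!identical(meta$type, type)) {
    abort(sprintf("'%s' holds a %s, not a %s", path, meta$type, type))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  chs <- unlist(meta$channels)
  nch <- length(chs)
  np <- meta$n_planes
  channels <- setNames(vector("list", nch), chs)
  for (ci in seq_len(nch)) {
    a <- array(0, c(meta$ny, meta$nx, np))
    for (k in seq_len(np)) a[, , k] <- pages[[(k - 1) * nch + ci]]
    channels[[ci]] <- a * meta$scales[[chs[ci]]]
  }
  list(channels = channels, meta = meta)
}

#' Write a kymograph as TIFF with metadata sidecar
#'
#' @param kymo A `kymograph`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kymo, path) {
  sc <- max(max(kymo$K), 1e-12)
  tiff::writeTIFF(kymo$K / sc, path, bits.per.sample = 32L)
  yaml::write_yaml(list(type = "kymograph", dt_s = kymo$dt_s,
                        pixel_size_um = kymo$pixel_size_um,
                        width_um = kymo$width_um, reducer = kymo$reducer,
                        source = kymo$source, scale = sc),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  K <- tiff::readTIFF(path) * meta$scale
  structure(list(K = K, s_um = (seq_len(ncol(K)) - 1) * meta$pixel_size_um,
                 dt_s = meta$dt_s, pixel_size_um = meta$pixel_size_um,
                 source = meta$source, width_um = meta$width_um,
                 reducer = meta$reducer),
            class = "kymograph")
}
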