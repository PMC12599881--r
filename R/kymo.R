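#' Estimate per-frame rigid drift by phase correlation
#'
#' Registers every frame of a time series against a reference frame (the
#' first frame or the temporal mean) by phase correlation, refined to
#' subpixel precision by locally upsampled cross-correlation (zoomed DFT,
#' default 10x). This reimplements rigid-translation stack registration of
#' the StackReg family.
#'
#' @param stack A [frame_stack()].
#' @param reference `"first"` (default), `"previous"` (frame-to-frame
#'   estimates composed into cumulative shifts) or `"mean"`.
#' @param channel Channel role used for registration (default the first
#'   channel; with about half the objects stationary, the correlation peak
#'   is dominated by the static constellation while movers smear out).
#' @param upsample Subpixel upsampling factor.
#' @param smooth_window Odd window width for a running-median smoothing of
#'   the per-frame shift series (stage drift is smooth in time, so
#'   high-frequency excursions are estimation noise); 0 disables.
#' @return A tibble `frame`, `dy`, `dx` of shifts **to apply** (the negative
#'   of the estimated drift).
#' @export
estimate_drift <- function(stack, reference = c("first", "previous", "mean"),
                           channel = NULL, upsample = 10, smooth_window = 7) {
  reference <- match.arg(reference)
  channel <- channel %||% stack$channel_roles[1]
  arr <- get_channel(stack, channel)
  nf <- dim(arr)[3]
  sh <- matrix(0, nf, 2)
  if (reference == "previous") {
    for (t in 2:nf) {
      a <- arr[, , t - 1]; b <- arr[, , t]
      if (sd(a) == 0 || sd(b) == 0) {
        warn(sprintf("flat frame near %d: zero incremental shift", t))
        sh[t, ] <- sh[t - 1, ]
        next
      }
      sh[t, ] <- sh[t - 1, ] + phase_corr_shift(a, b, upsample)
    }
  } else {
    ref <- if (reference == "first") arr[, , 1] else rowMeans(arr, dims = 2)
    if (sd(ref) == 0) {
      warn("flat reference frame: returning zero shifts")
      return(tibble(frame = seq_len(nf), dy = 0, dx = 0))
    }
    F1 <- prep_ref_fft(ref)
    for (t in seq_len(nf)) {
      fr <- arr[, , t]
      if (sd(fr) == 0) {
        warn(sprintf("flat frame %d: zero shift", t))
        next
      }
      est <- phase_corr_shift(F1, fr, upsample)
      # windowing biases large shifts toward zero: iterate on the residual
      # when the first estimate is large
      if (max(abs(est)) > 2) {
        for (it in 1:2) {
          fr2 <- cpp_shift_bilinear(fr, -est[1], -est[2])
          res <- phase_corr_shift(F1, fr2, upsample, prior = c(0, 0),
                                  search_radius = 4)
          est <- est + res
          if (max(abs(res)) < 0.2) break
        }
      }
      sh[t, ] <- est
    }
  }
  if (smooth_window >= 3 && nf >= smooth_window) {
    k <- smooth_window - (1 - smooth_window %% 2) # force odd
    sh[, 1] <- stats::runmed(sh[, 1], k, endrule = "median")
    sh[, 2] <- stats::runmed(sh[, 2], k, endrule = "median")
  }
  tibble(frame = seq_len(nf), dy = -sh[, 1], dx = -sh[, 2])
}

# Returns (dy, dx) such that img(y, x) ~= ref(y - dy, x - dx).
# Mean subtraction + Hann window suppress the non-circular edge artifacts
# that otherwise dominate the whitened spectrum. An optional prior
# restricts the integer peak search to +/- search_radius px around an
# expected shift (temporal continuity guard against lattice aliasing).
# `ref` may be a pre-windowed FFT from prep_ref_fft() to avoid recomputing
# it per frame.
phase_corr_shift <- function(ref, img, upsample = 10, prior = NULL,
                             search_radius = 3) {
  w <- outer(hann_window(nrow(img)), hann_window(ncol(img)))
  F1 <- if (is.complex(ref)) ref else fft((ref - mean(ref)) * w)
  F2 <- fft((img - mean(img)) * w)
  cp <- F2 * Conj(F1)
  r <- Re(fft(cp / (Mod(cp) + 0.01 * max(Mod(cp))), inverse = TRUE))
  ny <- nrow(r); nx <- ncol(r)
  if (!is.null(prior)) {
    sy <- seq_len(ny) - 1; sy[sy > ny / 2] <- sy[sy > ny / 2] - ny
    sx <- seq_len(nx) - 1; sx[sx > nx / 2] <- sx[sx > nx / 2] - nx
    ok <- outer(abs(sy - prior[1]) <= search_radius,
                abs(sx - prior[2]) <= search_radius, `&`)
    r[!ok] <- -Inf
  }
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  dy <- pk[1] - 1; dx <- pk[2] - 1
  if (dy > ny / 2) dy <- dy - ny
  if (dx > nx / 2) dx <- dx - nx
  if (upsample <= 1) return(c(dy, dx))
  # refine on a 1.5 px neighborhood sampled at 1/upsample steps
  nres <- ceiling(1.5 * upsample)
  dftshift <- floor(nres / 2)
  cc <- dftups(cp, nres, nres, upsample,
               dftshift - dy * upsample, dftshift - dx * upsample)
  pk2 <- which(Mod(cc) == max(Mod(cc)), arr.ind = TRUE)[1, ]
  dy <- dy + (pk2[1] - 1 - dftshift) / upsample
  dx <- dx + (pk2[2] - 1 - dftshift) / upsample
  c(dy, dx)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))

prep_ref_fft <- function(ref) {
  w <- outer(hann_window(nrow(ref)), hann_window(ncol(ref)))
  fft((ref - mean(ref)) * w)
}

# Zoomed inverse DFT of `input` on an upsampled local grid
# (matrix-multiply implementation of upsampled cross-correlation).
dftups <- function(input, nor, noc, usfac, roff, coff) {
  nr <- nrow(input); nc <- ncol(input)
  fy <- seq_len(nr) - 1; fy[fy >= nr / 2] <- fy[fy >= nr / 2] - nr
  fx <- seq_len(nc) - 1; fx[fx >= nc / 2] <- fx[fx >= nc / 2] - nc
  kernr <- exp((2i * pi / (nr * usfac)) * outer(seq_len(nor) - 1 - roff, fy))
  kernc <- exp((2i * pi / (nc * usfac)) * outer(fx, seq_len(noc) - 1 - coff))
  kernr %*% input %*% kernc
}

#' Apply per-frame translations to a stack
#'
#' Translates each frame of every channel by the given `(dy, dx)` with
#' bilinear interpolation; pixels sampled from outside the field are
#' zero-filled.
#'
#' @param stack A [frame_stack()].
#' @param shifts Tibble with `frame`, `dy`, `dx` (as from
#'   [estimate_drift()]).
#' @return The shifted [frame_stack()].
#' @export
apply_shifts <- function(stack, shifts) {
  nf <- n_frames(stack)
  stopifnot(nrow(shifts) == nf)
  out <- stack
  for (ch in names(out$channels)) {
    for (t in seq_len(nf)) {
      if (shifts$dy[t] == 0 && shifts$dx[t] == 0) next
      out$channels[[ch]][, , t] <-
        cpp_shift_bilinear(stack$channels[[ch]][, , t],
                           shifts$dy[t], shifts$dx[t])
    }
  }
  out
}

#' @rdname estimate_drift
#' @param two_pass After the first registration, re-estimate per-frame
#'   residuals against the temporal mean of the registered stack (a sharp
#'   static anchor) and fold them into the shifts; the stack is interpolated
#'   only once with the combined shifts.
#' @return `register_stack()` returns the registered [frame_stack()] with the
#'   applied shifts attached as attribute `"shifts"`.
#' @export
register_stack <- function(stack, reference = "first", channel = NULL,
                           upsample = 10, two_pass = TRUE) {
  channel <- channel %||% stack$channel_roles[1]
  sh <- estimate_drift(stack, reference, channel, upsample)
  if (two_pass) {
    # register only the registration channel, build its temporal mean as a
    # sharp static reference, and fold per-frame residuals into the shifts;
    # the full stack is interpolated once, with the combined shifts
    arr0 <- get_channel(stack, channel)
    nf <- dim(arr0)[3]
    arr <- arr0
    for (t in seq_len(nf)) {
      if (sh$dy[t] != 0 || sh$dx[t] != 0) {
        arr[, , t] <- cpp_shift_bilinear(arr0[, , t], sh$dy[t], sh$dx[t])
      }
    }
    M <- rowMeans(arr, dims = 2)
    if (sd(M) > 0) {
      FM <- prep_ref_fft(M)
      resid <- matrix(0, nf, 2)
      for (t in seq_len(nf)) {
        if (sd(arr[, , t]) == 0) next
        resid[t, ] <- phase_corr_shift(FM, arr[, , t], upsample,
                                       prior = c(0, 0), search_radius = 5)
      }
      if (nf >= 7) {
        resid[, 1] <- stats::runmed(resid[, 1], 7, endrule = "median")
        resid[, 2] <- stats::runmed(resid[, 2], 7, endrule = "median")
      }
      sh$dy <- sh$dy - resid[, 1]
      sh$dx <- sh$dx - resid[, 2]
    }
  }
  out <- apply_shifts(stack, sh)
  attr(out, "shifts") <- sh
  out
}

#' Trace the outer contour of the nerve on a temporal projection
#'
#' Thresholds a temporal mean/max projection of a structural channel (Otsu
#' or quantile), keeps the largest connected supra-threshold component, and
#' returns its boundary polygon together with the principal axis and the
#' diameter measured perpendicular to it.
#'
#' @param projection Numeric matrix (y by x), e.g.
#'   `apply(stack$channels$membrane, c(1, 2), mean)`.
#' @param pixel_size_um Pixel size (um).
#' @param method `"otsu"` or `"quantile"`.
#' @param quantile_p Threshold quantile when `method = "quantile"`.
#' @param manual_override Optional polygon (n x 2 matrix of y, x pixel
#'   coords) returned verbatim, bypassing detection.
#' @param min_area_px Smallest acceptable component (pixels).
#' @return A `nerve_contour`: list with `polygon_px` (n x 2, y/x), `axis`
#'   (unit vector, y/x components), `centroid_px`, `diameter_um`,
#'   `halfspan_px` (half extent along the axis) and `pixel_size_um`.
#' @export
trace_nerve_contour <- function(projection, pixel_size_um,
                                method = c("otsu", "quantile"),
                                quantile_p = 0.5, manual_override = NULL,
                                min_area_px = 100) {
  method <- match.arg(method)
  if (!is.null(manual_override)) {
    poly <- as.matrix(manual_override)
    return(contour_from_pixels(poly, poly, pixel_size_um, manual = TRUE))
  }
  thr <- if (method == "otsu") otsu_threshold(projection) else
    quantile(projection, quantile_p)
  bw <- projection > thr
  lab <- matrix(cpp_label3d(as.logical(bw), c(nrow(bw), ncol(bw), 1L)),
                nrow(bw), ncol(bw))
  if (max(lab) == 0) abort("no nerve found")
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  if (sizes[big] < min_area_px) abort("no nerve found")
  comp <- lab == big
  pix <- which(comp, arr.ind = TRUE) # (y, x)
  poly <- component_boundary(comp)
  contour_from_pixels(poly, pix, pixel_size_um)
}

contour_from_pixels <- function(poly, pix, pixel_size_um, manual = FALSE) {
  pc <- prcomp(pix[, c(2, 1)]) # (x, y) so PC1 is the long axis for wide fields
  axis_xy <- pc$rotation[, 1]
  if (axis_xy[1] < 0) axis_xy <- -axis_xy # +s toward +x (eye -> brain)
  perp_scores <- pc$x[, 2]
  main_scores <- pc$x[, 1]
  structure(list(
    polygon_px = poly,
    axis = c(y = unname(axis_xy[2]), x = unname(axis_xy[1])),
    centroid_px = c(y = mean(pix[, 1]), x = mean(pix[, 2])),
    diameter_um = diff(range(perp_scores)) * pixel_size_um,
    halfspan_px = max(abs(main_scores)),
    pixel_size_um = pixel_size_um,
    manual = manual
  ), class = "nerve_contour")
}

# boundary pixels of a logical component, ordered by angle around centroid
component_boundary <- function(comp) {
  ny <- nrow(comp); nx <- ncol(comp)
  pad <- matrix(FALSE, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- comp
  interior <- pad[2:(ny + 1), 2:(nx + 1)] &
    pad[1:ny, 2:(nx + 1)] & pad[3:(ny + 2), 2:(nx + 1)] &
    pad[2:(ny + 1), 1:nx] & pad[2:(ny + 1), 3:(nx + 2)]
  edge <- comp & !interior
  b <- which(edge, arr.ind = TRUE)
  cy <- mean(b[, 1]); cx <- mean(b[, 2])
  b[order(atan2(b[, 1] - cy, b[, 2] - cx)), , drop = FALSE]
}

otsu_threshold <- function(x) {
  v <- as.numeric(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  img <- EBImage::Image((v - rng[1]) / diff(rng), dim = c(length(v), 1))
  EBImage::otsu(img, range = c(0, 1)) * diff(rng) + rng[1]
}

#' Divide the nerve interior into parallel sampling swaths
#'
#' Tiles the contour interior with contiguous, non-overlapping bands
#' parallel to the principal axis. Widths outside the 0.9-1.8 um working
#' range are clamped with a warning; the band count is approximately
#' `diameter / width`.
#'
#' @param contour A `nerve_contour` from [trace_nerve_contour()].
#' @param swath_width_um Band width (um); default 1.5 (mid working range).
#' @return A `swath_set`: list with a `swaths` tibble (`swath_id`,
#'   `offset_um` of band centre from the nerve axis, `width_um`, and path
#'   endpoints `y0, x0, y1, x1` in pixels), plus the axis and contour.
#' @export
build_swaths <- function(contour, swath_width_um = 1.5) {
  stopifnot(inherits(contour, "nerve_contour"))
  if (swath_width_um <= 0) abort("swath width must be positive")
  w <- swath_width_um
  if (w < 0.9 || w > 1.8) {
    w <- min(max(w, 0.9), 1.8)
    warn(sprintf("swath width %g um outside 0.9-1.8 um; clamped to %g",
                 swath_width_um, w))
  }
  D <- contour$diameter_um
  n <- max(1L, as.integer(ceiling(D / w - 1e-9)))
  offsets <- -D / 2 + w * (seq_len(n) - 0.5)
  px <- contour$pixel_size_um
  ax <- contour$axis
  perp <- c(y = unname(ax["x"]), x = unname(-ax["y"]))
  ctr <- contour$centroid_px
  hs <- contour$halfspan_px
  sw <- tibble(
    swath_id = seq_len(n),
    offset_um = offsets,
    width_um = w,
    y0 = ctr["y"] + offsets / px * perp["y"] - hs * ax["y"],
    x0 = ctr["x"] + offsets / px * perp["x"] - hs * ax["x"],
    y1 = ctr["y"] + offsets / px * perp["y"] + hs * ax["y"],
    x1 = ctr["x"] + offsets / px * perp["x"] + hs * ax["x"]
  )
  structure(list(swaths = sw, axis = ax, perp = perp, contour = contour),
            class = "swath_set")
}

#' Extract a kymograph along a path
#'
#' Samples intensity along a path at pixel-size arclength steps for every
#' frame, reducing across the path width (max preserves punctate ridges and
#' is the default; mean is available). Rows are time, columns arclength;
#' `+s` follows the path order (by convention the eye-to-brain, anterograde
#' direction).
#'
#' @param stack A registered [frame_stack()].
#' @param path Either an n x 2 matrix of (y, x) pixel waypoints or a numeric
#'   vector `c(y0, x0, y1, x1)`.
#' @param width_um Sampling width across the path (um).
#' @param channel Channel role to sample.
#' @param reducer `"max"` or `"mean"` across the width.
#' @param source Identifier recorded on the kymograph (e.g. swath id).
#' @param spot_sigma_px Spot width (px) assumed by the subpixel cross-width
#'   localization.
#' @return A `kymograph`: list with `K` (`n_frames` x `n_s` matrix), `K_off`
#'   (subpixel transverse offset of the local maximum, px), `s_um`, `dt_s`,
#'   `pixel_size_um`, `source`.
#' @export
extract_kymograph <- function(stack, path, width_um = 1.5, channel = "mito",
                              reducer = c("max", "mean"), source = NA,
                              spot_sigma_px = 1) {
  reducer <- match.arg(reducer)
  px <- stack$pixel_size_um
  if (is.numeric(path) && is.null(dim(path))) {
    path <- matrix(path, 2, 2, byrow = TRUE)
  }
  path <- as.matrix(path)
  seg <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
  if (seg < 2) abort("path shorter than 2 px")
  n_s <- max(2L, floor(seg) + 1L)
  fr <- (seq_len(n_s) - 1) / (n_s - 1)
  ys <- path[1, 1] + fr * (path[nrow(path), 1] - path[1, 1])
  xs <- path[1, 2] + fr * (path[nrow(path), 2] - path[1, 2])
  dirv <- (path[nrow(path), ] - path[1, ]) / seg
  perp <- c(dirv[2], -dirv[1])
  half_w <- width_um / px / 2
  offs <- seq(-half_w + 0.5, half_w - 0.5, by = 1)
  if (length(offs) == 0) offs <- 0

  arr <- get_channel(stack, channel)
  nf <- dim(arr)[3]
  K <- matrix(0, nf, n_s)
  K_off <- matrix(0, nf, n_s) # subpixel cross-width offset of the maximum
  sy <- as.numeric(outer(ys, offs * perp[1], `+`))
  sx <- as.numeric(outer(xs, offs * perp[2], `+`))
  n_off <- length(offs)
  for (t in seq_len(nf)) {
    v <- matrix(bilinear_sample(arr[, , t], sy, sx), n_s, n_off)
    wm <- max.col(v, ties.method = "first")
    # Gaussian two-point refinement: for a spot of width spot_sigma_px the
    # log intensity ratio of the two samples bracketing the peak locates the
    # centre, even when it lies beyond the sampled band (ghost detection)
    if (n_off >= 2) {
      nb <- ifelse(wm == 1, 2L,
                   ifelse(wm == n_off, n_off - 1L,
                          ifelse(v[cbind(seq_len(n_s), pmin(wm + 1, n_off))] >=
                                   v[cbind(seq_len(n_s), pmax(wm - 1, 1))],
                                 wm + 1L, wm - 1L)))
      v1 <- v[cbind(seq_len(n_s), wm)]
      v2 <- pmax(v[cbind(seq_len(n_s), nb)], 1e-9)
      o1 <- offs[wm]; o2 <- offs[nb]
      corr <- spot_sigma_px^2 * log(pmax(v1, 1e-9) / v2) / (o1 - o2)
      corr <- pmin(pmax(corr, -2), 2)
      K_off[t, ] <- (o1 + o2) / 2 + corr
    } else {
      K_off[t, ] <- offs[wm]
    }
    K[t, ] <- if (reducer == "max") v[cbind(seq_len(n_s), wm)] else rowMeans(v)
  }
  structure(list(K = K, K_off = K_off, s_um = (seq_len(n_s) - 1) * px,
                 dt_s = stack$frame_interval_s, pixel_size_um = px,
                 source = source, width_um = width_um, reducer = reducer),
            class = "kymograph")
}

bilinear_sample <- function(mat, y, x) {
  ny <- nrow(mat); nx <- ncol(mat)
  y <- pmin(pmax(y, 1), ny); x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1); x0 <- pmin(floor(x), nx - 1)
  fy <- y - y0; fx <- x - x0
  mat[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
    mat[cbind(y0 + 1, x0)] * fy * (1 - fx) +
    mat[cbind(y0, x0 + 1)] * (1 - fy) * fx +
    mat[cbind(y0 + 1, x0 + 1)] * fy * fx
}

#' Extract one kymograph per swath
#'
#' @param stack A registered [frame_stack()].
#' @param swath_set A `swath_set` from [build_swaths()].
#' @inheritParams extract_kymograph
#' @return A list of `kymograph` objects, one per swath, named by swath id.
#' @export
extract_swath_kymographs <- function(stack, swath_set, channel = "mito",
                                     reducer = "max") {
  sw <- swath_set$swaths
  out <- lapply(seq_len(nrow(sw)), function(i) {
    extract_kymograph(stack,
                      rbind(c(sw$y0[i], sw$x0[i]), c(sw$y1[i], sw$x1[i])),
                      width_um = sw$width_um[i], channel = channel,
                      reducer = reducer, source = sw$swath_id[i])
  })
  names(out) <- sw$swath_id
  out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d positions (%.1f um @ %.2f um), dt %g s, swath %s\n",
              nrow(x$K), ncol(x$K), max(x$s_um), x$pixel_size_um, x$dt_s,
              as.character(x$source)))
  invisible(x)
}
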