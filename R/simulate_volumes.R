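#' Render a synthetic optic-nerve z-stack with known compartment truth
#'
#' Builds a nerve cylinder containing axon bundles (filled in the `lc3b`
#' channel, mirroring the cytoplasmic axon-mask reporter) and deposits
#' spherical signal blobs in the `mito` and `optn` channels such that the
#' voxel-volume fraction of signal outside the axon bundles matches
#' `cfg$extra_axonal_fraction` up to discretization, split between the nerve
#' surface and the parenchyma per `cfg$surface_share_of_outside`. Only
#' stationary-like deposits are rendered, mirroring frame-averaged z-scans
#' in which moving objects blur out.
#'
#' @param cfg A [scene_config()]. `extra_axonal_fraction` must lie in
#'   \[0, 1\].
#' @param seed Optional seed (defaults to `cfg$seed`).
#' @param length_um Length of the rendered nerve segment (um).
#' @param noise Render Poisson-Gaussian noise (default `TRUE`).
#' @return A [volume_stack()] with channels `mito`, `optn`, `lc3b`, a
#'   `voxel_truth` label array (0 background, 1 axon, 2 parenchyma,
#'   3 surface shell), plus attributes: `truth` (per-blob tibble),
#'   `true_outside_pct` (named per-channel true percentages outside the
#'   axon compartment), `true_surface_share_pct`, `nerve_mask` and
#'   `axon_truth_mask` (logical arrays).
#' @export
render_zstack <- function(cfg, seed = cfg$seed, length_um = 40, noise = TRUE) {
  validate_scene_config(cfg)
  f <- cfg$extra_axonal_fraction
  if (f < 0 || f > 1) abort("extra_axonal_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  px <- cfg$pixel_size_um
  dz <- cfg$z_step_um
  R <- cfg$nerve_diameter_um / 2
  side_um <- cfg$nerve_diameter_um + 10
  ny <- ceiling(side_um / px)
  nx <- ceiling(length_um / px)
  nz <- ceiling(side_um / dz)
  dims <- c(ny, nx, nz)
  yc <- side_um / 2; zc <- side_um / 2

  # radial coordinate of every (y, z) voxel centre, um
  yy <- ((seq_len(ny) - 1) * px) - yc
  zz <- ((seq_len(nz) - 1) * dz) - zc
  r_yz <- sqrt(outer(yy^2, zz^2, `+`))

  # axon bundles: packed parallel cylinders inside the nerve
  bundle_r <- 2
  centers <- pack_disk_centers(R - bundle_r - 0.5, spacing = 2 * bundle_r + 0.4,
                               n = 24)
  bundle_yz <- matrix(FALSE, ny, nz)
  for (k in seq_len(nrow(centers))) {
    bundle_yz <- bundle_yz |
      (outer((yy - centers[k, 1])^2, (zz - centers[k, 2])^2, `+`) <= bundle_r^2)
  }
  axon_mask <- replicate_yz(bundle_yz, nx)
  nerve_mask <- replicate_yz(r_yz <= R, nx)

  voxel_truth <- array(0L, dims)
  voxel_truth[nerve_mask] <- 2L
  voxel_truth[replicate_yz(abs(r_yz - R) <= 1.5, nx)] <- 3L
  voxel_truth[axon_mask] <- 1L

  # signal blobs: counts per compartment chosen to hit the target fraction
  n_blobs <- cfg$n_signal_blobs
  n_out <- round(f * n_blobs)
  n_surf <- round(cfg$surface_share_of_outside * n_out)
  n_par <- n_out - n_surf
  n_in <- n_blobs - n_out
  blob_r <- 0.8

  place_inside <- function() {
    k <- sample.int(nrow(centers), 1)
    repeat {
      dy <- runif(1, -1, 1) * (bundle_r - blob_r)
      dzo <- runif(1, -1, 1) * (bundle_r - blob_r)
      if (dy^2 + dzo^2 <= (bundle_r - blob_r)^2) break
    }
    c(centers[k, 1] + dy, centers[k, 2] + dzo)
  }
  place_parenchyma <- function() {
    repeat {
      y <- runif(1, -1, 1) * (R - 4)
      z <- runif(1, -1, 1) * (R - 4)
      if (y^2 + z^2 > (R - 4)^2) next
      dmin <- min(sqrt((centers[, 1] - y)^2 + (centers[, 2] - z)^2))
      if (dmin > bundle_r + blob_r + 0.2) return(c(y, z))
    }
  }
  place_surface <- function() {
    th <- runif(1, 0, 2 * pi)
    c(R * cos(th), R * sin(th))
  }

  comp <- rep(c("axon", "parenchyma", "surface"), c(n_in, n_par, n_surf))
  blob_yz <- t(vapply(comp, function(cc) switch(cc,
    axon = place_inside(), parenchyma = place_parenchyma(),
    surface = place_surface()), numeric(2)))
  blob_x <- runif(length(comp), blob_r, length_um - blob_r)
  carries <- runif(length(comp)) < cfg$coloc_coupling["stationary"]

  centers_vox <- cbind((blob_yz[, 1] + yc) / px + 1, blob_x / px + 1,
                       (blob_yz[, 2] + zc) / dz + 1)
  amp <- 25
  stamp <- function(sel) {
    v <- numeric(prod(dims))
    if (any(sel)) {
      v <- cpp_stamp_ellipsoids(v, dims, centers_vox[sel, , drop = FALSE],
                                rep(blob_r / px, sum(sel)),
                                rep(blob_r / px, sum(sel)),
                                rep(blob_r / dz, sum(sel)),
                                rep(amp, sum(sel)))
    }
    array(v, dims)
  }
  mito <- stamp(rep(TRUE, length(comp)))
  optn <- stamp(carries)
  lc3b <- array(0, dims)
  lc3b[axon_mask] <- 20

  # exact generator bookkeeping from the pre-noise voxel sets
  outside_pct <- function(sig) {
    s <- sig > 0
    if (!any(s)) return(NA_real_)
    100 * sum(s & !axon_mask) / sum(s)
  }
  surf_share <- {
    s <- mito > 0 & !axon_mask
    r_arr <- replicate_yz(r_yz, nx)
    if (any(s)) 100 * sum(s & r_arr >= R - 1.5) / sum(s) else NA_real_
  }
  true_out <- c(mito = outside_pct(mito), optn = outside_pct(optn))

  blur <- function(a) array(cpp_smooth3d(as.numeric(a), dims,
                                         cfg$psf_sigma_um / px,
                                         cfg$psf_sigma_um / px, 0), dims)
  mito <- blur(mito); optn <- blur(optn); lc3b <- blur(lc3b)
  if (noise) {
    mito <- add_noise(mito, cfg$noise_model)
    optn <- add_noise(optn, cfg$noise_model)
    lc3b <- add_noise(lc3b, cfg$noise_model)
  }

  vs <- volume_stack(list(mito = mito, optn = optn, lc3b = lc3b),
                     pixel_size_um = px, z_step_um = dz,
                     voxel_truth = voxel_truth)
  attr(vs, "truth") <- tibble(blob_id = seq_along(comp), compartment = comp,
                              y_um = blob_yz[, 1] + yc, x_um = blob_x,
                              z_um = blob_yz[, 2] + zc,
                              carries_partner = carries)
  attr(vs, "true_outside_pct") <- true_out
  attr(vs, "true_surface_share_pct") <- surf_share
  attr(vs, "nerve_mask") <- nerve_mask
  attr(vs, "axon_truth_mask") <- axon_mask
  vs
}

replicate_yz <- function(m_yz, nx) {
  # (y, z) template -> (y, x, z) array constant along x
  aperm(array(m_yz, c(nrow(m_yz), ncol(m_yz), nx)), c(1, 3, 2))
}

pack_disk_centers <- function(rmax, spacing, n) {
  g <- seq(-rmax, rmax, by = spacing)
  pts <- expand.grid(y = g, z = g)
  odd <- (match(pts$z, g) %% 2) == 1
  pts$y <- pts$y + ifelse(odd, spacing / 2, 0)
  pts <- pts[sqrt(pts$y^2 + pts$z^2) <= rmax, , drop = FALSE]
  pts <- pts[sample.int(nrow(pts)), , drop = FALSE]
  as.matrix(head(pts, n))
}

#' Render a solid sphere or capsule as a binary test volume
#'
#' Voxelized reference solids for 3D morphometry: a sphere of radius
#' `radius_um`, or a capsule (spherocylinder: cylinder of length `length_um`
#' capped by hemispheres) used to emulate elongated axonal mitochondria in
#' shape-contrast tests.
#'
#' @param radius_um Radius (um).
#' @param voxel_um Isotropic voxel size (um).
#' @param pad_vox Padding voxels around the solid.
#' @return A [volume_stack()] with a single `mito` channel (1 inside,
#'   0 outside).
#' @export
render_sphere_volume <- function(radius_um, voxel_um, pad_vox = 4) {
  render_capsule_volume(radius_um, 0, voxel_um, pad_vox)
}

#' @rdname render_sphere_volume
#' @param length_um Cylindrical (between-cap) length (um); 0 gives a sphere.
#' @export
render_capsule_volume <- function(radius_um, length_um, voxel_um,
                                  pad_vox = 4) {
  r_vox <- radius_um / voxel_um
  l_vox <- length_um / voxel_um
  ny <- ceiling(2 * r_vox) + 2 * pad_vox + 1
  nz <- ny
  nx <- ceiling(2 * r_vox + l_vox) + 2 * pad_vox + 1
  yc <- (ny + 1) / 2; zc <- (nz + 1) / 2
  x0 <- pad_vox + r_vox + 1
  x1 <- x0 + l_vox
  coords_y <- seq_len(ny) - yc
  coords_z <- seq_len(nz) - zc
  vol <- array(0, c(ny, nx, nz))
  for (x in seq_len(nx)) {
    dx <- if (x < x0) x0 - x else if (x > x1) x - x1 else 0
    rem <- r_vox^2 - dx^2
    if (rem < 0) next
    vol[, x, ] <- outer(coords_y^2, coords_z^2, `+`) <= rem
  }
  volume_stack(list(mito = vol), pixel_size_um = voxel_um,
               z_step_um = voxel_um)
}

#' Render a sparse-labeled axon with planted axolemmal protrusions
#'
#' Emulates the single-axon imaging mode: one long membrane-labeled axon
#' with asymmetric (one-sided) protrusions planted at known positions, an
#' optional set of symmetric swellings (which must *not* be called
#' protrusions), and a mitochondria channel filled inside a chosen subset
#' of protrusions.
#'
#' @param length_um Axon length (um).
#' @param protrusion_x_um Positions of planted asymmetric protrusions (um).
#' @param mito_present Logical, same length: does the protrusion contain
#'   mitochondrial signal?
#' @param swelling_x_um Positions of planted symmetric swellings (um).
#' @param pixel_size_um Pixel size (um).
#' @param axon_radius_um Axon tube radius (um).
#' @param bump_height_um Radial height of each protrusion above the tube
#'   (um).
#' @param bump_width_um Along-axon width of each protrusion (um).
#' @param noise_sd Additive Gaussian noise SD (0 = noiseless).
#' @param seed Optional seed.
#' @return A list: `membrane` and `mito` matrices (y by x), `centerline_y_px`,
#'   `pixel_size_um`, `length_um`, and a `truth` tibble.
#' @export
make_sparse_axon <- function(length_um = 1000, protrusion_x_um = numeric(),
                             mito_present = logical(), swelling_x_um = numeric(),
                             pixel_size_um = 0.2, axon_radius_um = 1,
                             bump_height_um = 1.2, bump_width_um = 2,
                             noise_sd = 0, seed = NULL) {
  stopifnot(length(protrusion_x_um) == length(mito_present))
  if (!is.null(seed)) set.seed(seed)
  px <- pixel_size_um
  margin <- axon_radius_um + bump_height_um + 1
  ny <- ceiling(2 * margin / px) + 1
  nx <- ceiling(length_um / px)
  y0 <- (ny + 1) / 2
  xs_um <- (seq_len(nx) - 0.5) * px
  ys_off <- (seq_len(ny) - y0) * px # signed offset from centerline, um

  radius_up <- rep(axon_radius_um, nx)
  radius_dn <- rep(axon_radius_um, nx)
  add_bump <- function(radius, x_p) {
    sel <- abs(xs_um - x_p) <= bump_width_um / 2
    lift <- bump_height_um * sqrt(pmax(0, 1 - (2 * (xs_um[sel] - x_p) /
                                                 bump_width_um)^2))
    radius[sel] <- pmax(radius[sel], axon_radius_um + lift)
    radius
  }
  for (x_p in protrusion_x_um) radius_up <- add_bump(radius_up, x_p)
  for (x_p in swelling_x_um) {
    radius_up <- add_bump(radius_up, x_p)
    radius_dn <- add_bump(radius_dn, x_p)
  }
  up <- outer(ys_off, radius_up, function(y, r) y >= 0 & y <= r)
  dn <- outer(ys_off, radius_dn, function(y, r) y < 0 & -y <= r)
  membrane <- 20 * (up | dn)

  mito <- matrix(0, ny, nx)
  for (i in seq_along(protrusion_x_um)) {
    if (!mito_present[i]) next
    xc <- protrusion_x_um[i] / px + 0.5
    ycb <- y0 + (axon_radius_um + bump_height_um / 2) / px
    mito <- cpp_stamp_gaussians(mito, ycb, xc, 30, 0.4 / px)
  }
  if (noise_sd > 0) {
    membrane <- membrane + matrix(pmax(rnorm(ny * nx, 0, noise_sd), 0), ny, nx)
    mito <- mito + matrix(pmax(rnorm(ny * nx, 0, noise_sd), 0), ny, nx)
  }
  list(membrane = membrane, mito = mito, centerline_y_px = y0,
       pixel_size_um = px, length_um = length_um,
       truth = tibble(x_um = protrusion_x_um, contains_mito = mito_present))
}
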