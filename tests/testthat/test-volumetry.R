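toy_volume <- function(arr, px = 0.5, dz = 0.5) {
  volume_stack(setNames(list(arr), "mito"), pixel_size_um = px, z_step_um = dz)
}

test_that("axon masks recover the true tube set from the axon-fill channel", {
  vz <- cached("vz15", render_zstack(scene_config(extra_axonal_fraction = 0.15,
                                                  seed = 41)))
  mask <- build_axon_mask(vz)
  truth <- attr(vz, "axon_truth_mask")
  jac <- sum(mask$mask & truth) / sum(mask$mask | truth)
  expect_gte(jac, 0.9)
  blank <- volume_stack(list(lc3b = array(0, c(8, 8, 4))), 0.5, 1)
  expect_error(build_axon_mask(blank), "empty mask")
})

test_that("closing a noiseless solid tube is idempotent", {
  # a single convex tube: closing cannot add or remove anything
  cap <- render_capsule_volume(2, 10, 0.25)
  vz <- volume_stack(list(lc3b = cap$channels$mito * 20),
                     pixel_size_um = 0.25, z_step_um = 0.25)
  m0 <- build_axon_mask(vz, closing_radius_um = 0)
  m1 <- build_axon_mask(vz, closing_radius_um = 1)
  expect_identical(m0$mask, m1$mask)
})

test_that("pct_outside matches a direct voxel-count oracle", {
  # 10x10x10 toy: 1000 signal voxels, 214 outside the mask
  arr <- array(10, c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  outside_idx <- sample(seq_len(1000), 214)
  mask[outside_idx] <- FALSE
  po <- pct_outside(toy_volume(arr), "mito", mask, signal_threshold = 5,
                    min_component_voxels = 1)
  expect_equal(po$pct_outside, 21.4)
  # degenerate masks
  expect_equal(pct_outside(toy_volume(arr), "mito",
                           array(TRUE, c(10, 10, 10)),
                           signal_threshold = 5,
                           min_component_voxels = 1)$pct_outside, 0)
  expect_equal(pct_outside(toy_volume(arr), "mito",
                           array(FALSE, c(10, 10, 10)),
                           signal_threshold = 5,
                           min_component_voxels = 1)$pct_outside, 100)
  expect_warning(po0 <- pct_outside(toy_volume(array(0, c(10, 10, 10))),
                                    "mito", mask, signal_threshold = 5),
                 "undefined")
  expect_true(is.na(po0$pct_outside))
})

test_that("voxel and object modes agree when components are uncut", {
  arr <- array(0, c(20, 20, 10))
  arr[3:5, 3:5, 3:5] <- 10   # inside block
  arr[14:16, 14:16, 6:8] <- 10 # outside block
  mask <- array(FALSE, c(20, 20, 10))
  mask[1:10, 1:10, ] <- TRUE
  v <- toy_volume(arr)
  pv <- pct_outside(v, "mito", mask, signal_threshold = 5,
                    min_component_voxels = 1)
  po <- pct_outside(v, "mito", mask, signal_threshold = 5, mode = "object",
                    min_component_voxels = 1)
  expect_equal(pv$pct_outside, po$pct_outside)
  expect_equal(pv$pct_outside, 50)
})

test_that("dilating the mask never increases pct_outside", {
  vz <- cached("vz15", render_zstack(scene_config(extra_axonal_fraction = 0.15,
                                                  seed = 41)))
  mask <- build_axon_mask(vz)$mask
  p0 <- pct_outside(vz, "mito", mask)$pct_outside
  grow <- axoshed:::dilate_mask_um(mask, 1, vz$pixel_size_um,
                                   vz$pixel_size_um, vz$z_step_um)
  p1 <- pct_outside(vz, "mito", grow)$pct_outside
  expect_lte(p1, p0)
})

test_that("generated extra-axonal fractions are recovered within 4 points", {
  for (f in c(0.05, 0.15, 0.35)) {
    vz <- if (f == 0.15) cached("vz15",
                                render_zstack(scene_config(
                                  extra_axonal_fraction = 0.15, seed = 41)))
    else render_zstack(scene_config(extra_axonal_fraction = f, seed = 41))
    mask <- build_axon_mask(vz)
    po <- pct_outside(vz, "mito", mask)
    expect_lt(abs(po$pct_outside - attr(vz, "true_outside_pct")[["mito"]]), 4)
  }
})

test_that("surface partition separates shell from parenchymal deposits", {
  cfg <- scene_config(extra_axonal_fraction = 0.5,
                      surface_share_of_outside = 1, n_signal_blobs = 40,
                      seed = 42)
  vz <- render_zstack(cfg)
  mask <- build_axon_mask(vz)
  ps <- partition_surface(vz, "mito", mask, attr(vz, "nerve_mask"), d_um = 3)
  expect_gte(ps$pct_on_surface, 95)
  cfg0 <- scene_config(extra_axonal_fraction = 0.5,
                       surface_share_of_outside = 0, n_signal_blobs = 40,
                       seed = 43)
  vz0 <- render_zstack(cfg0)
  ps0 <- partition_surface(vz0, "mito", build_axon_mask(vz0),
                           attr(vz0, "nerve_mask"), d_um = 3)
  expect_lte(ps0$pct_on_surface, 5)
  expect_equal(ps0$pct_on_surface + ps0$pct_in_parenchyma, 100,
               tolerance = 0.01)
  expect_error(partition_surface(vz0, "mito", build_axon_mask(vz0),
                                 attr(vz0, "nerve_mask"), d_um = 0), "d_um")
})

test_that("a generated ~24% surface share is measured within 5 points", {
  cfg <- scene_config(extra_axonal_fraction = 0.4,
                      surface_share_of_outside = 0.239,
                      n_signal_blobs = 150, seed = 44)
  vz <- render_zstack(cfg)
  ps <- partition_surface(vz, "mito", build_axon_mask(vz),
                          attr(vz, "nerve_mask"), d_um = 3)
  expect_lt(abs(ps$pct_on_surface - attr(vz, "true_surface_share_pct")), 5)
})

test_that("surface trend regression matches its closed-form cases", {
  col <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  expect_equal(fit_surface_trend(col)$r_squared, 1)
  flat <- data.frame(x = c(1, 2, 3, 4), y = rep(5, 4))
  expect_equal(fit_surface_trend(flat)$r_squared, 0)
  expect_error(fit_surface_trend(data.frame(x = 1:2, y = 1:2)), "3 animals")
  # noisy slope-0.3 relation over 11 animals lands mid-range
  set.seed(45)
  x <- runif(11, 5, 40)
  y <- 0.3 * x + rnorm(11, 0, 2.7)
  ft <- fit_surface_trend(data.frame(x = x, y = y))
  expect_gt(ft$r_squared, 0.3)
  expect_lt(ft$r_squared, 0.7)
  expect_equal(ft$n, 11)
  expect_s3_class(tidy(ft), "tbl_df")
})
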