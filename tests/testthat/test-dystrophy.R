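test_that("segmentation measures a unit sphere's volume within 10%", {
  vs <- render_sphere_volume(1, 0.1)
  so <- segment_objects(vs, "mito", threshold = 0.5)
  expect_equal(nrow(so), 1)
  expect_lt(abs(so$volume_um3 - 4 / 3 * pi) / (4 / 3 * pi), 0.1)
  blank <- volume_stack(list(mito = array(0, c(8, 8, 8))), 0.1, 0.1)
  expect_equal(nrow(segment_objects(blank, "mito")), 0)
  two <- render_sphere_volume(1, 0.2)
  arr <- two$channels$mito
  arr2 <- array(0, dim(arr) + c(0, 20, 0))
  arr2[, seq_len(dim(arr)[2]), ] <- arr
  arr2[, 20 + seq_len(dim(arr)[2]), ] <- arr
  v2 <- volume_stack(list(mito = arr2), 0.2, 0.2)
  expect_equal(nrow(segment_objects(v2, "mito", threshold = 0.5)), 2)
})

test_that("sphericity matches closed forms and errors on bad input", {
  expect_equal(sphericity(4 / 3 * pi, 4 * pi), 1)
  expect_equal(sphericity(1, 6), (pi / 6)^(1 / 3))
  r <- 0.5
  Vc <- pi * r^2 * 4 * r + 4 / 3 * pi * r^3
  Ac <- 2 * pi * r * 4 * r + 4 * pi * r^2
  expect_lt(sphericity(Vc, Ac), 1)
  expect_error(sphericity(0, 1), "positive")
})

test_that("measured sphericity converges to 1 as voxels shrink", {
  errs <- vapply(c(0.2, 0.1), function(vox) {
    so <- segment_objects(render_sphere_volume(1, vox), "mito",
                          threshold = 0.5)
    abs(so$sphericity - 1)
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)
})

test_that("capsules score lower sphericity than spheres (shape contrast)", {
  psi_sphere <- segment_objects(render_sphere_volume(0.5, 0.05), "mito",
                                threshold = 0.5)$sphericity
  psi_capsule <- segment_objects(render_capsule_volume(0.5, 2, 0.05), "mito",
                                 threshold = 0.5)$sphericity
  expect_lt(psi_capsule, psi_sphere)
})

test_that("planted protrusions are recovered exactly on noiseless axons", {
  ax <- make_sparse_axon(1000, protrusion_x_um = c(100, 300, 500, 700, 900),
                         mito_present = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                         swelling_x_um = c(200, 600))
  pc <- detect_protrusions(ax$membrane, ax$mito, ax$centerline_y_px,
                           ax$pixel_size_um)
  expect_equal(pc$n_calls, 5)
  expect_equal(pc$density_per_100um, 0.5)
  expect_equal(pc$mito_fraction_pct, 60)
  expect_true(all(abs(sort(pc$calls$x_um) -
                        c(100, 300, 500, 700, 900)) < 2))
  # symmetric swellings are rejected by the asymmetry rule
  expect_false(any(abs(pc$calls$x_um - 200) < 5))
  # short axons are skipped with a warning
  tiny <- make_sparse_axon(8, numeric(), logical())
  expect_warning(p0 <- detect_protrusions(tiny$membrane, NULL,
                                          tiny$centerline_y_px,
                                          tiny$pixel_size_um), "skipped")
  expect_true(is.na(p0$density_per_100um))
})

test_that("no false protrusions are called on a plain noiseless axon", {
  ax <- make_sparse_axon(1000, numeric(), logical())
  pc <- detect_protrusions(ax$membrane, NULL, ax$centerline_y_px,
                           ax$pixel_size_um)
  expect_equal(pc$n_calls, 0)
  expect_lte(pc$density_per_100um, 0.05)
})

test_that("event tracking assigns the right kind to each generated series", {
  cfg <- scene_config()
  for (kind in c("swelling", "loading", "pinching_off", "detached")) {
    ser <- make_protrusion_series(cfg, kind, interval_s = 30, seed = 51)
    ev <- track_event(ser$volumes, ser$axon_masks, ser$truth$t_s)
    expect_equal(ev$kind, kind)
    expect_true(all(ev$timepoints$min_distance_um >= 0))
  }
})

test_that("pinch time is called within one interval of the truth", {
  cfg <- scene_config()
  for (int_s in c(30, 120)) {
    ser <- make_protrusion_series(cfg, "pinching_off", interval_s = int_s,
                                  seed = 52)
    ev <- track_event(ser$volumes, ser$axon_masks, ser$truth$t_s)
    expect_lte(abs(ev$pinch_time_s - ser$pinch_time_s), int_s)
    # the first positive measured distance defines pinch_time uniquely
    d <- ev$timepoints$min_distance_um
    expect_equal(ev$pinch_time_s, ev$timepoints$t_s[min(which(d > 0))])
    expect_true(all(d[ev$timepoints$t_s < ev$pinch_time_s] == 0))
  }
})

test_that("loading dynamics and away-region normalization are recovered", {
  ser <- make_protrusion_series(scene_config(), "loading", seed = 53)
  ev <- track_event(ser$volumes, ser$axon_masks, ser$truth$t_s)
  fit_p <- coef(lm(ev$timepoints$i_protrusion ~ ev$timepoints$t_s))[2]
  fit_b <- coef(lm(ev$timepoints$i_axon_beneath ~ ev$timepoints$t_s))[2]
  expect_gt(fit_p, 0)
  expect_lt(fit_b, 0)
  # the away-region itself normalizes to 1: at t = 1 the beneath region is
  # still close to baseline
  expect_lt(abs(ev$timepoints$i_axon_beneath[1] - 1), 0.15)
})

test_that("persistence bound follows survivors x span / tracked", {
  expect_equal(persistence_bound(18, 13, 8), 13 * 8 / 18)
  expect_gte(persistence_bound(18, 13, 8), 5)
  expect_equal(persistence_bound(10, 10, 8), 8)
  expect_equal(persistence_bound(10, 0, 8), 0)
  expect_error(persistence_bound(0, 0, 8), "positive")
})
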