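test_that("scene configuration enforces its invariants", {
  expect_error(scene_config(state_fractions = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(scene_config(coloc_coupling = c(1.2, 0.2, 0.2)), "0, 1")
  expect_error(scene_config(n_frames = 1), "n_frames")
  expect_error(scene_config(extra_axonal_fraction = 1.5), "0, 1")
  cfg <- scene_config()
  expect_s3_class(validate_scene_config(cfg), "scene_config")
})

test_that("degenerate fractions give a pure-state population", {
  tr <- simulate_trajectories(scene_config(n_particles = 50,
                                           state_fractions = c(1, 0, 0)),
                              seed = 1)
  expect_equal(nrow(tr), 50)
  expect_true(all(tr$state == "stationary"))
})

test_that("empirical state fractions converge to the configured ones", {
  tr <- simulate_trajectories(scene_config(n_particles = 4000), seed = 2)
  frac <- prop.table(table(tr$state))
  expect_lt(abs(frac[["stationary"]] - 0.5), 0.03)
  expect_lt(abs(frac[["anterograde"]] - 0.25), 0.03)
  expect_lt(abs(frac[["retrograde"]] - 0.25), 0.03)
})

test_that("zero speed SD gives exactly the configured mean speeds", {
  tr <- simulate_trajectories(scene_config(n_particles = 300,
                                           speed_sd_um_s = 0), seed = 3)
  expect_true(all(tr$speed_um_s[tr$state == "anterograde"] == 0.63))
  expect_true(all(tr$speed_um_s[tr$state == "retrograde"] == -0.78))
})

test_that("ground-truth movement is unambiguous at the 0.1 um/s boundary", {
  tr <- simulate_trajectories(scene_config(n_particles = 500), seed = 4)
  net_v <- vapply(tr$positions, function(p) (p[60] - p[1]) / 59, numeric(1))
  expect_true(all(abs(net_v[tr$state == "stationary"]) < 0.09))
  expect_true(all(net_v[tr$state == "anterograde"] > 0.1))
  expect_true(all(net_v[tr$state == "retrograde"] < -0.1))
  expect_equal(vapply(tr$positions, length, integer(1)),
               rep(60L, 500))
  # moving particles have constant-sign displacement at their drawn speed
  mv <- which(tr$state != "stationary")
  for (i in mv[1:20]) {
    d <- diff(tr$positions[[i]])
    expect_true(all(sign(d) == sign(tr$speed_um_s[i])))
  }
})

test_that("rendering places a stationary spot at a fixed argmax", {
  cfg <- small_cfg(n_particles = 1, noise_model = noiseless,
                   state_fractions = c(1, 0, 0),
                   stationary_jitter_sd_um = 0, stationary_net_sd_um_s = 0)
  tr <- simulate_trajectories(cfg, seed = 5)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  am <- apply(st$channels$mito, 3, which.max)
  expect_true(all(am == am[1]))
})

test_that("a 0.5 um/s particle advances 2 px per frame at 0.25 um pixels", {
  cfg <- small_cfg(n_particles = 1, noise_model = noiseless,
                   pixel_size_um = 0.25)
  tr <- simulate_trajectories(cfg, seed = 6)
  tr$positions[[1]] <- 10 + 0.5 * (0:(cfg$n_frames - 1))
  st <- render_timelapse(tr, cfg, noise = FALSE)
  cols <- vapply(seq_len(cfg$n_frames), function(t) {
    which(st$channels$mito[, , t] == max(st$channels$mito[, , t]),
          arr.ind = TRUE)[1, 2]
  }, integer(1))
  expect_true(all(diff(cols) == 2L))
})

test_that("rendering is bit-identical under a fixed seed and differs otherwise", {
  cfg <- small_cfg(n_particles = 5)
  tr <- simulate_trajectories(cfg, seed = 7)
  a <- render_timelapse(tr, cfg, seed = 99)
  b <- render_timelapse(tr, cfg, seed = 99)
  c <- render_timelapse(tr, cfg, seed = 100)
  expect_identical(a$channels$mito, b$channels$mito)
  expect_false(identical(a$channels$mito, c$channels$mito))
})

test_that("channel-B spots appear only for partner-carrying particles", {
  cfg <- small_cfg(n_particles = 10, noise_model = noiseless,
                   coloc_coupling = c(0, 0, 0))
  tr <- simulate_trajectories(cfg, seed = 8)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  expect_equal(max(st$channels$optn), 0)
  cfg2 <- small_cfg(n_particles = 10, noise_model = noiseless,
                    coloc_coupling = c(1, 1, 1))
  tr2 <- simulate_trajectories(cfg2, seed = 8)
  st2 <- render_timelapse(tr2, cfg2, noise = FALSE)
  expect_equal(st2$channels$optn, st2$channels$mito)
})

test_that("drift injection shifts frames by t x drift and refuses huge drifts", {
  cfg <- small_cfg(n_particles = 3, noise_model = noiseless)
  tr <- simulate_trajectories(cfg, seed = 9)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  same <- inject_drift(st, c(0, 0))
  expect_identical(same$stack$channels$mito, st$channels$mito)
  dr <- inject_drift(st, c(1, 0))
  f1 <- st$channels$mito[, , 5]
  f5 <- dr$stack$channels$mito[, , 5]
  # integer shift: frame 5 equals frame 5 of the clean stack moved 4 rows
  expect_equal(f5[5:nrow(f1), ], f1[1:(nrow(f1) - 4), ], tolerance = 1e-12)
  expect_error(inject_drift(st, c(10, 0)), "25%")
})

test_that("z-stacks hit the requested extra-axonal voxel fraction", {
  cfg <- scene_config(extra_axonal_fraction = 0.25, seed = 10)
  vz <- render_zstack(cfg, length_um = 30, noise = FALSE)
  truth_pct <- attr(vz, "true_outside_pct")[["mito"]]
  expect_gt(truth_pct, 22)
  expect_lt(truth_pct, 28)
  expect_false(is.null(vz$voxel_truth))
})

test_that("degenerate extra-axonal settings label voxels consistently", {
  # the generator's own (pre-blur) bookkeeping is exact
  cfg0 <- scene_config(extra_axonal_fraction = 0, seed = 11)
  vz0 <- render_zstack(cfg0, length_um = 20, noise = FALSE)
  expect_equal(attr(vz0, "true_outside_pct")[["mito"]], 0)
  cfg1 <- scene_config(extra_axonal_fraction = 1,
                       surface_share_of_outside = 1, seed = 12)
  vz1 <- render_zstack(cfg1, length_um = 20, noise = FALSE)
  # surface deposits sit on the nerve boundary and can graze the outermost
  # bundle, so the outside share is within a fraction of a point of 100
  expect_gte(attr(vz1, "true_outside_pct")[["mito"]], 99)
  expect_gte(attr(vz1, "true_surface_share_pct"), 95)
  # measured: supra-threshold interiors of the deposits respect the labels
  sig <- vz1$channels$mito > 15
  expect_lt(mean(attr(vz1, "axon_truth_mask")[sig]), 0.02)
})

test_that("protrusion event series encode their documented dynamics", {
  cfg <- scene_config()
  sw <- make_protrusion_series(cfg, "swelling", seed = 13, noise = FALSE)
  expect_true(all(sw$truth$min_distance_um == 0))

  ld <- make_protrusion_series(cfg, "loading", seed = 14, noise = FALSE)
  expect_true(all(diff(ld$truth$i_protrusion) > 0))
  expect_true(all(diff(ld$truth$i_axon_beneath) < 0))
  # conservation: summed amounts in bud + beneath are constant (pre-noise)
  v1 <- ld$volumes[[1]]$channels$optn
  tot <- vapply(ld$volumes, function(v) sum(v$channels$optn) , numeric(1))
  expect_lt(diff(range(tot)) / mean(tot), 0.02)

  pn <- make_protrusion_series(cfg, "pinching_off", pinch_time_s = 180,
                               seed = 15, noise = FALSE)
  expect_true(all(pn$truth$min_distance_um[pn$truth$t_s <= 180] == 0))
  expect_true(all(pn$truth$min_distance_um[pn$truth$t_s > 180] > 0))

  expect_error(make_protrusion_series(cfg, "loading", interval_s = 45),
               "interval_s")
  expect_error(make_protrusion_series(cfg, "loading", interval_s = 30,
                                      duration_s = 299), "multiple")
})
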