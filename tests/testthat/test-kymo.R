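test_that("identical frames give zero estimated drift", {
  cfg <- small_cfg(n_particles = 4, noise_model = noiseless)
  tr <- simulate_trajectories(cfg, seed = 21)
  tr$state <- "stationary"
  tr$positions <- lapply(tr$positions, function(p) rep(p[1], length(p)))
  st <- render_timelapse(tr, cfg, noise = FALSE)
  sh <- estimate_drift(st, channel = "mito")
  expect_true(all(abs(sh$dy) < 1e-6))
  expect_true(all(abs(sh$dx) < 1e-6))
})

test_that("integer and subpixel injected drifts are recovered", {
  cfg <- scene_config(n_particles = 100, n_frames = 12, seed = 22)
  tr <- simulate_trajectories(cfg)
  st <- render_timelapse(tr, cfg, seed = 23)
  for (d in list(c(1, 0), c(0.5, 0.25))) {
    dr <- inject_drift(st, d)
    sh <- estimate_drift(dr$stack, channel = "mito")
    err <- cbind(-sh$dy - dr$shifts$dy, -sh$dx - dr$shifts$dx)
    expect_lt(max(abs(err)), 0.25 + 1e-9)
    # cumulative error at frame 10
    expect_lt(sqrt(sum(err[10, ]^2)), 0.5)
  }
})

test_that("flat stacks register with a warning and zero shifts", {
  st <- frame_stack(list(mito = array(1, c(16, 16, 4))), 0.25, 1)
  expect_warning(sh <- estimate_drift(st, channel = "mito"), "flat")
  expect_true(all(sh$dy == 0 & sh$dx == 0))
})

test_that("apply_shifts is an involution for integer shifts on the interior", {
  cfg <- small_cfg(n_particles = 4, noise_model = noiseless)
  tr <- simulate_trajectories(cfg, seed = 24)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  nf <- dim(st$channels$mito)[3]
  sh <- tibble::tibble(frame = 1:nf, dy = 3, dx = -2)
  inv <- tibble::tibble(frame = 1:nf, dy = -3, dx = 2)
  back <- apply_shifts(apply_shifts(st, sh), inv)
  a <- st$channels$mito[10:60, 10:140, ]
  b <- back$channels$mito[10:60, 10:140, ]
  expect_equal(a, b, tolerance = 1e-10)
  expect_identical(apply_shifts(st, tibble::tibble(frame = 1:nf, dy = 0,
                                                   dx = 0))$channels$mito,
                   st$channels$mito)
})

test_that("nerve contour recovers the tube diameter and honours overrides", {
  cfg <- scene_config(n_particles = 5, seed = 25, noise_model = noiseless)
  tr <- simulate_trajectories(cfg)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  proj <- rowMeans(st$channels$membrane, dims = 2)
  ct <- trace_nerve_contour(proj, st$pixel_size_um)
  expect_lt(abs(ct$diameter_um - 30) / 30, 0.1)
  poly <- cbind(c(1, 1, 50, 50), c(1, 50, 50, 1))
  ct2 <- trace_nerve_contour(proj, st$pixel_size_um, manual_override = poly)
  expect_identical(ct2$polygon_px, poly)
  expect_error(trace_nerve_contour(matrix(0, 50, 50), 0.25), "no nerve")
})

test_that("swath division tiles the diameter at the requested width", {
  cfg <- scene_config(n_particles = 5, seed = 26, noise_model = noiseless)
  tr <- simulate_trajectories(cfg)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  proj <- rowMeans(st$channels$membrane, dims = 2)
  ct <- trace_nerve_contour(proj, st$pixel_size_um)
  sw <- build_swaths(ct, 1.5)
  expect_equal(nrow(sw$swaths), ceiling(ct$diameter_um / 1.5 - 1e-9))
  # a 30-um nerve at 1.5-um swaths gives 20 bands
  ct30 <- ct
  ct30$diameter_um <- 30
  expect_equal(nrow(build_swaths(ct30, 1.5)$swaths), 20)
  expect_warning(swc <- build_swaths(ct30, 0.5), "clamped")
  expect_equal(swc$swaths$width_um[1], 0.9)
  expect_error(build_swaths(ct30, -1), "positive")
  # abutting bands: adjacent offsets differ by exactly one width
  expect_equal(diff(sw$swaths$offset_um),
               rep(sw$swaths$width_um[1], nrow(sw$swaths) - 1))
  # tiling spans the measured diameter
  edges <- range(sw$swaths$offset_um) + c(-0.75, 0.75)
  expect_gte(diff(edges), ct$diameter_um - 1e-6)
})

test_that("kymographs show static columns and ridges at the true slope", {
  cfg <- small_cfg(n_particles = 1, noise_model = noiseless,
                   state_fractions = c(1, 0, 0), stationary_jitter_sd_um = 0,
                   stationary_net_sd_um_s = 0, n_frames = 30)
  tr <- simulate_trajectories(cfg, seed = 27)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  y_px <- tr$axon_y_um[1] / cfg$pixel_size_um + 1
  path <- rbind(c(y_px, 1), c(y_px, dim(st$channels$mito)[2]))
  k <- extract_kymograph(st, path, channel = "mito")
  am <- apply(k$K, 1, which.max)
  expect_true(all(am == am[1]))

  tr$positions[[1]] <- 5 + 0.5 * (0:29)
  st2 <- render_timelapse(tr, cfg, noise = FALSE)
  k2 <- extract_kymograph(st2, path, channel = "mito")
  ridge <- k2$s_um[apply(k2$K, 1, which.max)]
  slope <- coef(lm(ridge ~ seq(0, 29)))[2]
  expect_lt(abs(slope - 0.5), 0.02)

  # max and mean reducers locate the same ridge
  k3 <- extract_kymograph(st2, path, channel = "mito", reducer = "mean")
  expect_equal(apply(k2$K, 1, which.max), apply(k3$K, 1, which.max))
  expect_error(extract_kymograph(st, rbind(c(1, 1), c(1, 2))), "2 px")
})

test_that("kymographs round-trip through TIFF with sidecar metadata", {
  cfg <- small_cfg(n_particles = 2, seed = 28)
  tr <- simulate_trajectories(cfg)
  st <- render_timelapse(tr, cfg, seed = 29)
  k <- extract_kymograph(st, rbind(c(40, 1), c(40, 150)), channel = "mito")
  f <- tempfile(fileext = ".tif")
  write_kymograph(k, f)
  k2 <- read_kymograph(f)
  expect_equal(k2$K, k$K, tolerance = 1e-6)
  expect_equal(k2$dt_s, k$dt_s)
  expect_equal(k2$s_um, k$s_um)
})

test_that("registration after drift injection preserves kymograph ridges", {
  sc <- demo_scene()
  clean <- render_timelapse(sc$truth, sc$cfg, seed = 72)
  res_clean <- analyze_transport(clean, channels = "mito", register = FALSE)
  res_drift <- sc$res
  # ridge positions: compare per-class mean velocities between the
  # drift-free and drift-injected-then-registered analyses
  a <- res_clean$channels$mito$traces
  b <- res_drift$channels$mito$traces
  ka <- tapply(a$net_velocity_um_s, a$movement_class, mean)
  kb <- tapply(b$net_velocity_um_s, b$movement_class, mean)
  shared <- intersect(names(ka), names(kb))
  expect_true(all(abs(ka[shared] - kb[shared]) < 0.05))
})
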