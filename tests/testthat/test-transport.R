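mk_peaks <- function(frames, s, intensity = 30) {
  tibble::tibble(frame = frames, t_s = frames - 1, s_um = s,
                 intensity = intensity, off_px = 0)
}

test_that("peak detection finds one subpixel peak per noiseless ridge row", {
  cfg <- small_cfg(n_particles = 1, noise_model = noiseless, n_frames = 30)
  tr <- simulate_trajectories(cfg, seed = 31)
  tr$positions[[1]] <- 5 + 0.4 * (0:29)
  st <- render_timelapse(tr, cfg, noise = FALSE)
  y_px <- tr$axon_y_um[1] / cfg$pixel_size_um + 1
  k <- extract_kymograph(st, rbind(c(y_px, 1), c(y_px, 170)),
                         channel = "mito")
  pk <- detect_kymo_objects(k, min_prominence = 5)
  expect_equal(nrow(pk), 30)
  # kymograph arclength starts at the path origin: truth + field margin
  expect_true(all(abs(pk$s_um - (tr$positions[[1]] + 2.5)) < 0.25 * 0.25))
})

test_that("blank kymographs yield no detections and no traces", {
  k <- structure(list(K = matrix(0, 10, 50), K_off = matrix(0, 10, 50),
                      s_um = (0:49) * 0.25, dt_s = 1, pixel_size_um = 0.25,
                      source = NA, width_um = 1.5, reducer = "max"),
                 class = "kymograph")
  pk <- detect_kymo_objects(k, min_prominence = 1)
  expect_equal(nrow(pk), 0)
  expect_equal(nrow(link_traces(pk)), 0)
})

test_that("two ridges five microns apart stay two ordered peaks", {
  cfg <- small_cfg(n_particles = 2, noise_model = noiseless, n_frames = 20,
                   state_fractions = c(1, 0, 0), stationary_jitter_sd_um = 0,
                   stationary_net_sd_um_s = 0)
  tr <- simulate_trajectories(cfg, seed = 32)
  tr$axon_y_um <- rep(tr$axon_y_um[1], 2)
  tr$positions <- list(rep(10, 20), rep(15, 20))
  st <- render_timelapse(tr, cfg, noise = FALSE)
  y_px <- tr$axon_y_um[1] / cfg$pixel_size_um + 1
  k <- extract_kymograph(st, rbind(c(y_px, 1), c(y_px, 170)),
                         channel = "mito")
  pk <- detect_kymo_objects(k, min_prominence = 5)
  expect_equal(as.integer(table(pk$frame)), rep(2L, 20))
  expect_true(all(tapply(pk$s_um, pk$frame, diff) > 4))
})

test_that("linking spans dropouts and separates crossing ridges by slope", {
  p <- mk_peaks(1:60, 10 + 0.63 * (0:59))
  expect_equal(length(unique(link_traces(p)$trace_id)), 1)
  p2 <- p[-c(20, 21), ]
  l2 <- link_traces(p2, max_gap_frames = 2)
  expect_equal(length(unique(l2$trace_id)), 1)
  pa <- mk_peaks(1:60, 10 + 0.63 * (0:59))
  pb <- mk_peaks(1:60, 40 - 0.78 * (0:59))
  l3 <- link_traces(dplyr::arrange(dplyr::bind_rows(pa, pb), frame))
  tt <- traces_table(l3)
  expect_equal(nrow(tt), 2)
  expect_equal(sort(tt$net_velocity_um_s), c(-0.78, 0.63), tolerance = 0.1)
})

test_that("trace velocity is net displacement over the observed span", {
  expect_equal(trace_velocity(c(0, 60), c(0, 6)), 0.1)
  expect_equal(trace_velocity(c(0, 60), c(10, 10)), 0)
  expect_error(trace_velocity(c(5, 5), c(0, 1)), "zero-duration")
  # jittered stationary truth stays under the boundary
  tr <- simulate_trajectories(scene_config(n_particles = 200,
                                           state_fractions = c(1, 0, 0)),
                              seed = 33)
  v <- vapply(tr$positions, function(p) trace_velocity(0:59, p), numeric(1))
  expect_true(all(abs(v) < 0.1))
})

test_that("classification is inclusive at the boundary and symmetric", {
  expect_equal(classify_movement(0.1), "anterograde")
  expect_equal(classify_movement(-0.099), "stationary")
  expect_equal(classify_movement(-0.78), "retrograde")
  # s-axis flip swaps the moving classes and fixes stationary
  v <- c(-0.5, -0.1, -0.05, 0, 0.05, 0.1, 0.5)
  a <- classify_movement(v)
  b <- classify_movement(-v)
  swap <- c(anterograde = "retrograde", retrograde = "anterograde",
            stationary = "stationary")
  expect_equal(unname(swap[a]), b)
  # raising the threshold never decreases the stationary fraction
  set.seed(34)
  vv <- rnorm(500, 0, 0.3)
  fr <- vapply(c(0.05, 0.1, 0.2, 0.4),
               function(th) mean(classify_movement(vv, th) == "stationary"),
               numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("movement summaries aggregate per animal with exact percentages", {
  tt <- tibble::tibble(
    animal_id = 1,
    movement_class = rep(c("stationary", "anterograde", "retrograde"),
                         c(5, 3, 2)),
    net_velocity_um_s = c(rep(0, 5), rep(0.6, 3), rep(-0.8, 2)))
  ms <- summarize_movement(tt)
  pct <- setNames(ms$group$mean_pct, ms$group$movement_class)
  expect_equal(pct[["stationary"]], 50)
  expect_equal(pct[["anterograde"]], 30)
  expect_equal(pct[["retrograde"]], 20)
  expect_equal(sum(ms$per_animal$pct), 100)
})

test_that("co-localization matching handles the degenerate channel cases", {
  sc <- demo_scene()
  mt <- sc$res$channels$mito$traces
  ml <- sc$res$channels$mito$long
  # identical channels: everything co-localizes
  cs <- match_traces(mt, ml, mt, ml)
  expect_true(all(cs$by_class$frac_coloc[cs$by_class$n_total > 0] == 1))
  # empty partner channel: nothing does
  empty_t <- mt[0, ]
  cs0 <- match_traces(mt, ml, empty_t, ml[0, ])
  expect_true(all(cs0$by_class$n_coloc == 0))
  expect_equal(sum(cs0$by_class$n_total), nrow(mt))
  # counts per class are complementary
  expect_equal(cs$by_class$n_coloc + cs$by_class$n_solo, cs$by_class$n_total)
})

test_that("gap closing joins fragments of one object", {
  p <- mk_peaks(c(1:20, 26:60), 10 + 0.5 * c(0:19, 25:59))
  p$y_um <- 0
  l <- link_traces(p, max_gap_frames = 2)
  expect_gt(length(unique(l$trace_id)), 1)
  s <- stitch_traces(l)
  expect_equal(length(unique(s$trace_id)), 1)
})

test_that("crossing repair undoes identity swaps", {
  # build a swapped pair: trace 1 = mover then stationary, trace 2 reverse
  t_all <- 0:59
  mover <- 10 + 0.6 * t_all
  stat <- rep(28, 60)
  cross <- which.min(abs(mover - stat))
  l <- dplyr::bind_rows(
    tibble::tibble(trace_id = 1L, frame = t_all + 1, t_s = t_all,
                   s_um = c(mover[1:cross], stat[(cross + 1):60]),
                   intensity = 30, y_um = 0),
    tibble::tibble(trace_id = 2L, frame = t_all + 1, t_s = t_all,
                   s_um = c(stat[1:cross], mover[(cross + 1):60]),
                   intensity = 30, y_um = 0))
  r <- repair_crossings(l)
  tt <- traces_table(r)
  v <- sort(tt$net_velocity_um_s)
  expect_equal(v, c(0, 0.6), tolerance = 0.02)
})

test_that("transverse splitting separates lane-hopping chimeras only", {
  ob <- tibble::tibble(trace_id = 1L, frame = 1:40, t_s = 0:39,
                       s_um = rep(10, 40), intensity = 20,
                       y_um = c(rep(0, 20), rep(1, 20)))
  sp <- split_traces_by_y(ob)
  expect_equal(length(unique(sp$trace_id)), 2)
  # a same-lane direction change is left intact
  ob2 <- tibble::tibble(trace_id = 1L, frame = 1:40, t_s = 0:39,
                        s_um = c(10 + 0.5 * (0:19), 19.5 - 0.5 * (1:20)),
                        intensity = 20, y_um = 0)
  expect_equal(length(unique(split_traces_by_y(ob2)$trace_id)), 1)
})

test_that("a single moving particle yields exactly one trace per swath set", {
  cfg <- scene_config(n_particles = 1, seed = 35,
                      noise_model = list(gaussian_sd = 0.5,
                                         poisson_scale = 0))
  tr <- simulate_trajectories(cfg)
  tr$state <- "anterograde"
  tr$speed_um_s <- 0.6
  tr$positions[[1]] <- 15 + 0.6 * (0:59)
  st <- render_timelapse(tr, cfg, seed = 36)
  # no drift injected; registration would lock onto the only (moving) spot
  res <- analyze_transport(st, channels = "mito", register = FALSE)
  movers <- res$channels$mito$traces |>
    dplyr::filter(.data$movement_class != "stationary")
  expect_equal(nrow(movers), 1)
})
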