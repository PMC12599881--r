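# Shared fixtures: small noiseless configs and a cache so expensive
# simulations are computed once per test run.

noiseless <- list(gaussian_sd = 0, poisson_scale = 0)

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_particles = 20, n_axons = 10, axon_length_um = 40,
         nerve_diameter_um = 20, n_frames = 20),
    list(...))
  do.call(scene_config, args)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# one mid-size noisy scene used by several transport tests
demo_scene <- function() {
  cached("demo_scene", {
    cfg <- scene_config(n_particles = 150, seed = 71,
                        drift_per_frame_px = c(0.1, 0.1))
    tr <- simulate_trajectories(cfg)
    st <- render_timelapse(tr, cfg, seed = 72)
    st <- inject_drift(st, cfg$drift_per_frame_px)$stack
    list(cfg = cfg, truth = tr, stack = st,
         res = analyze_transport(st))
  })
}

# the transport/co-localization recovery experiment shared by the
# acceptance tests: 4000 particles across 20 fields of view
recovery_experiment <- function() {
  cached("recovery_experiment", {
    t0 <- Sys.time()
    traces <- list()
    coloc <- list()
    truth <- list()
    for (a in 1:20) {
      cfg <- scene_config(n_particles = 200, seed = 1000 + a,
                          drift_per_frame_px = c(0.1, 0.1))
      tr <- simulate_trajectories(cfg)
      st <- render_timelapse(tr, cfg, seed = 2000 + a)
      st <- inject_drift(st, cfg$drift_per_frame_px)$stack
      res <- analyze_transport(st)
      mt <- res$channels$mito$traces
      mt$animal_id <- a
      traces[[a]] <- mt
      cs <- match_traces(res$channels$mito$traces, res$channels$mito$long,
                         res$channels$optn$traces, res$channels$optn$long)
      coloc[[a]] <- cs$by_class
      truth[[a]] <- tr
    }
    list(traces = dplyr::bind_rows(traces),
         coloc = dplyr::bind_rows(coloc),
         truth = dplyr::bind_rows(lapply(truth, function(x) {
           x$positions <- NULL
           x
         })),
         runtime_s = as.numeric(Sys.time() - t0, units = "secs"))
  })
}
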