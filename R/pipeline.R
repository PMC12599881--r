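#' Whole-nerve transport analysis of a registered time series
#'
#' Runs the semi-automatic kymograph workflow on one time-lapse stack:
#' rigid registration (phase correlation on the structural channel), nerve
#' contour tracing on the temporal mean projection, swath division,
#' per-swath kymograph extraction, object detection and linking, per-trace
#' classification at the 0.1 um/s boundary, and cross-swath deduplication.
#'
#' @param stack A [frame_stack()] with a `membrane` structural channel.
#' @param channels Channel roles to trace (first is the reference channel
#'   for co-localization).
#' @param swath_width_um Swath width (um), clamped to 0.9-1.8.
#' @param min_prominence Detection prominence; `NULL` estimates
#'   `8 x mad(K)` per kymograph.
#' @param threshold Moving classification boundary (um/s).
#' @param max_jump_um,max_gap_frames,min_trace_len,max_dy_um Linking
#'   parameters, see [link_traces()].
#' @param dedup_y_tol_um Transverse tolerance for cross-swath trace
#'   deduplication; duplicates of one object reconstruct to nearly the same
#'   transverse position, while distinct neighbouring axons sit at least a
#'   lane spacing apart (see [dedup_traces()]).
#' @param register Run drift registration first (default `TRUE`).
#' @param reducer Width reducer for kymograph extraction.
#' @return An `axon_transport` list: per channel `traces` (deduplicated
#'   per-trace tibble) and `long` observation tables, plus `contour`,
#'   `swaths`, and per-channel raw/deduplicated stationary counts.
#' @export
analyze_transport <- function(stack, channels = c("mito", "optn"),
                              swath_width_um = 1.5, min_prominence = NULL,
                              threshold = 0.1, max_jump_um = 1.5,
                              max_gap_frames = 2, min_trace_len = 5,
                              max_dy_um = 0.8, dedup_y_tol_um = 0.35,
                              register = TRUE, reducer = "max") {
  if (register) stack <- register_stack(stack, channel = channels[1])
  proj <- rowMeans(get_channel(stack, "membrane"), dims = 2)
  contour <- trace_nerve_contour(proj, stack$pixel_size_um)
  swaths <- build_swaths(contour, swath_width_um)
  out <- list(contour = contour, swaths = swaths, channels = list())
  for (ch in channels) {
    kymos <- extract_swath_kymographs(stack, swaths, channel = ch,
                                      reducer = reducer)
    longs <- list()
    tbls <- list()
    for (k in seq_along(kymos)) {
      prom <- min_prominence %||%
        max(8 * stats::mad(as.numeric(kymos[[k]]$K)), 1e-9)
      pk <- detect_kymo_objects(kymos[[k]], prom)
      if (nrow(pk)) {
        # band ownership: a detection whose subpixel transverse position
        # falls outside this swath belongs to (and is traced in) the
        # neighbouring swath; keeping it here would double-count
        half_band <- swaths$swaths$width_um[k] / stack$pixel_size_um / 2
        pk <- pk[abs(pk$off_px) <= half_band + 0.25, , drop = FALSE]
      }
      if (nrow(pk)) {
        pk$y_um <- swaths$swaths$offset_um[k] +
          pk$off_px * stack$pixel_size_um
      }
      lng <- link_traces(pk, max_jump_um, max_gap_frames, min_trace_len,
                         max_dy_um)
      if (nrow(lng) == 0) next
      lng <- stitch_traces(lng)
      lng <- repair_crossings(lng)
      lng <- split_traces_by_y(lng)
      lng <- lng |>
        group_by(.data$trace_id) |>
        filter(dplyr::n() >= min_trace_len) |>
        ungroup()
      if (nrow(lng) == 0) next
      lng$swath <- k
      longs[[length(longs) + 1]] <- lng
      tb <- traces_table(lng, threshold, min_trace_len)
      tb$swath <- k
      tbls[[length(tbls) + 1]] <- tb
    }
    if (!length(tbls)) {
      out$channels[[ch]] <- list(traces = tibble(), long = tibble())
      next
    }
    # re-key trace ids to be unique across swaths
    for (i in seq_along(tbls)) {
      key <- i * 100000L
      tbls[[i]]$trace_id <- tbls[[i]]$trace_id + key
      longs[[i]]$trace_id <- longs[[i]]$trace_id + key
    }
    tbl <- dplyr::bind_rows(tbls)
    long <- dplyr::bind_rows(longs)
    dd <- dedup_traces(tbl, long, y_tol_um = dedup_y_tol_um)
    long_dd <- dplyr::semi_join(long, dd, by = "trace_id")
    # a mover whose transverse position sits near a band edge can flicker
    # between adjacent swaths and fragment in time: close those gaps
    # across the whole swath set (y-gated), then re-summarize
    long_dd <- stitch_traces(long_dd)
    tbl2 <- traces_table(long_dd, threshold, min_trace_len)
    # stitching consolidates fragments into full-span traces, which makes
    # remaining cross-swath duplicates unambiguous: deduplicate once more
    tbl2 <- dedup_traces(tbl2, long_dd, y_tol_um = dedup_y_tol_um)
    long_dd <- dplyr::semi_join(long_dd, tbl2, by = "trace_id")
    swath_of <- long_dd |>
      group_by(.data$trace_id) |>
      summarise(swath = as.integer(median(.data$swath)), .groups = "drop")
    tbl2 <- dplyr::left_join(tbl2, swath_of, by = "trace_id")
    out$channels[[ch]] <- list(
      traces = tbl2, long = long_dd,
      n_stationary_raw = attr(dd, "n_stationary_raw"),
      n_stationary_dedup = sum(tbl2$movement_class == "stationary"))
  }
  structure(out, class = "axon_transport")
}

#' Default pipeline configuration
#'
#' A small pure-simulation demonstration configuration for
#' [run_pipeline()]: a handful of animals, each with a simulated
#' time-lapse (transport + co-localization), a z-stack (extra-axonal
#' volumetry + surface partition) and a protrusion event series.
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @return A nested configuration list (serializable to YAML).
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    n_animals = 3,
    scene = list(n_particles = 80, n_axons = 24, axon_length_um = 60,
                 drift_per_frame_px = c(0.1, 0.05)),
    transport = list(swath_width_um = 1.5, threshold = 0.1,
                     coloc_max_dist_um = 0.5, coloc_min_overlap_frac = 0.5),
    volumetry = list(length_um = 20, d_um = 3),
    events = list(interval_s = 30, kinds = c("loading", "pinching_off")),
    out_dir = NULL
  )
}

#' Run the full simulation-to-statistics pipeline
#'
#' Executes simulate -> render -> drift -> register -> kymograph ->
#' transport -> co-localization -> z-stack volumetry -> protrusion event
#' tracking -> per-animal statistics, and collects every stage's outputs in
#' a report bundle. With `out_dir` set, per-trace and summary CSVs and a
#' summary JSON are written. Identical config + seed give byte-identical
#' summary JSON.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file holding one.
#' @return An `axoshed_report`: list with `movement` (a
#'   [summarize_movement()] result), `coloc` (per-class co-localization
#'   across animals), `volumetry` (per-animal outside/surface tibble),
#'   `events` (tracked event glances), `summary` (plain list serialized to
#'   JSON) and `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg0 <- default_pipeline_config()
  config <- utils::modifyList(cfg0, config)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    message(sprintf("[axoshed] %-12s %6.1f s", name,
                    as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }

  scene_args <- config$scene
  scene_args$drift_per_frame_px <-
    unlist(scene_args$drift_per_frame_px %||% c(0, 0))
  all_traces <- list()
  coloc_rows <- list()
  vol_rows <- list()
  for (a in seq_len(config$n_animals)) {
    seed_a <- (config$seed * 1009L + a * 7919L) %% .Machine$integer.max
    cfg <- do.call(scene_config, c(scene_args, list(seed = seed_a)))
    tr <- stage(sprintf("simulate %d", a), simulate_trajectories(cfg))
    st <- stage(sprintf("render %d", a),
                render_timelapse(tr, cfg, seed = seed_a + 1))
    if (any(cfg$drift_per_frame_px != 0)) {
      st <- inject_drift(st, cfg$drift_per_frame_px)$stack
    }
    tp <- config$transport
    res <- stage(sprintf("transport %d", a),
                 analyze_transport(st, swath_width_um = tp$swath_width_um,
                                   threshold = tp$threshold))
    mt <- res$channels$mito$traces
    if (nrow(mt)) {
      mt$animal_id <- a
      all_traces[[a]] <- mt
    }
    cs <- match_traces(res$channels$mito$traces, res$channels$mito$long,
                       res$channels$optn$traces, res$channels$optn$long,
                       max_dist_um = tp$coloc_max_dist_um,
                       min_overlap_frac = tp$coloc_min_overlap_frac)
    coloc_rows[[a]] <- mutate(cs$by_class, animal_id = a)

    vz <- stage(sprintf("zstack %d", a),
                render_zstack(cfg, seed = seed_a + 2,
                              length_um = config$volumetry$length_um))
    mask <- build_axon_mask(vz)
    po <- pct_outside(vz, "mito", mask)
    ps <- partition_surface(vz, "mito", mask, attr(vz, "nerve_mask"),
                            d_um = config$volumetry$d_um)
    vol_rows[[a]] <- tibble(animal_id = a, pct_outside = po$pct_outside,
                            pct_on_surface = ps$pct_on_surface,
                            pct_total_on_surface = ps$pct_total_on_surface)
  }
  traces <- dplyr::bind_rows(all_traces)
  movement <- summarize_movement(traces)
  coloc <- dplyr::bind_rows(coloc_rows) |>
    group_by(.data$movement_class) |>
    summarise(n_coloc = sum(.data$n_coloc), n_solo = sum(.data$n_solo),
              frac_coloc = sum(.data$n_coloc) /
                pmax(sum(.data$n_coloc + .data$n_solo), 1), .groups = "drop")
  volumetry <- dplyr::bind_rows(vol_rows)

  events <- list()
  for (kind in config$events$kinds) {
    ser <- stage(paste0("event ", kind),
                 make_protrusion_series(
                   do.call(scene_config, c(scene_args,
                                           list(seed = config$seed))),
                   kind = kind, interval_s = config$events$interval_s,
                   seed = config$seed + 17))
    ev <- track_event(ser$volumes, ser$axon_masks, ser$truth$t_s)
    events[[kind]] <- glance(ev)
  }
  events <- dplyr::bind_rows(events)

  out_meas <- per_animal_aggregate(volumetry, "pct_outside")
  summary <- list(
    movement = as.list(movement$group |>
                         select("movement_class", "mean_pct", "sem_pct",
                                "mean_speed_um_s")),
    coloc = as.list(coloc),
    volumetry = list(mean_pct_outside = out_meas$group$mean,
                     sem_pct_outside = out_meas$group$sem,
                     n_animals = out_meas$group$n_animals),
    events = as.list(events),
    n_traces = nrow(traces),
    seed = config$seed
  )
  report <- structure(list(movement = movement, coloc = coloc,
                           volumetry = volumetry, events = events,
                           traces = traces, summary = summary,
                           config = config),
                      class = "axoshed_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(traces, file.path(config$out_dir, "traces.csv"),
                     row.names = FALSE)
    utils::write.csv(volumetry, file.path(config$out_dir, "volumetry.csv"),
                     row.names = FALSE)
    utils::write.csv(movement$group, file.path(config$out_dir,
                                               "movement_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  message(sprintf("[axoshed] pipeline done in %.1f s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  report
}

#' @export
print.axoshed_report <- function(x, ...) {
  cat("<axoshed_report>\n")
  cat(sprintf("  %d traces from %d animals\n", nrow(x$traces),
              x$config$n_animals))
  print(x$movement$group)
  invisible(x)
}
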