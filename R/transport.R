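#' Detect punctate objects in a kymograph, row by row
#'
#' Finds subpixel 1D intensity peaks in every time row of a kymograph:
#' local maxima whose prominence over the neighbouring troughs exceeds
#' `min_prominence`, refined by parabolic interpolation.
#'
#' @param kymo A `kymograph`.
#' @param min_prominence Minimum peak prominence, in the kymograph's raw
#'   intensity units; `NULL` estimates `8 x mad(K)` (robust to sparse
#'   signal, since most kymograph pixels are background).
#' @param window_px Half-window (px) within which flanking troughs are
#'   searched.
#' @return A tibble `frame`, `t_s`, `s_um`, `intensity`; zero rows if the
#'   kymograph is blank.
#' @export
detect_kymo_objects <- function(kymo, min_prominence = NULL, window_px = 10) {
  stopifnot(inherits(kymo, "kymograph"))
  min_prominence <- min_prominence %||%
    max(8 * stats::mad(as.numeric(kymo$K)), 1e-9)
  px <- kymo$pixel_size_um
  fr_l <- list(); pos_l <- list(); ht_l <- list(); off_l <- list()
  for (t in seq_len(nrow(kymo$K))) {
    v <- kymo$K[t, ]
    pk <- find_peaks_1d(v, min_prominence, window_px)
    if (length(pk$pos)) {
      fr_l[[length(fr_l) + 1]] <- rep(t, length(pk$pos))
      pos_l[[length(pos_l) + 1]] <- pk$pos
      ht_l[[length(ht_l) + 1]] <- pk$height
      off_l[[length(off_l) + 1]] <- if (!is.null(kymo$K_off))
        kymo$K_off[t, pmin(pmax(round(pk$pos), 1), ncol(kymo$K))] else
        rep(0, length(pk$pos))
    }
  }
  fr <- unlist(fr_l) %||% integer()
  tibble(frame = as.integer(fr), t_s = (fr - 1) * kymo$dt_s,
         s_um = (unlist(pos_l) %||% numeric() - 1) * px,
         intensity = unlist(ht_l) %||% numeric(),
         off_px = unlist(off_l) %||% numeric())
}

find_peaks_1d <- function(v, min_prominence, window_px) {
  n <- length(v)
  if (n < 3) return(list(pos = numeric(), height = numeric()))
  core <- 2:(n - 1)
  is_max <- v[core] > v[core - 1] & v[core] >= v[core + 1]
  cand <- core[is_max]
  pos <- numeric(); height <- numeric()
  for (i in cand) {
    lo <- max(1, i - window_px); hi <- min(n, i + window_px)
    prom <- v[i] - max(min(v[lo:i]), min(v[i:hi]))
    if (prom < min_prominence) next
    # parabolic subpixel refinement
    denom <- v[i - 1] - 2 * v[i] + v[i + 1]
    delta <- if (denom < 0) 0.5 * (v[i - 1] - v[i + 1]) / denom else 0
    delta <- min(max(delta, -0.5), 0.5)
    pos <- c(pos, i + delta)
    height <- c(height, v[i])
  }
  list(pos = pos, height = height)
}

#' Link per-frame detections into traces
#'
#' Greedy nearest-neighbour frame-to-frame linking with a
#' velocity-continuity prediction: each open trace predicts its next
#' position from its recent velocity, candidate links are assigned in order
#' of prediction error, links longer than `max_jump_um` are refused, gaps up
#' to `max_gap_frames` are bridged, and traces observed fewer than
#' `min_trace_len` frames are discarded (their count is kept in the
#' `"n_discarded_short"` attribute).
#'
#' When detections carry a transverse coordinate (`y_um`, reconstructed from
#' the cross-width argmax), links are restricted to `max_dy_um` of transverse
#' motion and the assignment cost penalizes transverse jumps — an object
#' stays in its axon, so candidate links that hop lanes are chimeras.
#'
#' @param peaks Tibble from [detect_kymo_objects()].
#' @param max_jump_um Largest allowed frame-to-frame displacement (um),
#'   scaled by the bridged gap length.
#' @param max_gap_frames Longest bridged dropout (frames).
#' @param min_trace_len Minimum observed frames for a trace to be kept.
#' @param max_dy_um Largest transverse step between consecutive
#'   observations (um), when `y_um` is available.
#' @return A tibble `trace_id`, `frame`, `t_s`, `s_um`, `intensity` (one row
#'   per observation).
#' @export
link_traces <- function(peaks, max_jump_um = 1.5, max_gap_frames = 2,
                        min_trace_len = 5, max_dy_um = 0.8) {
  empty <- tibble(trace_id = integer(), frame = integer(), t_s = numeric(),
                  s_um = numeric(), intensity = numeric())
  if (nrow(peaks) == 0) {
    attr(empty, "n_discarded_short") <- 0L
    return(empty)
  }
  have_y <- "y_um" %in% names(peaks)
  ord_pk <- order(peaks$frame)
  pk_frame <- peaks$frame[ord_pk]
  pk_s <- peaks$s_um[ord_pk]
  pk_y <- if (have_y) peaks$y_um[ord_pk] else numeric(nrow(peaks))
  frames <- unique(pk_frame)
  row_of_frame <- split(seq_along(pk_frame), pk_frame)

  # active track state (plain vectors; observations stored as row indices)
  tr_s <- numeric(); tr_v <- numeric(); tr_y <- numeric()
  tr_last_frame <- integer(); tr_n <- integer()
  obs <- list() # per track: integer vector of peak row indices
  assign_to <- integer(length(pk_frame)) # track index per observation

  for (f in frames) {
    rows <- row_of_frame[[as.character(f)]]
    ps <- pk_s[rows]
    py <- pk_y[rows]
    assigned_pk <- rep(FALSE, length(rows))
    if (length(tr_s)) {
      cand <- which((f - tr_last_frame) <= (max_gap_frames + 1) &
                      (f - tr_last_frame) >= 1)
      if (length(cand) && length(rows)) {
        gap <- f - tr_last_frame[cand]
        pred <- tr_s[cand] + tr_v[cand] * gap
        cost_s <- abs(outer(pred, ps, `-`))
        cost_y <- if (have_y) abs(outer(tr_y[cand], py, `-`)) else
          matrix(0, length(cand), length(ps))
        cost <- cost_s + cost_y
        lim <- max_jump_um * gap
        ord <- order(cost)
        used_tr <- rep(FALSE, length(cand))
        for (o in ord) {
          i <- (o - 1) %% length(cand) + 1
          j <- (o - 1) %/% length(cand) + 1
          if (used_tr[i] || assigned_pk[j]) next
          if (cost_s[i, j] > lim[i]) next
          if (have_y && cost_y[i, j] > max_dy_um) next
          k <- cand[i]
          dtf <- f - tr_last_frame[k]
          v_new <- (ps[j] - tr_s[k]) / dtf
          tr_v[k] <- if (tr_n[k] >= 2) 0.5 * tr_v[k] + 0.5 * v_new else v_new
          tr_s[k] <- ps[j]
          tr_y[k] <- 0.7 * tr_y[k] + 0.3 * py[j]
          tr_last_frame[k] <- f
          tr_n[k] <- tr_n[k] + 1L
          obs[[k]] <- c(obs[[k]], rows[j])
          used_tr[i] <- TRUE
          assigned_pk[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned_pk)) {
      tr_s <- c(tr_s, ps[j]); tr_v <- c(tr_v, 0); tr_y <- c(tr_y, py[j])
      tr_last_frame <- c(tr_last_frame, f); tr_n <- c(tr_n, 1L)
      obs[[length(tr_s)]] <- rows[j]
    }
  }
  lens <- lengths(obs)
  keep <- which(lens >= min_trace_len)
  n_short <- sum(lens < min_trace_len)
  if (!length(keep)) {
    attr(empty, "n_discarded_short") <- as.integer(n_short)
    return(empty)
  }
  idx <- unlist(obs[keep])
  out <- peaks[ord_pk, ][idx, ]
  out <- dplyr::mutate(out, trace_id = rep(seq_along(keep), lens[keep]),
                       .before = 1)
  attr(out, "n_discarded_short") <- as.integer(n_short)
  out
}

#' Stitch trace fragments across gaps (gap closing)
#'
#' Second-pass segment linking: when one trace ends and another starts
#' shortly after at the position the first trace's velocity predicts, the
#' two are fragments of one object (typical after occlusions where two
#' ridges cross) and are merged. Greedy, nearest-prediction-first.
#'
#' @param traces_long Long observation table from [link_traces()].
#' @param max_gap_frames Largest bridged temporal gap between fragments.
#' @param max_dist_um Largest deviation from the extrapolated position (um),
#'   plus `0.1 um` per gap frame of slack.
#' @return The long table with merged `trace_id`s.
#' @export
stitch_traces <- function(traces_long, max_gap_frames = 10,
                          max_dist_um = 0.8) {
  if (nrow(traces_long) == 0) return(traces_long)
  have_y <- "y_um" %in% names(traces_long)
  summarize_tt <- function() {
    o <- order(traces_long$trace_id, traces_long$frame)
    id <- traces_long$trace_id[o]
    first <- !duplicated(id)
    last <- !duplicated(id, fromLast = TRUE)
    y <- if (have_y) {
      unname(vapply(split(traces_long$y_um[o], id), mean, numeric(1)))
    } else {
      rep(0, sum(first))
    }
    list(trace_id = id[first],
         f0 = traces_long$frame[o][first], f1 = traces_long$frame[o][last],
         s0 = traces_long$s_um[o][first], s1 = traces_long$s_um[o][last],
         t0 = traces_long$t_s[o][first], t1 = traces_long$t_s[o][last],
         y = y)
  }
  repeat {
    tt <- summarize_tt()
    n <- length(tt$trace_id)
    if (n < 2) break
    v <- ifelse(tt$t1 > tt$t0, (tt$s1 - tt$s0) / (tt$t1 - tt$t0), 0)
    best <- NULL
    for (i in seq_len(n)) {
      gap <- tt$f0 - tt$f1[i]
      dtg <- tt$t0 - tt$t1[i]
      pred_err <- abs(tt$s0 - (tt$s1[i] + v[i] * dtg))
      ok <- which(gap >= 1 & gap <= max_gap_frames &
                    pred_err <= max_dist_um + 0.1 * gap &
                    abs(tt$y - tt$y[i]) <= 0.6)
      if (length(ok)) {
        j <- unname(ok[which.min(pred_err[ok])])
        cand <- c(i = i, j = j, err = unname(pred_err[j]))
        if (is.null(best) || cand[["err"]] < best[["err"]]) best <- cand
      }
    }
    if (is.null(best)) break
    keep_id <- tt$trace_id[best[["i"]]]
    drop_id <- tt$trace_id[best[["j"]]]
    traces_long$trace_id[traces_long$trace_id == drop_id] <- keep_id
  }
  traces_long
}

#' Repair identity swaps at trace crossings
#'
#' When two ridges cross, greedy frame-to-frame linking can exchange the
#' identities, yielding two kinked traces (e.g. a mover that "stops" at the
#' moment a stationary ridge passes, and vice versa). For every pair of
#' temporally overlapping traces that approach within `approach_um`, the
#' post-crossing segments are tentatively exchanged; if the summed residual
#' of per-trace linear fits drops by more than `improve_frac`, the exchange
#' is kept. A genuinely direction-changing object is left alone: exchanging
#' its segments with a straight neighbour would not reduce the residuals.
#'
#' @param traces_long Long observation table.
#' @param approach_um Crossing detection distance (um).
#' @param improve_frac Required relative improvement of the linear-fit SSE.
#' @return The long table with swapped identities repaired.
#' @export
repair_crossings <- function(traces_long, approach_um = 1, improve_frac = 0.5) {
  if (nrow(traces_long) == 0) return(traces_long)
  sse <- function(t, s) {
    if (length(t) < 3) return(0)
    f <- stats::lm.fit(cbind(1, t), s)
    sum(f$residuals^2)
  }
  changed <- TRUE
  pass <- 0
  while (changed && pass < 3) {
    changed <- FALSE
    pass <- pass + 1
    ids <- unique(traces_long$trace_id)
    if (length(ids) < 2) break
    fr_l <- split(traces_long$frame, traces_long$trace_id)[as.character(ids)]
    s_l <- split(traces_long$s_um, traces_long$trace_id)[as.character(ids)]
    t_l <- split(traces_long$t_s, traces_long$trace_id)[as.character(ids)]
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (b <= a) next
        common <- intersect(fr_l[[a]], fr_l[[b]])
        if (length(common) < 4) next
        sa <- s_l[[a]][match(common, fr_l[[a]])]
        sb <- s_l[[b]][match(common, fr_l[[b]])]
        dmin <- min(abs(sa - sb))
        if (dmin > approach_um) next
        f_cross <- common[which.min(abs(sa - sb))]
        a1 <- fr_l[[a]] <= f_cross; b1 <- fr_l[[b]] <= f_cross
        if (!any(a1) || all(a1) || !any(b1) || all(b1)) next
        orig <- sse(t_l[[a]], s_l[[a]]) + sse(t_l[[b]], s_l[[b]])
        swapped <- sse(c(t_l[[a]][a1], t_l[[b]][!b1]),
                       c(s_l[[a]][a1], s_l[[b]][!b1])) +
          sse(c(t_l[[b]][b1], t_l[[a]][!a1]),
              c(s_l[[b]][b1], s_l[[a]][!a1]))
        if (swapped < improve_frac * orig) {
          sel_a2 <- traces_long$trace_id == ids[a] &
            traces_long$frame > f_cross
          sel_b2 <- traces_long$trace_id == ids[b] &
            traces_long$frame > f_cross
          traces_long$trace_id[sel_a2] <- ids[b]
          traces_long$trace_id[sel_b2] <- ids[a]
          # refresh the cached per-trace vectors for the swapped pair
          fa <- c(fr_l[[a]][a1], fr_l[[b]][!b1])
          fb <- c(fr_l[[b]][b1], fr_l[[a]][!a1])
          oa <- order(fa); ob <- order(fb)
          new_sa <- c(s_l[[a]][a1], s_l[[b]][!b1])[oa]
          new_ta <- c(t_l[[a]][a1], t_l[[b]][!b1])[oa]
          new_sb <- c(s_l[[b]][b1], s_l[[a]][!a1])[ob]
          new_tb <- c(t_l[[b]][b1], t_l[[a]][!a1])[ob]
          fr_l[[a]] <- fa[oa]; s_l[[a]] <- new_sa; t_l[[a]] <- new_ta
          fr_l[[b]] <- fb[ob]; s_l[[b]] <- new_sb; t_l[[b]] <- new_tb
          changed <- TRUE
        }
      }
    }
  }
  traces_long
}

#' Split traces at sustained transverse jumps
#'
#' A linked trace that hops to a different axon lane mid-stream (a chimera
#' of two objects, typically created when ridges blend during a crossing)
#' shows a sustained shift of its reconstructed transverse position. Each
#' trace is split at the change-point maximizing the between-segment
#' difference in mean `y_um` whenever that difference exceeds `y_jump_um`,
#' recursively; genuine direction changes along one axon leave `y_um`
#' unchanged and are never split.
#'
#' @param traces_long Long observation table carrying `y_um`.
#' @param y_jump_um Smallest sustained transverse shift treated as a chimera
#'   boundary (um).
#' @param min_seg Minimum segment length (frames) on either side of a split.
#' @return The long table with chimeric traces split into new `trace_id`s.
#' @export
split_traces_by_y <- function(traces_long, y_jump_um = 0.45, min_seg = 5) {
  if (nrow(traces_long) == 0 || !"y_um" %in% names(traces_long)) {
    return(traces_long)
  }
  next_id <- max(traces_long$trace_id) + 1L
  out <- split(traces_long, traces_long$trace_id)
  res <- list()
  while (length(out)) {
    ob <- out[[1]]
    out <- out[-1]
    ob <- ob[order(ob$frame), ]
    n <- nrow(ob)
    if (n < 2 * min_seg) {
      res[[length(res) + 1]] <- ob
      next
    }
    cs <- cumsum(ob$y_um)
    ks <- min_seg:(n - min_seg)
    d <- abs(cs[ks] / ks - (cs[n] - cs[ks]) / (n - ks))
    if (max(d) > y_jump_um) {
      k <- ks[which.max(d)]
      a <- ob[1:k, ]
      b <- ob[(k + 1):n, ]
      b$trace_id <- next_id
      next_id <- next_id + 1L
      out <- c(out, list(a, b))
    } else {
      res[[length(res) + 1]] <- ob
    }
  }
  dplyr::bind_rows(res)
}

#' Net velocity of a trace
#'
#' Net displacement over the observed span: `(s_last - s_first) /
#' (t_last - t_first)`, signed with anterograde positive. This matches
#' speed-over-the-imaging-period measurement and is robust to positional
#' jitter.
#'
#' @param t_s,s_um Observation times (s) and positions (um), or a data frame
#'   with those columns as first argument.
#' @return Signed velocity (um/s).
#' @examples
#' trace_velocity(c(0, 60), c(0, 6)) # +0.1 um/s
#' @export
trace_velocity <- function(t_s, s_um = NULL) {
  if (is.data.frame(t_s)) {
    s_um <- t_s$s_um
    t_s <- t_s$t_s
  }
  span <- t_s[length(t_s)] - t_s[1]
  if (span <= 0) abort("zero-duration trace")
  (s_um[length(s_um)] - s_um[1]) / span
}

#' Classify movement at the 0.1 um/s boundary
#'
#' Objects moving at 0.1 um/s **or faster** are moving (boundary inclusive):
#' anterograde when the signed velocity is positive, retrograde when
#' negative; otherwise stationary.
#'
#' @param v_um_s Signed net velocity (um/s); vectorized.
#' @param threshold Moving threshold (um/s), default 0.1.
#' @return Character vector in `stationary`, `anterograde`, `retrograde`.
#' @examples
#' classify_movement(c(0.1, -0.099, -0.78))
#' @export
classify_movement <- function(v_um_s, threshold = 0.1) {
  stopifnot(threshold > 0)
  moving <- abs(v_um_s) >= threshold - 1e-12
  ifelse(!moving, "stationary",
         ifelse(v_um_s > 0, "anterograde", "retrograde"))
}

#' Per-trace summary table
#'
#' Collapses a long observation table (one row per detection) to one row
#' per trace with observed span, net velocity and movement class.
#'
#' @param traces_long Tibble from [link_traces()].
#' @param threshold Moving threshold (um/s).
#' @param min_frames Traces observed fewer frames are dropped (kept in
#'   attribute `"n_dropped_short"`); classification needs a reliable span.
#' @return Tibble `trace_id`, `n_frames_observed`, `t_first`, `t_last`,
#'   `s_first`, `s_last`, `mean_intensity`, `net_velocity_um_s`,
#'   `movement_class`.
#' @export
traces_table <- function(traces_long, threshold = 0.1, min_frames = 5) {
  tt <- traces_long |>
    group_by(.data$trace_id) |>
    arrange(.data$frame, .by_group = TRUE) |>
    summarise(
      n_frames_observed = dplyr::n(),
      t_first = dplyr::first(.data$t_s), t_last = dplyr::last(.data$t_s),
      s_first = dplyr::first(.data$s_um), s_last = dplyr::last(.data$s_um),
      s_mean = mean(.data$s_um),
      mean_intensity = mean(.data$intensity),
      y_mean_um = if ("y_um" %in% names(traces_long))
        mean(.data$y_um) else NA_real_,
      off_abs_px = if ("off_px" %in% names(traces_long))
        mean(abs(.data$off_px)) else NA_real_,
      .groups = "drop"
    )
  n_short <- sum(tt$n_frames_observed < min_frames)
  tt <- tt |>
    filter(.data$n_frames_observed >= min_frames) |>
    mutate(
      net_velocity_um_s = (.data$s_last - .data$s_first) /
        (.data$t_last - .data$t_first),
      movement_class = classify_movement(.data$net_velocity_um_s, threshold)
    )
  attr(tt, "n_dropped_short") <- n_short
  tt
}

#' Deduplicate traces observed in several swaths
#'
#' A PSF-blurred object near a swath edge also leaves a (weaker) ridge in
#' the adjacent swath. Two traces are treated as one object when they
#' overlap in time for at least `min_overlap_frac` of the shorter trace,
#' their mean arclength separation is below `max_dist_um`, their net
#' velocities agree, and their reconstructed absolute transverse positions
#' (swath offset + cross-width argmax) coincide within `y_tol_um` — a
#' ghost reconstructs to its source's transverse position, while distinct
#' objects in adjacent swaths sit at least an axon spacing apart. Of each
#' duplicate pair the trace sampled nearer its own swath centre is kept
#' (the ghost's maximum is pinned at the band edge). Raw and deduplicated
#' stationary counts are reported in attributes, since large immotile
#' objects are the ones liable to multiple counting.
#'
#' @param trace_tbl Per-trace tibble from [traces_table()], with a `swath`
#'   column and a `traces_long` attribute or accompanying long table.
#' @param traces_long Long observation table with matching `trace_id`.
#' @param max_dist_um Largest mean |delta s| for a duplicate (um).
#' @param min_overlap_frac Minimum temporal overlap fraction.
#' @param y_tol_um Largest difference in reconstructed transverse position
#'   for a duplicate pair (um); used when both traces carry `y_mean_um`.
#' @param intensity_ratio Fallback rule when transverse positions are
#'   unavailable: pairs whose dimmer/brighter mean-intensity ratio exceeds
#'   this are kept as distinct objects.
#' @param max_dv_um_s Largest net-velocity difference for a duplicate pair
#'   (the same object must show the same motion in both swaths).
#' @return The deduplicated per-trace tibble, with attributes
#'   `"n_stationary_raw"` and `"n_stationary_dedup"`.
#' @export
dedup_traces <- function(trace_tbl, traces_long, max_dist_um = 0.6,
                         min_overlap_frac = 0.5, y_tol_um = 0.35,
                         intensity_ratio = 0.95, max_dv_um_s = 0.15) {
  if (nrow(trace_tbl) <= 1) {
    attr(trace_tbl, "n_stationary_raw") <-
      sum(trace_tbl$movement_class == "stationary")
    attr(trace_tbl, "n_stationary_dedup") <-
      sum(trace_tbl$movement_class == "stationary")
    return(trace_tbl)
  }
  pos_f <- split(traces_long$frame, traces_long$trace_id)
  pos_s <- split(traces_long$s_um, traces_long$trace_id)
  drop <- rep(FALSE, nrow(trace_tbl))
  have_y <- "y_mean_um" %in% names(trace_tbl) &&
    all(!is.na(trace_tbl$y_mean_um))
  # prefer traces sampled nearest their own swath centre (non-ghosts first)
  ord <- if (have_y) order(trace_tbl$off_abs_px, -trace_tbl$mean_intensity)
    else order(-trace_tbl$mean_intensity)
  for (a in seq_along(ord)) {
    i <- ord[a]
    if (drop[i]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      j <- ord[b]
      if (drop[j]) next
      # quick reject on span overlap
      if (trace_tbl$t_first[j] > trace_tbl$t_last[i] ||
          trace_tbl$t_last[j] < trace_tbl$t_first[i]) next
      # quick reject when the arclength ranges are far apart
      lo_i <- min(trace_tbl$s_first[i], trace_tbl$s_last[i])
      hi_i <- max(trace_tbl$s_first[i], trace_tbl$s_last[i])
      lo_j <- min(trace_tbl$s_first[j], trace_tbl$s_last[j])
      hi_j <- max(trace_tbl$s_first[j], trace_tbl$s_last[j])
      if (max(lo_i, lo_j) - min(hi_i, hi_j) > 2) next
      if (abs(trace_tbl$net_velocity_um_s[i] -
                trace_tbl$net_velocity_um_s[j]) > max_dv_um_s) next
      if (have_y) {
        if (abs(trace_tbl$y_mean_um[i] - trace_tbl$y_mean_um[j]) > y_tol_um)
          next
      } else if (trace_tbl$mean_intensity[j] >
                 intensity_ratio * trace_tbl$mean_intensity[i]) {
        next
      }
      fi <- pos_f[[as.character(trace_tbl$trace_id[i])]]
      fj <- pos_f[[as.character(trace_tbl$trace_id[j])]]
      common <- intersect(fi, fj)
      if (length(common) < min_overlap_frac * min(length(fi), length(fj)))
        next
      si <- pos_s[[as.character(trace_tbl$trace_id[i])]][match(common, fi)]
      sj <- pos_s[[as.character(trace_tbl$trace_id[j])]][match(common, fj)]
      if (mean(abs(si - sj)) > max_dist_um) next
      drop[j] <- TRUE
    }
  }
  out <- trace_tbl[!drop, ]
  attr(out, "n_stationary_raw") <-
    sum(trace_tbl$movement_class == "stationary")
  attr(out, "n_stationary_dedup") <-
    sum(out$movement_class == "stationary")
  out
}

#' Movement summary with per-animal aggregation
#'
#' Computes, per animal, the percentage of traces in each movement class
#' (summing to 100 exactly) and the mean unsigned speeds of the moving
#' classes, then averages across animals within each group
#' (mean +/- SEM). N is the number of animals, never the number of objects.
#'
#' @param trace_tbl Per-trace tibble (needs `movement_class`,
#'   `net_velocity_um_s`, an animal column and optionally group columns).
#' @param group_vars Character vector of grouping columns (e.g. genotype);
#'   may be empty.
#' @param animal_var Name of the animal id column.
#' @return A `movement_summary`: list of tibbles `per_animal` (one row per
#'   animal x class) and `group` (class means +/- SEM across animals, and
#'   mean anterograde/retrograde speeds).
#' @export
summarize_movement <- function(trace_tbl, group_vars = character(),
                               animal_var = "animal_id") {
  stopifnot(animal_var %in% names(trace_tbl))
  classes <- c("stationary", "anterograde", "retrograde")
  keys <- c(group_vars, animal_var)
  counts <- trace_tbl |>
    count(dplyr::across(dplyr::all_of(c(keys, "movement_class")))) |>
    tidyr::complete(tidyr::nesting(!!!rlang::syms(keys)),
                    movement_class = classes, fill = list(n = 0L)) |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup()
  speeds <- trace_tbl |>
    filter(.data$movement_class != "stationary") |>
    group_by(dplyr::across(dplyr::all_of(c(keys, "movement_class")))) |>
    summarise(mean_speed_um_s = mean(abs(.data$net_velocity_um_s)),
              .groups = "drop")
  per_animal <- dplyr::left_join(counts, speeds,
                                 by = c(keys, "movement_class"))

  empty_groups <- per_animal |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(total = sum(.data$n), .groups = "drop") |>
    filter(.data$total == 0)
  if (nrow(empty_groups) > 0) {
    warn(sprintf("%d animal(s) with zero traces omitted", nrow(empty_groups)))
    per_animal <- dplyr::anti_join(per_animal, empty_groups, by = keys)
  }

  group <- per_animal |>
    group_by(dplyr::across(dplyr::all_of(c(group_vars, "movement_class")))) |>
    summarise(
      n_animals = dplyr::n_distinct(.data[[animal_var]]),
      mean_pct = mean(.data$pct),
      sem_pct = sd(.data$pct) / sqrt(dplyr::n()),
      mean_speed_um_s = mean(.data$mean_speed_um_s, na.rm = TRUE),
      sem_speed_um_s = sd(.data$mean_speed_um_s, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$mean_speed_um_s))),
      .groups = "drop"
    ) |>
    mutate(mean_speed_um_s = ifelse(.data$movement_class == "stationary",
                                    NA_real_, .data$mean_speed_um_s))
  structure(list(per_animal = per_animal, group = group,
                 group_vars = group_vars, animal_var = animal_var),
            class = "movement_summary")
}

#' @export
print.movement_summary <- function(x, ...) {
  cat("<movement_summary>\n")
  print(x$group)
  invisible(x)
}

#' Two-channel trace co-localization, stratified by movement class
#'
#' Marks a channel-A trace as co-localized when some channel-B trace stays
#' within `max_dist_um` of it for at least `min_overlap_frac` of its
#' observed frames, with one-to-one greedy assignment by mean distance
#' (ties broken toward longer overlap). The summary is stratified by the
#' A-trace movement class, mirroring co-localized versus solo pools.
#'
#' @param traces_a,traces_b Per-trace tibbles ([traces_table()]) for the two
#'   channels, with matching long tables.
#' @param long_a,long_b Long observation tables for the two channels.
#' @param max_dist_um Co-localization distance criterion (um).
#' @param min_overlap_frac Minimum fraction of A's observed frames within
#'   distance.
#' @return A `coloc_summary`: list with `traces` (A-table plus
#'   `colocalized`), `by_class` (per-class co-localized/solo counts and
#'   fractions) and `pools` (class distribution within the co-localized and
#'   solo pools).
#' @export
match_traces <- function(traces_a, long_a, traces_b, long_b,
                         max_dist_um = 0.5, min_overlap_frac = 0.5) {
  classes <- c("stationary", "anterograde", "retrograde")
  na <- nrow(traces_a)
  coloc <- rep(FALSE, na)
  if (na > 0 && nrow(traces_b) > 0) {
    fa <- split(long_a$frame, long_a$trace_id)
    sa <- split(long_a$s_um, long_a$trace_id)
    fb <- split(long_b$frame, long_b$trace_id)
    sb <- split(long_b$s_um, long_b$trace_id)
    cand <- list()
    for (i in seq_len(na)) {
      fi <- fa[[as.character(traces_a$trace_id[i])]]
      si <- sa[[as.character(traces_a$trace_id[i])]]
      for (j in seq_len(nrow(traces_b))) {
        if (traces_b$t_first[j] > traces_a$t_last[i] ||
            traces_b$t_last[j] < traces_a$t_first[i]) next
        fj <- fb[[as.character(traces_b$trace_id[j])]]
        common <- intersect(fi, fj)
        if (length(common) == 0) next
        d <- abs(si[match(common, fi)] -
                   sb[[as.character(traces_b$trace_id[j])]][match(common, fj)])
        n_close <- sum(d <= max_dist_um)
        if (n_close < min_overlap_frac * length(fi)) next
        cand[[length(cand) + 1]] <- c(i = i, j = j, mean_d = mean(d),
                                      overlap = n_close)
      }
    }
    if (length(cand)) {
      cd <- do.call(rbind, cand)
      cd <- cd[order(cd[, "mean_d"], -cd[, "overlap"]), , drop = FALSE]
      used_b <- rep(FALSE, nrow(traces_b))
      for (r in seq_len(nrow(cd))) {
        i <- cd[r, "i"]; j <- cd[r, "j"]
        if (coloc[i] || used_b[j]) next
        coloc[i] <- TRUE
        used_b[j] <- TRUE
      }
    }
  }
  traces <- mutate(traces_a, colocalized = coloc)
  by_class <- traces |>
    mutate(movement_class = factor(.data$movement_class, classes)) |>
    group_by(.data$movement_class, .drop = FALSE) |>
    summarise(n_coloc = sum(.data$colocalized),
              n_solo = sum(!.data$colocalized), .groups = "drop") |>
    mutate(n_total = .data$n_coloc + .data$n_solo,
           frac_coloc = ifelse(.data$n_total > 0,
                               .data$n_coloc / .data$n_total, NA_real_),
           movement_class = as.character(.data$movement_class))
  pools <- traces |>
    mutate(pool = ifelse(.data$colocalized, "colocalized", "solo"),
           movement_class = factor(.data$movement_class, classes)) |>
    group_by(.data$pool, .data$movement_class, .drop = FALSE) |>
    summarise(n = dplyr::n(), .groups = "drop_last") |>
    mutate(pct = ifelse(sum(.data$n) > 0, 100 * .data$n / sum(.data$n),
                        NA_real_)) |>
    ungroup() |>
    mutate(movement_class = as.character(.data$movement_class))
  structure(list(traces = traces, by_class = by_class, pools = pools,
                 max_dist_um = max_dist_um,
                 min_overlap_frac = min_overlap_frac),
            class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  cat("<coloc_summary>\n")
  print(x$by_class)
  invisible(x)
}
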