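# Map-matching of individual tracks onto the reference course and the
# lap/segment speed matrix derived from the matched traces.

new_projected_trace <- function(skier_id, distance, time, lap_length, n_laps,
                                source = "gnss", flagged_share = 0) {
  structure(list(skier_id = skier_id, distance = distance, time = time,
                 lap = pmin(floor(distance / lap_length) + 1L, n_laps),
                 lap_length_m = lap_length, n_laps = n_laps,
                 source = source, flagged_share = flagged_share),
            class = "projected_trace")
}

#' @export
print.projected_trace <- function(x, ...) {
  cat(sprintf("<projected_trace> %s (%s): %.0f m in %.1f s\n", x$skier_id,
              x$source, max(x$distance), max(x$time, na.rm = TRUE)))
  invisible(x)
}

# Arrival time of a trace at arbitrary course distances.
trace_time_at <- function(trace, d) {
  approx(trace$distance, trace$time, xout = d, ties = "ordered")$y
}

#' Project a GNSS track onto the reference course
#'
#' Fixes are matched to the course polyline by 2D nearest point under a
#' monotone non-decreasing distance constraint with bounded per-fix advance;
#' arrival times at every integer metre are then linearly interpolated from
#' the matched (distance, time) pairs. A reversed or largely off-course track
#' fails the coverage check rather than being silently projected.
#'
#' @param track a [gnss_track()].
#' @param course a `race_course`.
#' @param max_advance_m maximum course-distance advance per fix, metres.
#' @param corridor_m fixes further than this from the course are flagged.
#' @param init_window_m course window searched for the first fix, metres.
#' @param min_coverage minimum fraction of the race distance the matched
#'   track must span.
#' @return A `projected_trace`: monotone arrival time per 1 m course node.
#' @export
project_track <- function(track, course, max_advance_m = 6, corridor_m = 15,
                          init_window_m = 60, min_coverage = 0.9) {
  if (track_quality(track) == "missing") stopf("track has no fixes")
  total <- course$lap_length_m * course$n_laps
  m <- match_track_cpp(track$x, track$y, course$x, course$y,
                       max_advance = max_advance_m, corridor = corridor_m,
                       init_window = init_window_m)
  span <- max(m$distance) - min(m$distance)
  if (span < min_coverage * total)
    stopf("incomplete race: track '%s' covers %.0f of %.0f m",
          track_id(track), span, total)
  d <- 0:total
  t_at <- approx(m$distance, track$time_s, xout = d, ties = min, rule = 2)$y
  t_at <- cummax(t_at) + (d - d[1]) * 1e-9 # strictly increasing
  new_projected_trace(track_id(track), d, t_at, course$lap_length_m,
                      course$n_laps, source = "gnss",
                      flagged_share = mean(m$flagged))
}

#' Project a collection of tracks
#'
#' @param tracks a `gnss_tracks` collection.
#' @param course a `race_course`.
#' @param include_degraded project degraded tracks too? They are projected
#'   either way, but carry their quality in `$source` so speed analyses can
#'   drop them; with `FALSE` (default) they are omitted entirely.
#' @param ... passed to [project_track()].
#' @return A named list of `projected_trace`, class `projected_traces`.
#' @export
project_tracks <- function(tracks, course, include_degraded = FALSE, ...) {
  use <- Filter(function(tr) {
    q <- track_quality(tr)
    q == "ok" || (include_degraded && q == "degraded")
  }, tracks)
  out <- lapply(use, project_track, course = course, ...)
  names(out) <- vapply(out, function(tr) tr$skier_id, character(1))
  structure(out, class = "projected_traces")
}

#' Lap and segment times and speeds for one trace
#'
#' Per lap and terrain segment: time between arrival at the segment ends and
#' the resulting speed. On lap 1 the segments in `lap1_excluded` are dropped
#' (the reduced Lap-1 course).
#'
#' @param trace a `projected_trace`.
#' @param segmentation a `terrain_segments` data frame.
#' @param lap1_excluded segment ids excluded from lap 1.
#' @return Data frame `skier_id`, `lap`, `segment_id`, `label`, `length_m`,
#'   `time_s`, `speed_ms`.
#' @export
segment_times <- function(trace, segmentation, lap1_excluded = character()) {
  lap <- attr(segmentation, "lap_length_m") %||% trace$lap_length_m
  n_laps <- trace$n_laps
  rows <- lapply(seq_len(n_laps), function(k) {
    seg <- segmentation
    if (k == 1 && length(lap1_excluded))
      seg <- seg[!(seg$segment_id %in% lap1_excluded), , drop = FALSE]
    off <- (k - 1) * lap
    t0 <- trace_time_at(trace, off + seg$start_m)
    t1 <- trace_time_at(trace, off + seg$end_m)
    dt <- t1 - t0
    if (any(!is.na(dt) & dt <= 0))
      stopf("non-positive segment time for '%s' lap %d (projection fault)",
            trace$skier_id, k)
    data.frame(skier_id = trace$skier_id, lap = k,
               segment_id = seg$segment_id, label = seg$label,
               length_m = seg$length_m, time_s = dt,
               speed_ms = seg$length_m / dt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Skier x lap x segment speed matrix
#'
#' @param traces a `projected_traces` list.
#' @param segmentation a `terrain_segments` data frame.
#' @param lap1_excluded segment ids excluded from lap 1 (defaults to the
#'   course's, if recorded on `segmentation`).
#' @param exclude_synthetic drop traces whose `$source` is `"synthetic"`
#'   (split-time reconstructions are kept out of speed statistics).
#' @return A `speed_matrix` data frame (long form).
#' @export
speed_matrix <- function(traces, segmentation, lap1_excluded = character(),
                         exclude_synthetic = TRUE) {
  use <- Filter(function(tr) !(exclude_synthetic && tr$source == "synthetic"),
                traces)
  out <- do.call(rbind, lapply(use, segment_times, segmentation = segmentation,
                               lap1_excluded = lap1_excluded))
  rownames(out) <- NULL
  structure(out, lap1_excluded = lap1_excluded,
            class = c("speed_matrix", "data.frame"))
}

#' Aggregate a speed matrix over laps, terrain or segment subsets
#'
#' @param sm a [speed_matrix()].
#' @param by `"lap"` (full-lap speed), `"terrain"` (per lap and terrain
#'   label) or `"segment"` (identity).
#' @param segments optional segment ids to restrict to (e.g. the Lap-1
#'   comparable set).
#' @return Data frame with `skier_id`, `lap`, (`label`,) `length_m`,
#'   `time_s`, `speed_ms`.
#' @export
aggregate_speeds <- function(sm, by = c("lap", "terrain", "segment"),
                             segments = NULL) {
  by <- match.arg(by)
  if (!is.null(segments)) sm <- sm[sm$segment_id %in% segments, , drop = FALSE]
  if (by == "segment") return(as.data.frame(sm))
  keys <- if (by == "lap") list(skier_id = sm$skier_id, lap = sm$lap)
          else list(skier_id = sm$skier_id, lap = sm$lap, label = sm$label)
  agg <- aggregate(cbind(length_m = sm$length_m, time_s = sm$time_s), keys, sum)
  agg$speed_ms <- agg$length_m / agg$time_s
  agg[order(agg$skier_id, agg$lap), , drop = FALSE]
}

#' Validate projected traces against the official split table
#'
#' Offsets are trace arrival time minus official split time, pooled over
#' skiers and checkpoints.
#'
#' @param traces a `projected_traces` list.
#' @param splits a `split_table`.
#' @return List with `offsets` (long data frame), `per_checkpoint` summary,
#'   `mean_offset_s` and `sd_offset_s`.
#' @export
validate_against_splits <- function(traces, splits) {
  cps <- splits$checkpoints
  total <- max(vapply(traces, function(tr) max(tr$distance), numeric(1)))
  if (any(cps$distance_m > total))
    stopf("checkpoint distance %.0f m outside course (%.0f m)",
          max(cps$distance_m), total)
  rows <- lapply(traces, function(tr) {
    off <- splits$entries[splits$entries$skier_id == tr$skier_id, , drop = FALSE]
    if (nrow(off) == 0) return(NULL)
    dmap <- cps$distance_m[match(off$checkpoint_id, cps$checkpoint_id)]
    data.frame(skier_id = tr$skier_id, checkpoint_id = off$checkpoint_id,
               distance_m = dmap,
               offset_s = trace_time_at(tr, dmap) - off$time_s)
  })
  offsets <- do.call(rbind, rows)
  rownames(offsets) <- NULL
  per_cp <- aggregate(offset_s ~ checkpoint_id + distance_m, offsets,
                      function(v) c(mean = mean(v), sd = sd(v)))
  per_cp <- do.call(data.frame, per_cp)
  names(per_cp) <- c("checkpoint_id", "distance_m", "mean_offset_s",
                     "sd_offset_s")
  per_cp <- per_cp[order(per_cp$distance_m), ]
  list(offsets = offsets, per_checkpoint = per_cp,
       mean_offset_s = mean(offsets$offset_s),
       sd_offset_s = sd(offsets$offset_s))
}
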