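# Reference-course construction from raw tracks and terrain segmentation.

#' Build the 1 m reference course from GNSS tracks
#'
#' One clean track seeds the arc-length parameterisation: its smoothed path
#' is cut at the loop closure to give a provisional lap polyline. Every fix
#' of every track and lap is then map-matched onto that polyline (monotone,
#' corridor-bounded) and pooled into 1 m bins of lap distance; the robust
#' (median) bin positions and elevations form the course, which is finally
#' re-parameterised by its own arc length so node spacing is exactly 1 m.
#'
#' @param tracks a `gnss_tracks` collection (or list of [gnss_track()]).
#' @param n_laps number of laps skied.
#' @param smooth_window_s seed-path smoothing window, seconds.
#' @param corridor_m fixes further than this from the course are flagged and
#'   excluded from the bin medians.
#' @param reparam_window_m circular smoothing window applied to the median
#'   polyline before re-measuring its arc length, metres.
#' @param min_coverage minimum fraction of 1 m bins that must receive at
#'   least one fix.
#' @return A `race_course` (source `"estimated"`), without terrain segments
#'   (see [classify_terrain()]).
#' @export
build_reference_course <- function(tracks, n_laps, smooth_window_s = 2,
                                   corridor_m = 15, reparam_window_m = 15,
                                   min_coverage = 0.5) {
  ok <- Filter(function(tr) track_quality(tr) == "ok", tracks)
  if (length(ok) == 0) stopf("no track with quality 'ok'")
  seed <- ok[[1]]
  lapline <- seed_lap_polyline(seed, n_laps, smooth_window_s)
  L0 <- nrow(lapline) # provisional lap length, 1 m spacing
  # tiled matching polyline: the same lap copy for every lap, so lap binning
  # is exact by construction
  nx <- rep(lapline$x, n_laps)
  ny <- rep(lapline$y, n_laps)

  pool <- lapply(ok, function(tr) {
    m <- match_track_cpp(tr$x, tr$y, nx, ny, max_advance = 6,
                         corridor = corridor_m, init_window = 60)
    keep <- !m$flagged
    data.table::data.table(bin = lap_bin_cpp(m$distance[keep], L0),
                           x = tr$x[keep], y = tr$y[keep], e = tr$ele_m[keep])
  })
  dt <- data.table::rbindlist(pool)
  bin <- NULL; e <- NULL # NSE guards
  med <- dt[, list(x = median(x), y = median(y), e = median(e)), by = bin]
  coverage <- nrow(med) / L0
  if (coverage < min_coverage)
    stopf("insufficient coverage: only %.0f%% of 1 m bins populated",
          100 * coverage)
  full <- data.frame(bin = 0:(L0 - 1))
  med <- merge(full, as.data.frame(med), by = "bin", all.x = TRUE)
  for (col in c("x", "y", "e")) {
    v <- med[[col]]
    if (anyNA(v)) { # circular linear interpolation of empty bins
      idx <- which(!is.na(v))
      v <- approx(c(idx - L0, idx, idx + L0), rep(v[idx], 3),
                  xout = seq_len(L0))$y
      med[[col]] <- v
    }
  }

  # re-parameterise by arc length of the (lightly smoothed) median loop
  xs <- moving_average(med$x, reparam_window_m, circular = TRUE)
  ys <- moving_average(med$y, reparam_window_m, circular = TRUE)
  es <- moving_average(med$e, reparam_window_m, circular = TRUE)
  dx <- diff(c(xs, xs[1])); dy <- diff(c(ys, ys[1]))
  steps <- sqrt(dx^2 + dy^2)
  cum <- c(0, cumsum(steps))           # length L0 + 1, closed
  L_loop <- cum[L0 + 1]
  L <- max(2L, round(L_loop))
  s_new <- seq_len(L) - 1L
  lap_x <- approx(cum, c(xs, xs[1]), xout = s_new)$y
  lap_y <- approx(cum, c(ys, ys[1]), xout = s_new)$y
  lap_e <- approx(cum, c(es, es[1]), xout = s_new)$y

  total <- L * n_laps
  d <- 0:total
  idx <- (d %% L) + 1
  new_race_course(d, lap_x[idx], lap_y[idx], lap_e[idx],
                  lap_length_m = L, n_laps = n_laps, source = "estimated")
}

# Smooth and downsample the seed track, cut at loop closure, resample at 1 m.
seed_lap_polyline <- function(seed, n_laps, smooth_window_s) {
  md <- median(diff(seed$time_s))
  w <- max(1L, round(smooth_window_s / md))
  xs <- moving_average(seed$x, w)
  ys <- moving_average(seed$y, w)
  # downsample to ~10 m spacing before measuring arc length so that residual
  # position noise does not inflate it
  cum0 <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  keep <- !duplicated(floor(cum0 / 10))
  keep[length(keep)] <- TRUE
  xs <- xs[keep]; ys <- ys[keep]
  cum <- c(0, cumsum(sqrt(diff(xs)^2 + diff(ys)^2)))
  L_est <- cum[length(cum)] / n_laps
  # refine the lap length by loop closure: where does the path come back
  # closest to its start, near the provisional lap length?
  cand <- which(cum > 0.9 * L_est & cum < 1.1 * L_est)
  if (length(cand) == 0) stopf("seed track too short to close a lap")
  d2 <- (xs[cand] - xs[1])^2 + (ys[cand] - ys[1])^2
  j <- cand[which.min(d2)]
  # continuous refinement: project the start point onto the polyline
  # segments adjacent to the best candidate vertex
  L_seed <- cum[j]
  best <- d2[which.min(d2)]
  for (a in c(j - 1L, j)) {
    if (a < 1 || a + 1 > length(xs)) next
    dx <- xs[a + 1] - xs[a]; dy <- ys[a + 1] - ys[a]
    l2 <- dx^2 + dy^2
    if (l2 < 1e-12) next
    tt <- ((xs[1] - xs[a]) * dx + (ys[1] - ys[a]) * dy) / l2
    tt <- min(max(tt, 0), 1)
    dd <- (xs[a] + tt * dx - xs[1])^2 + (ys[a] + tt * dy - ys[1])^2
    if (dd < best) {
      best <- dd
      L_seed <- cum[a] + tt * (cum[a + 1] - cum[a])
    }
  }
  n <- max(2L, floor(L_seed))
  s <- seq_len(n) - 1L
  data.frame(x = approx(cum, xs, xout = s)$y,
             y = approx(cum, ys, xout = s)$y)
}

#' Segment a course's elevation profile into terrain
#'
#' The lap elevation profile is smoothed with a centred circular moving
#' average, its gradient classified against uphill/downhill thresholds, and
#' contiguous runs shorter than `min_segment_length_m` merged into the
#' neighbour whose mean gradient is closer. Segments tile the lap exactly.
#'
#' @param course a `race_course`.
#' @param smooth_window_m smoothing window, metres.
#' @param uphill_threshold_pct gradients above this are uphill (%).
#' @param downhill_threshold_pct gradients below this are downhill (%).
#' @param min_segment_length_m shorter runs are merged into a neighbour.
#' @return A `terrain_segments` data frame (`segment_id`, `start_m`, `end_m`,
#'   `length_m`, `label`, `mean_gradient_pct`, `climb_m`, `merged` flag).
#' @export
classify_terrain <- function(course, smooth_window_m = 30,
                             uphill_threshold_pct = 2,
                             downhill_threshold_pct = -2,
                             min_segment_length_m = 50) {
  lap <- course$lap_length_m
  if (lap <= smooth_window_m) stopf("course shorter than smoothing window")
  elev <- course$elevation[seq_len(lap)] # bins 0..lap-1, one lap
  es <- moving_average(elev, smooth_window_m, circular = TRUE)
  # central-difference gradient, circular
  g <- 100 * (es[c(2:lap, 1)] - es[c(lap, 1:(lap - 1))]) / 2
  lab <- ifelse(g > uphill_threshold_pct, "uphill",
                ifelse(g < downhill_threshold_pct, "downhill", "flat"))

  r <- rle(lab)
  runs <- data.frame(label = r$values, len = r$lengths)
  runs$merged <- FALSE
  runs$grad <- run_gradients(runs$len, elev, lap)

  # merge short runs into the neighbour with closer mean gradient
  repeat {
    if (nrow(runs) <= 1) break
    short <- which(runs$len < min_segment_length_m)
    if (length(short) == 0) break
    i <- short[which.min(runs$len[short])]
    nb <- c(if (i > 1) i - 1L, if (i < nrow(runs)) i + 1L)
    j <- nb[which.min(abs(runs$grad[nb] - runs$grad[i]))]
    absorbed_label <- runs$label[j] # short run is absorbed by the neighbour
    k <- sort(c(i, j))
    runs$len[k[1]] <- runs$len[k[1]] + runs$len[k[2]]
    runs$label[k[1]] <- absorbed_label
    runs$merged[k[1]] <- TRUE
    runs <- runs[-k[2], , drop = FALSE]
    runs$grad <- run_gradients(runs$len, elev, lap)
    # collapse neighbours that ended up with the same label
    r2 <- rle(runs$label)
    if (any(r2$lengths > 1)) {
      grp <- rep(seq_along(r2$lengths), r2$lengths)
      runs <- data.frame(label = r2$values,
                         len = as.vector(tapply(runs$len, grp, sum)),
                         merged = as.vector(tapply(runs$merged, grp, any)))
      runs$grad <- run_gradients(runs$len, elev, lap)
    }
  }

  ends <- cumsum(runs$len)
  starts <- c(0, ends[-length(ends)])
  elev_c <- c(elev, elev[1]) # elevation at 0..lap
  climb <- elev_c[pmin(ends, lap) + 1] - elev_c[starts + 1]
  out <- data.frame(segment_id = paste0("S", seq_len(nrow(runs))),
                    start_m = starts, end_m = ends, length_m = runs$len,
                    label = runs$label,
                    mean_gradient_pct = 100 * climb / runs$len,
                    climb_m = climb, merged = runs$merged,
                    stringsAsFactors = FALSE)
  structure(out, lap_length_m = lap,
            class = c("terrain_segments", "data.frame"))
}

run_gradients <- function(lens, elev, lap) {
  ends <- cumsum(lens)
  starts <- c(0, ends[-length(ends)])
  elev_c <- c(elev, elev[1])
  100 * (elev_c[pmin(ends, lap) + 1] - elev_c[starts + 1]) / lens
}

#' Distance fractions of uphill, flat and downhill terrain
#'
#' @param segmentation a `terrain_segments` data frame.
#' @return Named numeric: percentage of lap distance per label (uphill, flat,
#'   downhill); sums to 100.
#' @export
terrain_fractions <- function(segmentation) {
  tot <- sum(segmentation$length_m)
  f <- vapply(c("uphill", "flat", "downhill"), function(lb) {
    100 * sum(segmentation$length_m[segmentation$label == lb]) / tot
  }, numeric(1))
  f
}
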