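# Synthetic race generation: course geometry, agent-based race dynamics and
# ground truth for validating the analysis pipeline.

# Speed model coefficients: flat cruise speed is scaled by a gradient factor
# 1/(1 + UPHILL_DRAG * g) uphill and min(1 + DOWNHILL_BOOST * |g|,
# DOWNHILL_CAP) downhill (g in %). At a 7 m/s cruise this gives ~3.6 m/s on
# an 8 % climb and ~11.6 m/s on a -12 % descent, in the range reported for
# elite skating races.
UPHILL_DRAG <- 0.115
DOWNHILL_BOOST <- 0.055
DOWNHILL_CAP <- 1.8
FLAT_BAND <- 0.5  # |gradient| below this (in %) is treated as flat

terrain_speed_factor <- function(gradient_pct, uphill_factor = 1,
                                 downhill_factor = 1) {
  ifelse(gradient_pct > FLAT_BAND,
         uphill_factor / (1 + UPHILL_DRAG * gradient_pct),
         ifelse(gradient_pct < -FLAT_BAND,
                downhill_factor * pmin(1 + DOWNHILL_BOOST * (-gradient_pct),
                                       DOWNHILL_CAP),
                1))
}

new_race_course <- function(distance, x, y, elevation, lap_length_m, n_laps,
                            lap1_excluded = character(),
                            checkpoints = NULL, segments = NULL,
                            source = "synthetic") {
  structure(list(distance = distance, x = x, y = y, elevation = elevation,
                 lap_length_m = lap_length_m, n_laps = n_laps,
                 lap_boundaries = seq(0, lap_length_m * n_laps,
                                      by = lap_length_m),
                 lap1_excluded = lap1_excluded,
                 checkpoints = checkpoints, segments = segments,
                 source = source),
            class = "race_course")
}

#' @export
print.race_course <- function(x, ...) {
  cat(sprintf("<race_course> %d laps x %.0f m (%s), %d nodes at 1 m\n",
              x$n_laps, x$lap_length_m, x$source, length(x$distance)))
  if (!is.null(x$segments))
    cat(sprintf("  %d terrain segments (%s)\n", nrow(x$segments),
                paste(table(x$segments$label)[c("uphill", "flat", "downhill")],
                      c("uphill", "flat", "downhill"), collapse = ", ")))
  invisible(x)
}

# Per-metre elevation profile of one lap (length lap+1) from a segment plan,
# plus optional smooth periodic noise (closed loop preserved).
lap_elevation_profile <- function(plan, lap_length, noise_amp = 0, seed = 1) {
  bounds <- c(0, cumsum(plan$length_m))
  elev_at <- c(0, cumsum(plan$climb_m))
  d <- 0:lap_length
  elev <- approx(bounds, elev_at, xout = d)$y
  if (noise_amp > 0) {
    ph <- with_seed(seed, runif(3, 0, 2 * pi))
    w <- 2 * pi * d / lap_length
    elev <- elev + noise_amp * (0.55 * sin(2 * w + ph[1]) +
                                0.30 * sin(5 * w + ph[2]) +
                                0.15 * sin(9 * w + ph[3]))
  }
  elev
}

# True terrain segmentation implied by a segment plan.
plan_segments <- function(plan, lap_length) {
  bounds <- c(0, cumsum(plan$length_m))
  structure(data.frame(segment_id = plan$segment_id,
                       start_m = bounds[-length(bounds)],
                       end_m = bounds[-1],
                       length_m = plan$length_m,
                       label = plan$label,
                       mean_gradient_pct = plan$gradient_pct,
                       climb_m = plan$climb_m,
                       stringsAsFactors = FALSE),
            lap_length_m = lap_length,
            class = c("terrain_segments", "data.frame"))
}

#' Generate a synthetic reference course
#'
#' Lays the lap out as a closed loop (a circle of the right circumference) in
#' a local planar frame with one node per metre of course distance, with
#' piecewise-linear elevation from the segment plan plus a small smooth
#' periodic undulation (amplitude <= 0.5 m). Timing checkpoints are spread
#' evenly over the race distance.
#'
#' @param spec a [course_spec()].
#' @param seed RNG seed for the elevation undulation.
#' @param noise_amp amplitude of the elevation undulation, metres.
#' @return A `race_course` whose `$segments` holds the ground-truth
#'   [plan_segments()] terrain segmentation and whose `$checkpoints` holds
#'   the checkpoint distances.
#' @export
generate_course <- function(spec, seed = 1, noise_amp = 0.45) {
  lap <- spec$lap_length_m
  total <- lap * spec$n_laps
  d <- 0:total
  theta <- 2 * pi * (d %% lap) / lap
  R <- lap / (2 * pi)
  x <- R * sin(theta)
  y <- R * (1 - cos(theta))
  lap_elev <- lap_elevation_profile(spec$segment_plan, lap, noise_amp, seed)
  elev <- lap_elev[(d %% lap) + 1]
  ncp <- spec$n_checkpoints
  cps <- data.frame(checkpoint_id = sprintf("cp%02d", seq_len(ncp)),
                    distance_m = round(seq_len(ncp) * total / ncp))
  new_race_course(d, x, y, elev, lap, spec$n_laps,
                  lap1_excluded = spec$lap1_excluded_segments,
                  checkpoints = cps,
                  segments = plan_segments(spec$segment_plan, lap),
                  source = "synthetic")
}

# Interpolate planar coordinates and elevation of the course at arbitrary
# course distances.
course_point <- function(course, d) {
  list(x = approx(course$distance, course$x, xout = d, rule = 2)$y,
       y = approx(course$distance, course$y, xout = d, rule = 2)$y,
       elevation = approx(course$distance, course$elevation, xout = d,
                          rule = 2)$y)
}

#' Simulate a mass-start race
#'
#' Time-stepped agent simulation at `config$dt_s` resolution. Each skier's
#' speed is their terrain- and fatigue-adjusted natural pace, modified by
#' pack behaviour: a follow reserve to close on the skier ahead, a drafting
#' bonus when within `drafting_window_s`, backward-propagating deceleration
#' waves at uphill entries (the accordion effect, with per-position lag and
#' linearly growing amplitude), rare incidents for skiers far back in the
#' field, and a no-overtaking congestion zone after the start. Emitted fixes
#' carry Gaussian GNSS noise.
#'
#' @param course a synthetic `race_course` from [generate_course()] (its
#'   segment plan drives gradients).
#' @param skiers a `skier_specs` data frame from [make_skiers()].
#' @param config a [sim_config()].
#' @return A list of class `ski_race_sim` with `tracks` (GNSS tracks),
#'   `splits` (official split table), `ranks` (start order = seeding,
#'   final ranks from finish times) and `truth` (ground truth: split and
#'   arrival times, per-lap/segment times, pack partition, accordion event
#'   counts, incidents, finish times).
#' @export
simulate_race <- function(course, skiers, config = sim_config()) {
  stopifnot(inherits(course, "race_course"), nrow(skiers) >= 2)
  if (is.null(course$segments))
    stopf("simulate_race needs a course with ground-truth segments")
  with_seed(config$seed, simulate_race_impl(course, skiers, config))
}

simulate_race_impl <- function(course, skiers, config) {
  lap <- course$lap_length_m
  n_laps <- course$n_laps
  total <- lap * n_laps
  dt <- config$dt_s
  n <- nrow(skiers)
  seg <- course$segments

  # per-metre gradient of one lap (piecewise constant per segment)
  grad <- rep(seg$mean_gradient_pct, times = seg$length_m)

  ability <- skiers$ability
  uf <- skiers$uphill_factor
  df_ <- skiers$downhill_factor
  fat <- skiers$fatigue_rate
  fgain <- skiers$follow_gain

  # scripted permanent slow-downs (used to script pack splits)
  sc_at <- rep(Inf, n)
  sc_f <- rep(1, n)
  for (drop in config$scripted_drops %||% list()) {
    idx <- match(drop$skier_ids, skiers$skier_id)
    sc_at[idx] <- drop$at_m
    sc_f[idx] <- drop$factor
  }

  # accordion trigger distances: every uphill-segment entry on every lap
  up_starts <- seg$start_m[seg$label == "uphill"]
  triggers <- sort(as.vector(outer(up_starts, lap * (0:(n_laps - 1)), "+")))
  amp <- config$accordion$amplitude
  acc_lag <- config$accordion$propagation_lag_s
  acc_dur <- config$accordion$duration_s %||% 2

  pos <- -(skiers$start_position - 1) * config$start_spacing_m # start grid
  vprev <- rep(0, n)
  finished <- rep(FALSE, n)
  finish_time <- rep(NA_real_, n)
  ev_start <- rep(Inf, n); ev_amp <- rep(0, n)      # accordion events
  inc_until <- rep(-Inf, n)                          # incident events
  acc_count <- integer(n)
  incidents <- list()
  next_trigger <- 1L
  next_lapx <- rep(1L, n)  # next lap boundary index each skier will cross

  cap <- 20000L
  posm <- matrix(NA_real_, cap, n)
  step <- 0L
  t <- 0
  posm[1, ] <- pos

  while (!all(finished)) {
    lapno <- pmin(floor(pmax(pos, 0) / lap) + 1, n_laps)
    gi <- ifelse(pos < 0, 0, grad[(floor(pmin(pos, total - 0.5)) %% lap) + 1])
    f_t <- terrain_speed_factor(gi, uf, df_)
    ev_mult <- ifelse(t >= ev_start & t < ev_start + acc_dur, 1 - ev_amp, 1)
    ev_mult[t < inc_until] <- ev_mult[t < inc_until] * 0.3
    v_nat <- ability * f_t * pmax(1 - fat * (lapno - 1), 0.5) *
      ifelse(pos >= sc_at, sc_f, 1) * ev_mult

    ord <- order(-pos, skiers$start_position)
    rk <- integer(n); rk[ord] <- seq_len(n)
    ahead <- rep(NA_integer_, n)
    ahead[ord[-1]] <- ord[-n]
    gap_t <- rep(Inf, n)
    has_ahead <- !is.na(ahead) & !finished
    gap_t[has_ahead] <- (pos[ahead[has_ahead]] - pos[has_ahead]) /
      pmax(v_nat[has_ahead], 0.5)

    v <- v_nat
    can <- v_nat * (1 + fgain)
    closing <- has_ahead & gap_t < config$follow_window_s & gap_t > 0.4
    v[closing] <- can[closing]
    locked <- has_ahead & gap_t <= 0.4
    v[locked] <- pmin(can[locked], pmax(vprev[ahead[locked]], v_nat[locked]))
    drafting <- has_ahead & gap_t < config$drafting_window_s
    v[drafting] <- v[drafting] * (1 + config$drafting_saving)
    v <- pmax(v, 0.3)
    v[finished] <- 0

    new_pos <- pos + v * dt

    # congestion zone: no overtaking near the start
    if (any(pos < config$congestion_zone_m & !finished)) {
      for (k in 2:n) {
        i <- ord[k]; j <- ord[k - 1]
        if (!finished[i] && pos[i] < config$congestion_zone_m &&
            new_pos[i] > new_pos[j] - 1.2)
          new_pos[i] <- max(pos[i], new_pos[j] - 1.2)
      }
    }

    # accordion: leader crossing an uphill entry schedules a braking wave
    lead_new <- max(new_pos)
    while (next_trigger <= length(triggers) &&
           lead_new >= triggers[next_trigger]) {
      if (amp > 0) {
        live <- !finished & rk > 1
        ev_start[live] <- t + (rk[live] - 1) * acc_lag
        ev_amp[live] <- pmin(0.5, amp * (rk[live] - 1))
        acc_count[live] <- acc_count[live] + 1L
      }
      next_trigger <- next_trigger + 1L
    }

    # incidents at lap crossings for skiers far back in the field
    if (config$incident_rate > 0) {
      for (i in which(!finished)) {
        b <- next_lapx[i] * lap
        if (new_pos[i] >= b && b < total) {
          next_lapx[i] <- next_lapx[i] + 1L
          if (rk[i] > config$incident_behind &&
              runif(1) < config$incident_rate) {
            inc_until[i] <- t + 4
            incidents[[length(incidents) + 1L]] <-
              data.frame(skier_id = skiers$skier_id[i], distance_m = new_pos[i],
                         time_s = t)
          }
        }
      }
    }

    just <- !finished & new_pos >= total
    if (any(just)) {
      finish_time[just] <- t + (total - pos[just]) / pmax(v[just], 1e-9)
      new_pos[just] <- total
      finished[just] <- TRUE
    }
    pos <- new_pos
    vprev <- v
    t <- t + dt
    step <- step + 1L
    if (step + 1L > cap) {
      cap <- cap * 2L
      posm <- rbind(posm, matrix(NA_real_, cap - nrow(posm), n))
    }
    posm[step + 1L, ] <- pos
    if (t > 4 * total / min(ability)) stopf("simulation failed to terminate")
  }
  posm <- posm[seq_len(step + 1L), , drop = FALSE]
  times <- (0:step) * dt

  truth <- build_ground_truth(posm, times, finish_time, skiers, course, config)
  truth$accordion_counts <- setNames(acc_count, skiers$skier_id)
  truth$incidents <- if (length(incidents)) {
    do.call(rbind, incidents)
  } else {
    data.frame(skier_id = character(), distance_m = numeric(),
               time_s = numeric())
  }
  tracks <- emit_tracks(posm, times, finish_time, skiers, course, config)
  splits <- split_table(truth$split_entries)
  ranks <- rank_list(skiers$skier_id, skiers$start_position,
                     truth$final_rank)
  structure(list(tracks = tracks, splits = splits, ranks = ranks,
                 truth = truth, course = course, config = config,
                 skiers = skiers),
            class = "ski_race_sim")
}

# Ground truth: arrival times at 1 m, checkpoint splits, lap/segment times,
# pack partition on a 10 m grid, final ranks.
build_ground_truth <- function(posm, times, finish_time, skiers, course,
                               config, grid_step = 10) {
  n <- nrow(skiers)
  lap <- course$lap_length_m
  total <- lap * course$n_laps
  seg <- course$segments
  d1 <- 0:total
  arrival <- matrix(NA_real_, n, length(d1),
                    dimnames = list(skiers$skier_id, NULL))
  for (i in seq_len(n)) {
    p <- posm[, i]
    keep <- c(TRUE, diff(p) > 0)
    arrival[i, ] <- approx(p[keep], times[keep], xout = d1, ties = "ordered")$y
  }
  arrival[, 1] <- ifelse(is.na(arrival[, 1]), 0, arrival[, 1])
  # skiers starting behind the line reach d = 0 after the gun
  for (i in seq_len(n)) {
    na <- is.na(arrival[i, ])
    if (any(na)) {
      p <- posm[, i]
      t0 <- approx(p, times, xout = 0, ties = "ordered", rule = 2)$y
      arrival[i, na] <- t0
    }
  }

  cps <- course$checkpoints
  split_entries <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(skier_id = skiers$skier_id[i],
               checkpoint_id = cps$checkpoint_id,
               course_distance_m = cps$distance_m,
               time_s = arrival[i, cps$distance_m + 1])
  }))

  # lap and segment times
  lap_times <- sapply(seq_len(course$n_laps), function(k) {
    arrival[, k * lap + 1] - arrival[, (k - 1) * lap + 1]
  })
  seg_times <- array(NA_real_, c(n, course$n_laps, nrow(seg)),
                     dimnames = list(skiers$skier_id, NULL, seg$segment_id))
  for (k in seq_len(course$n_laps)) {
    off <- (k - 1) * lap
    for (s in seq_len(nrow(seg))) {
      seg_times[, k, s] <- arrival[, off + seg$end_m[s] + 1] -
        arrival[, off + seg$start_m[s] + 1]
    }
  }

  grid <- seq(0, total, by = grid_step)
  packs <- lapply(seq_along(grid), function(g) {
    detect_packs(setNames(arrival[, grid[g] + 1], skiers$skier_id))
  })

  final_rank <- as.integer(rank(finish_time, ties.method = "first"))
  list(arrival_1m = arrival, split_entries = split_entries,
       finish_time = finish_time, final_rank = final_rank,
       lap_times = lap_times, segment_times = seg_times,
       segments = seg, pack_grid = grid, packs = packs,
       accordion_counts = NULL, incidents = NULL)
}

emit_tracks <- function(posm, times, finish_time, skiers, course, config) {
  n <- nrow(skiers)
  total <- course$lap_length_m * course$n_laps
  sd_xy <- config$gnss_noise_sd
  tracks <- lapply(seq_len(n), function(i) {
    p <- posm[, i]
    sel <- which(p >= 0 & p < total)
    tt <- times[sel]
    pp <- p[sel]
    # append a final fix at the finish line
    ft <- finish_time[i]
    if (length(tt) == 0 || ft > tt[length(tt)] + 1e-9) {
      tt <- c(tt, ft)
      pp <- c(pp, total)
    }
    pt <- course_point(course, pp)
    m <- length(tt)
    x <- pt$x + rnorm(m, 0, sd_xy)
    y <- pt$y + rnorm(m, 0, sd_xy)
    e <- pt$elevation + rnorm(m, 0, 1.5 * sd_xy)
    geo <- planar_to_geo(x, y)
    gnss_track(skiers$skier_id[i], tt, geo$lat, geo$lon, e, "ok")
  })
  new_gnss_tracks(tracks)
}

#' @export
print.ski_race_sim <- function(x, ...) {
  cat(sprintf("<ski_race_sim> %d skiers, %d x %.0f m laps; winner %.1f s\n",
              length(x$tracks), x$course$n_laps, x$course$lap_length_m,
              min(x$truth$finish_time)))
  invisible(x)
}

#' Degrade a GNSS track
#'
#' Emulates poor satellite reception: either a dropout (fixes removed over a
#' random window) or a noise burst (position noise inflated tenfold over a
#' random window). The returned track is flagged `degraded`.
#'
#' @param track a [gnss_track()].
#' @param mode `"dropout"` or `"noise_burst"`.
#' @param seed RNG seed.
#' @param window_s length of the affected window, seconds; 0 returns the
#'   track unchanged (apart from the quality flag never being touched).
#' @param noise_sd base noise level whose tenfold is added during a burst,
#'   metres.
#' @return A degraded `gnss_track`.
#' @export
degrade_track <- function(track, mode = c("dropout", "noise_burst"), seed = 1,
                          window_s = 30, noise_sd = 2) {
  mode <- match.arg(mode)
  if (window_s <= 0) return(track)
  with_seed(seed, {
    t0 <- runif(1, min(track$time_s), max(track$time_s) - window_s)
    win <- track$time_s >= t0 & track$time_s < t0 + window_s
    if (mode == "dropout") {
      d <- track[!win, , drop = FALSE]
      gnss_track(track_id(track), d$time_s, d$lat, d$lon, d$ele_m,
                 "degraded", attr(track, "anchor"))
    } else {
      nw <- sum(win)
      pl <- geo_to_planar(track$lat, track$lon, attr(track, "anchor"))
      pl$x[win] <- pl$x[win] + rnorm(nw, 0, 10 * noise_sd)
      pl$y[win] <- pl$y[win] + rnorm(nw, 0, 10 * noise_sd)
      ele <- track$ele_m
      ele[win] <- ele[win] + rnorm(nw, 0, 15 * noise_sd)
      geo <- planar_to_geo(pl$x, pl$y, attr(track, "anchor"))
      gnss_track(track_id(track), track$time_s, geo$lat, geo$lon, ele,
                 "degraded", attr(track, "anchor"))
    }
  })
}
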