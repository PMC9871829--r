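# Pack dynamics: gap matrices, the 3 s pack rule, pack identity over the
# course, loss of the leader pack, accordion metrics and the final sprint.

#' Time-gap matrix over a course-distance grid
#'
#' Gaps are computed in the distance domain: at each grid distance, the gap
#' is the difference in arrival time at that distance (split-time semantics).
#' The current leader is whoever arrives first at the grid point; the winner
#' is the skier who arrives first at the finish line.
#'
#' @param traces a `projected_traces` list (all on the same course).
#' @param grid_step_m grid spacing, metres.
#' @return A `gap_matrix`: list with `grid` (distances), `skiers`, `arrival`
#'   (skier x grid arrival times), `behind_leader`, `behind_winner`, `rank`
#'   matrices, `winner`, `lap_length_m`, `n_laps`.
#' @export
gap_matrix <- function(traces, grid_step_m = 10) {
  lens <- vapply(traces, function(tr) max(tr$distance), numeric(1))
  if (length(unique(lens)) != 1 ||
      length(unique(vapply(traces, function(tr) tr$lap_length_m, numeric(1)))) != 1)
    stopf("traces are not projected onto the same course")
  total <- lens[1]
  grid <- seq(0, total, by = grid_step_m)
  ids <- vapply(traces, function(tr) tr$skier_id, character(1))
  arrival <- t(vapply(traces, function(tr) trace_time_at(tr, grid),
                      numeric(length(grid))))
  rownames(arrival) <- ids
  lead_t <- apply(arrival, 2, min)
  behind_leader <- sweep(arrival, 2, lead_t)
  winner <- ids[which.min(arrival[, length(grid)])]
  behind_winner <- sweep(arrival, 2, arrival[winner, ])
  # ranks by arrival, ties broken by skier id
  ord_id <- rank(ids, ties.method = "first")
  rnk <- apply(arrival + ord_id * 1e-9, 2, rank, ties.method = "first")
  if (!is.matrix(rnk)) rnk <- matrix(rnk, nrow = nrow(arrival))
  dimnames(rnk) <- dimnames(arrival)
  structure(list(grid = grid, skiers = ids, arrival = arrival,
                 behind_leader = behind_leader,
                 behind_winner = behind_winner, rank = rnk, winner = winner,
                 lap_length_m = traces[[1]]$lap_length_m,
                 n_laps = traces[[1]]$n_laps),
            class = "gap_matrix")
}

#' @export
print.gap_matrix <- function(x, ...) {
  cat(sprintf("<gap_matrix> %d skiers x %d grid points (%g m step); winner %s\n",
              length(x$skiers), length(x$grid), diff(x$grid[1:2]), x$winner))
  invisible(x)
}

#' Partition skiers at one course position into packs
#'
#' Skiers are sorted by arrival time; a new pack starts whenever the gap to
#' the previous skier is 3 s or more (a pack is a run of consecutive skiers
#' each less than `gap_threshold_s` apart, strict `<`).
#'
#' @param arrival_times named numeric vector of arrival times at one point.
#' @param gap_threshold_s the pack gap rule, seconds.
#' @return List of character vectors (pack members in arrival order), fastest
#'   pack first.
#' @export
detect_packs <- function(arrival_times, gap_threshold_s = 3) {
  stopifnot(all(is.finite(arrival_times)))
  ord <- order(arrival_times, names(arrival_times) %||% seq_along(arrival_times))
  tt <- arrival_times[ord]
  if (length(tt) == 0) return(list())
  new_pack <- c(TRUE, diff(tt) >= gap_threshold_s)
  grp <- cumsum(new_pack)
  nm <- names(tt) %||% as.character(ord)
  unname(split(nm, grp))
}

#' Track pack membership and identity along the course
#'
#' Packs are detected at every grid point of a [gap_matrix()]; identities are
#' carried forward by maximal member overlap with the previous grid point
#' (ties go to the larger pack), and split/merge events are recorded whenever
#' the members of one pack spread over several packs (or several collapse
#' into one) between consecutive grid points.
#'
#' @param gm a [gap_matrix()].
#' @param gap_threshold_s pack gap rule, seconds.
#' @return A `pack_series`: list with `grid`, `membership` (skier x grid
#'   matrix of pack ids), `packs` (per grid point, list of member lists) and
#'   `events` (data frame: distance, type, parent and child pack ids).
#' @export
pack_timeline <- function(gm, gap_threshold_s = 3) {
  n <- length(gm$skiers)
  ng <- length(gm$grid)
  membership <- matrix(NA_integer_, n, ng, dimnames = list(gm$skiers, NULL))
  packs <- vector("list", ng)
  events <- list()
  next_id <- 1L
  prev_ids <- NULL
  for (g in seq_len(ng)) {
    pk <- detect_packs(setNames(gm$arrival[, g], gm$skiers), gap_threshold_s)
    ids <- integer(length(pk))
    if (g == 1) {
      ids <- seq_along(pk)
      next_id <- length(pk) + 1L
    } else {
      # assign ids by maximal overlap, larger packs first
      taken <- integer(0)
      for (p in order(-lengths(pk))) {
        ov <- vapply(seq_along(prev_ids$packs), function(q) {
          length(intersect(pk[[p]], prev_ids$packs[[q]]))
        }, integer(1))
        ov[prev_ids$ids %in% taken] <- -1L
        q <- which.max(ov)
        if (length(q) && ov[q] > 0) {
          ids[p] <- prev_ids$ids[q]
          taken <- c(taken, prev_ids$ids[q])
        } else {
          ids[p] <- next_id
          next_id <- next_id + 1L
        }
      }
      # events: one previous pack whose members now sit in >1 pack = split;
      # members of >1 previous packs in one pack = merge
      cur_of <- setNames(rep(ids, lengths(pk)), unlist(pk))
      for (q in seq_along(prev_ids$packs)) {
        dest <- unique(cur_of[prev_ids$packs[[q]]])
        if (length(dest) > 1)
          events[[length(events) + 1L]] <-
            data.frame(distance_m = gm$grid[g], type = "split",
                       parents = as.character(prev_ids$ids[q]),
                       children = paste(sort(dest), collapse = "+"))
      }
      prev_of <- setNames(rep(prev_ids$ids, lengths(prev_ids$packs)),
                          unlist(prev_ids$packs))
      for (p in seq_along(pk)) {
        src <- unique(prev_of[pk[[p]]])
        if (length(src) > 1)
          events[[length(events) + 1L]] <-
            data.frame(distance_m = gm$grid[g], type = "merge",
                       parents = paste(sort(src), collapse = "+"),
                       children = as.character(ids[p]))
      }
    }
    for (p in seq_along(pk)) membership[pk[[p]], g] <- ids[p]
    packs[[g]] <- pk
    prev_ids <- list(packs = pk, ids = ids)
  }
  events <- if (length(events)) do.call(rbind, events) else {
    data.frame(distance_m = numeric(), type = character(),
               parents = character(), children = character())
  }
  structure(list(grid = gm$grid, membership = membership, packs = packs,
                 events = events, lap_length_m = gm$lap_length_m,
                 arrival = gm$arrival),
            class = "pack_series")
}

#' @export
print.pack_series <- function(x, ...) {
  cat(sprintf("<pack_series> %d skiers, %d grid points, %d split/merge events\n",
              nrow(x$membership), length(x$grid), nrow(x$events)))
  invisible(x)
}

#' Where (and on which lap) a skier loses the leader pack
#'
#' The first grid distance at which the skier is no longer in the pack
#' containing the current leader and stays out for at least `sustain_m`
#' metres without rejoining.
#'
#' @param ps a [pack_series()].
#' @param skier skier id.
#' @param sustain_m sustained-detachment rule, metres.
#' @return List `(distance_m, lap)` or `NULL` if always attached.
#' @export
leader_pack_loss <- function(ps, skier, sustain_m = 200) {
  grid <- ps$grid
  step <- diff(grid[1:2])
  lead <- rownames(ps$arrival)[apply(ps$arrival, 2, which.min)]
  lead_pack <- ps$membership[cbind(match(lead, rownames(ps$membership)),
                                   seq_along(grid))]
  out <- ps$membership[skier, ] != lead_pack
  need <- max(1L, ceiling(sustain_m / step))
  r <- rle(out)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & (r$lengths >= need | ends == length(grid)))
  if (length(cand) == 0) return(NULL)
  g <- starts[cand[1]]
  list(distance_m = grid[g],
       lap = min(floor(grid[g] / ps$lap_length_m) + 1, ncol(ps$membership)))
}

#' Accordion-effect summary
#'
#' Counts, at every grid point, how many skiers are within each threshold of
#' the current leader; the mean gap per performance group; and, per skier, an
#' accordion exposure index: the number of deceleration-reacceleration
#' cycles, i.e. maximal runs where the skier's speed over a grid interval
#' drops more than 10 % below the current leader's with recovery within
#' `recovery_m` metres.
#'
#' @param gm a [gap_matrix()].
#' @param thresholds_s gap thresholds, seconds.
#' @param groups optional named vector/factor of group labels per skier id.
#' @param drop_frac speed deficit that counts as a deceleration (0.10 = 10 %).
#' @param recovery_m a drop only counts as a cycle if the skier recovers
#'   within this many metres.
#' @return An `accordion_summary`: list with `counts` (threshold x grid),
#'   `group_mean_gap` (group x grid), `exposure` (per-skier cycle count).
#' @export
accordion_summary <- function(gm, thresholds_s = c(1, 5, 10, 30, 60, 90, 120),
                              groups = NULL, drop_frac = 0.10,
                              recovery_m = 200) {
  counts <- t(vapply(thresholds_s, function(tau) {
    colSums(gm$behind_leader <= tau)
  }, numeric(length(gm$grid))))
  rownames(counts) <- paste0("within_", thresholds_s, "s")

  group_mean_gap <- NULL
  if (!is.null(groups)) {
    groups <- groups[gm$skiers]
    gl <- sort(unique(as.character(groups[!is.na(groups)])))
    group_mean_gap <- t(vapply(gl, function(g) {
      colMeans(gm$behind_leader[which(groups == g), , drop = FALSE])
    }, numeric(length(gm$grid))))
  }

  step <- diff(gm$grid[1:2])
  dtm <- t(apply(gm$arrival, 1, diff))   # time per grid interval
  spd <- step / dtm
  lead_idx <- apply(gm$arrival[, -ncol(gm$arrival), drop = FALSE], 2, which.min)
  lead_spd <- spd[cbind(lead_idx, seq_len(ncol(spd)))]
  need <- ceiling(recovery_m / step)
  exposure <- apply(spd, 1, function(v) {
    slow <- v < (1 - drop_frac) * lead_spd
    r <- rle(slow)
    sum(r$values & r$lengths <= need &
          cumsum(r$lengths) < length(slow)) # recovered before the finish
  })
  names(exposure) <- gm$skiers
  structure(list(thresholds_s = thresholds_s, grid = gm$grid, counts = counts,
                 group_mean_gap = group_mean_gap, exposure = exposure),
            class = "accordion_summary")
}

#' Final-sprint gaps
#'
#' Time behind the eventual winner at the finish line and at the start of the
#' final window, plus the gap evolution over that window.
#'
#' @param traces a `projected_traces` list.
#' @param window_m length of the final sprint window, metres.
#' @param grid_step_m sampling step for the gap evolution, metres.
#' @return List with `gaps` (per skier: gap at window start and finish) and
#'   `evolution` (skier x grid matrix over the window).
#' @export
final_sprint_gaps <- function(traces, window_m = 1200, grid_step_m = 10) {
  total <- max(traces[[1]]$distance)
  ids <- vapply(traces, function(tr) tr$skier_id, character(1))
  finish <- vapply(traces, function(tr) trace_time_at(tr, total), numeric(1))
  winner <- which.min(finish)
  d <- seq(total - window_m, total, by = grid_step_m)
  arr <- t(vapply(traces, function(tr) trace_time_at(tr, d),
                  numeric(length(d))))
  evol <- sweep(arr, 2, arr[winner, ])
  dimnames(evol) <- list(ids, d)
  gaps <- data.frame(skier_id = ids,
                     gap_at_window_start_s = evol[, 1],
                     gap_at_finish_s = evol[, ncol(evol)])
  gaps <- gaps[order(gaps$gap_at_finish_s), ]
  rownames(gaps) <- NULL
  list(gaps = gaps, evolution = evol, winner = ids[winner])
}
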