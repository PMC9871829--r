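# Reconstruction of a full distance-time trace from official split times,
# using the within-interval time-allocation shapes of peer skiers.

#' Fit a peer-profile model from complete traces and official splits
#'
#' For every checkpoint interval, each training skier contributes a
#' normalised time-allocation curve: the cumulative fraction of the interval
#' time spent as a function of the fraction of interval distance covered,
#' sampled at 1 m. Together with each skier's normalised split vector (split
#' times divided by finish time) these shapes let a skier with splits only be
#' reconstructed from their most similar peers.
#'
#' @param traces a `projected_traces` list of complete traces.
#' @param splits a `split_table` covering (at least) the trace skiers.
#' @param k number of nearest peers used at synthesis time.
#' @return A `profile_model`.
#' @export
fit_profile_model <- function(traces, splits, k = 5) {
  sm <- split_matrix(splits)
  ids <- intersect(vapply(traces, function(tr) tr$skier_id, character(1)),
                   rownames(sm)[complete.cases(sm)])
  if (length(ids) < k)
    stopf("need at least k = %d training skiers with traces and splits, have %d",
          k, length(ids))
  cps <- splits$checkpoints$distance_m
  anchors <- if (cps[1] > 0) c(0, cps) else cps
  total <- max(vapply(traces, function(tr) max(tr$distance), numeric(1)))
  if (max(anchors) > total) stopf("checkpoint beyond the course end")

  shapes <- vector("list", length(anchors) - 1)
  for (j in seq_along(shapes)) {
    d <- anchors[j]:anchors[j + 1]
    mat <- t(vapply(ids, function(id) {
      tt <- trace_time_at(traces[[id]], d)
      (tt - tt[1]) / (tt[length(tt)] - tt[1])
    }, numeric(length(d))))
    shapes[[j]] <- mat
  }
  # In a mass start the line is crossed some seconds after the gun, so the
  # first interval cannot be anchored at t = 0. The crossing delay is highly
  # predictable from the first checkpoint time (field position is roughly
  # conserved early on); regress it on the training skiers.
  delay <- vapply(ids, function(id) trace_time_at(traces[[id]], 0), numeric(1))
  cp1 <- sm[ids, 1]
  b <- if (stats::var(cp1) > 1e-12) {
    stats::cov(cp1, delay) / stats::var(cp1)
  } else 0
  delay_fit <- c(intercept = mean(delay) - b * mean(cp1), slope = b)
  split_norm <- sm[ids, , drop = FALSE] / sm[ids, ncol(sm)]
  structure(list(anchors = anchors, shapes = shapes, train_ids = ids,
                 delay_fit = delay_fit,
                 split_norm = split_norm, k = k, total = total,
                 lap_length_m = traces[[ids[1]]]$lap_length_m,
                 n_laps = traces[[ids[1]]]$n_laps),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf("<profile_model> %d peers, %d checkpoint intervals, k = %d\n",
              length(x$train_ids), length(x$shapes), x$k))
  invisible(x)
}

#' Synthesise a distance-time trace from official splits
#'
#' The target skier's normalised split vector selects the `k` nearest
#' training peers (Euclidean distance); within each checkpoint interval the
#' peers' mean time-allocation shape distributes the official interval time
#' over distance. The synthesised arrival time equals the official split
#' exactly at every checkpoint, and the trace is monotone.
#'
#' @param model a [fit_profile_model()].
#' @param splits a `split_table` containing the target skier.
#' @param skier_id the skier to synthesise.
#' @return A `projected_trace` with `source = "synthetic"`.
#' @export
synthesize_trace <- function(model, splits, skier_id) {
  sm <- split_matrix(splits)
  if (!skier_id %in% rownames(sm) || anyNA(sm[skier_id, ]))
    stopf("skier '%s' is missing checkpoint times", skier_id)
  target <- sm[skier_id, ]
  tn <- target / target[length(target)]
  train <- setdiff(model$train_ids, skier_id)
  dist2 <- rowSums(sweep(model$split_norm[train, , drop = FALSE], 2, tn)^2)
  peers <- train[order(dist2)][seq_len(min(model$k, length(train)))]

  anchors <- model$anchors
  s <- if (anchors[1] == 0 && length(target) == length(anchors) - 1) {
    t0 <- model$delay_fit[["intercept"]] + model$delay_fit[["slope"]] * target[1]
    c(max(0, min(t0, 0.9 * target[1])), target)
  } else target
  tt <- numeric(model$total + 1)
  for (j in seq_along(model$shapes)) {
    idx <- match(peers, model$train_ids)
    shape <- colMeans(model$shapes[[j]][idx, , drop = FALSE])
    d <- anchors[j]:anchors[j + 1]
    tt[d + 1] <- s[j] + shape * (s[j + 1] - s[j])
  }
  A <- max(anchors)
  if (A < model$total) { # beyond the last checkpoint: hold the final pace
    d <- (A + 1):model$total
    dt_per_m <- tt[A + 1] - tt[A]
    tt[d + 1] <- tt[A + 1] + (d - A) * dt_per_m
  }
  new_projected_trace(skier_id, 0:model$total, tt, model$lap_length_m,
                      model$n_laps, source = "synthetic")
}

#' @rdname synthesize_trace
#' @param object a `profile_model`.
#' @param ... unused.
#' @export
predict.profile_model <- function(object, splits, skier_id, ...) {
  synthesize_trace(object, splits, skier_id)
}
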