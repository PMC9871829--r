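# Performance groups, pacing statistics, start-finish correlation, time in
# terrain and terrain time-loss decomposition.

#' Assign performance groups from final ranks
#'
#' Finishers ranked 1-10 form group `R1-10`, 11-20 `R11-20`, 21-30 `R21-30`,
#' 31-40 `R31-40`; ranks beyond 40 (and non-finishers) stay ungrouped (`NA`).
#'
#' @param ranks a [rank_list()].
#' @return Named character vector: group label per skier id (`NA` =
#'   ungrouped).
#' @export
assign_groups <- function(ranks) {
  fr <- ranks$final_rank
  if (any(duplicated(fr[!is.na(fr)]))) stopf("duplicate final ranks")
  g <- rep(NA_character_, nrow(ranks))
  bands <- list("R1-10" = 1:10, "R11-20" = 11:20, "R21-30" = 21:30,
                "R31-40" = 31:40)
  for (lb in names(bands)) g[fr %in% bands[[lb]]] <- lb
  setNames(g, ranks$skier_id)
}

#' Between-group and between-lap speed comparisons
#'
#' One-way ANOVA with Tukey post-hoc pairwise comparisons, laid out both
#' ways: per lap between performance groups, and per group between laps.
#' Lap 1 is compared with other laps only on the common segment set (the
#' Lap-1 course omits some segments), via `lap1_common_segments`.
#'
#' @param sm a [speed_matrix()].
#' @param groups named group labels per skier id (see [assign_groups()]).
#' @param by aggregation for the compared speeds: `"lap"` or `"terrain"`.
#' @param lap1_common_segments segment ids on which lap 1 is comparable to
#'   the other laps; if `NULL`, lap 1 is left out of between-lap comparisons.
#' @return A `comparison_table` data frame: `comparison` (between_groups /
#'   between_laps), `stratum`, `a`, `b`, `diff_ms` (mean speed of `a` minus
#'   `b`, m/s), `p_adj`, `f_statistic`, `df`, `skipped` flag. Both orders of
#'   each pair are reported, so differences are antisymmetric by
#'   construction.
#' @export
lap_speed_comparisons <- function(sm, groups, by = "lap",
                                  lap1_common_segments = NULL) {
  spd <- aggregate_speeds(sm, by = by)
  spd$group <- groups[spd$skier_id]
  spd <- spd[!is.na(spd$group), , drop = FALSE]
  out <- list()

  # between groups, per lap
  for (k in sort(unique(spd$lap))) {
    d <- spd[spd$lap == k, , drop = FALSE]
    out[[length(out) + 1L]] <- tukey_pairs(d$speed_ms, d$group,
                                           "between_groups",
                                           sprintf("lap%d", k))
  }
  # between laps, per group (lap 1 only on the common segment set)
  spd2 <- spd[spd$lap > 1, , drop = FALSE]
  if (!is.null(lap1_common_segments)) {
    common <- aggregate_speeds(sm, by = by, segments = lap1_common_segments)
    common$group <- groups[common$skier_id]
    l1 <- common[common$lap == 1 & !is.na(common$group), , drop = FALSE]
    spd2 <- rbind(spd2[, names(l1)], l1)
  }
  for (g in sort(unique(spd2$group))) {
    d <- spd2[spd2$group == g, , drop = FALSE]
    out[[length(out) + 1L]] <- tukey_pairs(d$speed_ms,
                                           sprintf("lap%d", d$lap),
                                           "between_laps", g)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("comparison_table", "data.frame"))
}

# One-way ANOVA + Tukey HSD on speed ~ level; returns both orders of every
# pair. Levels with n < 2 (no within-group variance estimate) are skipped
# with a flag.
tukey_pairs <- function(speed, level, comparison, stratum) {
  level <- as.character(level)
  tab <- table(level)
  usable <- names(tab)[tab >= 2]
  skipped <- setdiff(names(tab), usable)
  skip_rows <- if (length(skipped)) {
    data.frame(comparison = comparison, stratum = stratum, a = skipped,
               b = NA_character_, diff_ms = NA_real_, p_adj = NA_real_,
               f_statistic = NA_real_, df = NA_real_, skipped = TRUE)
  } else {
    data.frame(comparison = character(), stratum = character(),
               a = character(), b = character(), diff_ms = numeric(),
               p_adj = numeric(), f_statistic = numeric(),
               df = numeric(), skipped = logical())
  }
  if (length(usable) < 2) return(skip_rows)
  keep <- level %in% usable
  d <- data.frame(speed = speed[keep], level = factor(level[keep]))
  if (stats::var(d$speed) < 1e-12) { # degenerate: identical values
    prs <- utils::combn(levels(d$level), 2)
    return(data.frame(comparison = comparison, stratum = stratum,
                      a = c(prs[1, ], prs[2, ]), b = c(prs[2, ], prs[1, ]),
                      diff_ms = 0, p_adj = NA_real_, f_statistic = NA_real_,
                      df = NA_real_, skipped = TRUE))
  }
  fit <- aov(speed ~ level, data = d)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$level
  pr <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  res <- data.frame(comparison = comparison, stratum = stratum,
                    a = pr[, 1], b = pr[, 2], diff_ms = tk[, "diff"],
                    p_adj = tk[, "p adj"],
                    f_statistic = sm[["F value"]][1],
                    df = sm[["Df"]][1], skipped = FALSE)
  mirror <- res
  mirror$a <- res$b; mirror$b <- res$a; mirror$diff_ms <- -res$diff_ms
  res <- rbind(res, mirror, skip_rows)
  rownames(res) <- NULL
  res
}

#' Correlation between starting position and final rank
#'
#' Spearman rank correlation, plus the share of finishers whose final rank is
#' within `within_ranks` of their starting position.
#'
#' @param ranks a [rank_list()].
#' @param within_ranks band for the share statistic.
#' @return List `rho`, `p_value`, `share_within` (fraction), `n`.
#' @export
start_finish_correlation <- function(ranks, within_ranks = 15) {
  d <- ranks[!is.na(ranks$final_rank), , drop = FALSE]
  if (nrow(d) < 3) stopf("need at least 3 finishers")
  if (length(unique(d$final_rank)) == 1 ||
      length(unique(d$start_position)) == 1) stopf("all ranks tied")
  ct <- suppressWarnings(cor.test(d$start_position, d$final_rank,
                                  method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       share_within = mean(abs(d$final_rank - d$start_position) <= within_ranks),
       n = nrow(d))
}

#' Share of race time spent in each terrain type
#'
#' @param sm a [speed_matrix()].
#' @return List with `per_skier` (data frame of percentages per label,
#'   summing to 100 per skier) and `mean`/`sd` aggregate percentages.
#' @export
time_in_terrain <- function(sm) {
  agg <- aggregate(time_s ~ skier_id + label, as.data.frame(sm), sum)
  tot <- aggregate(time_s ~ skier_id, as.data.frame(sm), sum)
  m <- merge(agg, tot, by = "skier_id", suffixes = c("", "_total"))
  m$pct <- 100 * m$time_s / m$time_s_total
  wide <- reshape_terrain(m)
  list(per_skier = wide,
       mean = colMeans(wide[, -1, drop = FALSE]),
       sd = apply(wide[, -1, drop = FALSE], 2, sd))
}

reshape_terrain <- function(m) {
  ids <- sort(unique(m$skier_id))
  labs <- c("uphill", "flat", "downhill")
  out <- data.frame(skier_id = ids)
  for (lb in labs) {
    v <- m$pct[m$label == lb][match(ids, m$skier_id[m$label == lb])]
    out[[lb]] <- ifelse(is.na(v), 0, v)
  }
  out
}

#' Terrain decomposition of time loss relative to a reference group
#'
#' For each group, the time lost to the reference group is the sum over laps
#' and segments of the difference in group-mean segment time, attributed to
#' the terrain label of each segment. Shares are signed percentages of the
#' total loss and sum to 100 % whenever the total loss is positive.
#'
#' @param sm a [speed_matrix()].
#' @param groups named group labels per skier id.
#' @param reference label of the reference group.
#' @return A data frame per non-reference group: absolute loss (s) and share
#'   (%) per terrain label, total loss, and a `degenerate` flag when the
#'   total loss is not positive (shares undefined).
#' @export
time_loss_decomposition <- function(sm, groups, reference = "R1-10") {
  d <- as.data.frame(sm)
  d$group <- groups[d$skier_id]
  d <- d[!is.na(d$group), , drop = FALSE]
  if (!reference %in% d$group) stopf("reference group '%s' is empty", reference)
  cell <- aggregate(time_s ~ group + lap + segment_id + label, d, mean)
  ref <- cell[cell$group == reference, c("lap", "segment_id", "time_s")]
  names(ref)[3] <- "ref_time_s"
  cell <- merge(cell, ref, by = c("lap", "segment_id"))
  cell$loss_s <- cell$time_s - cell$ref_time_s
  out <- lapply(setdiff(sort(unique(cell$group)), reference), function(g) {
    cg <- cell[cell$group == g, , drop = FALSE]
    by_lab <- tapply(cg$loss_s, cg$label, sum)
    labs <- c("uphill", "flat", "downhill")
    loss <- setNames(as.numeric(by_lab[labs]), labs)
    loss[is.na(loss)] <- 0
    total <- sum(loss)
    share <- if (total > 0) 100 * loss / total else rep(NA_real_, 3)
    data.frame(group = g,
               uphill_loss_s = loss["uphill"], flat_loss_s = loss["flat"],
               downhill_loss_s = loss["downhill"], total_loss_s = total,
               uphill_share_pct = share[1], flat_share_pct = share[2],
               downhill_share_pct = share[3],
               degenerate = total <= 0, row.names = NULL)
  })
  do.call(rbind, out)
}
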