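# Base-graphics views of the main result objects.

TERRAIN_COLS <- c(uphill = "#c0392b", flat = "#7f8c8d", downhill = "#27ae60")

#' Plot a lap elevation profile with its terrain segments
#'
#' @param x a `race_course` with `$segments` (or pass a segmentation).
#' @param segments a `terrain_segments` data frame; defaults to
#'   `x$segments`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.race_course <- function(x, segments = x$segments, ...) {
  lap <- x$lap_length_m
  d <- 0:lap
  elev <- x$elevation[d + 1]
  graphics::plot(d, elev, type = "n", xlab = "lap distance [m]",
                 ylab = "elevation [m]", ...)
  if (!is.null(segments)) {
    for (i in seq_len(nrow(segments))) {
      sel <- d >= segments$start_m[i] & d <= segments$end_m[i]
      graphics::polygon(c(d[sel], rev(d[sel])),
                        c(elev[sel], rep(min(elev), sum(sel))),
                        col = grDevices::adjustcolor(
                          TERRAIN_COLS[[segments$label[i]]], 0.35),
                        border = NA)
      graphics::text(mean(range(d[sel])), max(elev) * 1.0,
                     segments$segment_id[i], cex = 0.6)
    }
  }
  graphics::lines(d, elev, lwd = 2)
  invisible(x)
}

#' Plot time behind the current leader along the course
#'
#' One line per skier, optionally coloured by performance group: the classic
#' pack-dynamics view in which splits, regroupings and the accordion effect
#' are visible.
#'
#' @param x a `gap_matrix`.
#' @param groups optional named group labels per skier id.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.gap_matrix <- function(x, groups = NULL, ...) {
  cols <- "#00000055"
  if (!is.null(groups)) {
    pal <- setNames(grDevices::hcl.colors(length(unique(stats::na.omit(groups))),
                                          "Dark 3"),
                    sort(unique(stats::na.omit(groups))))
    cols <- ifelse(is.na(groups[x$skiers]), "#00000022",
                   pal[groups[x$skiers]])
  }
  graphics::matplot(x$grid / 1000, t(x$behind_leader), type = "l", lty = 1,
                    col = cols, xlab = "distance [km]",
                    ylab = "time behind current leader [s]", ...)
  invisible(x)
}
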