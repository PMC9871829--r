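#' Construct a GNSS track
#'
#' A track holds the ordered 10 Hz fixes of one skier: race-relative time in
#' seconds, geographic coordinates and elevation. Planar east/north
#' coordinates (metres, local equirectangular projection about `anchor`) are
#' derived on construction; all geometry downstream works in the planar frame.
#'
#' @param skier_id character scalar identifying the skier.
#' @param time_s numeric vector, seconds from the race gun, strictly
#'   increasing.
#' @param lat,lon numeric vectors, degrees.
#' @param ele_m numeric vector, metres; missing values are linearly
#'   interpolated from neighbouring fixes.
#' @param quality one of `"ok"`, `"degraded"`, `"missing"`.
#' @param anchor named numeric `c(lat=, lon=)` anchoring the planar frame.
#' @return An object of class `gnss_track`: a data frame with columns
#'   `time_s`, `lat`, `lon`, `ele_m`, `x`, `y` and attributes `skier_id`,
#'   `quality`, `anchor`.
#' @export
gnss_track <- function(skier_id, time_s, lat, lon, ele_m,
                       quality = c("ok", "degraded", "missing"),
                       anchor = DEFAULT_ANCHOR) {
  quality <- match.arg(quality)
  n <- length(time_s)
  if (quality != "missing" && n < 2)
    stopf("track '%s': at least 2 fixes required", skier_id)
  if (any(lat < -90 | lat > 90, na.rm = TRUE))
    stopf("track '%s': latitude outside [-90, 90]", skier_id)
  if (any(lon < -180 | lon > 180, na.rm = TRUE))
    stopf("track '%s': longitude outside [-180, 180]", skier_id)
  if (n > 1 && any(diff(time_s) <= 0))
    stopf("track '%s': times not strictly increasing", skier_id)
  if (anyNA(ele_m)) {
    ok <- !is.na(ele_m)
    if (sum(ok) >= 2) {
      ele_m <- approx(time_s[ok], ele_m[ok], xout = time_s, rule = 2)$y
    } else {
      ele_m[!ok] <- if (any(ok)) ele_m[ok][1] else 0
    }
  }
  pl <- geo_to_planar(lat, lon, anchor)
  out <- data.frame(time_s = as.numeric(time_s), lat = as.numeric(lat),
                    lon = as.numeric(lon), ele_m = as.numeric(ele_m),
                    x = pl$x, y = pl$y)
  structure(out, skier_id = as.character(skier_id), quality = quality,
            anchor = anchor, class = c("gnss_track", "data.frame"))
}

track_quality <- function(track) attr(track, "quality")
track_id <- function(track) attr(track, "skier_id")

new_gnss_tracks <- function(tracks) {
  names(tracks) <- vapply(tracks, track_id, character(1))
  structure(tracks, class = "gnss_tracks")
}

#' Read GNSS tracks from CSV or GPX
#'
#' The CSV dialect (canonical) has header columns `skier_id`, `time_s`,
#' `lat`, `lon`, `ele_m`. GPX 1.1 files are read one `<trk>` per skier, with
#' absolute `<time>` stamps converted to race-relative seconds using
#' `race_start`. Fixes are sorted by time; duplicated timestamps are
#' collapsed to their first occurrence with a warning. Gaps longer than
#' `gap_flag_s` seconds mark a track as degraded.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"gpx"`.
#' @param race_start for GPX, the race-gun timestamp (`POSIXct` or ISO 8601
#'   string, UTC); defaults to the earliest timestamp in the file.
#' @param anchor planar-frame anchor, see [gnss_track()].
#' @param gap_flag_s sampling gaps exceeding this many seconds flag the track
#'   as degraded (default 2).
#' @return A `gnss_tracks` list of [gnss_track()] objects, named by skier.
#' @export
read_gnss_tracks <- function(path, dialect = c("csv", "gpx"),
                             race_start = NULL, anchor = DEFAULT_ANCHOR,
                             gap_flag_s = 2) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("skier_id", "time_s", "lat", "lon", "ele_m")
    if (!all(need %in% names(df)))
      stopf("CSV must have columns %s", paste(need, collapse = ", "))
    for (col in c("time_s", "lat", "lon")) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
      if (length(bad))
        stopf("malformed value in column '%s' at data line %d", col, bad[1])
      if (anyNA(v))
        stopf("missing value in column '%s' at data line %d", col,
              which(is.na(v))[1])
      df[[col]] <- v
    }
    df$ele_m <- suppressWarnings(as.numeric(df$ele_m))
    rows <- split(df, df$skier_id)
  } else {
    rows <- read_gpx_rows(path, race_start)
  }
  tracks <- lapply(names(rows), function(id) {
    d <- rows[[id]]
    d <- d[order(d$time_s), , drop = FALSE]
    dup <- duplicated(d$time_s)
    if (any(dup)) {
      warnf("track '%s': %d duplicated timestamp(s) collapsed to first", id,
            sum(dup))
      d <- d[!dup, , drop = FALSE]
    }
    quality <- "ok"
    if (nrow(d) > 1 && any(diff(d$time_s) > gap_flag_s)) {
      warnf("track '%s': sampling gap > %g s, flagged degraded", id, gap_flag_s)
      quality <- "degraded"
    }
    gnss_track(id, d$time_s, d$lat, d$lon, d$ele_m, quality, anchor)
  })
  new_gnss_tracks(tracks)
}

read_gpx_rows <- function(path, race_start) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stopf("no <trk> elements in %s", path)
  rows <- list()
  all_t0 <- NULL
  parsed <- lapply(seq_along(trks), function(i) {
    trk <- trks[[i]]
    id <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(id) || id == "") id <- sprintf("trk%02d", i)
    pts <- xml2::xml_find_all(trk, ".//trkpt")
    lat <- as.numeric(xml2::xml_attr(pts, "lat"))
    lon <- as.numeric(xml2::xml_attr(pts, "lon"))
    ele <- as.numeric(xml2::xml_text(xml2::xml_find_first(pts, "./ele")))
    tim <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
    tt <- as.POSIXct(tim, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    if (anyNA(tt)) stopf("track '%s': unparseable <time> element", id)
    list(id = id, lat = lat, lon = lon, ele = ele, t = tt)
  })
  t0 <- if (is.null(race_start)) {
    min(do.call(c, lapply(parsed, function(p) min(p$t))))
  } else if (inherits(race_start, "POSIXct")) race_start else {
    as.POSIXct(race_start, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  }
  for (p in parsed) {
    rows[[p$id]] <- data.frame(time_s = as.numeric(difftime(p$t, t0, units = "secs")),
                               lat = p$lat, lon = p$lon, ele_m = p$ele)
  }
  rows
}

#' Write GNSS tracks to CSV or GPX
#'
#' CSV uses the canonical dialect of [read_gnss_tracks()], times to 1e-3 s
#' and coordinates to 1e-7 degrees. GPX 1.1 writes one `<trk>` per skier with
#' absolute timestamps `race_start + time_s`.
#'
#' @param tracks a `gnss_tracks` collection.
#' @param path output file.
#' @param dialect `"csv"` or `"gpx"`.
#' @param race_start race-gun timestamp used for GPX absolute times.
#' @return `path`, invisibly.
#' @export
write_gnss_tracks <- function(tracks, path, dialect = c("csv", "gpx"),
                              race_start = "2022-01-29T12:00:00") {
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    rows <- lapply(tracks, function(tr) {
      data.frame(skier_id = track_id(tr),
                 time_s = sprintf("%.3f", tr$time_s),
                 lat = sprintf("%.7f", tr$lat),
                 lon = sprintf("%.7f", tr$lon),
                 ele_m = sprintf("%.3f", tr$ele_m))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  } else {
    t0 <- if (inherits(race_start, "POSIXct")) race_start else {
      as.POSIXct(race_start, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
    }
    doc <- xml2::xml_new_root("gpx", version = "1.1", creator = "skipack",
                              xmlns = "http://www.topografix.com/GPX/1/1")
    for (tr in tracks) {
      trk <- xml2::xml_add_child(doc, "trk")
      xml2::xml_add_child(trk, "name", track_id(tr))
      seg <- xml2::xml_add_child(trk, "trkseg")
      stamp <- format(t0 + tr$time_s, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
      for (i in seq_len(nrow(tr))) {
        pt <- xml2::xml_add_child(seg, "trkpt",
                                  lat = sprintf("%.7f", tr$lat[i]),
                                  lon = sprintf("%.7f", tr$lon[i]))
        xml2::xml_add_child(pt, "ele", sprintf("%.3f", tr$ele_m[i]))
        xml2::xml_add_child(pt, "time", stamp[i])
      }
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Read an official split table
#'
#' CSV with columns `skier_id`, `checkpoint_id`, `course_distance_m`,
#' `time_s`: one row per (skier, checkpoint) with the official elapsed time.
#'
#' @param path file path.
#' @return A `split_table`: list with `checkpoints` (data frame
#'   `checkpoint_id`, `distance_m`, sorted by distance) and `entries` (long
#'   data frame of times).
#' @export
read_split_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("skier_id", "checkpoint_id", "course_distance_m", "time_s")
  if (!all(need %in% names(df)))
    stopf("split table must have columns %s", paste(need, collapse = ", "))
  split_table(df)
}

#' Build a split table from long-format entries
#'
#' @param entries data frame with columns `skier_id`, `checkpoint_id`,
#'   `course_distance_m`, `time_s`.
#' @return A `split_table`, see [read_split_table()].
#' @export
split_table <- function(entries) {
  cp <- unique(entries[, c("checkpoint_id", "course_distance_m")])
  cp <- cp[order(cp$course_distance_m), , drop = FALSE]
  if (any(duplicated(cp$checkpoint_id)))
    stopf("checkpoint ids map to multiple distances")
  if (any(diff(cp$course_distance_m) <= 0))
    stopf("checkpoint distances not strictly increasing")
  ord <- match(entries$checkpoint_id, cp$checkpoint_id)
  for (id in unique(entries$skier_id)) {
    sel <- entries$skier_id == id
    tt <- entries$time_s[sel][order(ord[sel])]
    if (any(diff(tt) <= 0))
      stopf("skier '%s': checkpoint times not strictly increasing", id)
  }
  rownames(cp) <- NULL
  structure(list(checkpoints = data.frame(checkpoint_id = cp$checkpoint_id,
                                          distance_m = cp$course_distance_m),
                 entries = entries[, c("skier_id", "checkpoint_id", "time_s")]),
            class = "split_table")
}

#' @export
print.split_table <- function(x, ...) {
  cat(sprintf("<split_table> %d checkpoints (%.0f-%.0f m), %d skiers\n",
              nrow(x$checkpoints), min(x$checkpoints$distance_m),
              max(x$checkpoints$distance_m),
              length(unique(x$entries$skier_id))))
  invisible(x)
}

# Matrix of split times, skiers x checkpoints (checkpoint distance order).
split_matrix <- function(splits) {
  cps <- splits$checkpoints$checkpoint_id
  ids <- sort(unique(splits$entries$skier_id))
  m <- matrix(NA_real_, length(ids), length(cps),
              dimnames = list(ids, as.character(cps)))
  i <- cbind(match(splits$entries$skier_id, ids),
             match(splits$entries$checkpoint_id, cps))
  m[i] <- splits$entries$time_s
  m
}

#' Write a split table to CSV
#'
#' @param splits a `split_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_split_table <- function(splits, path) {
  df <- merge(splits$entries, splits$checkpoints, by = "checkpoint_id")
  df <- df[order(df$skier_id, df$distance_m),
           c("skier_id", "checkpoint_id", "distance_m", "time_s")]
  names(df)[3] <- "course_distance_m"
  df$time_s <- round(df$time_s, 3)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a rank list (start order and final ranks)
#'
#' CSV with columns `skier_id`, `start_position`, `final_rank`; an empty or
#' `NA` final rank marks a non-finisher.
#'
#' @param path file path.
#' @return A `rank_list` data frame.
#' @export
read_rank_list <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  rank_list(df$skier_id, df$start_position, df$final_rank)
}

#' Build a rank list
#'
#' @param skier_id character vector.
#' @param start_position integer bib order, unique, >= 1.
#' @param final_rank integer final rank (unique among finishers) or `NA` for
#'   non-finishers.
#' @return A `rank_list` data frame.
#' @export
rank_list <- function(skier_id, start_position, final_rank) {
  start_position <- as.integer(start_position)
  final_rank <- as.integer(final_rank)
  if (any(duplicated(start_position))) stopf("start positions not unique")
  fr <- final_rank[!is.na(final_rank)]
  if (any(duplicated(fr))) stopf("final ranks of finishers not unique")
  structure(data.frame(skier_id = as.character(skier_id),
                       start_position = start_position,
                       final_rank = final_rank),
            class = c("rank_list", "data.frame"))
}

#' Write an analysis result to CSV or JSON
#'
#' Data frames round-trip through CSV; lists (and data frames) round-trip
#' through JSON. Field order is preserved, so output is deterministic for a
#' given input.
#'
#' @param results a data frame (csv or json) or list (json).
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results)) stopf("csv format requires a data frame")
    write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`.
#' @return A data frame (csv) or list (json).
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") read.csv(path, stringsAsFactors = FALSE)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}
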