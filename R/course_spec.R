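#' Default 14-segment lap plan
#'
#' A 3,550 m lap split into 14 terrain segments (S1--S14) alternating uphill,
#' flat and downhill, designed so that uphill/flat/downhill make up
#' 1321/724/1505 m (37.2/20.4/42.4 % of lap distance), total climb is exactly
#' 114 m, the peak-to-trough height difference is 42 m, and removing the
#' steepest downhill S5 (-12 %) together with its return climb S6 leaves a
#' 3,170 m Lap-1 variant with 93 m of climb.
#'
#' @return Data frame with columns `segment_id`, `length_m`, `climb_m`,
#'   `gradient_pct`, `label`.
#' @export
default_segment_plan <- function() {
  plan <- data.frame(
    segment_id = paste0("S", 1:14),
    length_m = c(160, 300, 140, 200, 230, 150, 300, 174, 280, 250, 200, 421, 250, 495),
    climb_m  = c(0, 24, 0, 18, -27.6, 21, -21, 0, -14, 20, -12, 31, 0, -39.4),
    stringsAsFactors = FALSE
  )
  plan$gradient_pct <- 100 * plan$climb_m / plan$length_m
  plan$label <- ifelse(plan$climb_m > 0, "uphill",
                       ifelse(plan$climb_m < 0, "downhill", "flat"))
  plan
}

#' Course specification for the synthetic race generator
#'
#' Defaults mirror the reference venue: a 3,550 m lap skied 6 times, 114 m of
#' climb per lap, 42 m maximal height difference, and a Lap-1 variant of
#' 3,170 m that omits segments S5 and S6.
#'
#' @param lap_length_m lap length in metres.
#' @param n_laps number of laps.
#' @param segment_plan data frame as returned by [default_segment_plan()]
#'   with columns `segment_id`, `length_m`, `climb_m` (gradient and label are
#'   derived if absent).
#' @param total_climb_m expected climb per lap, metres (validated within 1 %).
#' @param max_height_diff_m expected peak-to-trough height difference, metres.
#' @param lap1_excluded_segments segment ids excluded from Lap-1 analysis.
#' @param lap1_length_m length of the Lap-1 segment set, metres.
#' @param n_checkpoints number of official timing checkpoints spread evenly
#'   over the full race distance (the last one is the finish line).
#' @return A `course_spec` list.
#' @export
course_spec <- function(lap_length_m = 3550, n_laps = 6,
                        segment_plan = default_segment_plan(),
                        total_climb_m = 114, max_height_diff_m = 42,
                        lap1_excluded_segments = c("S5", "S6"),
                        lap1_length_m = 3170, n_checkpoints = 17) {
  if (is.null(segment_plan$gradient_pct))
    segment_plan$gradient_pct <- 100 * segment_plan$climb_m / segment_plan$length_m
  if (is.null(segment_plan$label))
    segment_plan$label <- ifelse(segment_plan$climb_m > 0, "uphill",
                                 ifelse(segment_plan$climb_m < 0, "downhill", "flat"))
  if (abs(sum(segment_plan$length_m) - lap_length_m) > 1e-6)
    stopf("segment lengths sum to %.1f m, not lap_length_m = %.1f m",
          sum(segment_plan$length_m), lap_length_m)
  if (abs(sum(segment_plan$climb_m)) > 1e-6)
    stopf("segment plan does not close the loop (net elevation %.2f m)",
          sum(segment_plan$climb_m))
  climb <- sum(segment_plan$climb_m[segment_plan$climb_m > 0])
  if (abs(climb - total_climb_m) > 0.01 * total_climb_m)
    stopf("plan climb %.1f m differs from total_climb_m %.1f m by > 1%%",
          climb, total_climb_m)
  excl <- match(lap1_excluded_segments, segment_plan$segment_id)
  if (anyNA(excl)) stopf("unknown lap-1 excluded segment id")
  l1 <- sum(segment_plan$length_m) -
    sum(segment_plan$length_m[excl])
  if (abs(l1 - lap1_length_m) > 1e-6)
    stopf("lap-1 segment set is %.0f m, not lap1_length_m = %.0f m", l1,
          lap1_length_m)
  structure(list(lap_length_m = lap_length_m, n_laps = n_laps,
                 segment_plan = segment_plan, total_climb_m = total_climb_m,
                 max_height_diff_m = max_height_diff_m,
                 lap1_excluded_segments = lap1_excluded_segments,
                 lap1_length_m = lap1_length_m,
                 n_checkpoints = n_checkpoints),
            class = "course_spec")
}

#' Specify the skier field for a simulated race
#'
#' Each skier has a flat-terrain cruise speed (`ability`, m/s), multipliers
#' for uphill and downhill speed, a per-lap fractional fatigue rate, and a
#' `follow_gain`: the fraction above natural pace the skier will sustain to
#' stay with the skier ahead (pack cohesion). The default field mirrors a
#' national-level start list: ability declines with start position and
#' fatigue accumulates faster for skiers seeded further back, so the front
#' group holds its lap speed while rear groups fade over the laps.
#'
#' @param n number of skiers.
#' @param base_ability flat speed of the top seed, m/s.
#' @param ability_slope drop in flat speed per start position, m/s.
#' @param ability_sd skier-to-skier random spread in flat speed, m/s.
#' @param fatigue_base per-lap fractional speed loss of the top seed.
#' @param fatigue_slope coefficient of the superlinear (power 1.8) growth of
#'   the per-lap fatigue rate with start position: the front of the field
#'   holds its pace over the race while the back sheds speed lap by lap,
#'   progressively from the rear.
#' @param follow_gain fractional speed reserve available for following.
#' @param seed RNG seed for the random spread.
#' @return A `skier_specs` data frame, one row per skier.
#' @export
make_skiers <- function(n = 40, base_ability = 7.0, ability_slope = 0.005,
                        ability_sd = 0.02, fatigue_base = 0.001,
                        fatigue_slope = 4.5e-5,
                        follow_gain = 0.05, seed = 1) {
  stopifnot(n >= 2)
  fat <- fatigue_base + fatigue_slope * (seq_len(n) - 1)^1.8
  ab <- with_seed(seed, base_ability - ability_slope * (seq_len(n) - 1) +
                    rnorm(n, 0, ability_sd))
  structure(data.frame(
    skier_id = sprintf("sk%02d", seq_len(n)),
    start_position = seq_len(n),
    ability = ab,
    uphill_factor = rep(1, n),
    downhill_factor = rep(1, n),
    fatigue_rate = fat,
    follow_gain = rep(follow_gain, n),
    stringsAsFactors = FALSE
  ), class = c("skier_specs", "data.frame"))
}

#' Simulation configuration
#'
#' @param seed integer RNG seed; a fixed seed yields bit-identical output.
#' @param sample_rate_hz GNSS sampling rate (fixes per second).
#' @param gnss_noise_sd planar position noise, metres (vertical noise is
#'   1.5x this value).
#' @param accordion list with `amplitude` (fractional deceleration per field
#'   position), `propagation_lag_s` (delay per position) and `duration_s` of
#'   the braking wave triggered when the leader enters an uphill segment.
#' @param drafting_saving fractional speed bonus while within
#'   `drafting_window_s` of the skier ahead.
#' @param drafting_window_s time gap under which drafting applies, seconds.
#' @param follow_window_s time gap under which a skier works to close on the
#'   skier ahead, seconds.
#' @param incident_rate per-skier, per-lap probability of an incident
#'   (crash/obstruction, 4 s at 30 % speed), applied only to skiers whose
#'   field position is behind `incident_behind`.
#' @param incident_behind field position from which incidents can occur.
#' @param congestion_zone_m no-overtaking zone after the start, metres.
#' @param start_spacing_m spacing of the start grid, metres per bib position.
#' @param scripted_drops optional list of `list(skier_ids=, at_m=, factor=)`
#'   entries: from distance `at_m` the listed skiers' natural speed is
#'   multiplied by `factor` (used to script pack splits at a known distance).
#' @param dt_s integration step, seconds (also the emitted fix spacing).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, sample_rate_hz = 10, gnss_noise_sd = 2,
                       accordion = list(amplitude = 0.008,
                                        propagation_lag_s = 0.3,
                                        duration_s = 2),
                       drafting_saving = 0.015, drafting_window_s = 3,
                       follow_window_s = 8,
                       incident_rate = 0.02, incident_behind = 10,
                       congestion_zone_m = 400, start_spacing_m = 1,
                       scripted_drops = NULL, dt_s = NULL) {
  stopifnot(accordion$amplitude >= 0, accordion$propagation_lag_s >= 0,
            drafting_saving >= 0, drafting_saving < 1,
            incident_rate >= 0, incident_rate <= 1, gnss_noise_sd >= 0)
  structure(list(seed = as.integer(seed), sample_rate_hz = sample_rate_hz,
                 gnss_noise_sd = gnss_noise_sd, accordion = accordion,
                 drafting_saving = drafting_saving,
                 drafting_window_s = drafting_window_s,
                 follow_window_s = follow_window_s,
                 incident_rate = incident_rate,
                 incident_behind = incident_behind,
                 congestion_zone_m = congestion_zone_m,
                 start_spacing_m = start_spacing_m,
                 scripted_drops = scripted_drops,
                 dt_s = dt_s %||% (1 / sample_rate_hz)),
            class = "sim_config")
}
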