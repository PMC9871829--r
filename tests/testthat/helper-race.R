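# Shared fixtures: a small 600 m / 4-segment loop keeps unit tests fast; the
# full default course is reserved for the acceptance suite.

tiny_plan <- function() {
  data.frame(segment_id = paste0("S", 1:4),
             length_m = c(150, 150, 150, 150),
             climb_m = c(0, 12, -12, 0),
             stringsAsFactors = FALSE)
}

tiny_spec <- function(n_laps = 2, n_checkpoints = 5) {
  course_spec(lap_length_m = 600, n_laps = n_laps,
              segment_plan = tiny_plan(), total_climb_m = 12,
              max_height_diff_m = 12,
              lap1_excluded_segments = character(0), lap1_length_m = 600,
              n_checkpoints = n_checkpoints)
}

# A quiet field: no pack behaviour, no accordion, no incidents.
plain_config <- function(seed = 1, noise = 0, ...) {
  sim_config(seed = seed, gnss_noise_sd = noise,
             accordion = list(amplitude = 0, propagation_lag_s = 0.3,
                              duration_s = 2),
             drafting_saving = 0, incident_rate = 0, congestion_zone_m = 0,
             start_spacing_m = 0, ...)
}

plain_skiers <- function(n, ability = 7, fatigue = 0) {
  data.frame(skier_id = sprintf("sk%02d", seq_len(n)),
             start_position = seq_len(n),
             ability = rep_len(ability, n),
             uphill_factor = 1, downhill_factor = 1,
             fatigue_rate = rep_len(fatigue, n),
             follow_gain = 0, stringsAsFactors = FALSE)
}

tiny_race <- function(seed = 1, noise = 0, n = 4, n_laps = 2,
                      skiers = NULL, config = NULL) {
  spec <- tiny_spec(n_laps = n_laps)
  course <- generate_course(spec, seed = seed)
  if (is.null(skiers)) skiers <- plain_skiers(n)
  if (is.null(config)) config <- plain_config(seed = seed, noise = noise)
  sim <- simulate_race(course, skiers, config)
  list(spec = spec, course = course, skiers = skiers, sim = sim)
}

# A straight flat reference course of the given length (metres).
straight_course <- function(total = 600) {
  skipack:::new_race_course(0:total, x = 0:total, y = rep(0, total + 1),
                            elevation = rep(0, total + 1),
                            lap_length_m = total, n_laps = 1,
                            source = "synthetic")
}

# Track of a constant-speed skier along a straight course.
constant_speed_track <- function(v = 5, total = 600, id = "cs",
                                 dt = 0.1) {
  tt <- seq(0, total / v, by = dt)
  x <- v * tt
  geo <- skipack:::planar_to_geo(x, rep(0, length(x)))
  gnss_track(id, tt, geo$lat, geo$lon, rep(0, length(x)))
}
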