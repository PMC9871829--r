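# Reconstruction of distance-time traces from official split times.

# Traces and splits for constant-speed skiers on a straight course.
constant_speed_setup <- function(vs, total = 600, n_cp = 3) {
  co <- straight_course(total)
  ids <- sprintf("cs%02d", seq_along(vs))
  trs <- structure(lapply(seq_along(vs), function(i) {
    project_track(constant_speed_track(vs[i], total, ids[i]), co)
  }), class = "projected_traces")
  names(trs) <- ids
  cpd <- round(seq_len(n_cp) * total / n_cp)
  entries <- do.call(rbind, lapply(seq_along(vs), function(i) {
    data.frame(skier_id = ids[i], checkpoint_id = sprintf("c%d", seq_len(n_cp)),
               course_distance_m = cpd, time_s = cpd / vs[i])
  }))
  list(traces = trs, splits = split_table(entries), ids = ids)
}

test_that("constant-speed training skiers give diagonal shape curves", {
  su <- constant_speed_setup(c(5, 5.5, 6, 6.5, 4.5, 5.2))
  pm <- fit_profile_model(su$traces, su$splits, k = 5)
  for (shape in pm$shapes) {
    frac <- seq(0, 1, length.out = ncol(shape))
    expect_lt(max(abs(sweep(shape, 2, frac))), 0.02)
  }
  # a constant-speed target synthesises to a constant-speed trace
  syn <- synthesize_trace(pm, su$splits, "cs01")
  expect_lt(max(abs(syn$time - syn$distance / 5)), 0.2)
  expect_identical(syn$source, "synthetic")
})

test_that("shapes are monotone from (0,0) to (1,1) on simulator output", {
  rc <- tiny_race(seed = 12, noise = 1, n = 6,
                  skiers = plain_skiers(6, ability = seq(7, 6.5, by = -0.1)))
  trs <- project_tracks(rc$sim$tracks, rc$course)
  pm <- fit_profile_model(trs, rc$sim$splits, k = 3)
  for (j in seq_along(pm$shapes)[-1]) { # interval 1 is gun-anchored
    shape <- pm$shapes[[j]]
    expect_true(all(apply(shape, 1, function(v) all(diff(v) > -1e-9))))
    expect_equal(unname(shape[, 1]), rep(0, nrow(shape)))
    expect_equal(unname(shape[, ncol(shape)]), rep(1, nrow(shape)))
  }
})

test_that("fitting fails below k training skiers", {
  su <- constant_speed_setup(c(5, 6))
  expect_error(fit_profile_model(su$traces, su$splits, k = 5), "at least k")
})

test_that("k = 1 selection returns the nearer pacing archetype", {
  # archetypes differ within the second interval: fade vs negative split
  co <- straight_course(600)
  mk <- function(v1, v2a, v2b, id) {
    brk <- c(300 / v1, 300 / v1 + 150 / v2a)
    tt <- seq(0, brk[2] + 150 / v2b, by = 0.05)
    x <- ifelse(tt <= brk[1], v1 * tt,
                ifelse(tt <= brk[2], 300 + v2a * (tt - brk[1]),
                       450 + v2b * (tt - brk[2])))
    x <- pmin(x, 600)
    geo <- skipack:::planar_to_geo(x, rep(0, length(x)))
    project_track(gnss_track(id, tt, geo$lat, geo$lon, rep(0, length(x))), co)
  }
  trs <- structure(list(mk(6, 6, 4, "fade"), mk(4, 4, 6, "neg")),
                   class = "projected_traces")
  names(trs) <- c("fade", "neg")
  entries <- do.call(rbind, lapply(names(trs), function(id) {
    data.frame(skier_id = id, checkpoint_id = c("c1", "c2"),
               course_distance_m = c(300, 600),
               time_s = skipack:::trace_time_at(trs[[id]], c(300, 600)))
  }))
  # target split vector close to the fade archetype (cp1/cp2 ~ 50/112.5)
  target <- data.frame(skier_id = "t", checkpoint_id = c("c1", "c2"),
                       course_distance_m = c(300, 600),
                       time_s = c(52, 116))
  splits <- split_table(rbind(entries, target))
  pm <- fit_profile_model(trs, splits, k = 1)
  syn <- synthesize_trace(pm, splits, "t")
  # fade shape spends 40% of the interval time over the first half,
  # the negative-split shape 60%: 52 + 0.4 * 64 vs 52 + 0.6 * 64
  expect_lt(abs(skipack:::trace_time_at(syn, 450) - (52 + 0.4 * 64)), 1)
})

test_that("synthesised traces hit every official split exactly", {
  rc <- tiny_race(seed = 13, noise = 1, n = 8,
                  skiers = plain_skiers(8, ability = seq(7, 6.3, by = -0.1),
                                        fatigue = 0.01))
  trs <- project_tracks(rc$sim$tracks, rc$course)
  sm <- skipack:::split_matrix(rc$sim$splits)
  cpd <- rc$sim$splits$checkpoints$distance_m
  for (id in c("sk02", "sk07")) {
    pm <- fit_profile_model(trs[names(trs) != id], rc$sim$splits, k = 4)
    syn <- synthesize_trace(pm, rc$sim$splits, id)
    expect_equal(skipack:::trace_time_at(syn, cpd), unname(sm[id, ]))
    expect_true(all(diff(syn$time) > 0))
    expect_lt(max(abs(syn$time - rc$sim$truth$arrival_1m[id, ])), 3)
  }
})

test_that("a skier with a missing checkpoint is rejected", {
  su <- constant_speed_setup(c(5, 5.5, 6))
  pm <- fit_profile_model(su$traces, su$splits, k = 2)
  partial <- su$splits
  partial$entries <- partial$entries[-1, ]
  expect_error(synthesize_trace(pm, partial, "cs01"), "missing")
})

test_that("synthesised traces keep pack membership consistent downstream", {
  spec <- tiny_spec(n_laps = 4)
  co <- generate_course(spec, seed = 14)
  sk <- make_skiers(12, seed = 14)
  sim <- simulate_race(co, sk, sim_config(seed = 14, gnss_noise_sd = 1,
                                          incident_rate = 0))
  trs <- project_tracks(sim$tracks, co)
  id <- "sk06"
  pm <- fit_profile_model(trs[names(trs) != id], sim$splits, k = 5)
  syn <- synthesize_trace(pm, sim$splits, id)
  mixed <- trs
  mixed[[id]] <- syn
  ps_mixed <- pack_timeline(gap_matrix(mixed))
  # truth-based pack membership of the same skier
  grid <- sim$truth$pack_grid
  true_pack <- vapply(seq_along(grid), function(g) {
    which(vapply(sim$truth$packs[[g]], function(p) id %in% p, logical(1)))[1]
  }, integer(1))
  mixed_pack <- vapply(seq_along(grid), function(g) {
    members <- ps_mixed$packs[[match(grid[g], ps_mixed$grid)]]
    which(vapply(members, function(p) id %in% p, logical(1)))[1]
  }, integer(1))
  # same co-members (pack content), compared by membership sets
  agree <- vapply(seq_along(grid), function(g) {
    setequal(sim$truth$packs[[g]][[true_pack[g]]],
             ps_mixed$packs[[match(grid[g], ps_mixed$grid)]][[mixed_pack[g]]])
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})
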