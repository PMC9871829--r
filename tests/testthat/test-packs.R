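# Pack detection, pack identity, leader-pack loss, accordion and the sprint.

brute_force_packs <- function(times, threshold = 3) {
  ord <- order(times, names(times))
  tt <- times[ord]
  packs <- list(names(tt)[1])
  for (i in seq_along(tt)[-1]) {
    if (tt[i] - tt[i - 1] < threshold) {
      packs[[length(packs)]] <- c(packs[[length(packs)]], names(tt)[i])
    } else {
      packs[[length(packs) + 1]] <- names(tt)[i]
    }
  }
  packs
}

test_that("the 3 s rule is strict: a 3.0 s gap splits the pack", {
  tt <- setNames(c(0, 2.9, 5.9, 9.0), c("a", "b", "c", "d"))
  pk <- detect_packs(tt)
  expect_equal(pk, list(c("a", "b"), "c", "d"))
  expect_equal(detect_packs(setNames(5, "solo")), list("solo"))
})

test_that("detect_packs matches a brute-force oracle on random fields", {
  set.seed(101)
  for (r in 1:1000) {
    n <- sample(2:30, 1)
    tt <- setNames(cumsum(runif(n, 0, 6)), sprintf("s%02d", 1:n))
    # salt in exact-boundary gaps to probe the strict-< rule
    if (r %% 3 == 0 && n > 2) tt[2] <- tt[1] + 3
    expect_identical(detect_packs(tt), brute_force_packs(tt))
  }
})

test_that("two constant-speed skiers produce the closed-form gap", {
  co <- straight_course(600)
  trs <- structure(list(project_track(constant_speed_track(5, 600, "fast"), co),
                        project_track(constant_speed_track(4, 600, "slow"), co)),
                   class = "projected_traces")
  gm <- gap_matrix(trs, grid_step_m = 10)
  expect_equal(unname(gm$behind_leader["slow", ]), gm$grid / 20,
               tolerance = 0.01)
  expect_true(all(gm$behind_leader["fast", ] == 0))
  expect_true(all(gm$behind_winner["fast", ] == 0))
  expect_equal(unname(gm$rank["fast", ]), rep(1, length(gm$grid)))
})

test_that("a single skier has zero gaps and rank one everywhere", {
  co <- straight_course(600)
  trs <- structure(list(project_track(constant_speed_track(5, 600, "only"), co)),
                   class = "projected_traces")
  gm <- gap_matrix(trs)
  expect_true(all(gm$behind_leader == 0))
  expect_true(all(gm$rank == 1))
})

test_that("pack membership is an exhaustive disjoint partition everywhere", {
  rc <- tiny_race(seed = 3, noise = 1, n = 8,
                  skiers = plain_skiers(8, ability = seq(7, 6.3, by = -0.1)))
  gm <- gap_matrix(project_tracks(rc$sim$tracks, rc$course))
  ps <- pack_timeline(gm)
  expect_false(anyNA(ps$membership))
  for (g in seq_along(ps$grid)) {
    expect_setequal(unlist(ps$packs[[g]]), gm$skiers)
  }
  # ranks are a permutation at every grid point
  expect_true(all(apply(gm$rank, 2, sort) == seq_along(gm$skiers)))
})

test_that("identical skiers form one pack with a stable id", {
  rc <- tiny_race(seed = 4, noise = 0, n = 5)
  gm <- gap_matrix(project_tracks(rc$sim$tracks, rc$course))
  ps <- pack_timeline(gm)
  expect_equal(length(unique(as.vector(ps$membership))), 1)
  expect_equal(nrow(ps$events), 0)
})

test_that("a scripted break is located where the pack actually splits", {
  spec <- tiny_spec(n_laps = 6)
  co <- generate_course(spec, seed = 5)
  sk <- plain_skiers(10)
  cfg <- plain_config(seed = 5, noise = 1)
  cfg$scripted_drops <- list(list(skier_ids = sprintf("sk%02d", 6:10),
                                  at_m = 2300, factor = 0.6))
  sim <- simulate_race(co, sk, cfg)
  gm <- gap_matrix(project_tracks(sim$tracks, co))
  ps <- pack_timeline(gm)
  ev <- ps$events[ps$events$type == "split", ]
  expect_gt(nrow(ev), 0)
  first_split <- min(ev$distance_m)
  np <- vapply(sim$truth$packs, length, integer(1))
  truth_split <- sim$truth$pack_grid[which(np > 1)[1]]
  expect_lt(abs(first_split - truth_split), 100)
  expect_lt(abs(first_split - 2300), 150) # shortly after the scripted break
})

test_that("leader-pack loss reports the scripted dropout point and lap", {
  spec <- tiny_spec(n_laps = 6) # 6 x 600 m
  co <- generate_course(spec, seed = 6)
  sk <- plain_skiers(4)
  cfg <- plain_config(seed = 6, noise = 0.5)
  cfg$scripted_drops <- list(list(skier_ids = "sk04", at_m = 2000,
                                  factor = 0.5))
  sim <- simulate_race(co, sk, cfg)
  ps <- pack_timeline(gap_matrix(project_tracks(sim$tracks, co)))
  expect_null(leader_pack_loss(ps, "sk01"))
  loss <- leader_pack_loss(ps, "sk04")
  # 3 s at 50% of ~6 m/s opens within a few tens of metres of the break
  expect_lt(abs(loss$distance_m - 2000), 120)
  expect_equal(loss$lap, 4) # 2000 m into 600 m laps
})

test_that("accordion counts nest over thresholds and exposure is ordered", {
  spec <- tiny_spec(n_laps = 2)
  co <- generate_course(spec, seed = 7)
  sk <- make_skiers(16, seed = 7)
  cfg <- sim_config(seed = 7, gnss_noise_sd = 1, incident_rate = 0)
  sim <- simulate_race(co, sk, cfg)
  gm <- gap_matrix(project_tracks(sim$tracks, co))
  acc <- accordion_summary(gm, groups = setNames(rep(c("front", "rear"), each = 8),
                                                 sprintf("sk%02d", 1:16)))
  # nesting: counts non-decreasing in the threshold at every grid point
  expect_true(all(diff(acc$counts) >= 0))
  expect_true(all(acc$counts <= 16))
  expect_true(all(acc$counts >= 1)) # the leader always counts
  expect_gt(mean(acc$exposure[9:16]), mean(acc$exposure[1:8]))
})

test_that("all skiers within 1 s gives full counts at every threshold", {
  rc <- tiny_race(seed = 8, noise = 0, n = 6)
  gm <- gap_matrix(project_tracks(rc$sim$tracks, rc$course))
  acc <- accordion_summary(gm)
  expect_true(all(acc$counts == 6))
})

test_that("final sprint gaps match the closed form and the scripted scenario", {
  co <- straight_course(3000)
  mk <- function(v, id) project_track(constant_speed_track(v, 3000, id), co)
  trs <- structure(list(mk(6, "w"), mk(5.9, "p2")), class = "projected_traces")
  fs <- final_sprint_gaps(trs, window_m = 1200)
  expect_equal(fs$winner, "w")
  expect_equal(fs$gaps$gap_at_finish_s[fs$gaps$skier_id == "w"], 0)
  expect_equal(fs$gaps$gap_at_finish_s[fs$gaps$skier_id == "p2"],
               3000 / 5.9 - 3000 / 6, tolerance = 0.01)

  # five near-equal skiers sprint within ~2.4 s of each other
  vs <- 6 + cumsum(c(0, rep(-0.004, 4)))
  trs5 <- structure(lapply(1:5, function(i) mk(vs[i], sprintf("s%d", i))),
                    class = "projected_traces")
  fs5 <- final_sprint_gaps(trs5, window_m = 1200)
  want <- 3000 / vs - 3000 / vs[1]
  expect_equal(unname(fs5$gaps$gap_at_finish_s), want, tolerance = 0.1)
  expect_lt(max(fs5$gaps$gap_at_finish_s), 2.5)
})

test_that("group medians of leader-pack loss follow the field structure", {
  spec <- tiny_spec(n_laps = 6)
  co <- generate_course(spec, seed = 9)
  # short test laps: steepen the fatigue gradient so the field still sheds
  # back-to-front within six laps
  sk <- make_skiers(40, seed = 9, fatigue_slope = 2e-4)
  sim <- simulate_race(co, sk, sim_config(seed = 9, gnss_noise_sd = 1))
  ps <- pack_timeline(gap_matrix(project_tracks(sim$tracks, co)))
  groups <- assign_groups(sim$ranks)
  loss <- vapply(names(groups)[!is.na(groups)], function(id) {
    l <- leader_pack_loss(ps, id)
    if (is.null(l)) Inf else l$distance_m
  }, numeric(1))
  med <- tapply(loss, groups[!is.na(groups)], median)
  expect_lte(med[["R31-40"]], med[["R21-30"]])
  expect_lte(med[["R21-30"]], med[["R11-20"]])
  expect_lt(med[["R31-40"]], med[["R11-20"]])
})
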