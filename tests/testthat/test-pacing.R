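# Performance groups, comparison statistics, rank correlation, time in
# terrain and the time-loss decomposition.

# Hand-built speed matrix: one row per skier x lap x segment.
fake_sm <- function(ids, laps, segments, speeds, lengths = 100,
                    labels = "flat") {
  g <- expand.grid(segment_id = segments, lap = laps, skier_id = ids,
                   stringsAsFactors = FALSE)
  g$label <- rep_len(labels, nrow(g))
  g$length_m <- rep_len(lengths, nrow(g))
  g$speed_ms <- speeds
  g$time_s <- g$length_m / g$speed_ms
  structure(g[, c("skier_id", "lap", "segment_id", "label", "length_m",
                  "time_s", "speed_ms")],
            class = c("speed_matrix", "data.frame"))
}

test_that("performance groups follow the rank bands", {
  rl <- rank_list(sprintf("s%02d", 1:45), 1:45, 1:45)
  g <- assign_groups(rl)
  expect_identical(unname(g[rl$final_rank == 1]), "R1-10")
  expect_identical(unname(g[rl$final_rank == 40]), "R31-40")
  expect_true(is.na(g[rl$final_rank == 41]))
  expect_equal(sum(!is.na(g)), 40)
  empty <- assign_groups(rank_list(character(0), integer(0), integer(0)))
  expect_length(empty, 0)
})

test_that("duplicate final ranks are rejected", {
  rl <- rank_list(c("a", "b"), 1:2, c(3, NA))
  rl$final_rank <- c(3L, 3L) # bypass the constructor to hit the check
  expect_error(assign_groups(rl), "duplicate")
})

test_that("Spearman worked examples are exact", {
  r1 <- start_finish_correlation(rank_list(letters[1:5], 1:5, 1:5))
  expect_equal(r1$rho, 1)
  expect_equal(r1$share_within, 1)
  r2 <- start_finish_correlation(rank_list(letters[1:5], 1:5, 5:1))
  expect_equal(r2$rho, -1)
  r3 <- start_finish_correlation(rank_list(letters[1:5], 1:5, c(2, 1, 4, 3, 5)))
  expect_equal(r3$rho, 0.8)
  expect_error(start_finish_correlation(rank_list("a", 1, 1)), "3 finishers")
})

test_that("equal speeds make the time split equal the distance split", {
  sm <- fake_sm("a", 1, paste0("S", 1:3), speeds = 5,
                lengths = c(372, 204, 424),
                labels = c("uphill", "flat", "downhill"))
  tit <- time_in_terrain(sm)
  expect_equal(unname(tit$per_skier$uphill), 37.2)
  expect_equal(unname(tit$per_skier$flat), 20.4)
  expect_equal(unname(tit$per_skier$downhill), 42.4)
  expect_equal(sum(tit$per_skier[, -1]), 100)
})

test_that("slower climbing pushes uphill time share above its distance share", {
  sm <- fake_sm("a", 1, paste0("S", 1:3), speeds = c(2.5, 5, 5),
                lengths = c(372, 204, 424),
                labels = c("uphill", "flat", "downhill"))
  tit <- time_in_terrain(sm)
  expect_gt(tit$per_skier$uphill, 37.2)
  expect_equal(sum(tit$per_skier[, -1]), 100)
})

test_that("time-loss decomposition conserves shares and flags degeneracy", {
  ids <- sprintf("s%02d", 1:20)
  set.seed(2)
  speeds <- c(rnorm(10 * 3, 6, 0.05),      # reference group
              rep(c(4.8, 5.9, 6.9), each = 1, times = 10) + rnorm(30, 0, 0.05))
  sm <- fake_sm(ids, 1, paste0("S", 1:3), speeds = speeds,
                lengths = c(300, 200, 400),
                labels = c("uphill", "flat", "downhill"))
  groups <- setNames(rep(c("R1-10", "R11-20"), each = 10), ids)
  tld <- time_loss_decomposition(sm, groups, reference = "R1-10")
  expect_equal(tld$uphill_share_pct + tld$flat_share_pct +
                 tld$downhill_share_pct, 100)
  expect_false(tld$degenerate)

  # a mirror group with identical times is degenerate: zero loss, NA shares
  sm2 <- fake_sm(ids, 1, paste0("S", 1:3),
                 speeds = rep(speeds[1:30], 2),
                 lengths = c(300, 200, 400),
                 labels = c("uphill", "flat", "downhill"))
  same <- time_loss_decomposition(sm2, groups, reference = "R1-10")
  expect_true(same$degenerate)
  expect_true(is.na(same$uphill_share_pct))
  expect_equal(same$total_loss_s, 0, tolerance = 1e-9)
})

test_that("an uphill-only deficit is attributed almost fully to uphill", {
  spec <- tiny_spec(n_laps = 2)
  co <- generate_course(spec, seed = 10)
  sk <- plain_skiers(20)
  sk$uphill_factor <- rep(c(1, 0.9), each = 10)
  sim <- simulate_race(co, sk, plain_config(seed = 10))
  trs <- project_tracks(sim$tracks, co)
  sm <- speed_matrix(trs, co$segments)
  groups <- assign_groups(sim$ranks)
  tld <- time_loss_decomposition(sm, groups, reference = "R1-10")
  expect_gt(tld$uphill_share_pct[tld$group == "R11-20"], 95)
})

test_that("pairwise differences are antisymmetric and p-values valid", {
  ids <- sprintf("s%02d", 1:30)
  set.seed(3)
  sm <- fake_sm(ids, 2:4, "S1", speeds = rnorm(90, 6, 0.2))
  groups <- setNames(rep(c("A", "B", "C"), each = 10), ids)
  ct <- lap_speed_comparisons(sm, groups)
  ok <- !ct$skipped
  expect_true(all(ct$p_adj[ok] >= 0 & ct$p_adj[ok] <= 1))
  for (i in which(ok & ct$comparison == "between_groups")) {
    j <- which(ct$stratum == ct$stratum[i] & ct$a == ct$b[i] &
                 ct$b == ct$a[i] & ct$comparison == ct$comparison[i])
    expect_equal(ct$diff_ms[j], -ct$diff_ms[i])
  }
})

test_that("lap 1 enters between-lap comparisons only via common segments", {
  ids <- sprintf("s%02d", 1:10)
  set.seed(4)
  sm <- fake_sm(ids, 1:3, paste0("S", 1:4), speeds = rnorm(120, 6, 0.1))
  groups <- setNames(rep("A", 10), ids)
  ct_no <- lap_speed_comparisons(sm, groups)
  expect_false(any(grepl("lap1", c(ct_no$a, ct_no$b)) &
                     ct_no$comparison == "between_laps"))
  ct <- lap_speed_comparisons(sm, groups,
                              lap1_common_segments = c("S1", "S2"))
  bl <- ct[ct$comparison == "between_laps" & !ct$skipped, ]
  expect_true(any(bl$a == "lap1" | bl$b == "lap1"))
})

test_that("groups with a single skier are skipped with a flag", {
  ids <- sprintf("s%02d", 1:11)
  set.seed(5)
  sm <- fake_sm(ids, 2, "S1", speeds = rnorm(11, 6, 0.1))
  groups <- setNames(c(rep("A", 10), "B"), ids)
  ct <- lap_speed_comparisons(sm, groups)
  expect_true(any(ct$skipped & ct$a == "B"))
})

test_that("the comparison machinery holds its nominal type-I error", {
  set.seed(6)
  hits <- vapply(1:300, function(r) {
    ids <- sprintf("s%02d", 1:20)
    sm <- fake_sm(ids, 2, "S1", speeds = rnorm(20, 6, 0.1))
    groups <- setNames(rep(c("A", "B"), each = 10), ids)
    ct <- lap_speed_comparisons(sm, groups)
    any(ct$p_adj[ct$comparison == "between_groups"] < 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})
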