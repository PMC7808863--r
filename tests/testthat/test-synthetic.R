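test_that("parameter constructors reject invalid values", {
  expect_error(arena_spec(dish_radius_px = 300), "fit inside")
  expect_error(arena_spec(food_center = c(450, 200)), "inside the dish")
  expect_error(arena_spec(frame_interval_s = 0), "positive")
  expect_error(behavior_params(bout_duration_mean_s = -1), "positive")
  expect_error(behavior_params(heading_persistence = 1.2), "\\[0, 1\\]")
  expect_error(behavior_params(mode_switch_h = 30), "\\[0, 24\\]")
  expect_error(render_params(larva_intensity = 300), "\\[0, 255\\]")
  expect_error(render_params(dropout_prob = 2), "\\[0, 1\\]")
  expect_error(simulate_trajectory(arena_spec(), mock_params(), -1, 1),
               "positive")
})

test_that("a 24 h record at 3 s resolution has 28 801 frames / 28 800 intervals", {
  # checked via a short record scaled by the same arithmetic, plus the full
  # count from a cheap simulation
  tr <- simulate_trajectory(arena_spec(), mock_params(bout_rate_per_h = 0),
                            24, seed = 1)
  expect_equal(nrow(tr$positions), 28801)
  expect_equal(nrow(tr$intervals), 28800)
})

test_that("zero bout rate yields an entirely stationary, sub-threshold record", {
  tr <- simulate_trajectory(tiny_arena(), mock_params(bout_rate_per_h = 0),
                            0.5, seed = 3)
  expect_true(all(tr$intervals$state == "stationary"))
  expect_true(all(is.na(tr$intervals$bout_index)))
  expect_true(all(truth_steps(tr) < 0.5))
})

test_that("identical inputs and seed reproduce bit-identical trajectories", {
  a <- tiny_arena()
  t1 <- simulate_trajectory(a, mock_params(), 1, seed = 11)
  t2 <- simulate_trajectory(a, mock_params(), 1, seed = 11)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$intervals, t2$intervals)
  t3 <- simulate_trajectory(a, mock_params(), 1, seed = 12)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("every generated position is confined to the dish", {
  a <- tiny_arena()
  for (s in 1:5) {
    p <- mock_params(bout_rate_per_h = 20,
                     mode = if (s %% 2) "food_centered" else "edge_following")
    tr <- simulate_trajectory(a, p, 1, seed = s)
    r <- sqrt((tr$positions$x - a$dish_center[1])^2 +
              (tr$positions$y - a$dish_center[2])^2)
    expect_true(all(r <= a$dish_radius_px))
  }
})

test_that("interval labels are sound: stationary sub-threshold, bouts contiguous", {
  tr <- simulate_trajectory(arena_spec(), mock_params(bout_rate_per_h = 10),
                            2, seed = 7)
  steps <- truth_steps(tr)
  expect_true(all(steps[tr$intervals$state == "stationary"] < 0.5))
  expect_true(all(!is.na(tr$intervals$bout_index[
    tr$intervals$state == "moving"])))
  expect_true(all(is.na(tr$intervals$bout_index[
    tr$intervals$state == "stationary"])))
  # bout indices form contiguous non-overlapping runs 1..B
  bi <- tr$intervals$bout_index[!is.na(tr$intervals$bout_index)]
  runs <- rle(bi)
  expect_equal(runs$values, seq_along(runs$values))
})

test_that("moving step lengths match the stated lognormal mean", {
  means <- vapply(1:20, function(s) {
    tr <- simulate_trajectory(arena_spec(),
                              active_params(step_mean_px = 3), 2, seed = s)
    st <- truth_steps(tr)
    mean(st[tr$intervals$state == "moving"])
  }, numeric(1))
  expect_lt(abs(mean(means) - 3) / 3, 0.10)
})

test_that("cohorts are labelled, sized and seeded deterministically", {
  a <- tiny_arena()
  coh <- make_cohort(a, mock_params(), infected_params(), 6, seed = 42,
                     duration_h = 0.05)
  expect_length(coh, 12)
  expect_equal(sum(vapply(coh, function(l) l$group, "") == "mock"), 6)
  expect_equal(sum(vapply(coh, function(l) l$group, "") == "infected"), 6)
  seeds <- vapply(coh, function(l) l$seed, integer(1))
  expect_false(anyDuplicated(seeds) > 0)
  coh2 <- make_cohort(a, mock_params(), infected_params(), 6, seed = 42,
                      duration_h = 0.05)
  expect_identical(coh[[3]]$truth$positions, coh2[[3]]$truth$positions)
})

test_that("infected defaults travel farther than mock in every replicate cohort", {
  a <- arena_spec()
  med <- function(coh, g) {
    m <- cohort_metrics(coh)
    stats::median(m$total_distance_px[m$group == g])
  }
  wins <- vapply(1:20, function(s) {
    coh <- make_cohort(a, mock_params(), infected_params(), 3,
                       seed = 100 + s, duration_h = 6)
    med(coh, "infected") > med(coh, "mock")
  }, logical(1))
  expect_true(all(wins))
})
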