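test_that("to_greyscale averages channels with half-up rounding", {
  f <- array(0, c(2, 2, 3))
  f[1, 1, ] <- c(200, 200, 200)
  f[1, 2, ] <- c(255, 0, 0)
  g <- to_greyscale(f)
  expect_equal(g[1, 1], 200L)
  expect_equal(g[1, 2], 85L)
  expect_equal(g[2, 1], 0L)
  expect_identical(to_greyscale(matrix(7L, 3, 3)), matrix(7L, 3, 3))
  expect_error(to_greyscale(array(0, c(2, 2, 2))), "channels")
})

test_that("background model is the per-pixel mean and is order-invariant", {
  f1 <- matrix(10, 4, 4)
  f2 <- matrix(20, 4, 4)
  stk <- frame_stack(list(f1, f2))
  expect_equal(build_background(stk), matrix(15, 4, 4))
  same <- frame_stack(list(f1, f1, f1))
  expect_equal(build_background(same), f1)
  set.seed(1)
  fr <- lapply(1:6, function(i) matrix(sample(0:255, 16, TRUE), 4, 4))
  bg1 <- build_background(frame_stack(fr))
  bg2 <- build_background(frame_stack(rev(fr)))
  expect_equal(bg1, bg2)
  expect_error(build_background(frame_stack(list(f1))), "2 frames")
})

test_that("subtraction and binarization follow the threshold rules", {
  bg <- matrix(10, 20, 20)
  f <- bg
  expect_false(any(subtract_and_binarize(f, bg, "otsu")))
  f2 <- bg
  f2[3:7, 3:7] <- 200
  m <- subtract_and_binarize(f2, bg, "fixed", threshold = 50)
  expect_equal(sum(m), 25)
  expect_true(all(m[3:7, 3:7]))
  expect_error(subtract_and_binarize(f2, matrix(0, 3, 3), "otsu"),
               "dimensions")
  # monotonicity: raising a fixed threshold never adds mask pixels
  set.seed(2)
  fr <- matrix(sample(0:255, 400, TRUE), 20, 20)
  m1 <- subtract_and_binarize(fr, bg, "fixed", threshold = 40)
  m2 <- subtract_and_binarize(fr, bg, "fixed", threshold = 90)
  expect_true(all(m1 | !m2))
})

test_that("Otsu threshold maximizes between-class variance (brute force)", {
  set.seed(4)
  for (i in 1:5) {
    img <- matrix(round(c(rnorm(900, 40, 8), rnorm(100, 180, 12))), 100, 10)
    img <- pmin(255, pmax(0, img))
    v <- as.integer(round(img))
    bcv <- vapply(0:254, function(t) {
      w0 <- mean(v <= t)
      if (w0 == 0 || w0 == 1) return(0)
      w0 * (1 - w0) * (mean(v[v <= t]) - mean(v[v > t]))^2
    }, numeric(1))
    expect_equal(otsu_threshold(img), which.max(bcv) - 1L)
  }
})

test_that("detect_particles computes centroids, filters by area, sorts by size", {
  m <- matrix(FALSE, 40, 40)
  m[20:22, 10:12] <- TRUE              # 3x3: top-left (x=10, y=20)
  det <- detect_particles(m, min_area = 1)
  expect_equal(nrow(det), 1)
  expect_equal(det$x, 11)
  expect_equal(det$y, 21)
  expect_equal(det$area, 9L)

  m[5:6, 30:31] <- TRUE                # 2x2 block, area 4
  det2 <- detect_particles(m, min_area = 5)
  expect_equal(nrow(det2), 1)
  expect_equal(det2$area, 9L)
  det3 <- detect_particles(m, min_area = 1)
  expect_equal(det3$area, c(9L, 4L))   # sorted by area descending

  expect_equal(nrow(detect_particles(matrix(FALSE, 5, 5))), 0)
})

test_that("labeling is 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE
  m[2, 2] <- TRUE                      # diagonal touch: one component
  det <- detect_particles(m, min_area = 1)
  expect_equal(nrow(det), 1)
  expect_equal(det$area, 2L)
})

test_that("particle detection matches a flood-fill oracle on random masks", {
  set.seed(10)
  for (i in 1:50) {
    m <- matrix(runif(64 * 64) < runif(1, 0.05, 0.6), 64, 64)
    got <- canon_particles(detect_particles(m, min_area = 1))
    want <- oracle_particles(m)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("track_stack recovers a continuously moving larva end to end", {
  # idealized conditions for the sub-pixel invariant: the larva never rests
  # (so the background model is unbiased) and there is no food blob to
  # occlude it; rest-anchor ghosts are a documented limitation
  a <- arena_spec(width_px = 120, height_px = 100, dish_center = c(60, 50),
                  dish_radius_px = 45, food_center = c(60, 50),
                  food_radius_px = 0, frame_interval_s = 3)
  p <- mock_params(bout_rate_per_h = 60, bout_duration_mean_s = 36000,
                   step_mean_px = 3)
  tr <- simulate_trajectory(a, p, 200 * 3 / 3600, seed = 2)
  stk <- render_frames(tr, a, render_params(noise_sd = 0), seed = 3)
  det <- track_stack(stk)
  traj <- clean_detections(det, a, n_frames = length(stk))
  tt <- attr(stk, "truth_table")
  err <- sqrt((traj$x - tt$x)^2 + (traj$y - tt$y)^2)
  detected <- traj$provenance %in% c("detected", "averaged")
  expect_gt(mean(detected), 0.95)
  expect_true(all(err[detected] < 0.5))
})

test_that("an all-identical stack yields no detections", {
  f <- matrix(50, 30, 30)
  stk <- frame_stack(list(f, f, f))
  det <- track_stack(stk)
  expect_equal(nrow(det), 0)
  expect_equal(attr(det, "counts"), c(0L, 0L, 0L))
})
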