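test_that("summarize_flow matches the printed conventions and an oracle", {
  h <- 4; w <- 5
  up <- flow_field(matrix(0, h, w), matrix(-2, h, w))     # v file-down = -2
  s <- summarize_flow(up, eps = 1)
  expect_equal(s$median_direction, 90)
  expect_equal(s$median_magnitude, 2)
  right <- flow_field(matrix(1, h, w), matrix(0, h, w))
  s2 <- summarize_flow(right, eps = 0.5)
  expect_equal(s2$median_direction, 0)
  expect_equal(s2$median_magnitude, 1)
  # zero moving pixels -> undefined
  still <- summarize_flow(flow_field(matrix(0.1, h, w), matrix(0, h, w)), eps = 1)
  expect_false(still$defined)

  set.seed(42)
  for (rep in 1:20) {
    u <- matrix(stats::rnorm(64, sd = 3), 8, 8)
    v <- matrix(stats::rnorm(64, sd = 3), 8, 8)
    s <- summarize_flow(flow_field(u, v), eps = 1.5)
    o <- oracle_summary(u, v, 1.5)
    expect_equal(s$median_direction, o$direction)
    expect_equal(s$median_magnitude, o$magnitude)
    expect_equal(s$n_moving, o$n)
  }
})

test_that("take-off detection follows the run-then-preceding-downward rule", {
  mk <- function(classes) {
    lapply(seq_along(classes), function(t) {
      d <- switch(classes[t], up = 90, down = 270, none = 0)
      make_summary(t, d, 5, defined = classes[t] != "undef")
    })
  }
  s <- mk(c(rep("down", 40), rep("up", 35)))
  expect_equal(detect_takeoff(s, window = 30), 40)
  # shorter run than the window -> error
  expect_error(detect_takeoff(mk(c(rep("down", 10), rep("up", 20))), 30),
               class = "no_takeoff_error")
  # run at the start with no preceding downward frame -> error
  expect_error(detect_takeoff(mk(rep("up", 40)), 30),
               class = "no_takeoff_error")
  # neither-class frames are skipped when walking back
  s2 <- mk(c(rep("down", 5), rep("none", 3), rep("up", 31)))
  expect_equal(detect_takeoff(s2, window = 30), 5)
})

test_that("take-off and thrust equal brute-force oracles on random sequences", {
  set.seed(99)
  n_agree_t <- 0; n_agree_h <- 0
  for (rep in 1:300) {
    s <- random_summaries(60, p_undef = 0.15)
    got <- tryCatch(detect_takeoff(s, window = 4), error = function(e) NA_integer_)
    expect_identical(got, oracle_takeoff(s, 4))
    cs <- sample(1:20, 1)
    got2 <- tryCatch(detect_thrust(s, cs, lookback = 3, mag_lo = 4, mag_hi = 16),
                     error = function(e) NA_integer_)
    expect_identical(got2, oracle_thrust(s, cs, 3, 4, 16))
    if (!is.na(got)) n_agree_t <- n_agree_t + 1
    if (!is.na(got2)) n_agree_h <- n_agree_h + 1
  }
  # the random worlds actually exercise the detectors, not just the errors
  expect_gt(n_agree_t, 30)
  expect_gt(n_agree_h, 30)
})

test_that("detection is translation invariant", {
  set.seed(7)
  for (rep in 1:20) {
    s <- random_summaries(50, p_undef = 0.1)
    k <- sample(1:10, 1)
    shifted <- c(lapply(seq_len(k), function(t) make_summary(t, 0, 0, FALSE)), s)
    t1 <- tryCatch(detect_takeoff(s, 4), error = function(e) NA)
    t2 <- tryCatch(detect_takeoff(shifted, 4), error = function(e) NA)
    expect_equal(t2, if (is.na(t1)) NA else t1 + k)
    h1 <- tryCatch(detect_thrust(s, 10, 3, 4, 16), error = function(e) NA)
    h2 <- tryCatch(detect_thrust(shifted, 10 + k, 3, 4, 16),
                   error = function(e) NA)
    expect_equal(h2, if (is.na(h1)) NA else h1 + k)
  }
})

test_that("barycenter matches the coordinate-sum formula", {
  m <- matrix(FALSE, 6, 8)
  m[3, 4] <- TRUE                       # x = 3, y = 6 - 3 = 3
  expect_equal(barycenter(m), c(x = 3, y = 3))
  m2 <- matrix(FALSE, 10, 10); m2[3:6, 2:5] <- TRUE
  expect_equal(barycenter(m2), c(x = 2.5, y = 5.5))
  set.seed(3)
  for (rep in 1:10) {
    m3 <- matrix(stats::runif(80) < 0.3, 8, 10)
    if (!any(m3)) next
    idx <- which(m3, arr.ind = TRUE)
    expect_equal(barycenter(m3),
                 c(x = mean(idx[, 2] - 1), y = mean(8 - idx[, 1])))
  }
  expect_error(barycenter(matrix(FALSE, 3, 3)), class = "empty_mask_error")
})

test_that("lower-body split keeps the trailing side and partitions the mask", {
  bar <- matrix(FALSE, 5, 11); bar[3, 2:10] <- TRUE     # horizontal bar
  lb <- lower_body_mask(bar, "leftward")
  xs <- which(lb, arr.ind = TRUE)[, 2] - 1
  expect_true(all(xs > barycenter(bar)["x"]))           # right half kept
  rb <- lower_body_mask(bar, "rightward")
  expect_true(all((which(rb, arr.ind = TRUE)[, 2] - 1) < barycenter(bar)["x"]))
  set.seed(5)
  for (rep in 1:10) {
    m <- matrix(stats::runif(60) < 0.4, 6, 10)
    if (!any(m)) next
    keep <- lower_body_mask(m, "leftward")
    disc <- m & !keep
    expect_identical(keep | disc, m)
    expect_false(any(keep & disc))
  }
})

test_that("contact start requires a strictly-longer-than-threshold run", {
  wheel <- matrix(FALSE, 20, 20); wheel[12:14, 9:11] <- TRUE
  touch <- matrix(FALSE, 20, 20); touch[10:11, 10:12] <- TRUE  # overlaps when dilated
  clear <- matrix(FALSE, 20, 20); clear[2:3, 14:16] <- TRUE
  mk <- function(gym, t) mask_pair(wheel, gym, t)
  meta <- video_meta(fps = 60, width = 20, height = 20, n_frames = 200)

  masks <- c(lapply(1:49, mk, gym = clear), lapply(50:120, mk, gym = touch),
             lapply(121:140, mk, gym = clear))
  expect_equal(detect_contact_start(masks, meta, 0.5), 50)
  # 30 frames at 60 fps is not strictly more than 0.5 s
  masks2 <- c(lapply(1:49, mk, gym = clear), lapply(50:79, mk, gym = touch),
              lapply(80:100, mk, gym = clear))
  expect_error(detect_contact_start(masks2, meta, 0.5),
               class = "no_contact_error")
  masks3 <- c(lapply(1:49, mk, gym = clear), lapply(50:80, mk, gym = touch))
  expect_equal(detect_contact_start(masks3, meta, 0.5), 50)
  # random run layouts agree with a naive scan
  set.seed(11)
  for (rep in 1:20) {
    pattern <- stats::runif(80) < 0.4
    masks4 <- lapply(seq_along(pattern), function(t) {
      mk(if (pattern[t]) touch else clear, t)
    })
    got <- tryCatch(detect_contact_start(masks4, meta, 0.1),
                    error = function(e) NA_integer_)
    expect_identical(got, oracle_contact(pattern, 0.1 * 60))
  }
})

test_that("pike-mount is the argmax barycenter height with earliest-tie rule", {
  mk_at <- function(row) {
    g <- matrix(FALSE, 30, 10); g[row, 4:6] <- TRUE
    mask_pair(matrix(FALSE, 30, 10), g, 1)
  }
  rows <- c(25, 24, 20, 15, 10, 8, 12, 14, 20, 24)  # height peaks at frame 6
  masks <- lapply(rows, mk_at)
  expect_equal(detect_pikemount(masks, 1, 10), 6)
  # tie -> earliest
  rows2 <- c(25, 10, 20, 10, 25)
  expect_equal(detect_pikemount(lapply(rows2, mk_at), 1, 5), 2)
  # monotone rising -> last frame before contact
  rows3 <- 25:16
  expect_equal(detect_pikemount(lapply(rows3, mk_at), 1, 10), 9)
  expect_error(detect_pikemount(masks, 5, 6), class = "ordering_error")
})

test_that("thrust detection honours the magnitude band", {
  mk <- function(classes, mags) {
    lapply(seq_along(classes), function(t) {
      d <- switch(classes[t], up = 90, down = 270, none = 0)
      make_summary(t, d, mags[t])
    })
  }
  cls <- c(rep("down", 30), rep("up", 5))
  mags <- c(rep(2, 20), rep(8, 10), rep(3, 5))
  expect_equal(detect_thrust(mk(cls, mags), contact_start = 5), 31)
  # magnitude above the band: landing-scale motion is rejected
  mags2 <- c(rep(2, 20), rep(20, 10), rep(3, 5))
  expect_error(detect_thrust(mk(cls, mags2), contact_start = 5),
               class = "no_thrust_error")
  # below the band
  mags3 <- c(rep(2, 30), rep(3, 5))
  expect_error(detect_thrust(mk(cls, mags3), contact_start = 5),
               class = "no_thrust_error")
})

test_that("extract_events recovers ground truth and fails cleanly", {
  p <- simulate_performance(zero_noise_config(seed = 21,
                                              ride_time_range = c(3, 3)),
                            1, 1, render = TRUE)
  ev <- extract_events(p$series)
  expect_identical(unclass(ev), unclass(p$truth$event_frames))

  # truncated series ending before the ride -> failure carrying the stage
  short <- p$series
  short$flows <- short$flows[1:90]
  short$masks <- short$masks[1:90]
  short$meta$n_frames <- 90L
  err <- tryCatch(extract_events(short), wheelvault_error = function(e) e)
  expect_s3_class(err, "event_extraction_error")

  # shuffled frames break detection
  set.seed(1)
  shuf <- p$series
  o <- sample(seq_along(shuf$flows))
  shuf$flows <- shuf$flows[o]
  expect_error(extract_events(shuf), class = "event_extraction_error")
})

test_that("events are recovered within one frame at default noise", {
  cfg <- synth_config(seed = 1234)
  ok <- 0L; n <- 50L
  for (k in seq_len(n)) {
    p <- simulate_performance(cfg, day = (k - 1) %/% 13 + 1,
                              i = (k - 1) %% 13 + 1, render = TRUE)
    ev <- tryCatch(extract_events(p$series), error = function(e) NULL)
    if (!is.null(ev) &&
        max(abs(unclass(ev) - unclass(p$truth$event_frames))) <= 1) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n, 0.95)
})
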