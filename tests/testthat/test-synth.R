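test_that("same seed gives bit-identical performances", {
  cfg <- tiny_config(seed = 5)
  a <- simulate_performance(cfg, 1, 1, render = TRUE)
  b <- simulate_performance(cfg, 1, 1, render = TRUE)
  expect_identical(a$series$keypoints, b$series$keypoints)
  expect_identical(a$series$flows, b$series$flows)
  expect_identical(a$truth, b$truth)
  # different substream differs
  c2 <- simulate_performance(cfg, 1, 2, render = FALSE)
  expect_false(identical(a$truth$true_time_on_wheel,
                         c2$truth$true_time_on_wheel))
})

test_that("ground-truth events are strictly ordered and in range", {
  cfg <- tiny_config(seed = 2)
  for (i in 1:3) {
    p <- simulate_performance(cfg, 1, i, render = FALSE)
    ev <- p$truth$event_frames
    expect_true(ev["takeoff"] < ev["pikemount"])
    expect_true(ev["pikemount"] < ev["contact_start"])
    expect_true(ev["contact_start"] < ev["thrust"])
    expect_true(ev["thrust"] <= p$series$meta$n_frames)
  }
})

test_that("zero-noise judge mean equals the planted deduction", {
  cfg <- zero_noise_config(seed = 3, ride_time_range = c(3, 6.5),
                           knee_angle_range = c(150, 180))
  for (i in 1:4) {
    tr <- simulate_performance(cfg, 1, i, render = FALSE)$truth
    expect_equal(mean(tr$judge_scores), tr$true_deduction)
    expect_equal(tr$true_deduction,
                 regulation_time_deduction(tr$true_time_on_wheel) +
                   cfg$knee_penalty_rate *
                   max(0, cfg$straight_leg_threshold - tr$true_knee_angle_pikemount))
  }
})

test_that("generate_dataset has the right size, day tags and ride spread", {
  cfg <- synth_config(seed = 9, n_days = 8, performances_per_day = 13,
                      ride_time_range = c(3, 7))
  ds <- generate_dataset(cfg, render = FALSE)
  expect_length(ds, 104)
  days <- vapply(ds, function(p) p$truth$day, integer(1))
  expect_identical(sort(unique(days)), 1:8)
  expect_true(all(table(days) == 13))
  tows <- vapply(ds, function(p) p$truth$true_time_on_wheel, numeric(1))
  # quantised to the frame grid, so allow half a frame at the bounds
  expect_true(all(tows >= 3 - 1 / 60 & tows <= 7 + 1 / 60))
  expect_lt(min(tows), 3.5)
  expect_gt(max(tows), 6.5)
})

test_that("masks are disjoint before contact and intersect during the ride", {
  p <- simulate_performance(zero_noise_config(seed = 4,
                                              ride_time_range = c(3, 3)),
                            1, 1, render = TRUE)
  ev <- p$truth$event_frames
  raw_overlap <- vapply(p$series$masks, function(m) any(m$wheel & m$gymnast),
                        logical(1))
  expect_false(any(raw_overlap[1:(ev["contact_start"] - 1)]))
  dil_overlap <- vapply(p$series$masks, function(m) {
    any(wheelvault:::dilate1(m$gymnast) & m$wheel)
  }, logical(1))
  expect_true(all(dil_overlap[ev["contact_start"]:ev["thrust"]]))
})

test_that("zero-noise flow matches the keypoint displacement on rigid frames", {
  p <- simulate_performance(zero_noise_config(seed = 6,
                                              ride_time_range = c(3, 3)),
                            1, 1, render = TRUE)
  # frames 2..39 are a rigid whole-body translation of the run pose
  for (t in c(5, 15, 30)) {
    fl <- p$series$flows[[t]]
    g <- p$series$masks[[t]]$gymnast
    disp <- p$series$keypoints[[t + 1]]$points["hip", ] -
      p$series$keypoints[[t]]$points["hip", ]
    expect_equal(stats::median(fl$u[g]), unname(disp["x"]), tolerance = 1e-9)
    expect_equal(stats::median(-fl$v[g]), unname(disp["y"]), tolerance = 1e-9)
  }
  # cumulative: summed median flow tracks the net hip displacement
  g_med_u <- vapply(seq_along(p$series$flows), function(t) {
    g <- p$series$masks[[t]]$gymnast
    stats::median(p$series$flows[[t]]$u[g])
  }, numeric(1))
  net <- p$series$keypoints[[p$series$meta$n_frames]]$points["hip", "x"] -
    p$series$keypoints[[1]]$points["hip", "x"]
  expect_lt(abs(sum(g_med_u) - net) / length(g_med_u), 1)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(ride_time_range = c(5, 3)))
  expect_error(synth_config(judge_noise_sd = -1))
  expect_error(simulate_performance(synth_config(ride_time_range = c(0.05, 0.05)),
                                    1, 1, render = FALSE),
               class = "config_error")
})

test_that("synth_records builds the canonical table with planted features", {
  cfg <- zero_noise_config(seed = 8, n_days = 2, performances_per_day = 3)
  rec <- synth_records(cfg)
  expect_equal(nrow(rec), 6)
  expect_true(all(feature_names() %in% names(rec)))
  truth <- attr(rec, "truth")
  for (k in seq_len(nrow(rec))) {
    expect_equal(rec$time_on_wheel[k], truth[[k]]$true_time_on_wheel)
    expect_equal(rec$knee_pikemount[k], truth[[k]]$true_knee_angle_pikemount,
                 tolerance = 1e-6)
    expect_equal(rec$mean_deduction[k], truth[[k]]$true_deduction)
  }
  # ideal pike: hips above shoulders and feet above hands, both positive
  expect_true(all(rec$hips_above_shoulders > 0))
  expect_true(all(rec$feet_above_hands > 0))
})
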