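#' Video metadata
#'
#' Recording metadata shared by every per-frame artifact of a performance.
#' The default frame rate matches the 60 fps action-camera footage the
#' detection windows are calibrated for; the default raster is deliberately
#' small so that mask and flow rendering stays fast in tests.
#'
#' @param fps frames per second (> 0).
#' @param width,height raster size in pixels (>= 1).
#' @param n_frames number of frames (>= 1).
#' @param motion_direction travel direction of the gymnast on screen,
#'   `"leftward"` (the recording setup emulated here) or `"rightward"`.
#' @return an object of class `video_meta`.
#' @export
video_meta <- function(fps = 60, width = 160, height = 120, n_frames = 1L,
                       motion_direction = c("leftward", "rightward")) {
  motion_direction <- match.arg(motion_direction)
  stopifnot(is.numeric(fps), length(fps) == 1, fps > 0,
            width >= 1, height >= 1, n_frames >= 1)
  structure(list(fps = fps, width = as.integer(width),
                 height = as.integer(height), n_frames = as.integer(n_frames),
                 motion_direction = motion_direction),
            class = "video_meta")
}

#' Synthetic-performance configuration
#'
#' Stated world for the vault simulator.  A performance follows the scripted
#' Unit-2 phases (run-up with a crouch, jump to the pike apex, descent onto
#' the wheel, a ride of configurable duration, a squat and the extension into
#' the thrust).  The ground-truth deduction is driven by time on the wheel
#' (regulation ramp) and by how far the pike-mount knee angle falls below the
#' straight-leg threshold, plus independent judge noise.
#'
#' Defaults: ride times span 3--7 s so every regulation band is populated;
#' pike knee angles span 145--180 degrees around the 162.5 degree straight-leg
#' threshold; the knee penalty rate (0.015 deduction per degree of bend below
#' threshold) keeps the knee contribution clearly second to time on the wheel,
#' mirroring the importance ordering seen on real mounts; judge noise sd 0.05
#' is well under the judges' 0.1 scoring grain.
#'
#' @param seed integer master seed; all randomness flows from it through
#'   per-performance substreams (never the global RNG state).
#' @param n_days number of recording sessions.
#' @param performances_per_day performances per session.
#' @param ride_time_range seconds, `c(low, high)` for the uniform true time on
#'   the wheel.
#' @param knee_angle_range degrees, `c(low, high)` for the uniform true
#'   pike-mount knee angle.
#' @param knee_penalty_rate deduction per degree below
#'   `straight_leg_threshold`.
#' @param straight_leg_threshold degrees; knee angles above it draw no
#'   deduction.
#' @param judge_noise_sd sd of the i.i.d. Gaussian noise added to each judge's
#'   deduction (clipped to the 0--6 score range).
#' @param flow_noise_sd sd in px/frame of the Gaussian noise added to each
#'   rendered flow component.
#' @param pose_jitter_sd degrees; per-performance jitter applied to the
#'   non-planted pose parameters so that nuisance features vary.
#' @param meta a [video_meta()] (its `n_frames` is ignored; the script length
#'   determines it).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_days = 8L,
                         performances_per_day = 13L,
                         ride_time_range = c(3, 7),
                         knee_angle_range = c(145, 180),
                         knee_penalty_rate = 0.015,
                         straight_leg_threshold = 162.5,
                         judge_noise_sd = 0.05,
                         flow_noise_sd = 0.3,
                         pose_jitter_sd = 3,
                         meta = video_meta()) {
  stopifnot(length(ride_time_range) == 2, ride_time_range[1] <= ride_time_range[2],
            ride_time_range[1] >= 0,
            length(knee_angle_range) == 2,
            knee_angle_range[1] <= knee_angle_range[2],
            knee_angle_range[1] > 0, knee_angle_range[2] <= 180,
            judge_noise_sd >= 0, flow_noise_sd >= 0, pose_jitter_sd >= 0,
            knee_penalty_rate >= 0,
            n_days >= 1, performances_per_day >= 1,
            inherits(meta, "video_meta"))
  structure(list(seed = as.integer(seed),
                 n_days = as.integer(n_days),
                 performances_per_day = as.integer(performances_per_day),
                 ride_time_range = as.numeric(ride_time_range),
                 knee_angle_range = as.numeric(knee_angle_range),
                 knee_penalty_rate = knee_penalty_rate,
                 straight_leg_threshold = straight_leg_threshold,
                 judge_noise_sd = judge_noise_sd,
                 flow_noise_sd = flow_noise_sd,
                 pose_jitter_sd = pose_jitter_sd,
                 meta = meta),
            class = "synth_config")
}

# Derive an independent RNG substream seed for performance `i` of day `day`.
# Counter-based so streams never depend on global state or draw order; kept
# below 2^31 - 1.
substream_seed <- function(master, day, i, salt = 0L) {
  as.integer((as.numeric(master) * 2654435.0 + day * 97003 + i * 641 + salt) %%
               2147483587)
}

# Evaluate a function with a private RNG stream, restoring global state.
with_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}
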