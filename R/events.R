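# Key-frame event detection for Unit 2: take-off and thrust from optical-flow
# direction runs, start of time on the wheel from mask contact, pike-mount
# from the barycenter height of the gymnast mask.

#' Summarise a dense flow field
#'
#' Over pixels moving faster than `eps`, computes the median flow direction
#' and magnitude.  Directions use theta = atan2(-v, u) mapped to \[0, 360)
#' so that with image-convention `v` (downward positive) upward motion lies
#' in the open interval (0, 180) and downward motion in (180, 360).  The
#' median of directions is the ordinary (non-circular) median.  With no
#' moving pixel both statistics are flagged undefined.
#'
#' @param field a [flow_field()].
#' @param eps moving-pixel threshold in px/frame (strict `>`); the default
#'   1.0 excludes static background.
#' @param frame_index carried through for bookkeeping.
#' @return a `flow_summary`: frame_index, median_direction, median_magnitude,
#'   n_moving, defined.
#' @export
summarize_flow <- function(field, eps = 1.0, frame_index = NA_integer_) {
  stopifnot(inherits(field, "flow_field"), eps >= 0)
  mag <- sqrt(field$u^2 + field$v^2)
  mov <- mag > eps
  n <- sum(mov)
  if (n == 0) {
    return(structure(list(frame_index = as.integer(frame_index),
                          median_direction = NA_real_,
                          median_magnitude = NA_real_,
                          n_moving = 0L, defined = FALSE),
                     class = "flow_summary"))
  }
  theta <- atan2(-field$v[mov], field$u[mov]) * 180 / pi
  theta <- theta %% 360
  structure(list(frame_index = as.integer(frame_index),
                 median_direction = stats::median(theta),
                 median_magnitude = stats::median(mag[mov]),
                 n_moving = as.integer(n), defined = TRUE),
            class = "flow_summary")
}

#' @rdname summarize_flow
#' @param flows list of [flow_field()]s (element t = motion from frame t to
#'   t + 1).
#' @export
summarize_flows <- function(flows, eps = 1.0) {
  lapply(seq_along(flows), function(t) {
    summarize_flow(flows[[t]], eps = eps, frame_index = t)
  })
}

# direction class of a summary: "up" iff 0 < theta < 180, "down" iff
# 180 < theta < 360; exactly 0/180 or an undefined frame is neither and
# breaks runs.
direction_class <- function(s) {
  if (!isTRUE(s$defined)) return("none")
  th <- s$median_direction %% 360
  if (th > 0 && th < 180) "up" else if (th > 180 && th < 360) "down" else "none"
}

summary_classes <- function(summaries) {
  vapply(summaries, direction_class, character(1))
}

#' Detect the take-off frame
#'
#' Finds the first run of at least `window` consecutive frames with upward
#' median flow, then returns the nearest preceding frame whose median flow is
#' downward — the last frame before the jump.  The default window of 30
#' frames corresponds to 0.5 s at 60 fps.
#'
#' @param summaries list of `flow_summary` (frame t = motion t -> t + 1).
#' @param window minimum length of the upward run (frames, >= 1).
#' @return frame index of the take-off.
#' @export
detect_takeoff <- function(summaries, window = 30L) {
  stopifnot(window >= 1)
  cls <- summary_classes(summaries)
  n <- length(cls)
  run <- 0L
  for (t in seq_len(n)) {
    run <- if (cls[t] == "up") run + 1L else 0L
    if (run >= window) {
      start <- t - run + 1L
      prev <- start - 1L
      while (prev >= 1L && cls[prev] != "down") prev <- prev - 1L
      if (prev < 1L) {
        wv_stop("no_takeoff_error",
                "upward run has no preceding downward frame")
      }
      return(prev)
    }
  }
  wv_stop("no_takeoff_error",
          sprintf("no run of %d consecutive upward frames", window))
}

#' Barycenter of a binary mask
#'
#' Arithmetic mean of the foreground pixel coordinates, reported in analysis
#' coordinates (x rightward from 0, y up from 0 at the bottom row).
#'
#' @param mask logical matrix, row 1 = top of the image.
#' @return c(x, y).
#' @export
barycenter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) wv_stop("empty_mask_error", "mask has no foreground pixels")
  c(x = mean(idx[, 2] - 1), y = mean(nrow(mask) - idx[, 1]))
}

#' Lower-body half of the gymnast mask
#'
#' The lower body is the trailing side of the barycenter: for leftward travel
#' pixels strictly to the right of the barycenter x, mirrored for rightward
#' travel.  An empty result is allowed (the caller sees an all-FALSE mask).
#'
#' @param gymnast logical matrix.
#' @param motion_direction `"leftward"` or `"rightward"`.
#' @return logical matrix of the retained pixels.
#' @export
lower_body_mask <- function(gymnast, motion_direction = c("leftward", "rightward")) {
  motion_direction <- match.arg(motion_direction)
  bc <- barycenter(gymnast)
  xs <- matrix(rep(seq_len(ncol(gymnast)) - 1, each = nrow(gymnast)),
               nrow = nrow(gymnast))
  keep <- if (motion_direction == "leftward") xs > bc["x"] else xs < bc["x"]
  gymnast & keep
}

# 1-px binary dilation (8-neighbourhood) so touching-but-not-overlapping
# masks count as contact
dilate1 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  out <- mask
  out[-1, ] <- out[-1, ] | mask[-h, ]
  out[-h, ] <- out[-h, ] | mask[-1, ]
  out[, -1] <- out[, -1] | out[, -w]
  out[, -w] <- out[, -w] | out[, -1]
  out
}

mask_contact <- function(mp, motion_direction) {
  if (!any(mp$gymnast)) return(FALSE)
  lb <- lower_body_mask(mp$gymnast, motion_direction)
  if (!any(lb)) return(FALSE)
  any(dilate1(lb) & mp$wheel)
}

#' Detect the start of time on the wheel
#'
#' Contact holds at a frame when the 1-px dilated lower-body mask intersects
#' the wheel mask.  Returns the first frame of the first contact run strictly
#' longer than `min_contact_s * fps` frames, rejecting brief grazes (hands at
#' take-off, shoulders near the pike).
#'
#' @param masks list of [mask_pair()] per frame.
#' @param meta a [video_meta()] (fps and motion direction).
#' @param min_contact_s minimum contact duration in seconds (strict `>`).
#' @return frame index of the contact start.
#' @export
detect_contact_start <- function(masks, meta, min_contact_s = 0.5) {
  stopifnot(min_contact_s > 0)
  need <- min_contact_s * meta$fps
  contact <- vapply(masks, mask_contact, logical(1),
                    motion_direction = meta$motion_direction)
  n <- length(contact)
  t <- 1L
  while (t <= n) {
    if (contact[t]) {
      end <- t
      while (end < n && contact[end + 1L]) end <- end + 1L
      if (end - t + 1L > need) return(t)
      t <- end + 1L
    }
    t <- t + 1L
  }
  wv_stop("no_contact_error",
          sprintf("no contact run longer than %.2f s", min_contact_s))
}

#' Detect the pike-mount frame
#'
#' Among frames strictly between take-off and contact start, returns the one
#' whose gymnast-mask barycenter is highest (ties resolved to the earliest
#' frame).
#'
#' @param masks list of [mask_pair()].
#' @param takeoff,contact_start frame indices, `takeoff < contact_start`.
#' @return frame index of the pike-mount.
#' @export
detect_pikemount <- function(masks, takeoff, contact_start) {
  if (!(takeoff < contact_start - 1L)) {
    wv_stop("ordering_error", "empty pike-mount search range")
  }
  range <- (takeoff + 1L):(contact_start - 1L)
  heights <- vapply(range, function(t) {
    unname(barycenter(masks[[t]]$gymnast)["y"])
  }, numeric(1))
  range[which.max(heights)]
}

#' Detect the final position before the thrust
#'
#' Scans frames after `contact_start` for the first frame whose median flow
#' is upward while the `lookback` frames before it were all downward, and
#' whose maximum median magnitude over those frames lies within
#' `[mag_lo, mag_hi]`.  The magnitude band (defaults 5.5--15 px/frame)
#' rejects the faster landing motion of Unit 3.
#'
#' @param summaries list of `flow_summary`.
#' @param contact_start frame index; scanning starts strictly after it.
#' @param lookback number of preceding downward frames required (default 10,
#'   about 0.2 s at 60 fps).
#' @param mag_lo,mag_hi magnitude band in px/frame.
#' @return frame index of the thrust position.
#' @export
detect_thrust <- function(summaries, contact_start, lookback = 10L,
                          mag_lo = 5.5, mag_hi = 15) {
  stopifnot(lookback >= 1, mag_lo >= 0, mag_lo <= mag_hi)
  cls <- summary_classes(summaries)
  n <- length(cls)
  first <- max(contact_start + 1L, lookback + 1L)
  if (first > n) wv_stop("no_thrust_error", "sequence ends before any candidate")
  for (t in first:n) {
    if (cls[t] != "up") next
    prev <- (t - lookback):(t - 1L)
    if (!all(cls[prev] == "down")) next
    m <- max(vapply(summaries[prev], function(s) s$median_magnitude, numeric(1)))
    if (m >= mag_lo && m <= mag_hi) return(t)
  }
  wv_stop("no_thrust_error", "no qualifying upward transition after contact")
}

#' Extract all four Unit-2 key frames
#'
#' Runs the four detectors on a frame series and validates the strict event
#' ordering take-off < pike-mount < contact start < thrust.
#'
#' @param series a `frame_series` with rendered masks and flows.
#' @param params optional list overriding detector parameters: `eps`,
#'   `window`, `min_contact_s`, `lookback`, `mag_lo`, `mag_hi`.
#' @return an `event_set`: named integer vector of the four frame indices.
#' @export
extract_events <- function(series, params = list()) {
  p <- utils::modifyList(list(eps = 1.0, window = 30L, min_contact_s = 0.5,
                              lookback = 10L, mag_lo = 5.5, mag_hi = 15),
                         params)
  if (is.null(series$flows) || is.null(series$masks)) {
    wv_stop("event_extraction_error",
            "series lacks rendered flows/masks", stage = "input")
  }
  summaries <- summarize_flows(series$flows, eps = p$eps)
  stage <- "takeoff"
  res <- tryCatch({
    takeoff <- detect_takeoff(summaries, window = p$window)
    stage <- "contact_start"
    contact <- detect_contact_start(series$masks, series$meta,
                                    min_contact_s = p$min_contact_s)
    stage <- "pikemount"
    pike <- detect_pikemount(series$masks, takeoff, contact)
    stage <- "thrust"
    thrust <- detect_thrust(summaries, contact, lookback = p$lookback,
                            mag_lo = p$mag_lo, mag_hi = p$mag_hi)
    c(takeoff = takeoff, pikemount = pike,
      contact_start = contact, thrust = thrust)
  }, wheelvault_error = function(e) {
    wv_stop("event_extraction_error",
            sprintf("stage %s failed: %s", stage, conditionMessage(e)),
            stage = stage)
  })
  event_set(res[1], res[2], res[3], res[4], n_frames = series$meta$n_frames)
}

#' Event set
#'
#' @param takeoff,pikemount,contact_start,thrust 1-based frame indices with
#'   takeoff < pikemount < contact_start < thrust.
#' @param n_frames optional upper bound for validation.
#' @return named integer vector of class `event_set`.
#' @export
event_set <- function(takeoff, pikemount, contact_start, thrust,
                      n_frames = NULL) {
  ev <- c(takeoff = as.integer(takeoff), pikemount = as.integer(pikemount),
          contact_start = as.integer(contact_start), thrust = as.integer(thrust))
  if (!(ev[1] < ev[2] && ev[2] < ev[3] && ev[3] < ev[4])) {
    wv_stop("ordering_error",
            paste("event frames must be strictly increasing:",
                  paste(ev, collapse = " ")))
  }
  if (any(ev < 1L) || (!is.null(n_frames) && any(ev > n_frames))) {
    wv_stop("ordering_error", "event frames outside the recording")
  }
  structure(ev, class = "event_set")
}
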