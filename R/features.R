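# The 21 explanatory variables: six joint angles at each scored frame, the
# two pike-mount level features, and time on the wheel.

# angle triples: angle at the middle joint between the two outer joints.
# Shoulder (elbow, shoulder, hip) and hip (neck, hip, knee) follow the
# published triples; neck and ankle follow the adjacent-joint chain.
ANGLE_TRIPLES <- list(
  neck     = c("nose", "neck", "hip"),
  shoulder = c("elbow", "shoulder", "hip"),
  elbow    = c("shoulder", "elbow", "wrist"),
  hip      = c("neck", "hip", "knee"),
  knee     = c("hip", "knee", "ankle"),
  ankle    = c("knee", "ankle", "toes")
)

#' Angle at a joint from three adjacent joints
#'
#' The angle at vertex `b` between the limb vectors `a - b` and `c - b`,
#' computed as the arc cosine of their normalised dot product; always in
#' \[0, 180\] degrees.  Invariant under translation, rotation and uniform
#' scaling of the three points.
#'
#' @param a,b,c numeric length-2 points; `b` is the vertex.
#' @return angle in degrees.
#' @export
joint_angle <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-9 || n2 < 1e-9) {
    wv_stop("degenerate_geometry_error", "zero-length limb vector")
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Six joint angles of a keypoint set
#'
#' @param kp a complete [keypoint_set()].
#' @return named numeric vector (neck, shoulder, elbow, hip, knee, ankle),
#'   degrees.
#' @export
compute_angles <- function(kp) {
  stopifnot(inherits(kp, "keypoint_set"))
  if (!kp$complete) {
    wv_stop("missing_keypoint_error",
            "incomplete keypoint set; performance must be discarded")
  }
  vapply(ANGLE_TRIPLES, function(tr) {
    joint_angle(kp$points[tr[1], ], kp$points[tr[2], ], kp$points[tr[3], ])
  }, numeric(1))
}

#' Pike-mount level features
#'
#' Height differences in px (y-up coordinates): hips above shoulders
#' (`y_hip - y_shoulder`) and feet above hands (`y_toes - y_wrist`).
#' Positive means the first body part is higher; the regulations ask for
#' both to be positive in an ideal pike-mount.
#'
#' @param kp_pikemount a complete [keypoint_set()] at the pike-mount frame.
#' @return c(hips_above_shoulders, feet_above_hands).
#' @export
level_features <- function(kp_pikemount) {
  stopifnot(inherits(kp_pikemount, "keypoint_set"))
  if (!kp_pikemount$complete) {
    wv_stop("missing_keypoint_error", "incomplete keypoint set")
  }
  p <- kp_pikemount$points
  c(hips_above_shoulders = unname(p["hip", 2] - p["shoulder", 2]),
    feet_above_hands = unname(p["toes", 2] - p["wrist", 2]))
}

#' Time on the wheel
#'
#' Frame difference between the contact start and the thrust divided by the
#' recording frame rate.
#'
#' @param contact_start,thrust frame indices, `thrust >= contact_start`.
#' @param fps frames per second (> 0).
#' @return seconds.
#' @export
time_on_wheel <- function(contact_start, thrust, fps) {
  stopifnot(fps > 0)
  if (thrust < contact_start) {
    wv_stop("ordering_error", "thrust precedes contact start")
  }
  (thrust - contact_start) / fps
}

#' Assemble the 21-variable feature vector
#'
#' Joint angles are taken at the take-off, pike-mount and before-thrust
#' frames; the level features at the pike-mount frame; time on the wheel
#' from the contact-start/thrust frame difference.  Any incomplete keypoint
#' set raises a missing-keypoint error (such performances are discarded).
#'
#' @param events an `event_set`.
#' @param kp_by_frame list of [keypoint_set()] indexed by frame.
#' @param fps frames per second.
#' @return named numeric vector of length 21 in [feature_names()] order.
#' @export
build_feature_vector <- function(events, kp_by_frame, fps) {
  frames <- c(takeoff = events[["takeoff"]], pikemount = events[["pikemount"]],
              before_thrust = events[["thrust"]])
  out <- stats::setNames(numeric(21), feature_names())
  for (nm in names(frames)) {
    kp <- kp_by_frame[[frames[[nm]]]]
    if (is.null(kp)) {
      wv_stop("missing_keypoint_error",
              sprintf("no keypoints at the %s frame", nm))
    }
    ang <- compute_angles(kp)
    out[paste0(names(ang), "_", nm)] <- ang
  }
  lv <- level_features(kp_by_frame[[frames[["pikemount"]]]])
  out["hips_above_shoulders"] <- lv["hips_above_shoulders"]
  out["feet_above_hands"] <- lv["feet_above_hands"]
  out["time_on_wheel"] <- time_on_wheel(events[["contact_start"]],
                                        events[["thrust"]], fps)
  out
}
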