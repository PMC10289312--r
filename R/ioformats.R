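# ---------------------------------------------------------------------------
# Core containers
# ---------------------------------------------------------------------------

#' Dense optical-flow field
#'
#' Per-pixel displacement between two consecutive frames, stored in image
#' (file) convention: `u` rightward positive, `v` downward positive, both in
#' px/frame, as height x width matrices with row 1 at the top of the image.
#'
#' @param u,v numeric matrices of identical shape, finite values.
#' @return an object of class `flow_field`.
#' @export
flow_field <- function(u, v) {
  if (!is.matrix(u) || !is.matrix(v) || !all(dim(u) == dim(v))) {
    wv_stop("format_error", "u and v must be matrices of identical shape")
  }
  if (any(!is.finite(u)) || any(!is.finite(v))) {
    wv_stop("format_error", "flow components must be finite")
  }
  structure(list(u = u, v = v), class = "flow_field")
}

#' Wheel/gymnast segmentation mask pair
#'
#' @param wheel,gymnast logical matrices of identical shape (row 1 = top of
#'   the image).
#' @param frame_index 1-based frame number.
#' @return an object of class `mask_pair`.
#' @export
mask_pair <- function(wheel, gymnast, frame_index = NA_integer_) {
  if (!all(dim(wheel) == dim(gymnast))) {
    wv_stop("format_error", "wheel and gymnast masks must share one shape")
  }
  storage.mode(wheel) <- "logical"
  storage.mode(gymnast) <- "logical"
  structure(list(wheel = wheel, gymnast = gymnast,
                 frame_index = as.integer(frame_index)),
            class = "mask_pair")
}

#' The nine side-view keypoints
#'
#' Named 2D points for nose, neck, shoulder, elbow, wrist, hip, knee, ankle
#' and toes of one body side, in analysis coordinates (y up).  A set missing
#' any keypoint, or with zero confidence on one, is flagged incomplete;
#' downstream feature construction discards such performances.
#'
#' @param points 9 x 2 numeric matrix, rows named as above, columns x, y.
#' @param confidence numeric vector of length 9 in `[0, 1]`.
#' @param side `"left"` or `"right"`.
#' @return an object of class `keypoint_set` with a `complete` flag.
#' @export
keypoint_set <- function(points, confidence = rep(1, 9),
                         side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.matrix(points) || nrow(points) != 9 || ncol(points) != 2) {
    wv_stop("format_error", "points must be a 9 x 2 matrix")
  }
  if (is.null(rownames(points))) rownames(points) <- JOINT_NAMES
  if (!identical(rownames(points), JOINT_NAMES)) {
    wv_stop("format_error",
            paste("rows must be named", paste(JOINT_NAMES, collapse = ", ")))
  }
  if (any(confidence < 0 | confidence > 1)) {
    wv_stop("format_error", "confidence must lie in [0, 1]")
  }
  complete <- all(is.finite(points)) && all(confidence > 0)
  structure(list(points = points, confidence = confidence, side = side,
                 complete = complete),
            class = "keypoint_set")
}

#' Canonical feature names
#'
#' The 21 explanatory variables in canonical order: the six joint angles at
#' each of the three scored frames (take-off, pike-mount, before-thrust),
#' then the two pike-mount level features (px, positive = first body part
#' higher), then time on the wheel (s).  Writer, reader and model all use
#' this single definition.
#'
#' @return character vector of length 21.
#' @export
feature_names <- function() {
  angles <- c("neck", "shoulder", "elbow", "hip", "knee", "ankle")
  c(paste0(angles, "_takeoff"),
    paste0(angles, "_pikemount"),
    paste0(angles, "_before_thrust"),
    "hips_above_shoulders", "feet_above_hands", "time_on_wheel")
}

# ---------------------------------------------------------------------------
# Middlebury .flo
# ---------------------------------------------------------------------------

FLO_MAGIC <- 202021.25

#' Read / write Middlebury `.flo` dense flow files
#'
#' Layout: float32 magic tag 202021.25, int32 width, int32 height, then
#' width*height interleaved (u, v) float32 pairs in row-major order,
#' little-endian.  `v` is downward-positive as in the source imagery.
#'
#' @param path file path.
#' @return `read_flo()` returns a [flow_field()].
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  if (length(magic) != 1 || !isTRUE(all.equal(magic, FLO_MAGIC, tolerance = 1e-6))) {
    wv_stop("format_error", "not a .flo file (bad magic tag)")
  }
  dims <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  if (length(dims) != 2 || any(dims < 1)) {
    wv_stop("format_error", "corrupt .flo header")
  }
  w <- dims[1]; h <- dims[2]
  dat <- readBin(con, "numeric", n = 2 * w * h, size = 4, endian = "little")
  if (length(dat) != 2 * w * h) {
    wv_stop("format_error", "truncated .flo payload")
  }
  uv <- matrix(dat, nrow = 2)                 # interleaved u, v
  u <- matrix(uv[1, ], nrow = h, ncol = w, byrow = TRUE)
  v <- matrix(uv[2, ], nrow = h, ncol = w, byrow = TRUE)
  flow_field(u, v)
}

#' @rdname read_flo
#' @param field a [flow_field()].
#' @export
write_flo <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  h <- nrow(field$u); w <- ncol(field$u)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4, endian = "little")
  writeBin(c(as.integer(w), as.integer(h)), con, size = 4, endian = "little")
  uv <- rbind(as.vector(t(field$u)), as.vector(t(field$v)))
  writeBin(as.vector(uv), con, size = 4, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# BODY_25 pose JSON
# ---------------------------------------------------------------------------

# 0-based indices of the nine keypoints in the 25-keypoint layout ("toes" =
# big toe, the most distal stable foot point).  Overridable per call.
BODY25_INDEX <- list(
  left  = c(nose = 0, neck = 1, shoulder = 5, elbow = 6, wrist = 7,
            hip = 12, knee = 13, ankle = 14, toes = 19),
  right = c(nose = 0, neck = 1, shoulder = 2, elbow = 3, wrist = 4,
            hip = 9, knee = 10, ankle = 11, toes = 22)
)

#' Read a BODY_25 pose-estimation JSON file
#'
#' Expects the pose-estimator output layout: a `people` array whose entries
#' carry `pose_keypoints_2d`, a flat vector of 25 (x, y, confidence) triples
#' in image coordinates (y down, origin top-left).  The configured side's
#' nine keypoints are extracted with the standard BODY_25 index map and
#' converted once to analysis coordinates (y up) using `height`.  Frames with
#' several detected people keep the pose with the largest mean confidence.
#' A required keypoint with zero confidence flags the set incomplete.
#'
#' @param path JSON file path.
#' @param height image height in px (needed for the y-axis flip).
#' @param side which body side to extract.
#' @param index_map optional replacement for the built-in index map.
#' @return a [keypoint_set()].
#' @export
read_body25_json <- function(path, height, side = c("left", "right"),
                             index_map = NULL) {
  side <- match.arg(side)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    wv_stop("parse_error", paste("malformed JSON:",
                                                 conditionMessage(e)))
                  })
  people <- doc$people
  if (is.null(people) || length(people) == 0) {
    wv_stop("format_error", "no people in pose JSON")
  }
  poses <- lapply(people, function(p) unlist(p$pose_keypoints_2d))
  bad <- vapply(poses, function(p) length(p) != 75, logical(1))
  if (any(bad)) {
    wv_stop("format_error", "pose_keypoints_2d must hold 25 keypoints")
  }
  if (length(poses) > 1) {
    mc <- vapply(poses, function(p) mean(p[seq(3, 75, by = 3)]), numeric(1))
    message(sprintf("pose JSON %s: %d people, keeping the one with mean confidence %.3f",
                    basename(path), length(poses), max(mc)))
    pose <- poses[[which.max(mc)]]
  } else pose <- poses[[1]]
  idx <- if (is.null(index_map)) BODY25_INDEX[[side]] else index_map
  pts <- matrix(NA_real_, 9, 2, dimnames = list(JOINT_NAMES, c("x", "y")))
  conf <- numeric(9)
  for (i in seq_along(JOINT_NAMES)) {
    k <- idx[[JOINT_NAMES[i]]]
    pts[i, 1] <- pose[3 * k + 1]
    pts[i, 2] <- height - pose[3 * k + 2]     # to y-up analysis coordinates
    conf[i] <- pose[3 * k + 3]
  }
  keypoint_set(pts, confidence = conf, side = side)
}

#' @rdname read_body25_json
#' @param kp a [keypoint_set()] in analysis coordinates.
#' @export
write_body25_json <- function(kp, height, path) {
  stopifnot(inherits(kp, "keypoint_set"))
  flat <- numeric(75)
  idx <- BODY25_INDEX[[kp$side]]
  for (i in seq_along(JOINT_NAMES)) {
    k <- idx[[JOINT_NAMES[i]]]
    flat[3 * k + 1] <- kp$points[i, 1]
    flat[3 * k + 2] <- height - kp$points[i, 2]
    flat[3 * k + 3] <- kp$confidence[i]
  }
  doc <- list(version = 1.3,
              people = list(list(pose_keypoints_2d = flat)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Mask PNGs
# ---------------------------------------------------------------------------

# label convention for two-label grayscale masks: 0 background, 1 wheel,
# 2 gymnast, stored as gray levels 0 / 0.5 / 1
MASK_LEVELS <- c(background = 0, wheel = 1, gymnast = 2)

#' Read / write segmentation masks as PNG images
#'
#' Masks are stored as two-label grayscale PNGs (background 0, wheel 0.5,
#' gymnast 1.0).  `read_mask_dir` reads every `.png` in a directory, sorted
#' by name, and rejects resolution mismatches or unknown gray levels.
#'
#' @param dir directory of `.png` mask files.
#' @return list of [mask_pair()] in filename order.
#' @export
read_mask_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  out <- vector("list", length(files))
  shape <- NULL
  for (i in seq_along(files)) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1]
    if (is.null(shape)) shape <- dim(img)
    if (!all(dim(img) == shape)) {
      wv_stop("format_error", sprintf("mask %s: resolution mismatch",
                                      basename(files[i])))
    }
    lab <- round(img * 2)
    if (any(abs(img * 2 - lab) > 0.05) || any(!lab %in% 0:2)) {
      wv_stop("format_error", sprintf("mask %s: unknown label values",
                                      basename(files[i])))
    }
    out[[i]] <- mask_pair(wheel = lab == 1, gymnast = lab == 2, frame_index = i)
  }
  out
}

#' @rdname read_mask_dir
#' @param mp a [mask_pair()]; gymnast pixels win where the two masks overlap.
#' @param path output `.png` path.
#' @export
write_mask_png <- function(mp, path) {
  stopifnot(inherits(mp, "mask_pair"))
  img <- matrix(0, nrow(mp$wheel), ncol(mp$wheel))
  img[mp$wheel] <- 0.5
  img[mp$gymnast] <- 1
  png::writePNG(img, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Feature / score tables
# ---------------------------------------------------------------------------

RECORD_META_COLS <- c("gymnast_id", "day", "judge1", "judge2", "mean_deduction")

#' Read / write the per-performance feature table
#'
#' One row per performance: the 21 features in canonical order
#' (see [feature_names()]) plus gymnast id, session day, the two judge
#' deductions and their arithmetic mean (the regression target).  RFC-4180
#' CSV, UTF-8, `.` decimal separator.
#'
#' @param records data frame of performance records.
#' @param path CSV path.
#' @export
write_feature_table <- function(records, path) {
  cols <- c(RECORD_META_COLS, feature_names())
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) {
    wv_stop("format_error", paste("records lack columns:",
                                  paste(missing, collapse = ", ")))
  }
  out <- records[, cols]
  # %.17g guarantees doubles survive the round trip bit-exactly
  for (cn in cols) {
    if (is.double(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  expected <- c(RECORD_META_COLS, feature_names())
  if (!identical(names(df), expected)) {
    wv_stop("format_error", "feature table header does not match the canonical layout")
  }
  df
}
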