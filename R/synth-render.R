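# Raster rendering for the synthetic world: wheel annulus, stick-figure
# gymnast (capsule strokes), and dense flow fields equal to the rendered
# pixel displacement plus Gaussian estimator noise.
#
# Raster/storage convention (shared with ioformats): masks and flow
# components are height x width matrices, row 1 = top of the image.  Analysis
# coordinates are y-up: a point (x, y) maps to column x + 1, row height - y.

# limb segments drawn between joints, with stroke half-widths in px
BODY_SEGMENTS <- list(
  c("nose", "neck", 2.6),
  c("neck", "hip", 3.2),
  c("shoulder", "elbow", 2.0),
  c("elbow", "wrist", 2.0),
  c("hip", "knee", 2.2),
  c("knee", "ankle", 2.0),
  c("ankle", "toes", 1.6)
)

render_wheel_mask <- function(meta) {
  w <- meta$width; h <- meta$height
  px <- matrix(rep(0:(w - 1), each = h), nrow = h)       # x of each cell
  py <- matrix(rep(h - seq_len(h), times = w), nrow = h) # y-up of each cell
  d2 <- (px - WHEEL$cx)^2 + (py - WHEEL$cy)^2
  d2 >= WHEEL$r_in^2 & d2 <= WHEEL$r_out^2
}

# distance from grid points to segment a->b plus the projection parameter
# (0 at a, 1 at b), both vectorised over pixels
seg_dist <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 < 1e-12) {
    lam <- 0 * px
  } else {
    lam <- pmin(1, pmax(0, ((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2))
  }
  dx <- px - (a[1] + lam * ab[1])
  dy <- py - (a[2] + lam * ab[2])
  list(d2 = dx^2 + dy^2, lam = lam)
}

# Render the gymnast mask for one skeleton and, when `skel_next` is given,
# the per-pixel displacement each mask pixel will undergo (nearest-segment
# assignment, velocity interpolated along the segment).
render_gymnast <- function(sk, meta, skel_next = NULL) {
  w <- meta$width; h <- meta$height
  xr <- range(sk[, 1]); yr <- range(sk[, 2])
  pad <- 4
  c0 <- max(1L, floor(xr[1] - pad) + 1L); c1 <- min(w, ceiling(xr[2] + pad) + 1L)
  r0 <- max(1L, h - ceiling(yr[2] + pad)); r1 <- min(h, h - floor(yr[1] - pad))
  if (c0 > c1 || r0 > r1) {
    out <- list(mask = matrix(FALSE, h, w))
    if (!is.null(skel_next)) { out$du <- matrix(0, h, w); out$dv_up <- matrix(0, h, w) }
    return(out)
  }
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  px <- matrix(rep((c0:c1) - 1, each = nr), nrow = nr)
  py <- matrix(rep(h - (r0:r1), times = nc), nrow = nr)
  best_d2 <- matrix(Inf, nr, nc)
  best_seg <- matrix(0L, nr, nc)
  best_lam <- matrix(0, nr, nc)
  inside <- matrix(FALSE, nr, nc)
  for (s in seq_along(BODY_SEGMENTS)) {
    spec <- BODY_SEGMENTS[[s]]
    sd <- seg_dist(px, py, sk[spec[1], ], sk[spec[2], ])
    hw <- as.numeric(spec[3])
    inside <- inside | sd$d2 <= hw^2
    upd <- sd$d2 < best_d2
    best_d2[upd] <- sd$d2[upd]
    best_seg[upd] <- s
    best_lam[upd] <- sd$lam[upd]
  }
  mask <- matrix(FALSE, h, w)
  mask[r0:r1, c0:c1] <- inside
  out <- list(mask = mask)
  if (!is.null(skel_next)) {
    du_l <- matrix(0, nr, nc); dv_l <- matrix(0, nr, nc)
    for (s in seq_along(BODY_SEGMENTS)) {
      spec <- BODY_SEGMENTS[[s]]
      sel <- inside & best_seg == s
      if (!any(sel)) next
      va <- skel_next[spec[1], ] - sk[spec[1], ]
      vb <- skel_next[spec[2], ] - sk[spec[2], ]
      lam <- best_lam[sel]
      du_l[sel] <- (1 - lam) * va[1] + lam * vb[1]
      dv_l[sel] <- (1 - lam) * va[2] + lam * vb[2]
    }
    du <- matrix(0, h, w); dv <- matrix(0, h, w)
    du[r0:r1, c0:c1] <- du_l
    dv[r0:r1, c0:c1] <- dv_l
    out$du <- du
    out$dv_up <- dv
  }
  out
}

# Render all masks and flows for a scripted trajectory.  Flow fields follow
# the file convention of the `.flo` format: u rightward, v downward positive,
# so v = -(y-up displacement).  Noise is added over the whole field, as a
# flow estimator would produce it.
render_performance <- function(traj, meta, flow_noise_sd = 0) {
  n <- dim(traj)[3]
  wheel <- render_wheel_mask(meta)
  masks <- vector("list", n)
  flows <- vector("list", n - 1)
  for (t in seq_len(n)) {
    nxt <- if (t < n) traj[, , t + 1] else NULL
    g <- render_gymnast(traj[, , t], meta, skel_next = nxt)
    masks[[t]] <- mask_pair(wheel = wheel, gymnast = g$mask, frame_index = t)
    if (t < n) {
      u <- g$du
      v <- -g$dv_up
      if (flow_noise_sd > 0) {
        u <- u + matrix(stats::rnorm(length(u), 0, flow_noise_sd), nrow(u))
        v <- v + matrix(stats::rnorm(length(v), 0, flow_noise_sd), nrow(v))
      }
      flows[[t]] <- flow_field(u, v)
    }
  }
  list(masks = masks, flows = flows)
}
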