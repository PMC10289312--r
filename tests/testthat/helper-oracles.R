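# Independent brute-force oracles and tiny fixtures.  These deliberately
# re-derive every quantity with naive loops, never calling the package's
# internal helpers.

make_summary <- function(frame_index, direction, magnitude, defined = TRUE) {
  structure(list(frame_index = as.integer(frame_index),
                 median_direction = if (defined) direction else NA_real_,
                 median_magnitude = if (defined) magnitude else NA_real_,
                 n_moving = if (defined) 10L else 0L,
                 defined = defined),
            class = "flow_summary")
}

# random direction/magnitude sequences, with occasional undefined frames and
# exact 0/180 directions
random_summaries <- function(n, p_undef = 0.1) {
  lapply(seq_len(n), function(t) {
    if (stats::runif(1) < p_undef) return(make_summary(t, 0, 0, defined = FALSE))
    d <- if (stats::runif(1) < 0.05) sample(c(0, 180), 1) else stats::runif(1, 0, 360)
    make_summary(t, d, stats::runif(1, 0, 20))
  })
}

oracle_class <- function(s) {
  if (!isTRUE(s$defined)) return("none")
  th <- s$median_direction %% 360
  if (th > 0 && th < 180) "up" else if (th > 180) "down" else "none"
}

# naive take-off scan: first start position with `window` consecutive upward
# frames, then the nearest preceding downward frame
oracle_takeoff <- function(summaries, window) {
  cls <- vapply(summaries, oracle_class, character(1))
  n <- length(cls)
  for (start in seq_len(n - window + 1)) {
    if (all(cls[start:(start + window - 1)] == "up")) {
      for (prev in rev(seq_len(start - 1))) {
        if (cls[prev] == "down") return(prev)
      }
      return(NA_integer_)   # run with no preceding downward frame
    }
  }
  NA_integer_
}

# naive thrust scan
oracle_thrust <- function(summaries, contact_start, lookback, lo, hi) {
  cls <- vapply(summaries, oracle_class, character(1))
  n <- length(cls)
  for (t in seq_len(n)) {
    if (t <= contact_start || t <= lookback) next
    if (cls[t] != "up") next
    win <- (t - lookback):(t - 1)
    if (any(cls[win] != "down")) next
    mx <- max(vapply(summaries[win], function(s) s$median_magnitude, numeric(1)))
    if (mx >= lo && mx <= hi) return(t)
  }
  NA_integer_
}

# naive contact-run scan on a logical vector
oracle_contact <- function(contact, need_frames) {
  n <- length(contact)
  t <- 1
  while (t <= n) {
    if (contact[t]) {
      len <- 0
      while (t + len <= n && contact[t + len]) len <- len + 1
      if (len > need_frames) return(as.integer(t))
      t <- t + len
    }
    t <- t + 1
  }
  NA_integer_
}

# per-pixel flow summary recomputation
oracle_summary <- function(u, v, eps) {
  mags <- c(); dirs <- c()
  for (i in seq_len(nrow(u))) {
    for (jj in seq_len(ncol(u))) {
      m <- sqrt(u[i, jj]^2 + v[i, jj]^2)
      if (m > eps) {
        mags <- c(mags, m)
        d <- atan2(-v[i, jj], u[i, jj]) * 180 / pi
        dirs <- c(dirs, d %% 360)
      }
    }
  }
  if (length(mags) == 0) return(NULL)
  list(direction = stats::median(dirs), magnitude = stats::median(mags),
       n = length(mags))
}

# exact Mann-Whitney p by full enumeration of which pooled positions belong
# to x (all C(nx+ny, nx) label assignments of the observed values)
oracle_mw_exact <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

# small, fast synthetic configs
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_days = 2,
                                 performances_per_day = 2,
                                 ride_time_range = c(3, 3.6)),
                            list(...))
  do.call(synth_config, args)
}

zero_noise_config <- function(seed = 1, ...) {
  synth_config(seed = seed, judge_noise_sd = 0, flow_noise_sd = 0,
               pose_jitter_sd = 0, ...)
}
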