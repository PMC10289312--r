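#' Regulation deduction for time on the wheel
#'
#' The general vault regulations deduct from the execution score when the
#' gymnast stays on the wheel too long between the soles first contacting the
#' wheel and the final position before the thrust.  The printed bands are
#' 0.1--0.2 over 3--4 s, 0.3--0.4 over 5--6 s and a flat 0.5 above 6 s.  The
#' band between 4 and 5 s is not printed; it is filled by linear interpolation
#' (0.2 to 0.3) so that the map is continuous and nondecreasing past 3 s.
#' Within each printed band a linear ramp is used rather than a step, so the
#' endpoints match the regulation while the interior stays monotone.
#'
#' @param t time on the wheel in seconds; finite, nonnegative (vectorised).
#' @return deduction in E-score units, a value in \code{[0, 0.5]}.
#' @examples
#' regulation_time_deduction(c(2, 3.5, 6.5))  # 0.00 0.15 0.50
#' @export
regulation_time_deduction <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric seconds", call. = FALSE)
  }
  if (any(t < 0)) {
    stop("`t` must be nonnegative", call. = FALSE)
  }
  d <- numeric(length(t))
  d[t >= 3 & t <= 4] <- 0.1 + 0.1 * (t[t >= 3 & t <= 4] - 3)
  d[t > 4 & t < 5]   <- 0.2 + 0.1 * (t[t > 4 & t < 5] - 4)
  d[t >= 5 & t <= 6] <- 0.3 + 0.1 * (t[t >= 5 & t <= 6] - 5)
  d[t > 6]           <- 0.5
  d
}
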