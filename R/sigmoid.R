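#' Fit a sigmoid to an RR transition
#'
#' Least-squares fit of the four-parameter logistic
#' \deqn{f(t) = A + B / (1 + \exp(-(t - t_0)/s))}
#' to the (beat_time, RR) pairs inside `window`, by Levenberg-Marquardt.
#' A is the lower asymptote (ms), B the amplitude (ms), t0 the inflection
#' time (s) and s the time scale (s); the maximum slope of the fitted
#' curve is |B|/(4|s|) ms/s, attained at t0. The fit is normalized so that
#' s > 0 (the mirrored parameterization describes the same curve).
#'
#' Starting values: A = mean RR of the first third of the window, B = last
#' third mean minus first third mean, t0 = the location of the steepest
#' finite-difference slope, s = 1 s.
#'
#' @param series an [rr_series()].
#' @param window numeric length-2, `c(from, to)` seconds; must contain at
#'   least 6 beats.
#' @return A list of class `sigmoid_fit`: `A`, `B`, `t0`, `s`, `residual`
#'   (RMS, ms), `max_slope` (ms/s), `degenerate` (logical: no usable
#'   transition amplitude).
#' @export
fit_sigmoid <- function(series, window) {
  stopifnot(inherits(series, "rr_series"), length(window) == 2,
            window[2] > window[1])
  keep <- series$beat_time >= window[1] & series$beat_time <= window[2]
  t <- series$beat_time[keep]
  y <- series$rr[keep]
  if (length(t) < 6) {
    stop("sigmoid fit requires at least 6 beats in the window")
  }
  third <- max(2L, floor(length(y) / 3))
  a0 <- mean(y[seq_len(third)])
  b0 <- mean(y[seq.int(length(y) - third + 1L, length(y))]) - a0
  slopes <- diff(y) / pmax(diff(t), 1e-6)
  t00 <- t[which.max(abs(slopes))]
  if (abs(b0) < 1e-8) b0 <- sign(b0 + 1e-12) * 1e-3
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A + B / (1 + exp(-(t - t0) / s)),
      start = list(A = a0, B = b0, t0 = t00, s = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-13,
                                           ptol = 1e-13)
    ),
    error = function(e) stop("sigmoid fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  p <- as.list(stats::coef(fit))
  if (p$s < 0) {  # mirrored parameterization -> canonical s > 0
    p$A <- p$A + p$B
    p$B <- -p$B
    p$s <- -p$s
  }
  res <- sqrt(mean(stats::resid(fit)^2))
  structure(
    list(A = p$A, B = p$B, t0 = p$t0, s = p$s, residual = res,
         max_slope = abs(p$B) / (4 * abs(p$s)),
         degenerate = !all(vapply(p, is.finite, logical(1))) ||
           abs(p$B) < 1),
    class = "sigmoid_fit"
  )
}

# Earliest t with f'(t) > thr for a canonical (s > 0, B > 0) sigmoid fit.
# f'(t) = (B/s) u (1-u) with u = logistic((t-t0)/s); solving u(1-u) = thr*s/B
# gives the smaller root u-, and t = t0 + s*log(u/(1-u)). Requires
# max slope B/(4s) > thr; returns NA otherwise.
sigmoid_slope_crossing <- function(fit, thr = 1) {
  if (fit$degenerate || fit$B <= 0 || fit$max_slope <= thr) return(NA_real_)
  disc <- 1 - 4 * thr * fit$s / fit$B
  u <- (1 - sqrt(disc)) / 2
  fit$t0 + fit$s * log(u / (1 - u))
}

#' Adjust an annotated bradycardia onset by sigmoid interpolation
#'
#' Manual onset annotations carry jitter. The adjustment fits a sigmoid to
#' the RR series around the annotated onset and moves the onset to the
#' first point where the derivative of the interpolated sigmoid exceeds 1
#' (RR in ms, time in s: a sustained lengthening faster than 1 ms/s marks
#' the start of the deceleration). The crossing is computed in closed form
#' from the fitted parameters. When the fit is degenerate, the transition
#' is not rising, or its maximum slope never exceeds 1, the annotated
#' onset is returned unchanged with a warning.
#'
#' @param series an [rr_series()].
#' @param annotated_onset seconds; the manual (or threshold-crossing)
#'   annotation.
#' @param fit_window seconds on each side of `annotated_onset` used for the
#'   fit (default 15).
#' @param slope_threshold derivative threshold, ms/s (default 1).
#' @return Adjusted onset time in seconds.
#' @export
adjust_onset <- function(series, annotated_onset, fit_window = 15,
                         slope_threshold = 1) {
  fit <- tryCatch(
    fit_sigmoid(series, annotated_onset + c(-1, 1) * fit_window),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("sigmoid fit failed; returning annotated onset unchanged")
    return(annotated_onset)
  }
  adj <- sigmoid_slope_crossing(fit, slope_threshold)
  if (is.na(adj)) {
    warning("sigmoid slope never exceeds threshold; ",
            "returning annotated onset unchanged")
    return(annotated_onset)
  }
  adj
}

#' Adjust an annotated bradycardia offset
#'
#' Mirror of [adjust_onset()] applied to the recovery transition: the RR
#' series around the annotated offset is reversed in time (so the falling
#' recovery becomes a rising transition), the onset adjustment is applied,
#' and the result is mapped back.
#'
#' @inheritParams adjust_onset
#' @param annotated_offset seconds.
#' @return Adjusted offset time in seconds.
#' @export
adjust_offset <- function(series, annotated_offset, fit_window = 15,
                          slope_threshold = 1) {
  keep <- series$beat_time >= annotated_offset - fit_window - 2 &
    series$beat_time <= annotated_offset + fit_window + 2
  sub <- series[keep, , drop = FALSE]
  if (nrow(sub) < 6) {
    warning("too few beats around offset; returning annotated offset")
    return(annotated_offset)
  }
  rev_series <- rr_series(beat_time = rev(-sub$beat_time), rr = rev(sub$rr))
  -adjust_onset(rev_series, -annotated_offset, fit_window, slope_threshold)
}
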