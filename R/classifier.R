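#' Behaviour classifier settings
#'
#' Thresholds for the approximate behavioural classifier: a sample is a
#' tight turn when |a3| exceeds `a3_threshold`; otherwise it is forward or
#' backward crawling by the sign of the (a1, a2)-plane phase velocity,
#' provided the plane amplitude exceeds `delta` and |omega| exceeds
#' `epsilon`; otherwise unclassified. The classifier is an approximate
#' guide for interpreting error time series, not a precise ethogram.
#'
#' @param a3_threshold |a3| above which a sample is labelled a tight turn
#'   (dimensionless; default 10 — the conservative choice; 15 marks only
#'   the most extreme delta-turn excursions).
#' @param epsilon minimum |phase velocity| in rad/s for a motion label
#'   (default 0.1).
#' @param delta minimum (a1, a2)-plane amplitude for a motion label
#'   (dimensionless; default 3).
#' @param forward_positive if TRUE (default), positive estimated phase
#'   velocity (counterclockwise in the (a1, a2) plane, the synthetic
#'   generator's forward convention) is labelled forward; FALSE flips the
#'   mapping, matching data sets in which forward crawling rotates the
#'   other way.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(a3_threshold = 10, epsilon = 0.1, delta = 3,
                              forward_positive = TRUE) {
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  if (delta < 0) stop("'delta' must be >= 0")
  if (a3_threshold <= 0) stop("'a3_threshold' must be > 0")
  structure(list(a3_threshold = a3_threshold, epsilon = epsilon,
                 delta = delta, forward_positive = isTRUE(forward_positive)),
            class = "classifier_config")
}

#' Estimate the signed phase velocity in the (a1, a2) plane
#'
#' Central-difference estimate of the angular rate of the pose trajectory
#' in the plane of the first two eigenworm coefficients:
#' `alpha(t) = arctan(a2/a1)|_{t+dt} - arctan(a2/a1)|_{t-dt}` with the
#' two-quadrant (principal value) arctangent, then
#' `|omega| = min(|alpha|, pi - |alpha|) / (2 dt)` with
#' `sign(omega) = sign(alpha)` when `|alpha| < pi - |alpha|` and
#' `-sign(alpha)` otherwise. The min rule undoes the branch jumps of the
#' two-quadrant arctangent (which advances by pi, not 2*pi, per half
#' rotation), so the estimate is valid as long as the true rotation per
#' 2*dt stays under half a turn. Positive omega = counterclockwise
#' (phase increasing).
#'
#' @param series a [pose_series()].
#' @return Numeric vector of per-sample omega estimates in rad/s; `NA` at
#'   the first and last samples (central difference undefined) and wherever
#'   a1 or a2 is missing, or a1 is exactly zero, at a stencil point.
#' @export
phase_velocity <- function(series) {
  stopifnot(is_pose_series(series))
  n <- n_samples(series)
  a1 <- series$coeffs[, 1]; a2 <- series$coeffs[, 2]
  usable <- is.finite(a1) & is.finite(a2) & a1 != 0
  ang <- ifelse(usable, atan(a2 / a1), NA_real_)
  omega <- rep(NA_real_, n)
  if (n < 3L) return(omega)
  idx <- 2:(n - 1L)
  alpha <- ang[idx + 1L] - ang[idx - 1L]
  mag <- pmin(abs(alpha), pi - abs(alpha)) / (2 * series$dt)
  sgn <- ifelse(abs(alpha) < pi - abs(alpha), sign(alpha), -sign(alpha))
  omega[idx] <- sgn * mag
  omega
}

#' Approximate behavioural classification of a pose series
#'
#' Labels every sample as `tight_turn`, `forward`, `backward` or
#' `unclassified` using the rules described in [classifier_config()], with
#' the phase velocity estimated by [phase_velocity()]. The tight-turn rule
#' depends only on a3 and takes precedence everywhere; motion labels
#' require a defined phase velocity, so the first and last samples (and
#' samples adjacent to gaps) are otherwise unclassified.
#'
#' @param series a [pose_series()] with K >= 3 for the turn rule (with
#'   K = 2 no turns are ever labelled).
#' @param config a [classifier_config()].
#' @return An object of class `classification_series`: list with `times`,
#'   `labels` (character) and `omega` (rad/s, NA where undefined).
#' @examples
#' s <- generate_series(synthetic_config(duration_s = 10, noise_sd = 0,
#'                      turn_events = list(c(5, 0.25, 14))))$series
#' cl <- classify(s)
#' table(cl$labels)
#' @export
classify <- function(series, config = classifier_config()) {
  stopifnot(is_pose_series(series), inherits(config, "classifier_config"))
  omega <- phase_velocity(series)
  n <- n_samples(series)
  a1 <- series$coeffs[, 1]; a2 <- series$coeffs[, 2]
  amp <- sqrt(a1^2 + a2^2)
  labels <- rep("unclassified", n)
  fwd_sign <- if (config$forward_positive) 1 else -1
  moving <- !is.na(omega) & is.finite(amp) & amp > config$delta &
    abs(omega) > config$epsilon
  labels[moving & fwd_sign * omega > 0] <- "forward"
  labels[moving & fwd_sign * omega < 0] <- "backward"
  if (ncol(series$coeffs) >= 3L) {
    a3 <- series$coeffs[, 3]
    labels[is.finite(a3) & abs(a3) > config$a3_threshold] <- "tight_turn"
  }
  structure(list(times = series$times, labels = labels, omega = omega),
            class = "classification_series")
}

#' @export
print.classification_series <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("<classification_series>  %d samples: %s\n", length(x$labels),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.classification_series <- function(x, ...) {
  data.frame(time = x$times, label = x$labels, omega = x$omega,
             stringsAsFactors = FALSE)
}
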