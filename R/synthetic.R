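#' Configuration for the synthetic pose-series generator
#'
#' Describes a noisy limit cycle in the (a1, a2) plane — the planar rotation
#' that crawling traces through the first two eigenworm coefficients — with a
#' controllable signed phase velocity (positive = forward under the default
#' sign convention), transient large-|a3| excursions standing in for tight
#' turns, missing-sample gaps, and optional localized dynamic anomalies.
#'
#' @param duration_s total duration in seconds.
#' @param dt sampling interval in seconds.
#' @param amplitude limit-cycle amplitude A (dimensionless coefficient units).
#' @param omega_schedule signed phase velocity in rad/s: either a single
#'   number (constant) or a 2-column matrix/data.frame `(t, omega)` giving a
#'   piecewise-constant schedule — each `omega` applies from its `t` (seconds)
#'   until the next breakpoint.
#' @param turn_events list of numeric triples `c(center_s, half_width_s, peak)`:
#'   each adds a Gaussian bump `peak * exp(-(t - center)^2 / (2 * half_width^2))`
#'   to a3 (half_width is the Gaussian sigma, in seconds).
#' @param gap_intervals list of numeric pairs `c(from_s, to_s)`; samples in
#'   these time intervals are marked missing (`NA`) in all coefficients.
#'   Gaps win over overlapping turn events.
#' @param anomaly_windows list of `list(window = c(from_s, to_s), magnitude = m)`
#'   entries applied with [inject_anomaly()] after generation.
#' @param noise_sd standard deviation of independent additive Gaussian noise,
#'   per coefficient per sample (>= 0).
#' @param K number of eigenworm coefficients (default 5; a4..aK are pure noise).
#' @param seed integer seed; identical seed + config gives bit-identical output.
#' @param name series identifier.
#'
#' @return A list of class `synthetic_config`.
#' @seealso [generate_series()]
#' @export
synthetic_config <- function(duration_s = 60, dt = 1 / 16, amplitude = 5,
                             omega_schedule = 2 * pi * 0.5,
                             turn_events = list(), gap_intervals = list(),
                             anomaly_windows = list(), noise_sd = 0.25,
                             K = 5, seed = 1L, name = "synthetic") {
  if (dt <= 0) stop("'dt' must be positive")
  if (duration_s < dt) stop("'duration_s' must be at least one sampling interval")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (K < 2) stop("'K' must be >= 2")
  for (ev in turn_events) {
    if (length(ev) != 3L) stop("each turn event is c(center_s, half_width_s, peak)")
    if (ev[2] <= 0) stop("turn event half-width must be positive")
  }
  structure(list(duration_s = duration_s, dt = dt, amplitude = amplitude,
                 omega_schedule = omega_schedule, turn_events = turn_events,
                 gap_intervals = gap_intervals, anomaly_windows = anomaly_windows,
                 noise_sd = noise_sd, K = as.integer(K),
                 seed = as.integer(seed), name = name),
            class = "synthetic_config")
}

# per-sample omega from a piecewise-constant schedule
schedule_omega <- function(omega_schedule, times) {
  if (is.numeric(omega_schedule) && is.null(dim(omega_schedule)) &&
      length(omega_schedule) == 1L) {
    return(rep(omega_schedule, length(times)))
  }
  sched <- as.matrix(omega_schedule)
  if (ncol(sched) != 2L) stop("'omega_schedule' must be scalar or 2 columns (t, omega)")
  if (is.unsorted(sched[, 1], strictly = TRUE))
    stop("omega schedule breakpoints must be strictly increasing")
  idx <- findInterval(times, sched[, 1])
  idx[idx == 0L] <- 1L  # before first breakpoint: use first omega
  sched[idx, 2]
}

#' Generate a synthetic pose series with ground truth
#'
#' Builds `a1(t) = A cos(phi(t))`, `a2(t) = A sin(phi(t))` with `phi` the
#' cumulative integral of the scheduled phase velocity, Gaussian a3 turn
#' bumps, pure-noise higher coefficients, missing-sample gaps and injected
#' anomalies, plus per-sample ground truth (true phase velocity, behaviour
#' label, anomaly mask) for validating the classifier and the error metrics.
#'
#' Ground-truth labels follow the classifier's rules applied to the
#' noise-free signal: `tight_turn` where the clean |a3| exceeds
#' `label_config$a3_threshold`; otherwise `forward`/`backward` by the sign of
#' the scheduled phase velocity when the cycle amplitude exceeds
#' `label_config$delta` and |omega| exceeds `label_config$epsilon`; otherwise
#' `unclassified`.
#'
#' @param config a [synthetic_config()].
#' @param label_config a [classifier_config()] supplying the thresholds used
#'   for the ground-truth labels (defaults match the classifier defaults).
#'
#' @return A list with elements `series` (a [pose_series()]) and `truth`
#'   (data.frame: `time`, `true_omega` in rad/s, `true_label`,
#'   `anomaly_mask`).
#' @examples
#' out <- generate_series(synthetic_config(duration_s = 10, noise_sd = 0, seed = 7))
#' out$series
#' table(out$truth$true_label)
#' @export
generate_series <- function(config, label_config = classifier_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- round(config$duration_s / config$dt)
  times <- (seq_len(n) - 1) * config$dt
  omega <- schedule_omega(config$omega_schedule, times)
  # phi(t) = integral of omega; left-Riemann so phi[1] = 0
  phi <- cumsum(c(0, omega[-n] * config$dt))

  set.seed(config$seed)
  noise <- matrix(rnorm(n * config$K, sd = config$noise_sd), n, config$K)

  a3_clean <- numeric(n)
  for (ev in config$turn_events)
    a3_clean <- a3_clean + ev[3] * exp(-(times - ev[1])^2 / (2 * ev[2]^2))

  coeffs <- matrix(0, n, config$K)
  coeffs[, 1] <- config$amplitude * cos(phi)
  coeffs[, 2] <- config$amplitude * sin(phi)
  coeffs[, 3] <- a3_clean
  coeffs <- coeffs + noise

  series <- pose_series(coeffs, dt = config$dt, name = config$name)

  anomaly_mask <- rep(FALSE, n)
  for (an in config$anomaly_windows) {
    series <- inject_anomaly(series, an$window, an$magnitude)
    anomaly_mask <- anomaly_mask |
      (times >= an$window[1] & times <= an$window[2])
  }
  for (gap in config$gap_intervals) {
    series$coeffs[times >= gap[1] & times <= gap[2], ] <- NA_real_
  }

  label <- rep("unclassified", n)
  moving <- config$amplitude > label_config$delta & abs(omega) > label_config$epsilon
  label[moving & omega > 0] <- "forward"
  label[moving & omega < 0] <- "backward"
  label[abs(a3_clean) > label_config$a3_threshold] <- "tight_turn"

  truth <- data.frame(time = times, true_omega = omega, true_label = label,
                      anomaly_mask = anomaly_mask, stringsAsFactors = FALSE)
  list(series = series, truth = truth)
}

#' Inject a localized dynamic anomaly into a pose series
#'
#' Within the given time window the first two coefficients are blended
#' towards their swap: `a1' = (1 - m) a1 + m a2`, `a2' = (1 - m) a2 + m a1`.
#' This perturbs the *dynamics* of the planar cycle (its sense of rotation
#' collapses onto the diagonal as m -> 1) rather than simply adding noise,
#' which is the kind of change the prediction-error method is built to flag.
#' Samples outside the window are untouched; `magnitude = 0` is the identity.
#'
#' @param series a [pose_series()].
#' @param window numeric pair `c(from_s, to_s)` in seconds (inclusive); must
#'   contain at least one sample.
#' @param magnitude blend factor m (dimensionless).
#' @return The perturbed `pose_series`.
#' @export
inject_anomaly <- function(series, window, magnitude) {
  stopifnot(is_pose_series(series))
  if (length(window) != 2L || window[2] < window[1])
    stop("'window' must be c(from_s, to_s) with from <= to")
  sel <- series$times >= window[1] & series$times <= window[2]
  if (!any(sel)) stop("anomaly window contains no samples")
  a1 <- series$coeffs[sel, 1]
  a2 <- series$coeffs[sel, 2]
  series$coeffs[sel, 1] <- (1 - magnitude) * a1 + magnitude * a2
  series$coeffs[sel, 2] <- (1 - magnitude) * a2 + magnitude * a1
  series
}

#' Synthetic orthonormal eigenworm basis
#'
#' Columns are orthonormalised discrete sinusoids of increasing spatial
#' frequency along the body: column k is `cos(k * pi * x)` evaluated at the
#' n_angles segment midpoints and then orthonormalised, so column k has
#' exactly k sign changes from head to tail. This mimics the qualitative
#' structure of empirical eigenworms (smooth, increasingly oscillatory
#' principal components of body-segment tangent angles) and is exactly
#' orthonormal, which the error metrics rely on. It is a synthetic stand-in:
#' analyses of real recordings must use the basis shipped with the data.
#'
#' @param n_angles number of body-section angles (default 100; index 1 = head).
#' @param K number of basis columns (default 5); must satisfy `K <= n_angles`.
#' @return An `n_angles x K` matrix of class `eigen_basis`, radians per unit
#'   coefficient.
#' @export
make_synthetic_basis <- function(n_angles = 100L, K = 5L) {
  if (K > n_angles) stop("'K' must not exceed 'n_angles'")
  x <- (seq_len(n_angles) - 0.5) / n_angles
  raw <- sapply(seq_len(K), function(k) cos(k * pi * x))
  q <- qr.Q(qr(raw))
  # fix signs so every column starts positive at the head
  q <- sweep(q, 2, sign(q[1, ]), `*`)
  eigen_basis(q)
}

#' Deterministic chaotic benchmark series (partially observed Lorenz flow)
#'
#' Integrates the Lorenz system and observes only its x variable (written
#' into a1, with a2 identically zero). A single observed coordinate leaves
#' the state ambiguous, so one-step prediction from the instantaneous pose
#' alone (E = 1) carries an irreducible error, while a time-delay embedding
#' reconstructs the hidden state and prediction error falls sharply with E
#' — the canonical demonstration that embedding pays off on nonlinear
#' dynamics, used by the robustness-scan diagnostics.
#'
#' @param n number of samples.
#' @param dt sampling interval in seconds (default 0.02).
#' @param sigma,rho,beta Lorenz parameters (defaults 10, 28, 8/3: the
#'   chaotic regime).
#' @param scale multiplier applied to x (coefficient units).
#' @param transient leading samples discarded so the trajectory settles on
#'   the attractor.
#' @param name series identifier.
#' @return A [pose_series()] with K = 2. Deterministic: repeated calls give
#'   identical series.
#' @export
make_lorenz_series <- function(n, dt = 0.02, sigma = 10, rho = 28,
                               beta = 8 / 3, scale = 1, transient = 500L,
                               name = "lorenz") {
  deriv <- function(t, y, p) {
    list(c(sigma * (y[2] - y[1]),
           y[1] * (rho - y[3]) - y[2],
           y[1] * y[2] - beta * y[3]))
  }
  times <- seq(0, (n + transient - 1L) * dt, by = dt)
  out <- deSolve::ode(c(x = 1, y = 1, z = 20), times, deriv, NULL,
                      method = "lsoda")
  x <- out[-seq_len(transient), "x"]
  pose_series(cbind(scale * x[seq_len(n)], 0), dt = dt, name = name)
}

#' Deterministic chaotic benchmark series (Henon map)
#'
#' Observes only the x variable of the Henon map `x' = 1 - a x^2 + y`,
#' `y' = b x`, written into a1 with a2 identically zero. Because a single
#' observed coordinate does not determine the next state, one-step
#' prediction from the instantaneous pose alone is poor, while a time-delay
#' embedding recovers the full state — the canonical setting in which
#' increasing the embedding dimension must reduce prediction error. Used by
#' the robustness-scan diagnostics.
#'
#' @param n number of samples.
#' @param a,b Henon parameters (defaults 1.4, 0.3: the chaotic regime).
#' @param dt nominal sampling interval in seconds (the map is discrete; dt
#'   only sets the time axis).
#' @param scale multiplier applied to x (coefficient units).
#' @param transient leading iterations discarded before recording.
#' @param name series identifier.
#' @return A [pose_series()] with K = 2.
#' @export
make_henon_series <- function(n, a = 1.4, b = 0.3, dt = 0.05, scale = 5,
                              transient = 100L, name = "henon") {
  x <- 0.1; y <- 0.3
  out <- numeric(n)
  for (i in seq_len(n + transient)) {
    xn <- 1 - a * x^2 + y
    y <- b * x
    x <- xn
    if (i > transient) out[i - transient] <- x
  }
  pose_series(cbind(scale * out, 0), dt = dt, name = name)
}
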