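#' S-Map prediction settings
#'
#' The S-Map (sequential locally weighted global linear map) fits, for each
#' query point, one weighted linear model per output coefficient over the
#' library, with neighbour weights `w_i = exp(-theta * d_i / dbar)` where
#' `d_i` is the Euclidean distance from the query to library point i in the
#' full K*E-dimensional embedding space and `dbar` is the mean distance to
#' all admissible library points of that query. `theta = 0` gives a single
#' global linear model (all weights equal); larger `theta` makes the fit
#' increasingly local, tracking nonlinear attractor structure.
#'
#' @param theta nonlinearity parameter (>= 0, dimensionless; default 2).
#' @param include_intercept include an intercept in the local regression
#'   (default TRUE).
#' @param svd_rcond relative singular-value cutoff for the least-squares
#'   solve: singular values below `svd_rcond * max(s)` are discarded.
#'   Keeps the fit stable when the embedded trajectory is locally
#'   low-dimensional (e.g. a planar limit cycle embedded in 25 dimensions).
#' @param exclusion_steps temporal exclusion half-window in samples (a
#'   Theiler window): when library and queries come from the same source
#'   series, library points within this many samples of the query's time
#'   index are excluded from its fit. Default 0 (the typical use predicts
#'   from a disjoint library; set `>= Tp_steps` for within-library
#'   diagnostics).
#' @return A list of class `smap_config`.
#' @export
smap_config <- function(theta = 2, include_intercept = TRUE,
                        svd_rcond = 1e-8, exclusion_steps = 0L) {
  if (theta < 0) stop("'theta' must be >= 0")
  if (svd_rcond <= 0 || svd_rcond >= 1) stop("'svd_rcond' must lie in (0, 1)")
  if (exclusion_steps < 0) stop("'exclusion_steps' must be >= 0")
  structure(list(theta = theta, include_intercept = isTRUE(include_intercept),
                 svd_rcond = svd_rcond,
                 exclusion_steps = as.integer(exclusion_steps)),
            class = "smap_config")
}

new_prediction_result <- function(predicted, observed, time_index, Tp_steps,
                                  library_source, query_source,
                                  coefficients = NULL) {
  structure(list(predicted = predicted, observed = observed,
                 time_index = as.integer(time_index),
                 Tp_steps = as.integer(Tp_steps),
                 library_source = library_source, query_source = query_source,
                 coefficients = coefficients),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result>  %d predictions of %d coefficients (library '%s' -> query '%s')\n",
              nrow(x$predicted), ncol(x$predicted), x$library_source, x$query_source))
  cat(sprintf("  coefficient-space RMS error: %.6g\n",
              sqrt(mean((x$predicted - x$observed)^2))))
  invisible(x)
}

#' One-step S-Map prediction from a library attractor
#'
#' For every query lag vector, fits a locally weighted linear map from the
#' library embedding points to their one-step-ahead targets and evaluates it
#' at the query (see [smap_config()] for the weighting). Weights are shared
#' across the K output coefficients, which are fitted jointly on the same
#' design matrix. When the library and the queries come from the same source
#' series, library points within `exclusion_steps` of the query's own time
#' index are excluded so that prediction never leans on trivially
#' time-adjacent neighbours.
#'
#' @param library a [delay_embedding()] acting as the reference attractor;
#'   must have at least `K*E + 2` points.
#' @param queries a [delay_embedding()] of out-of-sample points with the
#'   same E, K, tau_steps and Tp_steps as the library.
#' @param config an [smap_config()].
#' @param save_coefficients keep the fitted local linear maps? If TRUE the
#'   result carries an array `coefficients` of dimension
#'   `(n_coef, K, n_queries)` (n_coef = K*E + 1 with intercept), with the
#'   intercept first and then the lag-major embedding coordinates.
#' @return A `prediction_result`: matrices `predicted` and `observed`
#'   (queries' targets), `time_index`, sources, and optionally the
#'   coefficient array.
#' @examples
#' s <- generate_series(synthetic_config(duration_s = 30, noise_sd = 0))$series
#' lib <- embed_continuous(s, E = 5, interval = c(1, 240))
#' qry <- embed_continuous(s, E = 5, interval = c(241, 480))
#' pr <- smap_predict(lib, qry)
#' pr
#' @export
smap_predict <- function(library, queries, config = smap_config(),
                         save_coefficients = FALSE) {
  stopifnot(inherits(library, "delay_embedding"),
            inherits(queries, "delay_embedding"),
            inherits(config, "smap_config"))
  if (library$E != queries$E || library$K != queries$K)
    stop("library and queries must share E and K")
  if (library$tau_steps != queries$tau_steps ||
      library$Tp_steps != queries$Tp_steps)
    stop("library and queries must share tau_steps and Tp_steps")
  if (nrow(library$points) < library$K * library$E + 2L)
    stop(sprintf("library has %d points; need at least K*E + 2 = %d",
                 nrow(library$points), library$K * library$E + 2L))
  if (!all(is.finite(queries$points)))
    stop("query embedding contains non-finite coordinates")
  same_source <- identical(library$source, queries$source)
  res <- smap_kernel(library$points, library$targets, library$time_index,
                     queries$points, queries$time_index,
                     theta = config$theta, rcond = config$svd_rcond,
                     exclusion_steps = config$exclusion_steps,
                     same_source = same_source,
                     intercept = config$include_intercept,
                     save_coef = isTRUE(save_coefficients))
  pred <- res$pred
  colnames(pred) <- colnames(queries$targets)
  new_prediction_result(pred, queries$targets, queries$time_index,
                        queries$Tp_steps, library$source, queries$source,
                        coefficients = res$coefficients)
}

#' Constant (persistence) predictor baseline
#'
#' Predicts that the pose `Tp_steps` ahead equals the current (lag-0) pose.
#' This is the reference baseline against which S-Map prediction error is
#' reported: at common video sampling rates successive poses are similar, so
#' any informative predictor must beat persistence.
#'
#' @param queries a [delay_embedding()].
#' @return A `prediction_result` with the lag-0 pose of each query as the
#'   prediction.
#' @export
constant_predict <- function(queries) {
  stopifnot(inherits(queries, "delay_embedding"))
  if (nrow(queries$points) == 0L) stop("no query points")
  pred <- queries$points[, seq_len(queries$K), drop = FALSE]
  colnames(pred) <- colnames(queries$targets)
  new_prediction_result(pred, queries$targets, queries$time_index,
                        queries$Tp_steps, "constant", queries$source)
}
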