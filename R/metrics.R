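#' Eigenworm basis
#'
#' An `n_angles x K` matrix whose columns are orthonormal eigenworms: each
#' column maps one pose coefficient to mean-centred tangent angles (radians)
#' of the `n_angles` equal body sections, with angle index 1 at the head.
#' A pose's body-angle profile is `coeffs %*% t(basis)`.
#'
#' @param matrix numeric `n_angles x K` matrix; columns must be orthonormal
#'   (checked to 1e-8).
#' @return The matrix with class `eigen_basis`.
#' @seealso [make_synthetic_basis()], [read_eigen_basis()]
#' @export
eigen_basis <- function(matrix) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (nrow(m) < ncol(m)) stop("basis must have at least as many angles as columns")
  g <- crossprod(m)
  if (max(abs(g - diag(ncol(m)))) > 1e-8)
    stop("basis columns are not orthonormal (tolerance 1e-8)")
  colnames(m) <- paste0("a", seq_len(ncol(m)))
  class(m) <- c("eigen_basis", "matrix")
  m
}

#' Read / write an eigenworm basis as a delimited matrix file
#'
#' The file holds the plain `n_angles x K` matrix (rows = body sections from
#' head to tail, columns = eigenworms), whitespace- or comma-delimited, no
#' header.
#'
#' @param path file path.
#' @param sep field separator (default whitespace on read, tab on write).
#' @return `read_eigen_basis()` returns an [eigen_basis()];
#'   `write_eigen_basis()` returns `path` invisibly.
#' @export
read_eigen_basis <- function(path, sep = "") {
  m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
  dimnames(m) <- NULL
  eigen_basis(m)
}

#' @rdname read_eigen_basis
#' @param basis an [eigen_basis()].
#' @export
write_eigen_basis <- function(basis, path, sep = "\t") {
  utils::write.table(format(unclass(basis), digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Convert eigenworm coefficients to body-section angles
#'
#' @param coeffs `T x K` matrix of coefficients (or a single pose vector).
#' @param basis an [eigen_basis()] with K columns.
#' @return `T x n_angles` matrix of mean-centred tangent angles in radians,
#'   head first. Linear in `coeffs`.
#' @export
eigen_to_angles <- function(coeffs, basis) {
  if (is.null(dim(coeffs))) coeffs <- matrix(coeffs, nrow = 1)
  if (ncol(coeffs) != ncol(basis))
    stop(sprintf("coefficient count %d does not match basis columns %d",
                 ncol(coeffs), ncol(basis)))
  coeffs %*% t(unclass(basis))
}

#' Per-sample RMS prediction error in body-angle and coefficient space
#'
#' Converts predicted and observed coefficients to body-section angles and
#' reports, per sample, the RMS angle error in radians (`rms_whole`, over
#' all `n_angles` sections) alongside the coefficient-space RMS error
#' (`rms_coeff`, over the K coefficients). With an orthonormal basis the two
#' are proportional: `rms_whole = rms_coeff * sqrt(K / n_angles)`.
#' Optionally also fills per-region errors (see [region_errors()]).
#'
#' @param pred a `prediction_result` from [smap_predict()] or
#'   [constant_predict()].
#' @param basis an [eigen_basis()].
#' @param n_regions if non-NULL, also compute per-region RMS errors over
#'   this many equal contiguous body regions.
#' @param constant_baseline_mean optional scalar: the time-mean `rms_whole`
#'   of the constant predictor on the same queries, carried as the
#'   reference baseline.
#' @return An object of class `error_series`: list with `time_index`,
#'   `rms_whole`, `rms_coeff`, `rms_regions` (R x T matrix or NULL),
#'   `constant_baseline_mean`.
#' @export
rms_angle_error <- function(pred, basis, n_regions = NULL,
                            constant_baseline_mean = NA_real_) {
  stopifnot(inherits(pred, "prediction_result"))
  d_ang <- eigen_to_angles(pred$predicted, basis) -
    eigen_to_angles(pred$observed, basis)
  rms_whole <- sqrt(rowMeans(d_ang^2))
  rms_coeff <- sqrt(rowMeans((pred$predicted - pred$observed)^2))
  rms_regions <- if (!is.null(n_regions)) region_errors(pred, basis, n_regions)
  structure(list(time_index = pred$time_index, rms_whole = rms_whole,
                 rms_coeff = rms_coeff, rms_regions = rms_regions,
                 constant_baseline_mean = constant_baseline_mean),
            class = "error_series")
}

#' @export
print.error_series <- function(x, ...) {
  cat(sprintf("<error_series>  %d samples; mean whole-body RMS error %.6g rad\n",
              length(x$rms_whole), mean(x$rms_whole)))
  if (is.finite(x$constant_baseline_mean))
    cat(sprintf("  constant-predictor baseline mean %.6g rad\n",
                x$constant_baseline_mean))
  invisible(x)
}

#' Prediction error localised along the body
#'
#' Splits the body-section angles into `n_regions` equal contiguous regions
#' ordered head to tail (with the defaults, region 1 = angles 1-20 at the
#' head, region 5 = angles 81-100 at the tail) and reports the RMS angle
#' error per region per sample. The squared whole-body error is the mean of
#' the squared region errors.
#'
#' @inheritParams rms_angle_error
#' @param n_regions number of regions; must divide `n_angles`.
#' @return `n_regions x T` matrix of RMS errors in radians, rows named
#'   `region_1..region_R` (head to tail).
#' @export
region_errors <- function(pred, basis, n_regions = 5L) {
  stopifnot(inherits(pred, "prediction_result"))
  n_angles <- nrow(basis)
  if (n_angles %% n_regions != 0L)
    stop(sprintf("n_regions = %d does not divide n_angles = %d", n_regions, n_angles))
  width <- n_angles %/% n_regions
  d_ang <- eigen_to_angles(pred$predicted, basis) -
    eigen_to_angles(pred$observed, basis)
  out <- matrix(NA_real_, n_regions, nrow(d_ang))
  for (r in seq_len(n_regions)) {
    cols <- ((r - 1L) * width + 1L):(r * width)
    out[r, ] <- sqrt(rowMeans(d_ang[, cols, drop = FALSE]^2))
  }
  rownames(out) <- paste0("region_", seq_len(n_regions))
  out
}

#' Reconstruct a planar worm shape from tangent angles
#'
#' Chains fixed-length segments: the head sits at the origin and each
#' successive joint advances by `segment_length` in the direction of that
#' section's tangent angle. Used to display predicted against observed worm
#' shapes (aligned at the head); purely a rendering device.
#'
#' @param angles vector of tangent angles in radians (head first).
#' @param segment_length length of one body section (default `1/n` so the
#'   worm has unit length).
#' @return `(n + 1) x 2` matrix of x, y vertex coordinates.
#' @export
angles_to_xy <- function(angles, segment_length = 1 / length(angles)) {
  stopifnot(all(is.finite(angles)))
  x <- c(0, cumsum(segment_length * cos(angles)))
  y <- c(0, cumsum(segment_length * sin(angles)))
  cbind(x = x, y = y)
}

# keep a row subset of an embedding (rows must be increasing)
take_points <- function(emb, rows) {
  delay_embedding(emb$points[rows, , drop = FALSE],
                  emb$targets[rows, , drop = FALSE],
                  emb$time_index[rows], emb$E, emb$tau_steps, emb$Tp_steps,
                  source = emb$source, shortfall = emb$shortfall)
}

mean_coeff_rms <- function(pred) {
  mean(sqrt(rowMeans((pred$predicted - pred$observed)^2)))
}

#' Robustness of prediction error to E and theta
#'
#' For each worm, builds one master discontinuous embedding at the largest
#' requested embedding dimension, splits its first `lib_points` points into
#' the library and the next `pred_points` into the prediction set, and
#' evaluates the time-mean coefficient-space RMS prediction error over a
#' scan of embedding dimensions E (at `fixed_theta`) and a scan of S-Map
#' theta values (at `fixed_E`). E values are evaluated on subsets of the
#' master embedding ([subset_embedding()]) so every cell uses the identical
#' point set. Coefficient-space error is used so worms recorded in
#' different coordinate conventions can be scanned with the same code.
#'
#' @param series_list list of [pose_series()] (one per worm), or a single
#'   series.
#' @param E_values integer vector of embedding dimensions (default 1:10).
#' @param theta_values numeric vector of S-Map theta values (default
#'   `seq(0, 8, by = 0.5)`).
#' @param lib_points,pred_points number of embedded points in the library
#'   and prediction sets (defaults 1000 each).
#' @param fixed_E embedding dimension held fixed for the theta scan
#'   (default 5).
#' @param fixed_theta theta held fixed for the E scan (default 2).
#' @param tau_steps,Tp_steps lag spacing and prediction horizon in samples.
#' @param start_sample first sample of the discontinuous scan (default 1).
#' @param svd_rcond,exclusion_steps passed to [smap_config()].
#' @return An object of class `robustness_grid`: `E_values`, `theta_values`,
#'   `fixed_E`, `fixed_theta`, matrices `e_scan` and `theta_scan` (one row
#'   per worm), their across-worm mean curves `e_scan_mean` and
#'   `theta_scan_mean`, and per-worm embedding `shortfalls`.
#' @export
robustness_scan <- function(series_list, E_values = 1:10,
                            theta_values = seq(0, 8, by = 0.5),
                            lib_points = 1000L, pred_points = 1000L,
                            fixed_E = 5L, fixed_theta = 2,
                            tau_steps = 1L, Tp_steps = 1L, start_sample = 1L,
                            svd_rcond = 1e-8, exclusion_steps = 0L) {
  if (is_pose_series(series_list)) series_list <- list(series_list)
  E_values <- sort(unique(as.integer(E_values)))
  E_max <- max(E_values, fixed_E)
  n_w <- length(series_list)
  worm_names <- vapply(series_list, function(s) s$name, character(1))
  e_scan <- matrix(NA_real_, n_w, length(E_values),
                   dimnames = list(worm_names, paste0("E", E_values)))
  theta_scan <- matrix(NA_real_, n_w, length(theta_values),
                       dimnames = list(worm_names, paste0("theta", theta_values)))
  shortfalls <- integer(n_w)

  for (w in seq_len(n_w)) {
    master <- embed_discontinuous(series_list[[w]], E = E_max,
                                  tau_steps = tau_steps, Tp_steps = Tp_steps,
                                  start_sample = start_sample,
                                  n_points = lib_points + pred_points)
    shortfalls[w] <- master$shortfall
    n_pts <- nrow(master$points)
    if (n_pts <= lib_points)
      stop(sprintf("worm '%s': only %d embedded points; need more than lib_points = %d",
                   worm_names[w], n_pts, lib_points))
    lib_rows <- seq_len(lib_points)
    pred_rows <- (lib_points + 1L):n_pts
    for (j in seq_along(E_values)) {
      sub <- subset_embedding(master, E_values[j])
      pr <- smap_predict(take_points(sub, lib_rows), take_points(sub, pred_rows),
                         smap_config(theta = fixed_theta, svd_rcond = svd_rcond,
                                     exclusion_steps = exclusion_steps))
      e_scan[w, j] <- mean_coeff_rms(pr)
    }
    sub <- subset_embedding(master, fixed_E)
    lib_e <- take_points(sub, lib_rows)
    qry_e <- take_points(sub, pred_rows)
    for (j in seq_along(theta_values)) {
      pr <- smap_predict(lib_e, qry_e,
                         smap_config(theta = theta_values[j],
                                     svd_rcond = svd_rcond,
                                     exclusion_steps = exclusion_steps))
      theta_scan[w, j] <- mean_coeff_rms(pr)
    }
  }
  structure(list(E_values = E_values, theta_values = theta_values,
                 fixed_E = as.integer(fixed_E), fixed_theta = fixed_theta,
                 e_scan = e_scan, theta_scan = theta_scan,
                 e_scan_mean = colMeans(e_scan),
                 theta_scan_mean = colMeans(theta_scan),
                 shortfalls = shortfalls),
            class = "robustness_grid")
}

#' @export
print.robustness_grid <- function(x, ...) {
  cat(sprintf("<robustness_grid>  %d worm(s); E scan at theta = %g over {%s}; theta scan at E = %d over [%g, %g]\n",
              nrow(x$e_scan), x$fixed_theta,
              paste(x$E_values, collapse = ","), x$fixed_E,
              min(x$theta_values), max(x$theta_values)))
  invisible(x)
}
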