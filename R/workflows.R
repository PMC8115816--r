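#' Shared analysis run configuration
#'
#' Bundles the parameters common to the analysis workflows. The defaults
#' are the mid-range settings used throughout the package's reference
#' analyses: embedding dimension `E = 5` poses (so 25 embedding coordinates
#' with K = 5 coefficients) and S-Map nonlinearity `theta = 2`, with lag
#' spacing and prediction horizon of one sample (`tau = Tp = dt`).
#'
#' @param E embedding dimension (number of successive poses; default 5).
#' @param theta S-Map nonlinearity (default 2).
#' @param tau_steps lag spacing in samples (default 1).
#' @param Tp_steps prediction horizon in samples (default 1).
#' @param basis an [eigen_basis()]; default `NULL` uses
#'   [make_synthetic_basis()] sized to the series (appropriate for synthetic
#'   data only — real data must supply their own basis).
#' @param classifier a [classifier_config()].
#' @param svd_rcond,exclusion_steps passed to [smap_config()].
#' @param n_regions body regions for error localisation (default 5).
#' @param embedding_method `"continuous"` (fixed gap-free intervals) or
#'   `"discontinuous"` (gap-tolerant scan).
#' @param out_dir if non-NULL, per-sample tables, a summary and a run
#'   manifest are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(E = 5L, theta = 2, tau_steps = 1L, Tp_steps = 1L,
                       basis = NULL, classifier = classifier_config(),
                       svd_rcond = 1e-8, exclusion_steps = 0L,
                       n_regions = 5L,
                       embedding_method = c("continuous", "discontinuous"),
                       out_dir = NULL) {
  structure(list(E = as.integer(E), theta = theta,
                 tau_steps = as.integer(tau_steps),
                 Tp_steps = as.integer(Tp_steps), basis = basis,
                 classifier = classifier, svd_rcond = svd_rcond,
                 exclusion_steps = as.integer(exclusion_steps),
                 n_regions = as.integer(n_regions),
                 embedding_method = match.arg(embedding_method),
                 out_dir = out_dir),
            class = "run_config")
}

resolve_basis <- function(config, series) {
  if (!is.null(config$basis)) return(config$basis)
  make_synthetic_basis(n_angles = 100L, K = ncol(series$coeffs))
}

# fixed-precision decimal (12 significant digits) for byte-stable outputs
fmt_num <- function(x) {
  out <- formatC(x, digits = 12, format = "g")
  out[is.na(x)] <- "NaN"
  trimws(out)
}

#' Read a delimited pose-coefficient table
#'
#' Expects a header row with a time column and one column per eigenworm
#' coefficient, comma- or tab/whitespace-delimited. Times must form a
#' regular, strictly increasing grid; cells equal to the missing token
#' become undefined (`NA`) samples. File rows are 1-based samples, so a
#' frame range quoted as e.g. 10001-11000 maps directly to
#' `interval = c(10001, 11000)`.
#'
#' @param path input file.
#' @param time_col name of the time column (default `"time"`, seconds).
#' @param coeff_cols coefficient column names (default all `a1, a2, ...`
#'   columns present, in order).
#' @param missing_token string marking missing values (default `"NaN"`).
#' @param sep field separator; `NULL` (default) picks comma when the header
#'   contains one, else whitespace.
#' @param name series identifier (default the file base name).
#' @param grid_tol relative tolerance on sampling-interval regularity.
#' @return A [pose_series()].
#' @export
read_pose_table <- function(path, time_col = "time", coeff_cols = NULL,
                            missing_token = "NaN", sep = NULL, name = NULL,
                            grid_tol = 1e-6) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      na.strings = unique(c(missing_token, "NA", "NaN")),
                      check.names = FALSE),
    error = function(e) stop("malformed pose table '", path, "': ",
                             conditionMessage(e)))
  if (!time_col %in% names(df))
    stop(sprintf("pose table '%s' is missing required time column '%s'",
                 path, time_col))
  if (is.null(coeff_cols)) {
    coeff_cols <- grep("^a[0-9]+$", names(df), value = TRUE)
    coeff_cols <- coeff_cols[order(as.integer(sub("^a", "", coeff_cols)))]
  }
  missing_cols <- setdiff(coeff_cols, names(df))
  if (length(missing_cols))
    stop(sprintf("pose table '%s' is missing coefficient column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  if (length(coeff_cols) < 2L)
    stop(sprintf("pose table '%s' has %d coefficient columns; need >= 2",
                 path, length(coeff_cols)))
  tm <- df[[time_col]]
  if (anyNA(tm) || !is.numeric(tm))
    stop(sprintf("pose table '%s': non-numeric or missing time values", path))
  d <- diff(tm)
  if (any(d <= 0))
    stop(sprintf("pose table '%s': time column is not strictly increasing (non-monotone at row %d)",
                 path, which(d <= 0)[1] + 1L))
  dt <- stats::median(d)
  if (any(abs(d - dt) > grid_tol * dt))
    stop(sprintf("pose table '%s': irregular sampling (max deviation %.3g s from dt = %.6g s)",
                 path, max(abs(d - dt)), dt))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pose_series(as.matrix(df[coeff_cols]), dt = dt, times = tm, name = name)
}

#' Write a pose series (and optional ground truth) to delimited files
#'
#' Writes columns `time, a1..aK` with `NaN` marking missing samples, at
#' full precision so a write/read round trip is lossless. Ground truth from
#' [generate_series()] goes to a sidecar file with columns
#' `time, true_omega, true_label, anomaly_mask`.
#'
#' @param series a [pose_series()].
#' @param path output file.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(series, path, sep = ",") {
  stopifnot(is_pose_series(series))
  df <- data.frame(time = sprintf("%.17g", series$times),
                   apply(series$coeffs, 2, function(x)
                     ifelse(is.na(x), "NaN", sprintf("%.17g", x))),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pose_table
#' @param truth ground-truth data.frame from [generate_series()].
#' @export
write_truth_table <- function(truth, path, sep = ",") {
  utils::write.table(truth, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

embed_interval <- function(series, interval, config) {
  if (config$embedding_method == "continuous") {
    embed_continuous(series, E = config$E, tau_steps = config$tau_steps,
                     Tp_steps = config$Tp_steps, interval = interval)
  } else {
    embed_discontinuous(series, E = config$E, tau_steps = config$tau_steps,
                        Tp_steps = config$Tp_steps,
                        start_sample = interval[1],
                        n_points = interval[2] - interval[1] + 1L)
  }
}

finish_run <- function(series, lib_emb, qry_emb, config, extra_summary = list()) {
  basis <- resolve_basis(config, series)
  sm_cfg <- smap_config(theta = config$theta, svd_rcond = config$svd_rcond,
                        exclusion_steps = config$exclusion_steps)
  pred <- smap_predict(lib_emb, qry_emb, sm_cfg)
  const <- constant_predict(qry_emb)
  const_err <- rms_angle_error(const, basis)
  errors <- rms_angle_error(pred, basis, n_regions = config$n_regions,
                            constant_baseline_mean = mean(const_err$rms_whole))
  classification <- classify(series, config$classifier)
  peak_i <- which.max(errors$rms_whole)
  summary <- c(list(
    E = config$E, theta = config$theta, tau_steps = config$tau_steps,
    Tp_steps = config$Tp_steps, embedding_method = config$embedding_method,
    library_source = lib_emb$source, query_source = qry_emb$source,
    library_points = nrow(lib_emb$points), prediction_points = nrow(qry_emb$points),
    library_shortfall = lib_emb$shortfall, prediction_shortfall = qry_emb$shortfall,
    mean_rms_whole_rad = mean(errors$rms_whole),
    mean_rms_coeff = mean(errors$rms_coeff),
    constant_baseline_mean_rad = errors$constant_baseline_mean,
    peak_error_rad = errors$rms_whole[peak_i],
    peak_error_sample = errors$time_index[peak_i],
    peak_error_predicted_sample = errors$time_index[peak_i] + config$Tp_steps
  ), extra_summary)
  run <- structure(list(errors = errors, constant_errors = const_err,
                        classification = classification, prediction = pred,
                        summary = summary, series = series, config = config),
                   class = "wormpred_run")
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' @export
print.wormpred_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<wormpred_run>  library '%s' (%d pts) -> query '%s' (%d pts), E = %d, theta = %g\n",
              s$library_source, s$library_points, s$query_source,
              s$prediction_points, s$E, s$theta))
  cat(sprintf("  mean body-angle RMS error %.6g rad (constant baseline %.6g rad)\n",
              s$mean_rms_whole_rad, s$constant_baseline_mean_rad))
  cat(sprintf("  peak error %.6g rad at sample %d (predicting sample %d)\n",
              s$peak_error_rad, s$peak_error_sample, s$peak_error_predicted_sample))
  invisible(x)
}

#' Write the per-sample tables, summary and manifest of a run
#'
#' Emits `errors.csv` (time, rms_whole, rms_coeff, region_1..R,
#' constant_error), `classification.csv` (time, label, omega),
#' `summary.txt` (key-value lines) and `manifest.json`. Numeric columns use
#' fixed 12-significant-digit formatting so repeated runs are byte-stable.
#'
#' @param run a `wormpred_run` from one of the workflow functions.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  err <- run$errors
  tab <- data.frame(time = fmt_num(run$series$times[err$time_index]),
                    rms_whole = fmt_num(err$rms_whole),
                    rms_coeff = fmt_num(err$rms_coeff),
                    stringsAsFactors = FALSE)
  if (!is.null(err$rms_regions))
    for (r in seq_len(nrow(err$rms_regions)))
      tab[[rownames(err$rms_regions)[r]]] <- fmt_num(err$rms_regions[r, ])
  tab$constant_error <- fmt_num(run$constant_errors$rms_whole)
  utils::write.table(tab, file.path(out_dir, "errors.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  cl <- as.data.frame(run$classification)
  cl$time <- fmt_num(cl$time); cl$omega <- fmt_num(cl$omega)
  utils::write.table(cl, file.path(out_dir, "classification.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  s <- run$summary
  writeLines(paste0(names(s), ": ",
                    vapply(s, function(v) if (is.numeric(v)) fmt_num(v) else
                      as.character(v), character(1))),
             file.path(out_dir, "summary.txt"))
  manifest <- c(s[!vapply(s, is.null, logical(1))],
                list(files = c("errors.csv", "classification.csv", "summary.txt")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Within-series change detection
#'
#' The core analysis: embed a reference library interval and a disjoint
#' prediction interval of the same series, predict each prediction-interval
#' pose one step ahead with the S-Map, and report whole-body and per-region
#' body-angle prediction error together with the constant-predictor
#' baseline and the behavioural classification of the full series.
#' Intervals are 1-based inclusive sample ranges (e.g. library
#' `c(10001, 11000)`, prediction `c(11001, 12000)`).
#'
#' @param series a [pose_series()].
#' @param lib_interval,pred_interval sample pairs `c(first, last)`; must not
#'   overlap.
#' @param config a [run_config()].
#' @return A `wormpred_run`: list with `errors` (an `error_series`),
#'   `constant_errors`, `classification`, `prediction`, `summary`.
#' @export
run_change_detection <- function(series, lib_interval, pred_interval,
                                 config = run_config()) {
  stopifnot(is_pose_series(series))
  if (max(lib_interval[1], pred_interval[1]) <=
      min(lib_interval[2], pred_interval[2]))
    stop("library and prediction intervals overlap")
  lib_emb <- embed_interval(series, lib_interval, config)
  qry_emb <- embed_interval(series, pred_interval, config)
  finish_run(series, lib_emb, qry_emb, config,
             list(workflow = "change_detection",
                  library_interval = paste(lib_interval, collapse = "-"),
                  prediction_interval = paste(pred_interval, collapse = "-"),
                  library_interval_samples = diff(lib_interval) + 1L,
                  prediction_interval_samples = diff(pred_interval) + 1L))
}

#' Escape-response analysis with a pre-stimulus baseline library
#'
#' Uses the first `library_fraction` of the samples recorded before the
#' stimulus as the baseline reference library, then predicts every later
#' sample with a defined embedding point. Elevated error after the stimulus
#' measures departure from baseline dynamics; its decay tracks the return
#' to baseline.
#'
#' @param series a [pose_series()].
#' @param stimulus_time stimulus onset in seconds (must lie inside the
#'   series).
#' @param library_fraction fraction of pre-stimulus samples used as the
#'   library (default 0.8).
#' @param config a [run_config()].
#' @return A `wormpred_run` (see [run_change_detection()]); the summary
#'   records `stimulus_time` and `library_samples`.
#' @export
run_escape_analysis <- function(series, stimulus_time, library_fraction = 0.8,
                                config = run_config()) {
  stopifnot(is_pose_series(series))
  if (stimulus_time <= series$times[1] ||
      stimulus_time >= series$times[n_samples(series)])
    stop("stimulus_time must lie inside the series")
  n_pre <- sum(series$times < stimulus_time)
  n_lib <- floor(library_fraction * n_pre)
  min_span <- (config$E - 1L) * config$tau_steps + config$Tp_steps + 1L
  if (n_lib < min_span)
    stop(sprintf("only %d pre-stimulus library samples; need >= %d for E = %d",
                 n_lib, min_span, config$E))
  if (n_lib >= n_samples(series) - config$Tp_steps)
    stop("no samples left to predict after the library")
  lib_emb <- embed_interval(series, c(1L, n_lib), config)
  qry_emb <- embed_discontinuous(series, E = config$E,
                                 tau_steps = config$tau_steps,
                                 Tp_steps = config$Tp_steps,
                                 start_sample = n_lib + 1L)
  finish_run(series, lib_emb, qry_emb, config,
             list(workflow = "escape_analysis", stimulus_time = stimulus_time,
                  library_fraction = library_fraction,
                  library_samples = n_lib))
}

#' Cross-individual prediction
#'
#' Uses the entire time series of one worm as the reference library and
#' predicts the entire time series of another. Error is asymmetric:
#' behaviours present in the query but absent from the library worm show up
#' as error peaks in one direction only. A sampling-rate mismatch between
#' the two series is tolerated with a warning (the method is robust to
#' moderate rate changes); a coefficient-count mismatch is fatal.
#'
#' @param library_series,query_series [pose_series()] objects sharing K.
#'   If they are the same series (same name), self-prediction uses the
#'   configured temporal exclusion window.
#' @param config a [run_config()].
#' @return A `wormpred_run` for the query series.
#' @export
run_cross_prediction <- function(library_series, query_series,
                                 config = run_config()) {
  stopifnot(is_pose_series(library_series), is_pose_series(query_series))
  if (ncol(library_series$coeffs) != ncol(query_series$coeffs))
    stop("library and query series have different numbers of coefficients")
  if (abs(library_series$dt - query_series$dt) > 1e-9)
    warning(sprintf("sampling interval mismatch (library %g s, query %g s); proceeding",
                    library_series$dt, query_series$dt))
  lib_emb <- embed_discontinuous(library_series, E = config$E,
                                 tau_steps = config$tau_steps,
                                 Tp_steps = config$Tp_steps, start_sample = 1L)
  qry_emb <- embed_discontinuous(query_series, E = config$E,
                                 tau_steps = config$tau_steps,
                                 Tp_steps = config$Tp_steps, start_sample = 1L)
  finish_run(query_series, lib_emb, qry_emb, config,
             list(workflow = "cross_prediction",
                  library_series = library_series$name,
                  query_series = query_series$name))
}

#' Robustness-scan workflow over several worms
#'
#' Runs [robustness_scan()] over a list of series, skipping (with a
#' message) worms that cannot supply enough embedded points, and optionally
#' writes the per-worm grids and across-worm mean curves as delimited
#' tables plus a manifest.
#'
#' @param series_list list of [pose_series()].
#' @param E_values,theta_values,lib_points,pred_points,fixed_E,fixed_theta
#'   see [robustness_scan()].
#' @param config a [run_config()] (supplies tau/Tp/rcond and `out_dir`).
#' @param min_points minimum embedded points for a worm to be scanned
#'   (default `lib_points + 50`).
#' @return The `robustness_grid` (invisibly NULL if every worm was
#'   skipped); skipped worms are reported via messages.
#' @export
run_robustness <- function(series_list, E_values = 1:10,
                           theta_values = seq(0, 8, by = 0.5),
                           lib_points = 1000L, pred_points = 1000L,
                           fixed_E = 5L, fixed_theta = 2,
                           config = run_config(),
                           min_points = lib_points + 50L) {
  if (is_pose_series(series_list)) series_list <- list(series_list)
  E_max <- max(E_values, fixed_E)
  keep <- vapply(series_list, function(s) {
    n_ok <- tryCatch(nrow(embed_discontinuous(
      s, E = E_max, tau_steps = config$tau_steps, Tp_steps = config$Tp_steps,
      start_sample = 1L)$points), error = function(e) 0L)
    if (n_ok < min_points) {
      message(sprintf("skipping worm '%s': %d embedded points < minimum %d",
                      s$name, n_ok, min_points))
      FALSE
    } else TRUE
  }, logical(1))
  series_list <- series_list[keep]
  if (!length(series_list)) return(invisible(NULL))
  grid <- robustness_scan(series_list, E_values = E_values,
                          theta_values = theta_values,
                          lib_points = lib_points, pred_points = pred_points,
                          fixed_E = fixed_E, fixed_theta = fixed_theta,
                          tau_steps = config$tau_steps,
                          Tp_steps = config$Tp_steps,
                          svd_rcond = config$svd_rcond,
                          exclusion_steps = config$exclusion_steps)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_grid <- function(m, mean_curve, path) {
      vals <- rbind(m, mean = mean_curve)
      df <- data.frame(worm = rownames(vals), stringsAsFactors = FALSE)
      for (j in colnames(m)) df[[j]] <- fmt_num(vals[, j])
      utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    }
    write_grid(grid$e_scan, grid$e_scan_mean,
               file.path(config$out_dir, "robustness_E.csv"))
    write_grid(grid$theta_scan, grid$theta_scan_mean,
               file.path(config$out_dir, "robustness_theta.csv"))
    jsonlite::write_json(list(workflow = "robustness",
                              E_values = grid$E_values,
                              theta_values = grid$theta_values,
                              fixed_E = grid$fixed_E,
                              fixed_theta = grid$fixed_theta,
                              lib_points = lib_points,
                              pred_points = pred_points,
                              worms = rownames(grid$e_scan),
                              shortfalls = grid$shortfalls),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  grid
}
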