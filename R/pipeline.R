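#' Pipeline configuration
#'
#' Bundles every tunable of the preprocess - transform - reduce - train -
#' slide-and-predict chain. Defaults follow the standard surveillance
#' settings: a 10 CFU/100 ml event threshold, 90-day windows (the
#' regulatory sampling-interval unit), and 30 retained DCT coefficients.
#'
#' @param threshold Event threshold, CFU/100 ml.
#' @param window_days Window (and pre-event span) length in days.
#' @param n_coeffs Number of DCT coefficients retained per window.
#' @param history_days Training-span length in days (a prefix of the
#'   grid); \code{NULL} means half the grid, set per well at run time.
#' @param classifier \code{"mve"}, \code{"svm"}, \code{"ann"} or
#'   \code{"energy"}.
#' @param seed Master seed (coefficient selection, ANN initialization).
#' @param stride Day step between prediction windows.
#' @param train_stride Day step between training windows (default 7;
#'   overlapping daily training windows add little beyond cost).
#' @param C,kernel SVM settings (see \code{\link{svm_train}}).
#' @param label_rule Window labeling, \code{"span"} or \code{"exceedance"}
#'   (see \code{\link{extract_windows}}).
#' @param standardize Standardize reduced coefficients with training-set
#'   center/scale before classification; off by default.
#' @param mve_tolerance Khachiyan convergence tolerance.
#' @param include_dc Force the DC coefficient into the selection.
#' @param energy_threshold,energy_window Parameters of the
#'   \code{"energy"} classifier mode.
#' @param ann_f_range,ann_d_range,ann_horizon Neural-baseline search
#'   ranges and forecast horizon.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(threshold = 10, window_days = 90, n_coeffs = 30,
                            history_days = NULL, classifier = c("mve", "svm",
                            "ann", "energy"), seed = 1, stride = 1,
                            train_stride = 7, C = 1, kernel = "linear",
                            label_rule = c("span", "exceedance"),
                            standardize = FALSE, mve_tolerance = 1e-7,
                            include_dc = FALSE, energy_threshold = NULL,
                            energy_window = NULL, ann_f_range = 1:4,
                            ann_d_range = c(7L, 14L), ann_horizon = 14L) {
  classifier <- match.arg(classifier)
  label_rule <- match.arg(label_rule)
  stopifnot(threshold > 0, window_days >= 1,
            n_coeffs >= 1, n_coeffs <= window_days)
  if (!is.null(history_days) && history_days < window_days)
    stop("history_days must be at least window_days")
  structure(list(threshold = threshold, window_days = as.integer(window_days),
                 n_coeffs = as.integer(n_coeffs), history_days = history_days,
                 classifier = classifier, seed = seed,
                 stride = as.integer(stride),
                 train_stride = as.integer(train_stride), C = C,
                 kernel = kernel, label_rule = label_rule,
                 standardize = standardize, mve_tolerance = mve_tolerance,
                 include_dc = include_dc,
                 energy_threshold = energy_threshold,
                 energy_window = energy_window, ann_f_range = ann_f_range,
                 ann_d_range = ann_d_range, ann_horizon = ann_horizon),
            class = "pipeline_config")
}

# Reduced spectral features for the window positions in `starts`.
.reduced_features <- function(grid, starts, config, selection) {
  sp <- sliding_spectra(grid, config$window_days, stride = 1L,
                        mode = "incremental")
  rows <- match(starts, sp$starts)
  sp$coefficients[rows, selection$indices + 1L, drop = FALSE]
}

.window_labels <- function(grid, labels, starts, config) {
  n <- length(grid$values)
  w <- config$window_days
  if (config$label_rule == "span") {
    cmask <- logical(n)
    if (length(labels$days)) cmask[labels$days + 1L] <- TRUE
    vapply(starts, function(s) any(cmask[(s + 1L):(s + w)]), logical(1))
  } else {
    vapply(starts, function(s) {
      i <- (s + 1L):(s + w)
      any(grid$observed[i] & grid$values[i] > config$threshold)
    }, logical(1))
  }
}

#' Train the configured classifier(s) on the historical prefix
#'
#' Windows are cut from the first \code{history_days} of the grid at
#' \code{train_stride}, transformed, reduced with a coefficient selection
#' drawn once from the run seed, and labeled. The SVM learns from
#' contaminated and non-contaminated windows; the minimum-volume ellipsoid
#' is fitted around the non-contaminated windows only (engineers care when
#' a sample deviates from the norm); the neural baseline delay-embeds the
#' daily counts of the training span.
#'
#' @param grid A \code{daily_grid}.
#' @param labels \code{\link{contaminated_spans}} labels for the grid.
#' @param config A \code{\link{pipeline_config}} with
#'   \code{history_days} set.
#' @return Object of class \code{swell_models}: the coefficient
#'   \code{selection}, trained \code{svm} / \code{mve} / \code{ann} (as
#'   configured), feature \code{scaling}, \code{trained_through} (first
#'   unseen day offset) and the config snapshot.
#' @export
train_models <- function(grid, labels, config) {
  stopifnot(inherits(grid, "daily_grid"), inherits(config, "pipeline_config"))
  hist <- config$history_days
  if (is.null(hist)) stop("config$history_days must be set before training")
  hist <- as.integer(min(hist, length(grid$values)))
  if (hist < config$window_days) stop("history shorter than one window")
  tgrid <- structure(list(start_date = grid$start_date,
                          values = grid$values[1:hist],
                          observed = grid$observed[1:hist],
                          well_id = grid$well_id),
                     class = "daily_grid")
  selection <- select_coefficients(config$window_days, config$n_coeffs,
                                   seed = derive_seed(config$seed, 17),
                                   include_dc = config$include_dc)
  starts <- seq.int(0L, hist - config$window_days, by = config$train_stride)
  F <- .reduced_features(tgrid, starts, config, selection)
  contaminated <- .window_labels(tgrid, labels, starts, config)
  scaling <- NULL
  if (config$standardize) {
    mu <- colMeans(F); sd <- apply(F, 2, stats::sd)
    sd[sd == 0] <- 1
    scaling <- list(center = mu, scale = sd)
    F <- scale(F, mu, sd)
  }
  svm <- mve <- ann <- NULL
  if (config$classifier == "svm") {
    if (length(unique(contaminated)) < 2L)
      stop("SVM training needs both contaminated and normal windows in ",
           "the historical span; none of one class found")
    svm <- svm_train(F, ifelse(contaminated, 1, -1), C = config$C,
                     kernel = config$kernel)
  } else if (config$classifier == "mve") {
    normals <- F[!contaminated, , drop = FALSE]
    if (nrow(normals) < config$n_coeffs + 1L)
      stop("too few non-contaminated training windows (", nrow(normals),
           ") for an ellipsoid in ", config$n_coeffs, " dimensions")
    mve <- mve_fit(normals, tolerance = config$mve_tolerance)
  } else if (config$classifier == "ann") {
    ann <- ann_fit_grid(tgrid$values, f_range = config$ann_f_range,
                        d_range = config$ann_d_range,
                        seed = derive_seed(config$seed, 29), maxit = 150)
  }
  structure(list(selection = selection, svm = svm, mve = mve, ann = ann,
                 scaling = scaling, trained_through = hist,
                 n_train_windows = length(starts),
                 n_train_contaminated = sum(contaminated),
                 config = config),
            class = "swell_models")
}

#' Slide across unseen data and throw alarms
#'
#' Every window position whose last day lies beyond the training span is
#' transformed, reduced with the stored coefficient selection, and
#' classified; a window classified contaminated throws an alarm on its
#' last day.
#'
#' @param grid The full \code{daily_grid}.
#' @param models A \code{\link{train_models}} result.
#' @param config Optional config override; must match the one the models
#'   were trained with (selection indices and window length).
#' @return Sorted 0-based alarm day offsets.
#' @export
predict_alarms <- function(grid, models, config = models$config) {
  stopifnot(inherits(models, "swell_models"))
  if (!identical(config$window_days, models$config$window_days) ||
      !identical(config$n_coeffs, models$config$n_coeffs) ||
      !identical(config$seed, models$config$seed))
    stop("config does not match the trained models ",
         "(window, coefficient count and seed must agree)")
  n <- length(grid$values)
  w <- config$window_days
  hist <- models$trained_through
  first_start <- max(0L, hist - w + 1L)
  if (first_start > n - w) return(integer(0))
  starts <- seq.int(first_start, n - w, by = config$stride)
  if (config$classifier == "energy") {
    if (is.null(config$energy_threshold) || is.null(config$energy_window))
      stop("energy mode needs energy_threshold and energy_window")
    jump <- energy_jump(grid, config$energy_window)
    al <- energy_alarm(jump, config$energy_threshold)
    return(al[al >= hist])
  }
  if (config$classifier == "ann") {
    flag <- vapply(starts, function(s) {
      recent <- grid$values[1:(s + w)]
      ann_alarm(models$ann, recent, event_threshold = config$threshold,
                horizon = config$ann_horizon) == "alarm"
    }, logical(1))
    return(starts[flag] + w - 1L)
  }
  F <- .reduced_features(grid, starts, config, models$selection)
  if (!is.null(models$scaling))
    F <- scale(F, models$scaling$center, models$scaling$scale)
  flag <- if (config$classifier == "svm") {
    svm_predict(models$svm, F) == 1L
  } else {
    mve_classify(models$mve, F) == "outlier"
  }
  starts[flag] + w - 1L
}

#' Score alarms against events
#'
#' An event counts as detected when at least one alarm falls in its
#' pre-event window \code{[e - window_days, e - 1]}; the time saved is the
#' gap from the first such alarm to the event day. False positives are
#' alarm days falling outside every contaminated span, as a fraction of
#' the evaluated days outside contaminated spans (alarms inside a span are
#' never false positives, even after the event day).
#'
#' @param alarms Alarm day offsets.
#' @param events Event day offsets.
#' @param labels \code{\link{contaminated_spans}} labels.
#' @param window_days Detection-crediting window, default
#'   \code{labels$span_days}.
#' @param eval_days Day offsets over which predictions were made (the
#'   false-positive denominator); defaults to all days up to the last
#'   alarm/event/label day.
#' @return Object of class \code{eval_report}: \code{n_events},
#'   \code{detected}, \code{fn_fraction}, \code{fp_fraction},
#'   \code{avg_time_saved}, per-event \code{time_saved} (NA when missed)
#'   and alarm counts. With zero events the FN fraction and time saved are
#'   NA and flagged.
#' @export
evaluate_alarms <- function(alarms, events, labels,
                            window_days = labels$span_days,
                            eval_days = NULL) {
  alarms <- sort(as.integer(alarms))
  events <- sort(as.integer(events))
  if (is.null(eval_days)) {
    top <- max(c(alarms, events, labels$days, 0L))
    eval_days <- 0:top
  }
  time_saved <- rep(NA_real_, length(events))
  for (i in seq_along(events)) {
    e <- events[i]
    hit <- alarms[alarms >= e - window_days & alarms < e]
    if (length(hit)) time_saved[i] <- e - hit[1L]
  }
  detected <- sum(!is.na(time_saved))
  n_events <- length(events)
  cset <- labels$days
  fp_alarms <- setdiff(alarms, cset)
  clean_days <- setdiff(eval_days, cset)
  structure(list(
    n_events = n_events, detected = detected,
    fn_fraction = if (n_events) 1 - detected / n_events else NA_real_,
    fp_fraction = if (length(clean_days))
      length(intersect(fp_alarms, clean_days)) / length(clean_days)
      else NA_real_,
    avg_time_saved = if (detected) mean(time_saved, na.rm = TRUE) else NA_real_,
    time_saved = time_saved, n_alarms = length(alarms),
    n_false_alarm_days = length(intersect(fp_alarms, clean_days)),
    events_defined = n_events > 0),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$n_events, "events,", x$detected, "detected",
      sprintf("(FN %.0f%%)", 100 * x$fn_fraction),
      "- FP day fraction", sprintf("%.3f", x$fp_fraction),
      "- avg time saved",
      if (is.na(x$avg_time_saved)) "NA" else
        sprintf("%.1f days", x$avg_time_saved), "\n")
  invisible(x)
}

#' Run the full early-warning chain on one well
#'
#' Categorizes the series, grids it, labels contamination spans, trains
#' the configured classifier on the historical prefix, slides across the
#' held-out remainder, and scores the alarms against the held-out events
#' (events falling after the training span). Optionally writes
#' \code{alarms.csv}, \code{report.json} and \code{model.json} to
#' \code{outdir}; identical config and seed reproduce the outputs byte for
#' byte.
#'
#' @param series A \code{\link{count_series}}.
#' @param config A \code{\link{pipeline_config}}; a \code{NULL}
#'   \code{history_days} defaults to half the grid span.
#' @param outdir Optional output directory.
#' @return A list: \code{report} (\code{eval_report}), \code{alarms},
#'   \code{events}, \code{heldout_events}, \code{models},
#'   \code{category}, \code{config}.
#' @export
run_well <- function(series, config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(series, "count_series"))
  category <- classify_series(series, config$threshold, config$window_days)
  if (category != "Action")
    warning("series '", series$well_id, "' is categorized ", category,
            ": outburst prediction needs repeated episodes with non-zero ",
            "run-ups and may be impossible here")
  grid <- to_daily_grid(series)
  n <- length(grid$values)
  if (is.null(config$history_days))
    config$history_days <- max(config$window_days, n %/% 2L)
  events <- mark_events(grid, config$threshold)
  labels <- contaminated_spans(events, config$window_days)
  models <- train_models(grid, labels, config)
  alarms <- predict_alarms(grid, models, config)
  hist <- models$trained_through
  heldout <- events[events >= hist]
  eval_days <- seq.int(hist, n - 1L)
  report <- evaluate_alarms(alarms, heldout, labels,
                            window_days = config$window_days,
                            eval_days = eval_days)
  out <- list(report = report, alarms = alarms, events = events,
              heldout_events = heldout, models = models,
              category = category, config = config)
  if (!is.null(outdir)) write_run(out, grid, outdir)
  out
}

# Serialize a run: alarms.csv, report.json, model.json.
write_run <- function(run, grid, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  al <- data.frame(day_offset = run$alarms,
                   date = format(grid$start_date + run$alarms))
  utils::write.csv(al, file.path(outdir, "alarms.csv"), row.names = FALSE,
                   quote = FALSE)
  rep <- run$report
  jsonlite::write_json(list(
    well_id = grid$well_id, category = run$category,
    n_events = rep$n_events, detected = rep$detected,
    fn_fraction = rep$fn_fraction, fp_fraction = rep$fp_fraction,
    avg_time_saved = rep$avg_time_saved, time_saved = rep$time_saved,
    n_alarms = rep$n_alarms,
    config = run$config[c("threshold", "window_days", "n_coeffs",
                          "history_days", "classifier", "seed", "stride",
                          "train_stride")]),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", na = "null", pretty = TRUE)
  m <- run$models
  model_json <- list(selection = list(indices = m$selection$indices,
                                      seed = m$selection$seed),
                     trained_through = m$trained_through)
  if (!is.null(m$svm))
    model_json$svm <- list(w = m$svm$w, b = m$svm$b, C = m$svm$C,
                           kernel = m$svm$kernel)
  if (!is.null(m$mve))
    model_json$mve <- list(center = m$mve$center,
                           shape = as.vector(m$mve$shape),
                           dim = length(m$mve$center),
                           tolerance = m$mve$tolerance)
  if (!is.null(m$ann))
    model_json$ann <- list(f = m$ann$f, d = m$ann$d, nmse = m$ann$nmse,
                           weights = m$ann$fit$wts, scale = m$ann$scale)
  jsonlite::write_json(model_json, file.path(outdir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Sweep the number of retained coefficients
#'
#' Repeats \code{\link{run_well}} over a grid of coefficient counts and
#' reports the missed-event fraction (and wall time, for information
#' only) per count -- the dimension-reduction trade-off curve.
#'
#' @param series A \code{count_series}.
#' @param config Base \code{pipeline_config}.
#' @param m_values Coefficient counts to try (within
#'   \code{[1, window_days]}).
#' @return \code{data.frame} with columns \code{m},
#'   \code{missed_fraction}, \code{n_heldout_events}, \code{seconds}.
#' @export
coefficient_sweep <- function(series, config, m_values) {
  stopifnot(all(m_values >= 1), all(m_values <= config$window_days))
  rows <- lapply(m_values, function(m) {
    cfg <- config
    cfg$n_coeffs <- as.integer(m)
    tm <- system.time(run <- suppressWarnings(run_well(series, cfg)))
    data.frame(m = m, missed_fraction = run$report$fn_fraction,
               n_heldout_events = run$report$n_events,
               seconds = unname(tm["elapsed"]))
  })
  do.call(rbind, rows)
}
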