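#' Signal energy of a count vector
#'
#' The energy of a discrete count signal is the sum of its squared values.
#' Higher counts mean higher energy, so a rise in energy flags bacterial
#' activity in the well.
#'
#' @param values Numeric vector of counts.
#' @return Scalar energy (squared-count units).
#' @export
signal_energy <- function(values) sum(as.numeric(values)^2)

#' Trailing-window energy jump
#'
#' For each day t the jump is \code{E(t) - E(t - window_days)}, where E is
#' the cumulative signal energy up to day t: the energy contributed by the
#' trailing \code{window_days} days. For the first \code{window_days - 1}
#' days the trailing window is truncated at the start of the grid.
#'
#' @param grid A \code{daily_grid} (or numeric vector of daily counts).
#' @param window_days Width of the trailing window in days.
#' @return Numeric vector, one jump per grid day (0-based day t at
#'   position t + 1).
#' @export
energy_jump <- function(grid, window_days) {
  values <- if (inherits(grid, "daily_grid")) grid$values else as.numeric(grid)
  n <- length(values)
  if (window_days < 1 || window_days > n)
    stop("window_days must lie in [1, grid length]")
  cs <- cumsum(values^2)
  lag <- c(rep(0, min(window_days, n)), cs[seq_len(n - window_days)])
  cs - lag
}

#' Threshold an energy-jump series into alarms
#'
#' @param jump Numeric jump series from \code{\link{energy_jump}}.
#' @param threshold Positive energy threshold (squared-count units).
#' @return Sorted 0-based day offsets where the jump strictly exceeds the
#'   threshold.
#' @export
energy_alarm <- function(jump, threshold) {
  stopifnot(threshold > 0)
  which(jump > threshold) - 1L
}

#' Pareto-frontier tuning of the energy alarm
#'
#' Every (threshold, window size) pair on the candidate grids is scored by
#' average warning time saved and false-positive day fraction; the
#' non-dominated set (more time saved, fewer false positives) is the
#' Pareto frontier. Each well gets its own optimum -- wells are
#' idiosyncratic, so neither parameter generalizes across wells.
#'
#' The returned \code{selected} operating point is the knee of the
#' frontier: the point at maximal perpendicular distance from the chord
#' joining the frontier extremes (objectives rescaled to [0, 1] first).
#' Alternatively \code{fp_cap} picks the point maximizing time saved
#' subject to a false-positive ceiling.
#'
#' @param grid A \code{daily_grid}.
#' @param events Event day offsets from \code{\link{mark_events}}.
#' @param thresholds Candidate energy thresholds; default 50 log-spaced
#'   values spanning the observed positive jump range.
#' @param windows Candidate window sizes in days; default
#'   \code{seq(10, 400, by = 10)} (capped at the grid length).
#' @param span_days Pre-event span for crediting detections, default 90.
#' @param fp_cap Optional false-positive ceiling for the alternative
#'   selection rule.
#' @return List: \code{points} (data frame of every candidate with
#'   objectives and a \code{frontier} flag), \code{frontier} (non-dominated
#'   subset, sorted by false-positive fraction), \code{selected} (one row).
#'   With no events the time-saved objective is undefined (\code{NA}) and
#'   only false positives are optimized.
#' @export
pareto_search <- function(grid, events, thresholds = NULL, windows = NULL,
                          span_days = 90, fp_cap = NULL) {
  stopifnot(inherits(grid, "daily_grid"))
  n <- length(grid$values)
  if (is.null(windows)) windows <- seq(10L, 400L, by = 10L)
  windows <- windows[windows <= n]
  if (!length(windows)) stop("no candidate window fits the grid")
  jumps <- lapply(windows, function(w) energy_jump(grid, w))
  if (is.null(thresholds)) {
    pos <- unlist(lapply(jumps, function(j) j[j > 0]))
    if (!length(pos)) stop("grid has no energy activity to threshold")
    thresholds <- exp(seq(log(max(min(pos), 1e-6)), log(max(pos)),
                          length.out = 50))
  }
  labels <- contaminated_spans(events, span_days)
  rows <- list()
  for (wi in seq_along(windows)) {
    for (th in thresholds) {
      alarms <- energy_alarm(jumps[[wi]], th)
      ev <- evaluate_alarms(alarms, events, labels, window_days = span_days,
                            eval_days = 0:(n - 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        threshold = th, window_days = windows[wi],
        avg_time_saved = ev$avg_time_saved,
        false_positive_fraction = ev$fp_fraction,
        true_positive_rate = if (ev$n_events) 1 - ev$fn_fraction else NA_real_,
        n_alarms = length(alarms))
    }
  }
  pts <- do.call(rbind, rows)
  no_events <- length(events) == 0L
  ts <- ifelse(is.na(pts$avg_time_saved), 0, pts$avg_time_saved)
  if (no_events) ts <- rep(0, nrow(pts))
  pts$frontier <- pareto_front(ts, pts$false_positive_fraction)
  front <- pts[pts$frontier, , drop = FALSE]
  front <- front[order(front$false_positive_fraction,
                       -ifelse(is.na(front$avg_time_saved), 0,
                               front$avg_time_saved)), , drop = FALSE]
  sel <- if (!is.null(fp_cap)) {
    ok <- front[front$false_positive_fraction <= fp_cap, , drop = FALSE]
    if (nrow(ok)) ok[which.max(ifelse(is.na(ok$avg_time_saved), 0,
                                      ok$avg_time_saved)), ]
    else front[1L, ]
  } else {
    front[knee_point(ifelse(is.na(front$avg_time_saved), 0,
                            front$avg_time_saved),
                     front$false_positive_fraction), ]
  }
  list(points = pts, frontier = front, selected = sel,
       time_saved_defined = !no_events)
}

# Non-dominated mask: maximize gain, minimize cost. Duplicated objective
# pairs are all kept (they tie).
pareto_front <- function(gain, cost) {
  n <- length(gain)
  vapply(seq_len(n), function(i)
    !any(gain >= gain[i] & cost <= cost[i] &
           (gain > gain[i] | cost < cost[i])), logical(1))
}

# Knee of a 2-d frontier: max perpendicular distance from the chord joining
# the extremes, after rescaling both axes to [0, 1].
knee_point <- function(gain, cost) {
  if (length(gain) == 1L) return(1L)
  rs <- function(v) if (diff(range(v)) == 0) rep(0.5, length(v))
                    else (v - min(v)) / diff(range(v))
  g <- rs(gain); c <- rs(cost)
  i1 <- which.min(c + (1 - g) * 1e-9)   # cheap extreme
  i2 <- which.max(g - c * 1e-9)         # high-gain extreme
  if (i1 == i2) return(i1)
  dx <- c[i2] - c[i1]; dy <- g[i2] - g[i1]
  d <- abs(dy * (c - c[i1]) - dx * (g - g[i1])) / sqrt(dx^2 + dy^2)
  which.max(d)
}
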