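#' Construct a dated bacteria-count series for one well
#'
#' A \code{count_series} holds irregularly spaced fecal coliform counts
#' (CFU/100 ml) for a single well. Dates must be strictly increasing and
#' counts non-negative integers.
#'
#' @param well_id Character scalar identifying the well.
#' @param dates \code{Date} vector (or ISO-8601 strings) of sampling dates.
#' @param counts Non-negative integer counts, one per date.
#' @return An object of class \code{count_series} with fields
#'   \code{well_id}, \code{dates}, \code{counts}.
#' @examples
#' cs <- count_series("w1", as.Date("2001-01-01") + c(0, 10, 40), c(0, 3, 25))
#' cs
#' @export
count_series <- function(well_id, dates, counts) {
  stopifnot(is.character(well_id), length(well_id) == 1L)
  dates <- parse_iso_date(dates)
  if (anyNA(dates)) stop("unparsable date in series '", well_id, "'")
  if (length(dates) < 1L) stop("a count series needs at least one sample")
  if (length(dates) != length(counts))
    stop("dates and counts differ in length")
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative (well '", well_id, "')")
  if (any(counts != round(counts)))
    stop("counts must be whole colony counts (well '", well_id, "')")
  o <- order(dates)
  dates <- dates[o]; counts <- counts[o]
  if (any(diff(as.numeric(dates)) == 0))
    stop("duplicate sampling dates in series '", well_id,
         "' (merge them first, see read_counts_csv)")
  structure(list(well_id = well_id, dates = dates, counts = counts),
            class = "count_series")
}

#' @export
print.count_series <- function(x, ...) {
  cat("<count_series> well", x$well_id, "-", length(x$counts), "samples,",
      format(min(x$dates)), "to", format(max(x$dates)),
      "- max count", max(x$counts), "CFU/100 ml\n")
  invisible(x)
}

#' Read well count series from CSV
#'
#' Reads a table with columns \code{well_id,date,count} (ISO-8601 dates) and
#' returns one \code{\link{count_series}} per well. Same-day duplicates are
#' either merged by keeping the larger count (conservative for contamination
#' surveillance) or rejected.
#'
#' @param path Path to a CSV file.
#' @param duplicates Either \code{"max"} (default; keep the maximum count of
#'   same-day samples) or \code{"error"}.
#' @return Named list of \code{count_series}, one element per well.
#' @export
read_counts_csv <- function(path, duplicates = c("max", "error")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty count table: ", path)
  need <- c("well_id", "date", "count")
  if (!all(need %in% names(df)))
    stop("count CSV must have columns well_id,date,count")
  df$date <- parse_iso_date(df$date)
  if (anyNA(df$date)) stop("unparsable date in ", path)
  if (anyNA(df$count) || any(df$count < 0))
    stop("negative or missing count in ", path)
  out <- lapply(split(df, df$well_id), function(d) {
    if (anyDuplicated(d$date)) {
      if (duplicates == "error")
        stop("duplicate same-day samples for well '", d$well_id[1], "'")
      d <- do.call(rbind, lapply(split(d, d$date), function(g)
        g[which.max(g$count), , drop = FALSE]))
    }
    count_series(as.character(d$well_id[1]), d$date, d$count)
  })
  out[order(names(out))]
}

#' Summary statistics of a count series
#'
#' @param series A \code{\link{count_series}}.
#' @return A list with \code{n_samples}, \code{mean_interval_days} (span
#'   divided by n-1, rounded to the nearest day), and \code{max_count}.
#'   Requires at least two samples; the interval is undefined otherwise.
#' @export
series_stats <- function(series) {
  stopifnot(inherits(series, "count_series"))
  n <- length(series$counts)
  if (n < 2L) stop("mean sampling interval undefined for a single sample")
  span <- as.numeric(max(series$dates) - min(series$dates))
  list(n_samples = n,
       mean_interval_days = round(span / (n - 1)),
       max_count = max(series$counts))
}

#' Place an irregular count series on a daily calendar grid
#'
#' Every calendar day between the first and last sample (inclusive) gets one
#' slot; unsampled days are filled with fictitious zeroes and flagged in the
#' \code{observed} mask. Day offsets are 0-based from \code{start_date}.
#' Zero padding is harmless downstream because a zero sample contributes
#' nothing to any DCT coefficient sum.
#'
#' @param series A \code{\link{count_series}}.
#' @return An object of class \code{daily_grid}: \code{start_date},
#'   \code{values} (length = inclusive day span), \code{observed} (logical),
#'   \code{well_id}.
#' @export
to_daily_grid <- function(series) {
  stopifnot(inherits(series, "count_series"))
  start <- min(series$dates)
  n <- as.numeric(max(series$dates) - start) + 1
  values <- numeric(n)
  observed <- logical(n)
  idx <- as.numeric(series$dates - start) + 1L
  values[idx] <- series$counts
  observed[idx] <- TRUE
  structure(list(start_date = start, values = values, observed = observed,
                 well_id = series$well_id),
            class = "daily_grid")
}

#' @export
print.daily_grid <- function(x, ...) {
  cat("<daily_grid>", length(x$values), "days from", format(x$start_date),
      "-", sum(x$observed), "observed,",
      sum(!x$observed), "fictitious zeroes\n")
  invisible(x)
}

#' Detect threshold exceedances (contamination events)
#'
#' An event is an observed day whose count strictly exceeds the regulatory
#' threshold (default 10 CFU/100 ml, the Israeli drinking-water standard).
#' Strict comparison is deliberate: a count of exactly 10 -- or the
#' borderline 9 -- does not constitute an exceedance.
#'
#' @param grid A \code{\link{to_daily_grid}} result.
#' @param threshold Positive count threshold; default 10.
#' @return Sorted integer vector of 0-based event day offsets.
#' @export
mark_events <- function(grid, threshold = 10) {
  stopifnot(inherits(grid, "daily_grid"), threshold > 0)
  which(grid$observed & grid$values > threshold) - 1L
}

#' Label days in the pre-event contamination span
#'
#' Each event marks the well as contaminated for \code{span_days} days prior
#' to (and including) the event, so classifiers can learn the run-up that
#' precedes an exceedance. Overlapping spans merge.
#'
#' @param events Integer event day offsets (from \code{\link{mark_events}}).
#' @param span_days Span length in days; default 90 (the regulatory
#'   sampling-interval unit).
#' @return Object of class \code{contamination_labels}: sorted integer
#'   vector \code{days} of contaminated 0-based day offsets, plus
#'   \code{span_days}.
#' @export
contaminated_spans <- function(events, span_days = 90) {
  stopifnot(span_days > 0)
  days <- integer(0)
  if (length(events)) {
    days <- sort(unique(unlist(lapply(as.integer(events), function(e)
      seq.int(max(0L, e - as.integer(span_days)), e)))))
  }
  structure(list(days = days, span_days = as.integer(span_days)),
            class = "contamination_labels")
}

#' Triage a series as Zeroes, NonAction or Action
#'
#' Wells fall into three surveillance categories: \code{"Zeroes"} (every
#' count is zero -- nothing to learn), \code{"NonAction"} (some non-zero
#' counts but no exploitable history before events; prediction is
#' impossible when every index preceding an outburst is zero), and
#' \code{"Action"} (repeated growth episodes with non-zero run-ups that a
#' classifier can learn from). The operational rule used here: Action
#' requires at least two events, each preceded by at least one non-zero
#' observed count within \code{span_days} days.
#'
#' @inheritParams mark_events
#' @param span_days Look-back span for run-up counts; default 90.
#' @return Character scalar: \code{"Zeroes"}, \code{"NonAction"} or
#'   \code{"Action"}.
#' @export
classify_series <- function(series, threshold = 10, span_days = 90) {
  stopifnot(inherits(series, "count_series"))
  if (all(series$counts == 0)) return("Zeroes")
  grid <- to_daily_grid(series)
  events <- mark_events(grid, threshold)
  if (length(events) < 2L) return("NonAction")
  has_runup <- vapply(events, function(e) {
    lo <- max(0L, e - as.integer(span_days))
    if (lo >= e) return(FALSE)
    i <- seq.int(lo, e - 1L) + 1L
    any(grid$observed[i] & grid$values[i] > 0)
  }, logical(1))
  if (sum(has_runup) >= 2L) "Action" else "NonAction"
}

#' Cut a daily grid into fixed-length labeled windows
#'
#' Slides a window of \code{window_days} consecutive days across the grid
#' and labels each window contaminated or not. Under the default
#' \code{"span"} rule a window is contaminated iff any of its days lies in
#' a pre-event contamination span; the alternative \code{"exceedance"} rule
#' labels by an actual in-window threshold exceedance.
#'
#' @param grid A \code{daily_grid}.
#' @param labels A \code{\link{contaminated_spans}} result (used by the
#'   \code{"span"} rule).
#' @param window_days Window length in days, default 90.
#' @param stride_days Step between consecutive window starts, default 1.
#' @param rule Labeling rule, \code{"span"} (default) or \code{"exceedance"}.
#' @param threshold Count threshold for the \code{"exceedance"} rule.
#' @return List with \code{starts} (0-based window start offsets),
#'   \code{values} (matrix, one row per window) and \code{contaminated}
#'   (logical).
#' @export
extract_windows <- function(grid, labels, window_days = 90, stride_days = 1,
                            rule = c("span", "exceedance"), threshold = 10) {
  rule <- match.arg(rule)
  stopifnot(inherits(grid, "daily_grid"), window_days >= 1, stride_days >= 1)
  n <- length(grid$values)
  if (window_days > n)
    stop("window (", window_days, " days) longer than grid (", n, " days)")
  starts <- seq.int(0L, n - window_days, by = stride_days)
  vals <- t(vapply(starts, function(s)
    grid$values[(s + 1L):(s + window_days)], numeric(window_days)))
  contaminated <- if (rule == "span") {
    cmask <- logical(n)
    cmask[labels$days + 1L] <- TRUE
    vapply(starts, function(s) any(cmask[(s + 1L):(s + window_days)]),
           logical(1))
  } else {
    vapply(starts, function(s) {
      i <- (s + 1L):(s + window_days)
      any(grid$observed[i] & grid$values[i] > threshold)
    }, logical(1))
  }
  list(starts = starts, values = vals, contaminated = contaminated)
}

#' Export a labeled daily grid as a data frame
#'
#' One row per calendar day with the grid value, observation flag and
#' contamination label; convenient for writing the standard
#' \code{day_offset,date,value,observed,contaminated} CSV.
#'
#' @param grid A \code{daily_grid}.
#' @param labels A \code{contamination_labels}.
#' @return \code{data.frame} with columns \code{day_offset}, \code{date},
#'   \code{value}, \code{observed}, \code{contaminated}.
#' @export
grid_to_frame <- function(grid, labels) {
  n <- length(grid$values)
  cmask <- logical(n)
  if (length(labels$days)) cmask[labels$days + 1L] <- TRUE
  data.frame(day_offset = 0:(n - 1L),
             date = grid$start_date + 0:(n - 1L),
             value = grid$values,
             observed = grid$observed,
             contaminated = cmask)
}
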