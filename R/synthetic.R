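#' Parameters of the synthetic well generator
#'
#' Defaults emulate the sampling regime and count structure of active
#' Israeli supply wells: multi-year records (here ~10.7 years), a mean
#' inter-sample gap of 15 days (observed well means range roughly 12-44
#' days), counts that are overwhelmingly zero, and occasional exponential
#' outburst episodes capped at 120 CFU/100 ml, during which the sampling
#' frequency is increased (the regulatory response to contamination).
#'
#' @param span_days Record length in days.
#' @param mean_interval_days Mean gap between routine samples (geometric,
#'   integer days).
#' @param outburst_rate Expected outburst episodes per year.
#' @param growth_rate Per-day exponential growth factor during an episode.
#' @param max_count Count cap, CFU/100 ml.
#' @param runup_samples Minimum non-zero, sub-threshold samples guaranteed
#'   before an episode's first exceedance (0 disables the run-up and makes
#'   outbursts unpredictable isolated spikes).
#' @param baseline_zero_prob Probability that a routine baseline sample is
#'   zero (the remainder are small 1-3 CFU/100 ml counts).
#' @param threshold Event threshold used by the episode log, default 10.
#' @param start_date Calendar date of day 0.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class \code{well_sim_params}.
#' @export
well_sim_params <- function(span_days = 3900, mean_interval_days = 15,
                            outburst_rate = 0.9, growth_rate = 0.15,
                            max_count = 120, runup_samples = 3,
                            baseline_zero_prob = 0.95, threshold = 10,
                            start_date = as.Date("2001-01-01"), seed = 1) {
  stopifnot(span_days >= 1, mean_interval_days >= 1, outburst_rate >= 0,
            growth_rate >= 0, max_count >= 1, runup_samples >= 0,
            baseline_zero_prob >= 0, baseline_zero_prob <= 1)
  structure(list(span_days = as.integer(span_days),
                 mean_interval_days = mean_interval_days,
                 outburst_rate = outburst_rate, growth_rate = growth_rate,
                 max_count = max_count, runup_samples = as.integer(runup_samples),
                 baseline_zero_prob = baseline_zero_prob,
                 threshold = threshold, start_date = as.Date(start_date),
                 seed = seed),
            class = "well_sim_params")
}

# One outburst episode: day offsets (relative to episode start) and counts.
# Counts rise exponentially, with `runup` guaranteed non-zero sub-threshold
# samples before the first exceedance, then densified sampling up to the
# peak and a short decay back to baseline.
.episode_profile <- function(peak, growth_rate, runup, gap, threshold,
                             max_count) {
  if (runup == 0)   # unpredictable isolated spike: no run-up, no tail
    return(list(days = 0L, counts = min(peak, max_count)))
  t_thr <- log(threshold * 1.05) / growth_rate       # crossing time
  t_peak <- log(peak) / growth_rate
  days <- integer(0); counts <- numeric(0)
  if (runup > 0) {
    rd <- round(t_thr * seq_len(runup) / (runup + 1))
    rc <- pmin(round(exp(growth_rate * rd)), threshold)
    rc <- pmax(rc, 1)
    for (j in seq_along(rc)[-1])                      # strictly rising run-up
      rc[j] <- min(max(rc[j], rc[j - 1] + 1), threshold)
    days <- rd; counts <- rc
  }
  up <- unique(c(seq(ceiling(t_thr) + 1, ceiling(t_peak), by = gap),
                 ceiling(t_peak)))
  days <- c(days, up)
  counts <- c(counts, pmin(round(exp(growth_rate * up)), peak, max_count))
  dec_d <- ceiling(t_peak) + c(4L, 9L)
  dec_c <- round(peak * exp(-0.6 * c(4, 9)))
  keep <- dec_c > 0
  days <- c(days, dec_d[keep]); counts <- c(counts, dec_c[keep])
  o <- !duplicated(days)
  list(days = days[o], counts = counts[o])
}

#' Generate one synthetic well
#'
#' Produces a sparse, irregularly sampled count series: routine samples at
#' geometric gaps around \code{mean_interval_days} (mostly zero), plus
#' outburst episodes in which counts grow exponentially to a random peak
#' between the threshold and \code{max_count}, sampled about three times
#' as densely (the increased regulatory sampling frequency), then decay.
#' Episode timing follows a Poisson count with a 180-day minimum
#' separation.
#'
#' @param params A \code{\link{well_sim_params}} object.
#' @param well_id Identifier for the generated series.
#' @return A list with \code{series} (a \code{\link{count_series}}) and
#'   \code{episodes} (data frame: \code{start_day}, \code{peak_day},
#'   \code{end_day}, \code{peak_count}, \code{first_event_day}; 0-based
#'   day offsets, \code{first_event_day} NA when the episode never
#'   exceeds the threshold).
#' @export
generate_well <- function(params, well_id = "synth") {
  stopifnot(inherits(params, "well_sim_params"))
  p <- params
  with_seed(p$seed, {
    span <- p$span_days
    # episode placement
    n_ep <- stats::rpois(1, p$outburst_rate * span / 365)
    margin <- 120L
    if (span < 2L * margin + 60L) {
      if (n_ep > 0) warning("span too short for outburst episodes; ",
                            "generating baseline only")
      n_ep <- 0L
    }
    starts <- integer(0)
    tries <- 0L
    while (length(starts) < n_ep && tries < 200L * max(n_ep, 1L)) {
      cand <- sample.int(span - 2L * margin, 1L) + margin
      if (!length(starts) || min(abs(starts - cand)) >= 180L)
        starts <- c(starts, cand)
      tries <- tries + 1L
    }
    starts <- sort(starts)
    gap_ep <- max(2L, round(p$mean_interval_days / 3))
    ep_days <- integer(0); ep_counts <- numeric(0)
    log_rows <- list()
    for (s in starts) {
      peak <- round(stats::runif(1, min = p$threshold + 5, max = p$max_count))
      prof <- .episode_profile(peak, p$growth_rate, p$runup_samples, gap_ep,
                               p$threshold, p$max_count)
      d <- s + prof$days
      keep <- d <= span
      d <- d[keep]; cts <- prof$counts[keep]
      if (!length(d)) next
      ep_days <- c(ep_days, d); ep_counts <- c(ep_counts, cts)
      ev <- d[cts > p$threshold]
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        start_day = s, peak_day = d[which.max(cts)], end_day = max(d),
        peak_count = max(cts),
        first_event_day = if (length(ev)) min(ev) else NA_integer_)
    }
    # routine baseline sampling, skipping episode stretches
    gaps <- stats::rgeom(ceiling(2.5 * span / p$mean_interval_days),
                         1 / p$mean_interval_days) + 1L
    base_days <- cumsum(gaps)
    base_days <- c(0L, base_days[base_days < span], span)
    in_ep <- rep(FALSE, length(base_days))
    for (r in log_rows)
      in_ep <- in_ep | (base_days >= r$start_day & base_days <= r$end_day)
    base_days <- base_days[!in_ep]
    base_counts <- ifelse(
      stats::runif(length(base_days)) < p$baseline_zero_prob, 0,
      sample(1:3, length(base_days), replace = TRUE))
    days <- c(base_days, ep_days)
    counts <- c(base_counts, ep_counts)
    df <- data.frame(day = days, count = counts)
    df <- do.call(rbind, lapply(split(df, df$day), function(g)
      g[which.max(g$count), , drop = FALSE]))
    df <- df[order(df$day), ]
    series <- count_series(well_id, p$start_date + df$day, df$count)
    episodes <- if (length(log_rows)) do.call(rbind, log_rows)
      else data.frame(start_day = integer(0), peak_day = integer(0),
                      end_day = integer(0), peak_count = numeric(0),
                      first_event_day = integer(0))
    list(series = series, episodes = episodes)
  })
}

#' Generate a cohort of independent synthetic wells
#'
#' Each well gets a seed derived from the cohort seed and its index, so
#' the cohort is reproducible as a whole while wells stay independent.
#'
#' @param n_wells Number of wells.
#' @param params Template \code{\link{well_sim_params}} (per-well seeds are
#'   derived, overriding \code{params$seed}).
#' @param seed Cohort seed.
#' @return List with \code{series} (named list of \code{count_series}) and
#'   \code{truth} (episode log data frame with a \code{well_id} column).
#' @export
generate_cohort <- function(n_wells, params, seed = 1) {
  stopifnot(n_wells >= 1)
  series <- list(); truth <- list()
  for (i in seq_len(n_wells)) {
    p <- params
    p$seed <- derive_seed(seed, i)
    id <- sprintf("synth%03d", i)
    w <- generate_well(p, well_id = id)
    series[[id]] <- w$series
    if (nrow(w$episodes)) {
      w$episodes$well_id <- id
      truth[[length(truth) + 1L]] <- w$episodes
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(start_day = integer(0), peak_day = integer(0),
                    end_day = integer(0), peak_count = numeric(0),
                    first_event_day = integer(0), well_id = character(0))
  list(series = series, truth = truth)
}

#' Write a cohort as the standard input CSV plus a truth log
#'
#' @param cohort A \code{\link{generate_cohort}} result.
#' @param counts_path Output CSV (\code{well_id,date,count}).
#' @param truth_path Optional CSV path for the episode log.
#' @return Invisibly, \code{counts_path}.
#' @export
write_cohort_csv <- function(cohort, counts_path, truth_path = NULL) {
  rows <- do.call(rbind, lapply(cohort$series, function(s)
    data.frame(well_id = s$well_id, date = format(s$dates),
               count = s$counts)))
  utils::write.csv(rows, counts_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path))
    utils::write.csv(cohort$truth, truth_path, row.names = FALSE,
                     quote = FALSE)
  invisible(counts_path)
}
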