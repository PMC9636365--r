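# Session-level metrics: rolling-window peaks, heart-rate recovery, and
# interval summaries of monitored HIIT sessions.

#' Resample session signals to 1 Hz
#'
#' Linear interpolation of all numeric columns onto a uniform 1-second
#' grid. Field exports differ (breath-by-breath, 5-s bins); all windowed
#' statistics in this package assume a uniform 1 Hz grid.
#'
#' @param series data.frame with a `time_s` column (seconds, strictly
#'   increasing) and numeric signal columns.
#' @return data.frame on the 1 Hz grid, same columns.
#' @export
resample_1hz <- function(series) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series))
  t <- series$time_s
  if (is.unsorted(t, strictly = TRUE))
    stop("time_s must be strictly increasing", call. = FALSE)
  grid <- seq(ceiling(min(t)), floor(max(t)), by = 1)
  out <- data.frame(time_s = grid)
  for (col in setdiff(names(series), "time_s"))
    out[[col]] <- stats::approx(t, series[[col]], xout = grid)$y
  out
}

#' Peak rolling-window mean of a signal
#'
#' The maximum, over all contiguous windows of the stated length, of the
#' window mean of a uniformly sampled signal — e.g. the "highest 30-s mean"
#' of heart rate anytime during a session, or the highest consecutive
#' 120 s of VO2 within an interval. Ties are broken in favour of the
#' earliest window.
#'
#' @param x Numeric signal sampled at `hz` Hz.
#' @param window Window length in seconds.
#' @param time Optional sample times (seconds); defaults to
#'   `0, 1/hz, 2/hz, ...`.
#' @param hz Sampling rate (default 1).
#' @return A list with `value` (peak windowed mean) and `start_time`
#'   (time of the first sample of the peak window).
#' @examples
#' rolling_window_peak(c(100, 110, 120, 130, 120, 110), window = 3)
#' @export
rolling_window_peak <- function(x, window, time = NULL, hz = 1) {
  stopifnot(is.numeric(x), window > 0, hz > 0)
  w <- as.integer(round(window * hz))
  n <- length(x)
  if (n < w)
    stop("series (", n, " samples) is shorter than the ", window,
         " s window", call. = FALSE)
  if (is.null(time)) time <- (seq_len(n) - 1) / hz
  cs <- cumsum(c(0, x))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  i <- which.max(means)  # which.max returns the earliest maximum
  list(value = means[i], start_time = time[i])
}

#' Heart-rate recovery after work bouts
#'
#' For each work bout, the reference is the highest `peak_window`-second
#' (default 30 s) mean heart rate within the bout; HRR at time t is that
#' reference minus the heart rate t seconds after the bout ends. When a
#' session has several intervals the per-interval HRR values are averaged
#' into a session mean. A recovery trace truncated before a requested
#' timepoint yields a missing value for that timepoint.
#'
#' @param series data.frame with `time_s` and `hr_bpm`, 1 Hz.
#' @param bouts data.frame with `start_s`, `end_s` (one row per work bout),
#'   optionally `label`.
#' @param timepoints Seconds after bout end at which to evaluate HRR.
#' @param peak_window Reference window length in seconds.
#' @return A list with `per_bout` (data.frame: bout, peak_hr, one `hrr_<t>`
#'   column per timepoint) and `session_mean` (named vector of HRR means
#'   over bouts, missing timepoints excluded).
#' @export
heart_rate_recovery <- function(series, bouts, timepoints = c(30, 60, 180),
                                peak_window = 30) {
  stopifnot(all(c("time_s", "hr_bpm") %in% names(series)),
            all(c("start_s", "end_s") %in% names(bouts)))
  res <- data.frame(bout = seq_len(nrow(bouts)), peak_hr = NA_real_)
  for (tp in timepoints) res[[paste0("hrr_", tp)]] <- NA_real_
  for (i in seq_len(nrow(bouts))) {
    in_bout <- series$time_s >= bouts$start_s[i] &
      series$time_s <= bouts$end_s[i]
    peak <- rolling_window_peak(series$hr_bpm[in_bout], peak_window,
                                time = series$time_s[in_bout])$value
    res$peak_hr[i] <- peak
    for (tp in timepoints) {
      j <- which(series$time_s == bouts$end_s[i] + tp)
      if (length(j) == 1L && !is.na(series$hr_bpm[j]))
        res[[paste0("hrr_", tp)]][i] <- peak - series$hr_bpm[j]
    }
  }
  sm <- vapply(paste0("hrr_", timepoints),
               function(cl) mean(res[[cl]], na.rm = TRUE), numeric(1))
  sm[is.nan(sm)] <- NA_real_
  list(per_bout = res, session_mean = sm)
}

#' Summarize a monitored HIIT session
#'
#' Computes the interval summaries and the session-level aggregates the
#' diagnostic model consumes. Power and heart rate are averaged over the
#' full interval length; the VO2 plateau is the highest consecutive 120 s
#' of VO2 within the interval; the session `hr_max` is the highest 30-s
#' heart-rate mean anytime during the session; end lactate/glucose are the
#' values sampled at the end of the session; `rpe_mean` is the mean of the
#' per-interval ratings.
#'
#' @param series 1 Hz session data.frame: `time_s`, `hr_bpm`, `vo2_lmin`,
#'   `vco2_lmin`, `power_w`.
#' @param markers data.frame `label`, `start_s`, `end_s`; intervals carry
#'   labels starting with `"interval"`.
#' @param rpe Optional numeric vector of per-interval Borg 6-20 ratings.
#' @param lactate_end,glucose_end Optional end-of-session blood values
#'   (mmol/L).
#' @param hrr_timepoints Seconds after interval end for HRR.
#' @return A list with `intervals` (one row per interval) and `session`
#'   (one-row data.frame with `hr_max`, `rpe_mean`, `lactate_end`,
#'   `glucose_end` and session-mean HRR columns).
#' @export
summarize_session <- function(series, markers, rpe = NULL,
                              lactate_end = NA_real_,
                              glucose_end = NA_real_,
                              hrr_timepoints = c(30, 60, 180)) {
  stopifnot(all(c("time_s", "hr_bpm", "vo2_lmin", "vco2_lmin", "power_w")
                %in% names(series)),
            all(c("label", "start_s", "end_s") %in% names(markers)))
  iv <- markers[startsWith(markers$label, "interval"), , drop = FALSE]
  if (nrow(iv) == 0L) stop("no interval markers found", call. = FALSE)
  if (!is.null(rpe) && length(rpe) != nrow(iv))
    stop("rpe must have one value per interval", call. = FALSE)
  rows <- lapply(seq_len(nrow(iv)), function(i) {
    sel <- series$time_s >= iv$start_s[i] & series$time_s <= iv$end_s[i]
    seg <- series[sel, , drop = FALSE]
    data.frame(
      interval = i,
      power_mean = mean(seg$power_w),
      hr_mean = mean(seg$hr_bpm),
      hr_peak30 = rolling_window_peak(seg$hr_bpm, 30, time = seg$time_s)$value,
      vo2_plateau = rolling_window_peak(seg$vo2_lmin, 120,
                                        time = seg$time_s)$value,
      rpe = if (is.null(rpe)) NA_real_ else rpe[i]
    )
  })
  intervals <- do.call(rbind, rows)
  hrr <- heart_rate_recovery(series, iv, timepoints = hrr_timepoints)
  for (tp in hrr_timepoints)
    intervals[[paste0("hrr_", tp)]] <- hrr$per_bout[[paste0("hrr_", tp)]]
  session <- data.frame(
    hr_max = rolling_window_peak(series$hr_bpm, 30,
                                 time = series$time_s)$value,
    rpe_mean = if (is.null(rpe)) NA_real_ else mean(rpe),
    lactate_end = lactate_end,
    glucose_end = glucose_end
  )
  for (tp in hrr_timepoints)
    session[[paste0("hrr_", tp, "_mean")]] <-
      unname(hrr$session_mean[paste0("hrr_", tp)])
  list(intervals = intervals, session = session)
}
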