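# CSV interchange, run configuration, and the end-to-end pipeline.

# internal CSV reader with schema checking and a comma-decimal guard
.read_table <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L)
    stop("empty input file: ", path, call. = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(trimws(raw)) & is.na(v))
    if (length(bad))
      stop(sprintf("%s: cannot parse numeric value '%s' (row %d, column %s)%s",
                   path, raw[bad[1]], bad[1], col,
                   if (grepl(",", raw[bad[1]], fixed = TRUE))
                     " - comma decimal separators are not supported" else ""),
           call. = FALSE)
    v[!nzchar(trimws(raw))] <- NA_real_
    df[[col]] <- v
  }
  df
}

#' Read measurement panels from CSV
#'
#' Expected columns: `subject_id`, `phase_id` and one numeric column per
#' diagnostic parameter (empty cell = missing). Unknown extra columns are
#' preserved and ignored by the model.
#'
#' @param path Path to `panels.csv`.
#' @param specs Parameter specification.
#' @return A panels data.frame.
#' @export
read_panels <- function(path, specs = parameter_specs()) {
  df <- .read_table(path, c("subject_id", "phase_id", specs$parameter),
                    specs$parameter)
  .check_panels(df, specs$parameter)
  df
}

#' Read respiration records from CSV
#'
#' Expected columns: `subject_id`, `phase_id`, `respiration`.
#'
#' @param path Path to `respiration.csv`.
#' @return A respiration data.frame.
#' @export
read_respiration <- function(path) {
  .read_table(path, c("subject_id", "phase_id", "respiration"), "respiration")
}

#' Read a session time series from CSV
#'
#' Expected columns: `time_s`, `hr_bpm`, `vo2_lmin`, `vco2_lmin`,
#' `power_w`.
#'
#' @param path Path to `session.csv`.
#' @return A session data.frame.
#' @export
read_session <- function(path) {
  cols <- c("time_s", "hr_bpm", "vo2_lmin", "vco2_lmin", "power_w")
  .read_table(path, cols, cols)
}

#' Read interval markers from CSV
#'
#' Expected columns: `label`, `start_s`, `end_s`.
#'
#' @param path Path to `markers.csv`.
#' @return A markers data.frame.
#' @export
read_markers <- function(path) {
  .read_table(path, c("label", "start_s", "end_s"), c("start_s", "end_s"))
}

#' Write a table to CSV
#'
#' Numeric values are written at full precision (values survive a read
#' round trip well beyond 6 significant digits); row names are dropped.
#'
#' @param x data.frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plain-text key-value run configuration
#'
#' Lines of the form `key = value`; `#` starts a comment; comma-separated
#' values become vectors; numeric-looking values are converted.
#'
#' @param path Path to the config file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L)
      stop("malformed config line (expected 'key = value'): ", ln,
           call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!any(is.na(num))) num else parts
  }
  out
}

# per-phase summary tables recomputed from a score matrix: positive-score
# counts per parameter, and cumulative counts of subjects with >= k scores
score_summary <- function(scores, phases = unique(scores$phase_id)) {
  pars <- attr(scores, "parameters") %||%
    intersect(parameter_specs()$parameter, names(scores))
  parameter_counts <- sapply(phases, function(ph)
    colSums(scores[scores$phase_id == ph, pars, drop = FALSE]))
  k_max <- length(pars)
  joint_cumulative <- sapply(phases, function(ph) {
    ns <- scores$n_scores[scores$phase_id == ph]
    vapply(seq_len(k_max), function(k) sum(ns >= k), numeric(1))
  })
  rownames(joint_cumulative) <- seq_len(k_max)
  list(parameter_counts = parameter_counts,
       joint_cumulative = joint_cumulative)
}

#' Run the diagnostic pipeline end to end
#'
#' Baselines -> cut-offs (derived, fixed, or individual) -> scoring ->
#' classification, with an optional respiration-delta and score-respiration
#' correlation step, and per-phase summary tables recomputed from the
#' detailed scores. If `out_dir` is given, `scores.csv`,
#' `classification.csv`, `cutoffs.csv` (for group cut-off modes),
#' optionally `respiration_deltas.csv`, and a human-readable `summary.txt`
#' are written there.
#'
#' @param panels Panels data.frame or path to `panels.csv`.
#' @param respiration Optional respiration data.frame or path.
#' @param schedule A [phase_schedule()].
#' @param specs Parameter specification.
#' @param threshold Classification threshold (default 3).
#' @param cutoff_mode `"derived"`, `"fixed"` or `"individual"`.
#' @param fixed_source Passed to [fixed_cutoffs()] when
#'   `cutoff_mode = "fixed"`.
#' @param pooling Passed to [derive_cutoffs()] when
#'   `cutoff_mode = "derived"`.
#' @param out_dir Optional output directory (created if absent).
#' @param verbose Print a short summary.
#' @return A `diagnostic_report` list: `baselines`, `cutoffs`, `scores`,
#'   `classification`, `summary` (parameter counts and joint cumulative
#'   counts per phase), `correlation` (or `NULL`), `settings`.
#' @export
run_pipeline <- function(panels, respiration = NULL,
                         schedule = phase_schedule(),
                         specs = parameter_specs(),
                         threshold = 3L,
                         cutoff_mode = c("derived", "fixed", "individual"),
                         fixed_source = "published",
                         pooling = "observation",
                         out_dir = NULL, verbose = FALSE) {
  cutoff_mode <- match.arg(cutoff_mode)
  if (is.character(panels)) panels <- read_panels(panels, specs)
  if (is.character(respiration)) respiration <- read_respiration(respiration)
  .check_panels(panels, specs$parameter)
  baselines <- compute_baselines(panels, schedule, specs)
  cutoffs <- switch(cutoff_mode,
    derived = derive_cutoffs(panels, schedule, specs, pooling = pooling),
    fixed = fixed_cutoffs(fixed_source),
    individual = individual_cutoffs(panels, schedule, specs))
  scores <- score_panels(panels, baselines, cutoffs, specs)
  classification <- classify(scores, threshold)
  summary <- score_summary(scores,
                           intersect(schedule$phases,
                                     unique(scores$phase_id)))
  correlation <- NULL
  deltas <- NULL
  if (!is.null(respiration)) {
    deltas <- respiration_deltas(respiration, schedule)
    correlation <- correlate_scores_respiration(scores, deltas)
  }
  report <- structure(list(
    baselines = baselines, cutoffs = cutoffs, scores = scores,
    classification = classification, summary = summary,
    correlation = correlation,
    settings = list(threshold = as.integer(threshold),
                    cutoff_mode = cutoff_mode,
                    fixed_source = if (cutoff_mode == "fixed") fixed_source
                                   else NULL,
                    pooling = if (cutoff_mode == "derived") pooling else NULL,
                    normal_phases = schedule$normal_phases,
                    mal_phase = schedule$mal_phase)),
    class = "diagnostic_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    sc_out <- merge(as.data.frame(scores),
                    classification[, c("subject_id", "phase_id", "flagged")],
                    by = c("subject_id", "phase_id"))
    sc_out <- sc_out[order(sc_out$subject_id, sc_out$phase_id), ]
    write_table(sc_out, file.path(out_dir, "scores.csv"))
    write_table(classification, file.path(out_dir, "classification.csv"))
    if (cutoff_mode != "individual")
      write_table(as.data.frame(cutoffs), file.path(out_dir, "cutoffs.csv"))
    if (!is.null(deltas))
      write_table(deltas, file.path(out_dir, "respiration_deltas.csv"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "summary.txt"))
  }
  if (verbose) print(report)
  report
}

#' @export
print.diagnostic_report <- function(x, ...) {
  s <- x$settings
  cat("Maladaptation diagnostic report\n")
  cat("  cut-off mode:", s$cutoff_mode,
      if (!is.null(s$fixed_source)) paste0("(", s$fixed_source, ")") else "",
      "| threshold:", s$threshold, "of",
      length(attr(x$scores, "parameters")), "\n")
  cat("  normal-reference phases:",
      paste(s$normal_phases, collapse = ", "),
      "| maladaptive phase:", s$mal_phase, "\n\n")
  cat("Positive scores per parameter and phase:\n")
  print(x$summary$parameter_counts)
  cat("\nSubjects with >= k scores per phase:\n")
  print(x$summary$joint_cumulative)
  flags <- tapply(x$classification$flagged, x$classification$phase_id, sum)
  cat("\nFlagged subjects per phase (n_scores >=", s$threshold, "):\n")
  print(flags)
  if (!is.null(x$correlation))
    cat(sprintf("\nScore-respiration association: Pearson r = %.3f, p = %.3g, n = %d\n",
                x$correlation$r, x$correlation$p_value, x$correlation$n))
  invisible(x)
}
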