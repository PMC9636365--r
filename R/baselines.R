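# Individual baselines over the normal-reference phases.

#' Compute individual baselines
#'
#' The individual "normal" value of each parameter for each subject is the
#' mean of that subject's measurements over the normal-reference phases
#' (default BL, LT, MT1 and RE), i.e. phases unaffected by maladaptive
#' training load. Missing phase values are skipped with a warning and the
#' contributing count reduced; a subject with no usable normal-reference
#' value for a parameter is an error.
#'
#' @param panels data.frame with columns `subject_id`, `phase_id` and one
#'   numeric column per diagnostic parameter (missing values as `NA`).
#' @param schedule A [phase_schedule()].
#' @param specs Parameter specification, see [parameter_specs()].
#' @return A data.frame with columns `subject_id`, `parameter`, `baseline`
#'   and `n_phases` (number of phases contributing to the mean).
#' @examples
#' p <- data.frame(subject_id = "S1", phase_id = c("BL", "LT", "MT1", "RE"),
#'                 poms_fatigue = c(40, 42, 44, 46), hr_max = 185,
#'                 glucose_end = 6, lactate_end = 13, rpe_mean = 17)
#' compute_baselines(p)
#' @export
compute_baselines <- function(panels, schedule = phase_schedule(),
                              specs = parameter_specs()) {
  .check_panels(panels, specs$parameter)
  normal <- panels[panels$phase_id %in% schedule$normal_phases, , drop = FALSE]
  if (nrow(normal) == 0L)
    stop("no observations in normal-reference phases", call. = FALSE)
  subjects <- unique(panels$subject_id)
  out <- expand.grid(subject_id = subjects, parameter = specs$parameter,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$baseline <- NA_real_
  out$n_phases <- 0L
  n_expected <- length(schedule$normal_phases)
  incomplete <- character(0)
  for (i in seq_len(nrow(out))) {
    v <- normal[normal$subject_id == out$subject_id[i], out$parameter[i]]
    v <- v[!is.na(v)]
    if (length(v) == 0L)
      stop(sprintf(
        "subject '%s' has no usable normal-reference value for parameter '%s'",
        out$subject_id[i], out$parameter[i]), call. = FALSE)
    if (length(v) < n_expected)
      incomplete <- c(incomplete,
                      sprintf("%s/%s", out$subject_id[i], out$parameter[i]))
    out$baseline[i] <- mean(v)
    out$n_phases[i] <- length(v)
  }
  if (length(incomplete))
    warning("baseline computed from fewer than ", n_expected,
            " normal-reference phases for: ",
            paste(incomplete, collapse = ", "), call. = FALSE)
  out
}
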