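# Parameter definitions and training-phase schedule.

#' Default diagnostic parameter specification
#'
#' The five diagnostic parameters of the maladaptation model, their adverse
#' direction and units. Direction `+1` means maladaptation manifests as an
#' increase above the individual baseline (POMS fatigue, mean RPE); `-1` means
#' it manifests as a decrease (session maximal heart rate, end-of-session
#' blood glucose and lactate).
#'
#' Additional parameters may be appended by the user as long as `direction`
#' is `+1` or `-1`.
#'
#' @return A data.frame with columns `parameter`, `direction`, `units`.
#' @examples
#' parameter_specs()
#' @export
parameter_specs <- function() {
  data.frame(
    parameter = c("poms_fatigue", "hr_max", "glucose_end", "lactate_end",
                  "rpe_mean"),
    direction = c(1L, -1L, -1L, -1L, 1L),
    units = c("score", "bpm", "mmol/L", "mmol/L", "Borg 6-20"),
    stringsAsFactors = FALSE
  )
}

#' Training-phase schedule
#'
#' Defines the ordered training phases, which of them are normal-reference
#' phases (used for individual baselines and the normal group mean), and
#' which is the designated maladaptive phase (used for cut-off derivation).
#' The default matches a six-phase design: baseline (BL), light (LT) and
#' moderate (MT1, MT2) training load, maladaptive load (MAL) and recovery
#' (RE), with baselines taken over BL, LT, MT1 and RE. MT2 is a test-only
#' phase: it is scored and classified but contributes neither to baselines
#' nor to cut-offs.
#'
#' @param phases Ordered character vector of phase identifiers.
#' @param normal_phases Phases defining the individual baseline and the
#'   normal group mean. At least two are required.
#' @param mal_phase The designated maladaptive phase; must be one of
#'   `phases` and not a normal-reference phase.
#' @return An object of class `phase_schedule`.
#' @examples
#' phase_schedule()
#' @export
phase_schedule <- function(phases = c("BL", "LT", "MT1", "MT2", "MAL", "RE"),
                           normal_phases = c("BL", "LT", "MT1", "RE"),
                           mal_phase = "MAL") {
  stopifnot(is.character(phases), length(phases) >= 3L, !anyDuplicated(phases))
  if (!all(normal_phases %in% phases))
    stop("normal_phases must be a subset of phases", call. = FALSE)
  if (length(normal_phases) < 2L)
    stop("at least two normal-reference phases are required", call. = FALSE)
  if (!(mal_phase %in% phases))
    stop("mal_phase must be one of phases", call. = FALSE)
  if (mal_phase %in% normal_phases)
    stop("the maladaptive phase cannot be a normal-reference phase",
         call. = FALSE)
  structure(list(phases = phases, normal_phases = normal_phases,
                 mal_phase = mal_phase),
            class = "phase_schedule")
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Phase schedule:", paste(x$phases, collapse = " -> "), "\n")
  cat("  normal-reference:", paste(x$normal_phases, collapse = ", "), "\n")
  cat("  maladaptive:     ", x$mal_phase, "\n")
  invisible(x)
}

# Published group means and cut-offs of the reference 11-subject cohort.
# Cut-off values are the rounded published ones; the unrounded halves of the
# printed mean differences are carried alongside.
.published_reference <- function() {
  data.frame(
    parameter = c("poms_fatigue", "hr_max", "glucose_end", "lactate_end",
                  "rpe_mean"),
    direction = c(1L, -1L, -1L, -1L, 1L),
    mean_normal = c(42.6, 183.6, 6.11, 13.28, 17.5),
    mean_mal = c(51.9, 178.5, 4.68, 12.03, 18.5),
    mean_diff = c(9.3, -5.1, -1.43, -1.25, 1.0),
    cutoff_published = c(4.7, -2.5, -0.71, -0.62, 0.5),
    stringsAsFactors = FALSE
  )
}

# internal: validate a panels data.frame against the expected layout
.check_panels <- function(panels, parameters) {
  if (!is.data.frame(panels) || nrow(panels) == 0L)
    stop("panels must be a non-empty data.frame", call. = FALSE)
  required <- c("subject_id", "phase_id")
  missing_cols <- setdiff(required, names(panels))
  if (length(missing_cols))
    stop("panels is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  missing_par <- setdiff(parameters, names(panels))
  if (length(missing_par))
    stop("panels is missing parameter column(s): ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  key <- paste(panels$subject_id, panels$phase_id)
  if (anyDuplicated(key))
    stop("duplicated (subject_id, phase_id) rows in panels", call. = FALSE)
  invisible(panels)
}
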