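# Directional positive scoring and the n-of-5 classification rule.

#' Score a cohort against individual baselines and cut-offs
#'
#' Each (subject, phase, parameter) cell receives a positive score of 1
#' when the deviation of the observation from the subject's individual
#' baseline exceeds the cut-off in the adverse direction, strictly:
#' `direction * (observed - baseline) > direction * cutoff`. A deviation
#' exactly equal to the cut-off scores 0. A missing observation scores 0
#' and is counted in `n_missing`.
#'
#' @param panels Cohort panels data.frame.
#' @param baselines Output of [compute_baselines()].
#' @param cutoffs A `cutoff_set` (group cut-offs) or
#'   `individual_cutoff_set` (per-subject cut-offs).
#' @param specs Parameter specification.
#' @return A `score_matrix` data.frame: `subject_id`, `phase_id`, one 0/1
#'   column per parameter, `n_scores` (their sum) and `n_missing`.
#' @export
score_panels <- function(panels, baselines, cutoffs,
                         specs = parameter_specs()) {
  .check_panels(panels, specs$parameter)
  pars <- specs$parameter
  miss_b <- setdiff(unique(panels$subject_id), unique(baselines$subject_id))
  if (length(miss_b))
    stop("baselines missing for subject(s): ",
         paste(miss_b, collapse = ", "), call. = FALSE)
  individual <- inherits(cutoffs, "individual_cutoff_set")
  if (!all(pars %in% cutoffs$parameter))
    stop("cut-offs missing for parameter(s): ",
         paste(setdiff(pars, cutoffs$parameter), collapse = ", "),
         call. = FALSE)
  out <- panels[order(panels$subject_id, panels$phase_id),
                c("subject_id", "phase_id")]
  rownames(out) <- NULL
  obs <- panels[order(panels$subject_id, panels$phase_id), , drop = FALSE]
  for (p in pars) {
    d <- specs$direction[specs$parameter == p]
    bl <- baselines[baselines$parameter == p, ]
    b <- bl$baseline[match(out$subject_id, bl$subject_id)]
    if (individual) {
      cs <- cutoffs[cutoffs$parameter == p, ]
      q <- cs$cutoff[match(out$subject_id, cs$subject_id)]
    } else {
      q <- cutoffs$cutoff[cutoffs$parameter == p]
    }
    dev <- obs[[p]] - b
    # strict inequality with a float-representation guard: a deviation that
    # equals the cut-off up to rounding noise must score 0, not 1
    eps <- 1e-9 * pmax(1, abs(q))
    cell <- as.integer(d * dev > d * q + eps)
    cell[is.na(cell)] <- 0L
    out[[p]] <- cell
  }
  out$n_scores <- rowSums(out[, pars, drop = FALSE])
  out$n_missing <- rowSums(is.na(obs[, pars, drop = FALSE]))
  structure(out, parameters = pars, class = c("score_matrix", "data.frame"))
}

#' Classify subject-phases by score count
#'
#' A subject-phase is flagged as showing maladaptation when it accumulates
#' positive scores on at least `threshold` of the diagnostic parameters
#' (default 3 of 5, the rule with the highest discriminative power in the
#' reference cohort).
#'
#' @param scores A `score_matrix` from [score_panels()], or any data.frame
#'   with `subject_id`, `phase_id`, `n_scores`.
#' @param threshold Minimum number of positive scores to flag; must lie in
#'   `1..n_parameters`.
#' @return A data.frame `subject_id`, `phase_id`, `n_scores`, `flagged`,
#'   `threshold`, ordered by (subject, phase).
#' @export
classify <- function(scores, threshold = 3L) {
  stopifnot(is.data.frame(scores),
            all(c("subject_id", "phase_id", "n_scores") %in% names(scores)))
  n_par <- length(attr(scores, "parameters") %||% parameter_specs()$parameter)
  if (!(threshold >= 1L && threshold <= n_par))
    stop("threshold must lie in 1..", n_par, call. = FALSE)
  out <- data.frame(subject_id = scores$subject_id,
                    phase_id = scores$phase_id,
                    n_scores = scores$n_scores,
                    flagged = scores$n_scores >= threshold,
                    threshold = as.integer(threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(out$subject_id, out$phase_id), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
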