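# Intrinsic mitochondrial respiration: per-subject normal reference,
# per-phase deltas, and the score-respiration association.

#' Respiration deltas relative to the per-subject normal mean
#'
#' Normal respiration for a subject is the mean of their coupled CI+CII
#' ADP-stimulated respiration over the normal-reference phases (BL, LT,
#' MT1, RE by default); each phase's delta is the difference from that
#' mean. When all normal phases are present the normal-phase deltas of a
#' subject sum to zero.
#'
#' @param records data.frame with columns `subject_id`, `phase_id`,
#'   `respiration` (consistent units, e.g. pmol O2 s^-1 mg^-1).
#' @param schedule A [phase_schedule()].
#' @return `records` with `normal_respiration` and `delta` columns added.
#' @export
respiration_deltas <- function(records, schedule = phase_schedule()) {
  stopifnot(is.data.frame(records),
            all(c("subject_id", "phase_id", "respiration") %in% names(records)))
  normal <- records[records$phase_id %in% schedule$normal_phases &
                      !is.na(records$respiration), , drop = FALSE]
  means <- tapply(normal$respiration, normal$subject_id, mean)
  counts <- tapply(normal$respiration, normal$subject_id, length)
  absent <- setdiff(unique(records$subject_id), names(means))
  if (length(absent))
    stop("no normal-phase respiration for subject(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  short <- names(counts)[counts < length(schedule$normal_phases)]
  if (length(short))
    warning("normal respiration averaged over fewer than ",
            length(schedule$normal_phases), " phases for: ",
            paste(short, collapse = ", "), call. = FALSE)
  records$normal_respiration <- as.vector(means[records$subject_id])
  records$delta <- records$respiration - records$normal_respiration
  records
}

#' Correlate accumulated scores with respiration changes
#'
#' Pearson correlation between the number of positive diagnostic scores of
#' each subject-phase and the change in intrinsic mitochondrial respiration
#' from the subject's normal mean, paired on (subject, phase) and
#' restricted to phases present in both inputs (biopsies are not collected
#' in every phase). The p-value is the standard two-sided t-transform with
#' n - 2 degrees of freedom; no multiple-testing correction is applied to
#' this single pre-specified association.
#'
#' @param scores A data.frame with `subject_id`, `phase_id`, `n_scores`.
#' @param deltas Output of [respiration_deltas()] (needs `delta`).
#' @return A list with `r`, `p_value`, `n` (pairs used), `n_dropped`
#'   (pairs lost to missing deltas).
#' @export
correlate_scores_respiration <- function(scores, deltas) {
  stopifnot(all(c("subject_id", "phase_id", "n_scores") %in% names(scores)),
            all(c("subject_id", "phase_id", "delta") %in% names(deltas)))
  m <- merge(scores[, c("subject_id", "phase_id", "n_scores")],
             deltas[, c("subject_id", "phase_id", "delta")],
             by = c("subject_id", "phase_id"))
  n_dropped <- sum(is.na(m$delta) | is.na(m$n_scores))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3L)
    stop("at least 3 paired (n_scores, delta) observations are required",
         call. = FALSE)
  if (stats::sd(m$n_scores) == 0 || stats::sd(m$delta) == 0)
    stop("zero variance in scores or respiration deltas: ",
         "correlation undefined", call. = FALSE)
  ct <- stats::cor.test(m$n_scores, m$delta, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(m),
       n_dropped = n_dropped)
}
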