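# Cut-off derivation: half the group mean difference between the maladaptive
# phase and normal training load.

#' Cut-offs from group means
#'
#' Given per-parameter group means under normal and maladaptive training
#' load, the signed cut-off is half of the difference
#' `(mean_mal - mean_normal) / 2`, kept at full precision. A cut-off whose
#' sign contradicts the parameter's declared adverse direction triggers a
#' direction-mismatch warning (it would make the parameter score in the
#' wrong direction).
#'
#' @param mean_normal,mean_mal Named numeric vectors (names = parameters) or
#'   unnamed vectors aligned with `specs$parameter`.
#' @param specs Parameter specification, see [parameter_specs()].
#' @return A `cutoff_set` data.frame with columns `parameter`, `direction`,
#'   `mean_normal`, `mean_mal`, `mean_diff`, `cutoff`, `provenance`.
#' @examples
#' cutoffs_from_means(c(rpe_mean = 17.5), c(rpe_mean = 18.5),
#'                    specs = parameter_specs()[5, ])
#' @export
cutoffs_from_means <- function(mean_normal, mean_mal,
                               specs = parameter_specs()) {
  if (!is.null(names(mean_normal))) mean_normal <- mean_normal[specs$parameter]
  if (!is.null(names(mean_mal)))    mean_mal <- mean_mal[specs$parameter]
  stopifnot(length(mean_normal) == nrow(specs),
            length(mean_mal) == nrow(specs))
  diff <- unname(mean_mal) - unname(mean_normal)
  cutoff <- diff / 2
  bad <- sign(cutoff) != specs$direction
  if (any(bad))
    warning("cut-off direction mismatch (sign of derived cut-off differs ",
            "from the declared adverse direction) for: ",
            paste(specs$parameter[bad], collapse = ", "), call. = FALSE)
  out <- data.frame(parameter = specs$parameter, direction = specs$direction,
                    mean_normal = unname(mean_normal),
                    mean_mal = unname(mean_mal),
                    mean_diff = diff, cutoff = cutoff,
                    provenance = "derived", stringsAsFactors = FALSE)
  class(out) <- c("cutoff_set", "data.frame")
  out
}

#' Derive cut-offs from a cohort
#'
#' Group means are taken over the maladaptive phase and over the
#' normal-reference phases, and the cut-off is half their difference.
#' By default every subject-by-phase observation enters the normal group
#' mean with equal weight (`pooling = "observation"`);
#' `pooling = "subject"` averages within subject first, so each subject
#' contributes equally regardless of missing phases.
#'
#' @param panels Cohort panels data.frame (see [compute_baselines()]).
#' @param schedule A [phase_schedule()].
#' @param specs Parameter specification.
#' @param pooling `"observation"` (default) or `"subject"`.
#' @return A `cutoff_set` data.frame.
#' @export
derive_cutoffs <- function(panels, schedule = phase_schedule(),
                           specs = parameter_specs(),
                           pooling = c("observation", "subject")) {
  pooling <- match.arg(pooling)
  .check_panels(panels, specs$parameter)
  normal <- panels[panels$phase_id %in% schedule$normal_phases, , drop = FALSE]
  mal <- panels[panels$phase_id == schedule$mal_phase, , drop = FALSE]
  if (nrow(mal) == 0L)
    stop("no observations in the maladaptive phase '", schedule$mal_phase,
         "'", call. = FALSE)
  if (length(unique(mal$subject_id)) < 2L)
    stop("cut-off derivation requires the maladaptive phase for at least ",
         "two subjects", call. = FALSE)
  if (nrow(normal) == 0L)
    stop("no observations in normal-reference phases", call. = FALSE)
  group_mean <- function(df, par) {
    v <- df[[par]]
    if (pooling == "subject") {
      m <- tapply(v, df$subject_id, mean, na.rm = TRUE)
      m <- m[is.finite(m)]
    } else {
      m <- v[!is.na(v)]
    }
    if (length(m) == 0L)
      stop("no usable observations for parameter '", par, "'", call. = FALSE)
    mean(m)
  }
  mn <- vapply(specs$parameter, group_mean, numeric(1), df = normal)
  mm <- vapply(specs$parameter, group_mean, numeric(1), df = mal)
  cutoffs_from_means(mn, mm, specs)
}

#' Published fixed cut-offs
#'
#' The published reference cut-offs of the 11-subject cohort, applied
#' verbatim (`source = "published"`, the printed, rounded values: +4.7,
#' -2.5, -0.71, -0.62, +0.5) or recomputed at full precision as half of the
#' printed group mean differences (`source = "exact"`: +4.65, -2.55,
#' -0.715, -0.625, +0.5). The printed cut-offs are inconsistently rounded,
#' so the exact mode is offered for audits; `"published"` is the default
#' for reproducing reference scores.
#'
#' @param source `"published"` or `"exact"`.
#' @return A `cutoff_set` data.frame with provenance `"fixed"`.
#' @examples
#' fixed_cutoffs()
#' @export
fixed_cutoffs <- function(source = c("published", "exact")) {
  source <- match.arg(source)
  ref <- .published_reference()
  cutoff <- if (source == "published") ref$cutoff_published else ref$mean_diff / 2
  out <- data.frame(parameter = ref$parameter, direction = ref$direction,
                    mean_normal = ref$mean_normal, mean_mal = ref$mean_mal,
                    mean_diff = ref$mean_diff, cutoff = cutoff,
                    provenance = "fixed", stringsAsFactors = FALSE)
  class(out) <- c("cutoff_set", "data.frame")
  out
}

#' Per-subject individual cut-offs
#'
#' A non-default, exploratory mode: cut-offs computed per subject as half
#' of the difference between that subject's maladaptive-phase value and
#' their own normal-phase mean. With few normal observations per subject
#' this yields unstable (too high or too low) cut-offs; the group-derived
#' mode is the recommended default.
#'
#' @inheritParams derive_cutoffs
#' @return A data.frame with columns `subject_id`, `parameter`, `direction`,
#'   `cutoff`, class `individual_cutoff_set`.
#' @export
individual_cutoffs <- function(panels, schedule = phase_schedule(),
                               specs = parameter_specs()) {
  .check_panels(panels, specs$parameter)
  baselines <- compute_baselines(panels, schedule, specs)
  mal <- panels[panels$phase_id == schedule$mal_phase, , drop = FALSE]
  if (nrow(mal) == 0L)
    stop("no observations in the maladaptive phase", call. = FALSE)
  out <- baselines[, c("subject_id", "parameter")]
  out$direction <- specs$direction[match(out$parameter, specs$parameter)]
  out$cutoff <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- mal[mal$subject_id == out$subject_id[i], out$parameter[i]]
    v <- v[!is.na(v)]
    if (length(v))
      out$cutoff[i] <- (mean(v) - baselines$baseline[i]) / 2
  }
  class(out) <- c("individual_cutoff_set", "data.frame")
  out
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat("Cut-off set (", x$provenance[1], "):\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
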