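# Constrained synthetic-cohort generation: a deterministic reference score
# matrix matching published per-parameter and joint score counts, continuous
# measurement panels that re-score to any feasible matrix, respiration
# records with a configurable maladaptive-phase effect, and simulated HIIT
# session time series.

#' Packaged reference score constraints
#'
#' The published marginal constraints of the reference 11-subject, 6-phase
#' cohort: per training phase, the number of subjects achieving a positive
#' score on each diagnostic parameter (column sums), and the cumulative
#' number of subjects achieving at least k of 5 scores, k = 1..5 (the joint
#' distribution of per-subject score totals).
#'
#' @param path Optional path to a constraints CSV; defaults to the file
#'   shipped with the package.
#' @return A list: `parameter_counts` (parameters x phases matrix),
#'   `joint_cumulative` (5 x phases matrix, rows = minimum score k),
#'   `phases`, `n_subjects`.
#' @export
reference_constraints <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_score_constraints.csv",
                        package = "maladapt", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  phases <- setdiff(names(raw), c("record", "key"))
  pc <- raw[raw$record == "parameter_count", , drop = FALSE]
  jc <- raw[raw$record == "min_scores_count", , drop = FALSE]
  parameter_counts <- as.matrix(pc[, phases, drop = FALSE])
  rownames(parameter_counts) <- pc$key
  joint_cumulative <- as.matrix(jc[, phases, drop = FALSE])
  rownames(joint_cumulative) <- jc$key
  out <- list(parameter_counts = parameter_counts,
              joint_cumulative = joint_cumulative,
              phases = phases, n_subjects = 11L)
  .check_constraints(out)
  out
}

# consistency invariant: per phase, sum of parameter counts equals the
# total number of scores implied by the joint distribution; cumulative
# counts non-increasing in k and bounded by cohort size
.check_constraints <- function(cn) {
  n <- cn$n_subjects
  for (ph in cn$phases) {
    cum <- cn$joint_cumulative[, ph]
    if (any(diff(cum) > 0))
      stop("cumulative joint counts must be non-increasing in k (phase ",
           ph, ")", call. = FALSE)
    if (any(cum > n) || any(cum < 0))
      stop("cumulative joint counts out of [0, ", n, "] in phase ", ph,
           call. = FALSE)
    # sum over subjects of score totals = sum_k cum_k for cumulative counts
    total_joint <- sum(cum)
    total_par <- sum(cn$parameter_counts[, ph])
    if (total_joint != total_par)
      stop("inconsistent constraints in phase ", ph, ": parameter counts ",
           "total ", total_par, " but joint distribution implies ",
           total_joint, call. = FALSE)
  }
  invisible(cn)
}

# per-subject score totals (descending) implied by cumulative >=k counts
.row_sums_from_cumulative <- function(cum, n_subjects) {
  k_max <- length(cum)
  exact <- c(cum, 0)
  exact <- exact[seq_len(k_max)] - exact[-1]        # exactly k, k = 1..k_max
  rows <- rep(seq_len(k_max), times = exact)
  rows <- c(rows, rep(0L, n_subjects - length(rows)))
  sort(rows, decreasing = TRUE)
}

# Gale-Ryser feasibility of a binary matrix with given margins; returns a
# description of the violated bound, or NULL if feasible
.gale_ryser_violation <- function(row_desc, col_sums) {
  if (sum(row_desc) != sum(col_sums))
    return(sprintf("row-sum total %d != column-sum total %d",
                   sum(row_desc), sum(col_sums)))
  if (any(row_desc > length(col_sums)))
    return("a row sum exceeds the number of parameters")
  if (any(col_sums > length(row_desc)))
    return("a column sum exceeds the number of subjects")
  for (k in seq_along(row_desc)) {
    lhs <- sum(row_desc[seq_len(k)])
    rhs <- sum(pmin(col_sums, k))
    if (lhs > rhs)
      return(sprintf("Gale-Ryser bound violated at k = %d (%d > %d)",
                     k, lhs, rhs))
  }
  NULL
}

# deterministic construction of a binary matrix with the given margins:
# process columns in order of decreasing sum and give each column's ones to
# the rows with the largest remaining row sums (index-order tie-breaking).
# Succeeds whenever the margins are Gale-Ryser feasible.
.construct_binary_matrix <- function(row_sums, col_sums) {
  n <- length(row_sums); p <- length(col_sums)
  m <- matrix(0L, n, p)
  residual <- row_sums
  for (j in order(col_sums, decreasing = TRUE)) {
    c_j <- col_sums[j]
    if (c_j == 0L) next
    pick <- order(residual, decreasing = TRUE)[seq_len(c_j)]
    m[pick, j] <- 1L
    residual[pick] <- residual[pick] - 1L
  }
  if (any(residual != 0L))
    stop("internal: greedy construction left unmet row sums", call. = FALSE)
  m
}

#' Build the deterministic reference score matrix
#'
#' Constructs an 11-subject by 6-phase by 5-parameter binary score matrix
#' whose per-phase column sums equal the published per-parameter positive
#' score counts and whose per-phase distribution of per-subject score
#' totals reproduces the published joint distribution. The subject-level
#' assignment (which subject holds which score) is not identified by the
#' published margins; the canonical assignment is deterministic — within
#' each phase, score totals are assigned to subjects in descending order,
#' and each parameter's positive scores (parameters processed by
#' descending count) go to the subjects with the largest remaining totals,
#' ties broken by index. This construction succeeds whenever the margins
#' are Gale-Ryser feasible; infeasible constraints raise an error naming
#' the phase and the violated bound. `randomize = TRUE` permutes the
#' subject assignment per phase for sensitivity checks.
#'
#' @param constraints From [reference_constraints()].
#' @param randomize Permute subject assignment within phases (seeded by the
#'   caller via `set.seed`).
#' @return A `score_matrix` data.frame (see [score_panels()]) with subjects
#'   `S01..S11`.
#' @export
build_reference_score_matrix <- function(constraints = reference_constraints(),
                                         randomize = FALSE) {
  .check_constraints(constraints)
  pars <- rownames(constraints$parameter_counts)
  n <- constraints$n_subjects
  subjects <- sprintf("S%02d", seq_len(n))
  blocks <- lapply(constraints$phases, function(ph) {
    col_sums <- constraints$parameter_counts[, ph]
    rows <- .row_sums_from_cumulative(constraints$joint_cumulative[, ph], n)
    viol <- .gale_ryser_violation(rows, col_sums)
    if (!is.null(viol))
      stop("infeasible score constraints in phase ", ph, ": ", viol,
           call. = FALSE)
    m <- .construct_binary_matrix(rows, col_sums)
    if (randomize) m <- m[sample.int(n), , drop = FALSE]
    df <- data.frame(subject_id = subjects, phase_id = ph,
                     stringsAsFactors = FALSE)
    for (j in seq_along(pars)) df[[pars[j]]] <- m[, j]
    df
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$subject_id, out$phase_id), ]
  rownames(out) <- NULL
  out$n_scores <- rowSums(out[, pars, drop = FALSE])
  out$n_missing <- 0L
  structure(out, parameters = pars, class = c("score_matrix", "data.frame"))
}

#' Synthetic-cohort generator configuration
#'
#' Default study conditions for the synthetic cohort: 11 subjects over the
#' six-phase schedule; per-parameter normal-load means taken from the
#' published reference cohort; approximate between-subject SDs (figure
#' error-bar scale); measurement noise defaulting to half the cut-off
#' magnitude; a -40% maladaptive-phase effect on intrinsic mitochondrial
#' respiration around a subject-level mean of 100 +/- 15 arbitrary units
#' with within-subject SD 8; and a moderate (0.5x) maladaptive effect in
#' the second moderate-load test phase.
#'
#' @param n_subjects Cohort size.
#' @param schedule A [phase_schedule()].
#' @param between_sd Named per-parameter between-subject SD of baselines.
#' @param noise_sd Named per-parameter measurement noise SD, or `NULL` for
#'   half the cut-off magnitude.
#' @param mt2_effect_scale Fraction of the full maladaptive effect applied
#'   in the `MT2` test phase by [simulate_cohort()].
#' @param respiration_mean,respiration_between_sd Subject-level normal
#'   respiration mean and SD (arbitrary consistent units).
#' @param respiration_within_sd Within-subject (phase-to-phase) SD.
#' @param mal_respiration_effect Relative change of respiration in the
#'   maladaptive phase (default -0.40, i.e. a 40% reduction).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 11L,
                             schedule = phase_schedule(),
                             between_sd = c(poms_fatigue = 6, hr_max = 8,
                                            glucose_end = 0.8,
                                            lactate_end = 2.5,
                                            rpe_mean = 1.0),
                             noise_sd = NULL,
                             mt2_effect_scale = 0.5,
                             respiration_mean = 100,
                             respiration_between_sd = 15,
                             respiration_within_sd = 8,
                             mal_respiration_effect = -0.40) {
  stopifnot(n_subjects >= 1L, all(between_sd >= 0),
            respiration_between_sd >= 0, respiration_within_sd >= 0)
  structure(list(n_subjects = as.integer(n_subjects), schedule = schedule,
                 between_sd = between_sd, noise_sd = noise_sd,
                 mt2_effect_scale = mt2_effect_scale,
                 respiration_mean = respiration_mean,
                 respiration_between_sd = respiration_between_sd,
                 respiration_within_sd = respiration_within_sd,
                 mal_respiration_effect = mal_respiration_effect),
            class = "generator_config")
}

#' Realize a score matrix as continuous measurement panels
#'
#' Generates measurement panels whose re-derived scores reproduce a given
#' binary score matrix exactly. Each subject draws a parameter baseline
#' from the normal-load group mean and between-subject SD; within the
#' normal-reference phases, deviations are constructed to average exactly
#' zero (so the re-computed individual baseline equals the draw) with
#' positive-score cells placed 1.2-2.0 cut-offs beyond the baseline in the
#' adverse direction and zero cells held at most 0.8 cut-offs in that
#' direction; in test phases the deviation is cut-off x U(1.2, 2.0) for a
#' positive cell and cut-off x U(0, 0.8) otherwise. The round trip is
#' verified by re-scoring; mismatching subjects are redrawn up to
#' `max_retries` times.
#'
#' A subject with positive scores in *all* normal-reference phases for one
#' parameter cannot be realized (deviations from their own mean must sum
#' to zero) and raises an error.
#'
#' @param matrix A `score_matrix` (e.g. [build_reference_score_matrix()]).
#' @param config A [generator_config()].
#' @param cutoffs The cut-offs the scores refer to (default the published
#'   fixed set).
#' @param specs Parameter specification.
#' @param seed Optional integer seed (`set.seed`).
#' @param max_retries Redraw budget per subject.
#' @return A panels data.frame (`subject_id`, `phase_id`, one column per
#'   parameter).
#' @export
generate_measurements <- function(matrix, config = generator_config(),
                                  cutoffs = fixed_cutoffs(),
                                  specs = parameter_specs(),
                                  seed = NULL, max_retries = 10L) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(matrix, "data.frame"))
  pars <- attr(matrix, "parameters") %||% specs$parameter
  sched <- config$schedule
  normal <- sched$normal_phases
  ref <- .published_reference()
  subjects <- unique(matrix$subject_id)
  draw_subject <- function(sid) {
    cells <- matrix[matrix$subject_id == sid, , drop = FALSE]
    out <- data.frame(subject_id = sid, phase_id = cells$phase_id,
                      stringsAsFactors = FALSE)
    for (p in pars) {
      d <- specs$direction[specs$parameter == p]
      q <- cutoffs$cutoff[cutoffs$parameter == p]
      cw <- abs(q)
      mu <- ref$mean_normal[match(p, ref$parameter)]
      if (is.na(mu)) mu <- 0
      sdev <- config$between_sd[[p]] %||% 0
      if (is.na(sdev) || is.null(sdev)) sdev <- 0
      b <- stats::rnorm(1, mu, sdev)
      is_norm <- cells$phase_id %in% normal
      m <- sum(is_norm)
      cell <- cells[[p]]
      if (cw == 0 && any(cell == 1L))
        stop("cannot realize positive scores for parameter '", p,
             "' with a zero cut-off", call. = FALSE)
      e <- numeric(nrow(cells))
      # normal-reference phases: adverse-direction excess, mean exactly zero
      k <- sum(cell[is_norm] == 1L)
      if (k == m && m > 0L)
        stop("subject '", sid, "' has positive scores in every ",
             "normal-reference phase for parameter '", p,
             "': not realizable under mean-zero baselines", call. = FALSE)
      if (m > 0L) {
        en <- numeric(m)
        pos <- cell[is_norm] == 1L
        if (k > 0L) {
          en[pos] <- stats::runif(k, 1.2, 2.0)
          jit <- stats::runif(m - k, -0.3, 0.3)
          en[!pos] <- -sum(en[pos]) / (m - k) + (jit - mean(jit))
        } else {
          jit <- stats::runif(m, -0.5, 0.5)
          en <- jit - mean(jit)
        }
        e[is_norm] <- en
      }
      # test phases: direct placement relative to the baseline
      nt <- sum(!is_norm)
      if (nt > 0L) {
        et <- ifelse(cells[[p]][!is_norm] == 1L,
                     stats::runif(nt, 1.2, 2.0),
                     stats::runif(nt, 0.0, 0.8))
        e[!is_norm] <- et
      }
      out[[p]] <- b + d * cw * e
    }
    out
  }
  panels_list <- lapply(subjects, function(sid) {
    target <- matrix[matrix$subject_id == sid, c("subject_id", "phase_id",
                                                 pars)]
    for (try in seq_len(max_retries)) {
      pan <- draw_subject(sid)
      bl <- compute_baselines(pan, sched, specs[specs$parameter %in% pars, ])
      sc <- score_panels(pan, bl, cutoffs, specs[specs$parameter %in% pars, ])
      got <- sc[match(paste(target$subject_id, target$phase_id),
                      paste(sc$subject_id, sc$phase_id)), pars]
      if (all(got == target[, pars])) return(pan)
    }
    stop("round-trip retry budget exhausted for subject '", sid,
         "': score matrix and generator config are incompatible",
         call. = FALSE)
  })
  out <- do.call(rbind, panels_list)
  rownames(out) <- NULL
  out
}

#' Generate intrinsic mitochondrial respiration records
#'
#' Subject-level normal respiration is drawn from the configured mean and
#' between-subject SD; normal-reference phases scatter around it with the
#' within-subject SD, and the maladaptive phase mean is shifted by the
#' configured relative effect (default -40%). No record is produced for
#' the `MT2` test phase (no biopsy is collected there).
#'
#' @param config A [generator_config()].
#' @param n_subjects Override of `config$n_subjects`.
#' @param seed Optional integer seed.
#' @return data.frame `subject_id`, `phase_id`, `respiration`.
#' @export
generate_respiration <- function(config = generator_config(),
                                 n_subjects = config$n_subjects,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sched <- config$schedule
  phases <- c(sched$normal_phases, sched$mal_phase)
  phases <- sched$phases[sched$phases %in% phases]   # keep schedule order
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  sm <- stats::rnorm(n_subjects, config$respiration_mean,
                     config$respiration_between_sd)
  sm <- pmax(sm, config$respiration_mean * 0.2)      # keep physiologic
  rows <- lapply(seq_len(n_subjects), function(i) {
    mu <- ifelse(phases == sched$mal_phase,
                 sm[i] * (1 + config$mal_respiration_effect), sm[i])
    data.frame(subject_id = subjects[i], phase_id = phases,
               respiration = stats::rnorm(length(phases), mu,
                                          config$respiration_within_sd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a maladaptive cohort under an effect-size model
#'
#' Unlike [generate_measurements()], which realizes a prescribed score
#' matrix, this simulates cohorts from a population model: each subject's
#' parameter baseline is drawn around the normal-load group mean; normal
#' phases add pure measurement noise; the maladaptive phase adds the
#' adverse-direction effect (default: the published group mean
#' differences) plus noise; the `MT2` test phase receives a scaled
#' fraction of the effect. Used for classifier sensitivity /
#' false-positive studies.
#'
#' @param config A [generator_config()]. `config$noise_sd` (named per
#'   parameter) defaults to half the cut-off magnitude.
#' @param effects Named per-parameter signed maladaptive effects; default
#'   the published mean differences.
#' @param specs Parameter specification.
#' @param seed Optional integer seed.
#' @return A panels data.frame.
#' @export
simulate_cohort <- function(config = generator_config(), effects = NULL,
                            specs = parameter_specs(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ref <- .published_reference()
  sched <- config$schedule
  if (is.null(effects)) {
    effects <- ref$mean_diff
    names(effects) <- ref$parameter
  }
  noise <- config$noise_sd
  if (is.null(noise)) {
    noise <- abs(effects) / 4          # half the cut-off magnitude
  }
  subjects <- sprintf("S%02d", seq_len(config$n_subjects))
  grid <- expand.grid(subject_id = subjects, phase_id = sched$phases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  for (p in specs$parameter) {
    mu <- ref$mean_normal[match(p, ref$parameter)]
    if (is.na(mu)) mu <- 0
    b <- stats::rnorm(config$n_subjects, mu, config$between_sd[[p]] %||% 0)
    shift <- ifelse(grid$phase_id == sched$mal_phase, effects[[p]],
                    ifelse(grid$phase_id == "MT2" &
                             !"MT2" %in% sched$normal_phases,
                           config$mt2_effect_scale * effects[[p]], 0))
    grid[[p]] <- b[match(grid$subject_id, subjects)] + shift +
      stats::rnorm(nrow(grid), 0, noise[[p]])
  }
  grid[order(grid$subject_id, grid$phase_id), ]
}

#' Generate a synthetic monitored HIIT session
#'
#' A 1 Hz session emulating the monitored design: 10 min of warm-up at
#' 100 W, 2 min of passive rest, then five 4-min intervals separated by
#' 3 min of passive rest. Heart rate follows first-order kinetics toward
#' segment-specific targets (rising within intervals, exponential decay in
#' rests); VO2 tracks power with first-order kinetics and VCO2 follows a
#' segment-specific respiratory exchange ratio.
#'
#' @param interval_power_w Mean target power of the intervals, W.
#' @param hr_noise_sd,power_noise_sd Per-sample Gaussian noise SDs (0 for
#'   a deterministic trace).
#' @param seed Optional integer seed.
#' @return list with `series` (`time_s`, `hr_bpm`, `vo2_lmin`,
#'   `vco2_lmin`, `power_w`, `label`) and `markers` (`label`, `start_s`,
#'   `end_s`).
#' @export
generate_session <- function(interval_power_w = 260, hr_noise_sd = 0.5,
                             power_noise_sd = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- data.frame(
    label = c("warmup", "rest_0",
              paste0(rep(c("interval_", "rest_"), 5), rep(1:5, each = 2))),
    dur = c(600, 120, rep(c(240, 180), 5)),
    stringsAsFactors = FALSE
  )
  segs$end_s <- cumsum(segs$dur) - 1
  segs$start_s <- segs$end_s - segs$dur + 1
  n <- sum(segs$dur)
  lab <- rep(segs$label, segs$dur)
  is_interval <- startsWith(lab, "interval")
  interval_no <- rep(0L, n)
  interval_no[is_interval] <- as.integer(sub("interval_", "",
                                             lab[is_interval]))
  power <- ifelse(lab == "warmup", 100,
                  ifelse(is_interval, interval_power_w, 0))
  power <- pmax(power + stats::rnorm(n, 0, power_noise_sd) *
                  (power > 0), 0)
  hr_target <- ifelse(lab == "warmup", 140,
                      ifelse(is_interval, 170 + 2 * interval_no, 100))
  hr_tau <- ifelse(is_interval, 45, 60)
  hr <- numeric(n); hr[1] <- 70
  decay <- exp(-1 / hr_tau)
  for (t in 2:n)
    hr[t] <- hr_target[t] + (hr[t - 1] - hr_target[t]) * decay[t] +
      stats::rnorm(1, 0, hr_noise_sd)
  vo2_target <- 0.35 + 0.0105 * power
  vo2 <- numeric(n); vo2[1] <- 0.35
  dv <- exp(-1 / 30)
  for (t in 2:n)
    vo2[t] <- vo2_target[t] + (vo2[t - 1] - vo2_target[t]) * dv
  rer <- ifelse(lab == "warmup", 0.90, ifelse(is_interval, 1.00, 0.95))
  series <- data.frame(time_s = seq_len(n) - 1, hr_bpm = pmax(hr, 40),
                       vo2_lmin = pmax(vo2, 0.2),
                       vco2_lmin = pmax(vo2, 0.2) * rer,
                       power_w = power, label = lab,
                       stringsAsFactors = FALSE)
  list(series = series,
       markers = segs[, c("label", "start_s", "end_s")])
}
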