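# Independent brute-force oracles and small cohort builders used across the
# test files. These deliberately re-evaluate the model definitions with
# explicit loops, independent of the vectorized implementation.

# brute-force per-cell evaluation of the scoring inequality
oracle_scores <- function(panels, baselines, cutoffs,
                          specs = parameter_specs()) {
  rows <- list()
  for (i in seq_len(nrow(panels))) {
    sid <- panels$subject_id[i]
    ph <- panels$phase_id[i]
    rec <- list(subject_id = sid, phase_id = ph)
    total <- 0L
    for (j in seq_len(nrow(specs))) {
      p <- specs$parameter[j]
      d <- specs$direction[j]
      b <- baselines$baseline[baselines$subject_id == sid &
                                baselines$parameter == p]
      q <- cutoffs$cutoff[cutoffs$parameter == p]
      obs <- panels[i, p]
      cell <- if (is.na(obs)) 0L else as.integer(d * (obs - b) > d * q)
      rec[[p]] <- cell
      total <- total + cell
    }
    rec$n_scores <- total
    rows[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$subject_id, out$phase_id), ]
}

# brute-force classification
oracle_classify <- function(scores, threshold) {
  flagged <- logical(nrow(scores))
  for (i in seq_len(nrow(scores))) flagged[i] <- scores$n_scores[i] >= threshold
  flagged
}

# brute-force rolling-window peak: loop over every window start
oracle_rolling_peak <- function(x, w) {
  best <- -Inf
  best_start <- NA_integer_
  for (s in 1:(length(x) - w + 1)) {
    m <- mean(x[s:(s + w - 1)])
    if (m > best) { best <- m; best_start <- s }
  }
  list(value = best, start = best_start)
}

# hand evaluation of the Pearson formula (oracle for cor.test-based code)
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# a small random cohort with known structure; values drawn wide enough to
# exercise both score outcomes
random_cohort <- function(n_subjects, specs = parameter_specs(),
                          schedule = phase_schedule()) {
  subjects <- sprintf("R%02d", seq_len(n_subjects))
  grid <- expand.grid(subject_id = subjects, phase_id = schedule$phases,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ref <- data.frame(parameter = specs$parameter,
                    mu = c(43, 184, 6, 13, 17.5)[seq_len(nrow(specs))])
  for (j in seq_len(nrow(specs))) {
    p <- specs$parameter[j]
    base <- rnorm(n_subjects, ref$mu[j], 2)
    grid[[p]] <- base[match(grid$subject_id, subjects)] +
      rnorm(nrow(grid), 0, 2)
  }
  grid
}

# minimal single-subject panel over the default schedule
one_subject_panel <- function(values_by_phase,
                              phases = c("BL", "LT", "MT1", "RE"),
                              parameter = "poms_fatigue") {
  df <- data.frame(subject_id = "S1", phase_id = phases,
                   poms_fatigue = 40, hr_max = 185, glucose_end = 6,
                   lactate_end = 13, rpe_mean = 17,
                   stringsAsFactors = FALSE)
  df[[parameter]] <- values_by_phase
  df
}
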