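# Pooling of stratified summary statistics.

#' Sample-size-weighted pooled mean
#'
#' Pools per-stratum means (e.g. published sex-stratified subject
#' characteristics) into an overall mean weighted by stratum size:
#' `sum(n_i * mean_i) / sum(n_i)`. Note that pooling *rounded* stratum
#' means need not reproduce a mean computed from raw data at the same
#' printed precision.
#'
#' @param n Integer vector of stratum sizes (all >= 1).
#' @param means Numeric vector of stratum means, same length as `n`.
#' @param digits Optional; round the pooled mean to this many digits
#'   (matching the input's printed precision). `NULL` returns full
#'   precision.
#' @return The pooled mean.
#' @examples
#' pooled_group_stats(c(6, 5), c(2848, 3947), digits = 0) # 3348
#' @export
pooled_group_stats <- function(n, means, digits = NULL) {
  stopifnot(length(n) == length(means), length(n) >= 1L)
  if (any(n < 1L)) stop("stratum sizes must be >= 1", call. = FALSE)
  if (sum(n) == 0L) stop("zero total n", call. = FALSE)
  pooled <- sum(n * means) / sum(n)
  if (!is.null(digits)) pooled <- round(pooled, digits)
  pooled
}
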