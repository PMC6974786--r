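# Per-target-set potency statistics: boxplot quartiles and IQR of the
# compound pKi distribution (pre-selection gate), and the target-set-
# dependent activity-cliff threshold: mean of the analog-pair delta-pKi
# distribution plus two standard deviations.

#' Quartiles and interquartile range of a potency distribution
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7 by default; the convention is configurable).
#'
#' @param pki Numeric vector of pKi values (or a `target_set`).
#' @param quartile_type Quantile type passed to [stats::quantile()].
#' @return List with `q1`, `q3`, `iqr`.
#' @export
compute_iqr <- function(pki, quartile_type = 7L) {
  if (inherits(pki, "target_set")) pki <- pki$compounds$pki
  stopifnot(is.numeric(pki))
  if (length(pki) < 2L) stop("need at least 2 potency values")
  q <- unname(stats::quantile(pki, probs = c(0.25, 0.75),
                              type = quartile_type, names = FALSE))
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}

#' Potency-difference threshold from an analog-pair distribution
#'
#' The activity-cliff criterion of a target set is the mean of its analog-pair
#' delta-pKi distribution plus two standard deviations.
#'
#' @param delta Numeric vector of pair potency differences (delta pKi >= 0),
#'   or a pair data.frame with a `delta_pki` column.
#' @param sigma_mode `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List with `n_pairs`, `delta_mean`, `delta_sigma`, `threshold`.
#'   `NULL` if fewer than 2 pairs (sigma undefined).
#' @export
compute_threshold <- function(delta, sigma_mode = c("sample", "population")) {
  sigma_mode <- match.arg(sigma_mode)
  if (is.data.frame(delta)) delta <- delta$delta_pki
  n <- length(delta)
  if (n < 2L) return(NULL)
  m <- mean(delta)
  s <- stats::sd(delta)
  if (sigma_mode == "population") s <- s * sqrt((n - 1) / n)
  list(n_pairs = n, delta_mean = m, delta_sigma = s, threshold = m + 2 * s)
}

#' Full statistics row for one target set
#'
#' @param target_set A `target_set`.
#' @param pairs Deduplicated analog-pair data.frame of the set (may be empty).
#' @param min_iqr IQR pre-selection cutoff (pKi units; default 1).
#' @param quartile_type,sigma_mode See [compute_iqr()], [compute_threshold()].
#' @return One-row data.frame: `target_id`, `n_compounds`, `q1`, `q3`, `iqr`,
#'   `n_pairs`, `delta_mean`, `delta_sigma`, `threshold`, `retained`.
#'   Threshold columns are `NA` when fewer than 2 pairs exist.
#' @export
target_set_stats <- function(target_set, pairs, min_iqr = 1,
                             quartile_type = 7L,
                             sigma_mode = c("sample", "population")) {
  sigma_mode <- match.arg(sigma_mode)
  iq <- compute_iqr(target_set, quartile_type = quartile_type)
  thr <- if (!is.null(pairs) && nrow(pairs) >= 2L) {
    compute_threshold(pairs, sigma_mode = sigma_mode)
  } else NULL
  data.frame(
    target_id = target_set$target_id,
    n_compounds = target_set$n,
    q1 = iq$q1, q3 = iq$q3, iqr = iq$iqr,
    n_pairs = if (is.null(thr)) if (is.null(pairs)) 0L else nrow(pairs)
              else thr$n_pairs,
    delta_mean = if (is.null(thr)) NA_real_ else thr$delta_mean,
    delta_sigma = if (is.null(thr)) NA_real_ else thr$delta_sigma,
    threshold = if (is.null(thr)) NA_real_ else thr$threshold,
    retained = iq$iqr >= min_iqr,
    stringsAsFactors = FALSE)
}

#' IQR pre-selection of target sets
#'
#' Target sets with an interquartile range of at least `min_iqr` (one order
#' of magnitude in potency by default) are retained; comparison is
#' non-strict, so a set at the boundary is kept.
#'
#' @param stats_tab data.frame of [target_set_stats()] rows.
#' @param min_iqr Cutoff in pKi units (default 1).
#' @return `stats_tab` restricted to retained sets.
#' @export
preselect_target_sets <- function(stats_tab, min_iqr = 1) {
  stats_tab[stats_tab$iqr >= min_iqr, , drop = FALSE]
}
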