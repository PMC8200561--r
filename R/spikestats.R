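#' Inter-spike intervals of a spike train
#'
#' Successive differences of the (sorted) spike times, in seconds. For a
#' merged multi-fiber train the intervals are computed on the merged sequence,
#' matching the whole-nerve usage.
#'
#' @param train Tibble with a `t_ms` column (spike times in ms), or a numeric
#'   vector of spike times (ms).
#' @return A tibble with column `isi_s`; empty for fewer than two spikes.
#' @export
interspike_intervals <- function(train) {
  t_ms <- if (is.data.frame(train)) train$t_ms else as.numeric(train)
  if (is.unsorted(t_ms, strictly = FALSE)) {
    abort("Spike times must be sorted.")
  }
  if (length(t_ms) < 2) return(tibble(isi_s = numeric(0)))
  tibble(isi_s = diff(t_ms) / 1000)
}

#' Two-sample Kolmogorov-Smirnov test on ISI samples
#'
#' D is the supremum distance between the two empirical CDFs; the p-value uses
#' the exact small-sample null when `n1 * n2 <= 100` and the asymptotic
#' formula otherwise. Distributions with p above 0.05 are treated as similar
#' (the null of a common distribution is retained).
#'
#' @param x,y Numeric vectors, or tibbles with an `isi_s` column.
#' @return A one-row tibble: `d_statistic`, `p_value`, `n1`, `n2`.
#' @export
ks_two_sample <- function(x, y) {
  x <- if (is.data.frame(x)) x$isi_s else as.numeric(x)
  y <- if (is.data.frame(y)) y$isi_s else as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be nonempty.")
  }
  exact <- length(x) * length(y) <= 100
  res <- suppressWarnings(ks.test(x, y, exact = exact))
  tibble(d_statistic = unname(res$statistic), p_value = min(1, res$p.value),
         n1 = length(x), n2 = length(y))
}

#' Firing summary of a spike train
#'
#' Spike count, mean rate and the fraction of inter-spike intervals shorter
#' than 0.1 s (i.e. instantaneous frequency above 10 Hz; the boundary ISI of
#' exactly 0.1 s is not counted).
#'
#' @param train Tibble with `t_ms`, or numeric spike times (ms).
#' @param window Length-2 numeric, analysis window in ms; defaults to
#'   `c(0, max spike time)`.
#' @return A one-row tibble: `n_spikes`, `rate_hz`, `fraction_isi_below_100ms`.
#' @export
firing_summary <- function(train, window = NULL) {
  t_ms <- if (is.data.frame(train)) train$t_ms else as.numeric(train)
  if (is.null(window)) window <- c(0, if (length(t_ms)) max(t_ms) else 0)
  t_ms <- t_ms[t_ms >= window[1] & t_ms <= window[2]]
  dur_s <- (window[2] - window[1]) / 1000
  isi <- if (length(t_ms) >= 2) diff(t_ms) / 1000 else numeric(0)
  tibble(
    n_spikes = length(t_ms),
    rate_hz = if (dur_s > 0) length(t_ms) / dur_s else 0,
    fraction_isi_below_100ms = if (length(isi)) mean(isi < 0.1) else 0
  )
}
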