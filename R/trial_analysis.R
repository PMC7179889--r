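#' Event-locked epoching
#'
#' Cuts onset-aligned windows (default 10 s at 4 Hz = 40 samples, half-open
#' \code{[onset, onset + window)}) out of a per-sample series. Trials whose
#' window overruns the recording are dropped and counted.
#'
#' @param series Numeric per-sample series at \code{rate} Hz (e.g. skin
#'   conductance or the smoothed arousal state).
#' @param onsets Data.frame with columns \code{onset_s} and \code{label}.
#' @param window_s Window length in seconds (default 10).
#' @param rate Sampling rate (default 4).
#' @return An object of class \code{epoch_table}: list with \code{windows}
#'   (trials x samples matrix), \code{condition}, \code{onset_s},
#'   \code{trial_mean} (per-trial window means), \code{dropped} (count) and
#'   \code{window_s}.
#' @export
epoch <- function(series, onsets, window_s = 10, rate = 4) {
  stopifnot(is.data.frame(onsets), all(c("onset_s", "label") %in% names(onsets)))
  w <- as.integer(round(window_s * rate))
  n <- length(series)
  start <- floor(onsets$onset_s * rate) + 1L  # 0-based time -> 1-based sample
  ok <- start + w - 1L <= n & start >= 1L
  dropped <- sum(!ok)
  windows <- if (any(ok))
    t(vapply(start[ok], function(s0) series[s0:(s0 + w - 1L)], numeric(w)))
  else matrix(numeric(0), 0, w)
  structure(list(windows = windows,
                 condition = as.character(onsets$label[ok]),
                 onset_s = onsets$onset_s[ok],
                 trial_mean = if (nrow(windows)) rowMeans(windows) else numeric(0),
                 dropped = dropped, window_s = window_s, rate = rate),
            class = "epoch_table")
}

#' @export
print.epoch_table <- function(x, ...) {
  cat(sprintf("epoch_table: %d trials (%d dropped), %g s windows\n",
              nrow(x$windows), x$dropped, x$window_s))
  print(table(x$condition))
  invisible(x)
}

#' Per-condition summary statistics with one-tailed tests
#'
#' Mean and standard deviation of per-trial window means per condition, plus
#' one-tailed Welch two-sample t-tests for the ordered contrasts
#' CS+US+ > CS+US- and CS+US- > CS-. Raw p-values are reported (no
#' multiplicity correction); stars mark p < 0.05.
#'
#' @param epochs An [epoch()] table.
#' @return A list with \code{summary} (data.frame: condition, n, mean, sd,
#'   pooled mean over all samples) and \code{tests} (data.frame: contrast,
#'   p_value, significant).
#' @export
condition_stats <- function(epochs) {
  conds <- c("CS+US+", "CS+US-", "CS-")
  per <- lapply(conds, function(cc) epochs$trial_mean[epochs$condition == cc])
  names(per) <- conds
  pooled <- vapply(conds, function(cc) {
    wi <- epochs$windows[epochs$condition == cc, , drop = FALSE]
    if (nrow(wi)) mean(wi) else NA_real_
  }, numeric(1))
  summ <- data.frame(
    condition = conds,
    n = vapply(per, length, integer(1)),
    mean = vapply(per, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
    sd = vapply(per, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, numeric(1)),
    pooled_mean = pooled,
    row.names = NULL
  )
  one_tail <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NA_real_)
    if (stats::sd(a) == 0 && stats::sd(b) == 0)
      return(if (mean(a) > mean(b)) 0 else if (mean(a) < mean(b)) 1 else 0.5)
    stats::t.test(a, b, alternative = "greater", var.equal = FALSE)$p.value
  }
  p1 <- one_tail(per[["CS+US+"]], per[["CS+US-"]])
  p2 <- one_tail(per[["CS+US-"]], per[["CS-"]])
  tests <- data.frame(
    contrast = c("CS+US+ > CS+US-", "CS+US- > CS-"),
    p_value = c(p1, p2),
    significant = c(isTRUE(p1 < 0.05), isTRUE(p2 < 0.05))
  )
  list(summary = summ, tests = tests)
}

#' Block-wise trend curves
#'
#' Averages window curves over blocks of trials (e.g. early/middle/late) for
#' one condition, exposing habituation or learning trends across the session.
#'
#' @param epochs An [epoch()] table.
#' @param blocks List of integer trial-index vectors (indices within the
#'   chosen condition, in presentation order).
#' @param condition Condition label to analyze.
#' @return A list per block with \code{curve} (mean window), \code{mean}
#'   (scalar mean) and \code{n_trials}; empty blocks yield empty entries.
#' @export
block_trends <- function(epochs, blocks, condition = "CS-") {
  sel <- which(epochs$condition == condition)
  sel <- sel[order(epochs$onset_s[sel])]
  lapply(blocks, function(idx) {
    idx <- idx[idx <= length(sel)]
    if (!length(idx))
      return(list(curve = numeric(0), mean = NA_real_, n_trials = 0L))
    wi <- epochs$windows[sel[idx], , drop = FALSE]
    list(curve = colMeans(wi), mean = mean(wi), n_trials = nrow(wi))
  })
}
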