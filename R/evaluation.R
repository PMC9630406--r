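#' Decile risk and sensitivity curve for a progression score
#'
#' Stratifies scored children by the tenth centiles of the score and
#' reports, per decile bin, the Kaplan-Meier cumulative risk of
#' progression at the horizon, together with the cumulative sensitivity
#' of thresholding at each decile edge (progressors within the horizon
#' scoring above the edge, as a fraction of all progressors within the
#' horizon).
#'
#' @param scores Numeric scores.
#' @param times,events Follow-up as in [km_fit()].
#' @param horizon Risk horizon in years (default 2).
#' @return A list of class `"decile_curve"`: `edges` (the decile grid,
#'   including the extremes), `bins` (data.frame with per-bin n, events
#'   within the horizon, KM risk and CI) and `sensitivity` (data.frame
#'   with one row per interior edge: centile, threshold, sensitivity).
#' @export
decile_curve <- function(scores, times, events, horizon = 2) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  events <- as.logical(events)
  probs <- seq(0, 1, by = 0.1)
  edges <- stats::quantile(scores, probs, names = FALSE, type = 7)
  if (length(unique(edges)) < length(edges)) {
    warning("fewer than 10 distinct score deciles; using coarser bins",
            call. = FALSE)
    edges <- unique(edges)
    probs <- probs[!duplicated(stats::quantile(scores, probs, names = FALSE,
                                               type = 7))]
  }
  bin <- cut(scores, breaks = edges, include.lowest = TRUE)
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- which(bin == b)
    r <- risk_at(km_fit(times[idx], events[idx]), horizon)
    data.frame(bin = b, n = length(idx),
               events_within = sum(events[idx] & times[idx] <= horizon),
               risk = r$risk, ci_low = r$ci_low, ci_high = r$ci_high)
  }))
  progressor <- events & times <= horizon
  n_prog <- sum(progressor)
  interior <- edges[-c(1, length(edges))]
  sens <- vapply(interior, function(thr) {
    if (n_prog == 0) return(NA_real_)
    sum(progressor & scores > thr) / n_prog
  }, numeric(1))
  structure(list(
    edges = edges,
    bins = bins,
    sensitivity = data.frame(centile = 100 * probs[-c(1, length(probs))],
                             threshold = interior, sensitivity = sens)
  ), class = "decile_curve")
}

#' Threshold diagnostics of a binary progression prediction
#'
#' Cross-classifies `score > threshold` against the binary outcome and
#' reports sensitivity, specificity, positive predictive value, the
#' positive and negative likelihood ratios, and the diagnostic odds ratio
#' in both of its algebraically equivalent forms (LR+/LR- and
#' (tp x tn)/(fp x fn)); the two agree when no intermediate rounding is
#' applied. Metrics whose denominator is zero are reported as `NA`
#' (undefined), never as infinity.
#'
#' @param scores Numeric scores.
#' @param outcome Logical 2-year progression outcome (see
#'   [restrict_to_outcome()]).
#' @param threshold Decision threshold; the positive call is strict
#'   (`score > threshold`).
#' @return A list of class `"diagnostic_metrics"` with counts and derived
#'   metrics.
#' @export
threshold_diagnostics <- function(scores, outcome, threshold) {
  stopifnot(length(scores) == length(outcome))
  outcome <- as.logical(outcome)
  pos <- scores > threshold
  tp <- sum(pos & outcome); fp <- sum(pos & !outcome)
  fn <- sum(!pos & outcome); tn <- sum(!pos & !outcome)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  lr_pos <- if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  lr_neg <- if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  dor_ratio <- if (!is.na(lr_pos) && !is.na(lr_neg) && lr_neg > 0) {
    lr_pos / lr_neg
  } else NA_real_
  dor_counts <- if (fp > 0 && fn > 0) (tp * tn) / (fp * fn) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = tp + fp + tn + fn,
                 threshold = threshold,
                 sensitivity = sens, specificity = spec, ppv = ppv,
                 lr_positive = lr_pos, lr_negative = lr_neg,
                 diagnostic_or = dor_ratio,
                 diagnostic_or_counts = dor_counts),
            class = "diagnostic_metrics")
}

#' Percentile bootstrap confidence interval
#'
#' Resamples children (rows) with replacement and returns the 2.5/97.5
#' percentile interval of a statistic. Reproducible under `seed`.
#'
#' @param statistic Function of a data object (data.frame or vector)
#'   returning a single number.
#' @param data Data.frame (resampled by row) or vector.
#' @param replicates Number of bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high`, `replicates_used`.
#' @export
bootstrap_ci <- function(statistic, data, replicates = 2000, seed = 1L,
                         conf = 0.95) {
  if (replicates < 100) stop("use at least 100 replicates", call. = FALSE)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE] else d[idx]
  set.seed(seed)
  stats <- vapply(seq_len(replicates), function(b) {
    statistic(take(data, sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  ok <- is.finite(stats)
  if (mean(ok) < 0.5) {
    stop("statistic undefined in more than half of the bootstrap ",
         "replicates (", sum(!ok), "/", replicates, ")", call. = FALSE)
  }
  a <- (1 - conf) / 2
  q <- stats::quantile(stats[ok], c(a, 1 - a), names = FALSE, type = 7)
  list(estimate = statistic(data), ci_low = q[1], ci_high = q[2],
       replicates_used = sum(ok))
}
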