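#' Match detected against reference R-peaks
#'
#' Greedy one-to-one matching in time order: each reference peak is matched
#' to the nearest unmatched detection within `tol_s` seconds.
#'
#' @param detected,reference Sorted integer index vectors.
#' @param fs Sampling rate in Hz.
#' @param tol_s Matching tolerance in seconds (default 0.05).
#' @return List with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`.
#' @export
#' @examples
#' match_rpeaks(c(100, 200, 300), c(101, 199, 305), fs = 1000)$f1
match_rpeaks <- function(detected, reference, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  used <- logical(length(detected))
  tp <- 0L
  for (r in reference) {
    cand <- which(!used & abs(detected - r) <= tol)
    if (length(cand) > 0) {
      best <- cand[which.min(abs(detected[cand] - r))]
      used[best] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- length(detected) - tp
  fn <- length(reference) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
       f1 = f1)
}

#' Lag-tolerant correlation coefficient
#'
#' Pearson correlation between `x` and `y` after shifting `y` by the lag
#' (within `max_lag_s`) that maximizes `|r|`; the signed correlation at that
#' lag is returned, so a polarity-inverted extraction reports a negative
#' value rather than hiding the inversion.
#'
#' @param x,y Equal-length numeric vectors.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Maximum alignment lag in seconds (default 0.05).
#' @return Correlation in \[-1, 1\], with attribute `lag` (samples).
#' @export
correlation_cc <- function(x, y, fs, max_lag_s = 0.05) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation for a constant input")
  max_lag <- round(max_lag_s * fs)
  best_r <- 0
  best_lag <- 0L
  n <- length(x)
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      xs <- x[1:(n - lag)]
      ys <- y[(1 + lag):n]
    } else {
      xs <- x[(1 - lag):n]
      ys <- y[1:(n + lag)]
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r <- stats::cor(xs, ys)
    if (abs(r) > abs(best_r)) {
      best_r <- r
      best_lag <- lag
    }
  }
  structure(best_r, lag = best_lag)
}

#' Signal-to-noise-ratio improvement against a fetal reference
#'
#' Both signals and the reference are bandpassed to `band` and least-squares
#' amplitude-normalized to the reference; the SNR of a signal is
#' `10 log10(P(ref) / P(signal - ref))` and the improvement is
#' `SNR(extracted) - SNR(raw)` in dB. Requires a known fetal reference, so
#' on real data without a direct lead this metric is not computed.
#'
#' @param raw The raw abdominal signal.
#' @param extracted The extracted fetal estimate.
#' @param fetal_ref The clean fetal reference.
#' @param fs Sampling rate in Hz.
#' @param band Analysis band in Hz (default c(10, 60)).
#' @return Improvement in dB.
#' @export
snr_improvement <- function(raw, extracted, fetal_ref, fs, band = c(10, 60)) {
  bp <- function(v) butter_bandpass_zerophase(v, fs, band[1],
                                              min(band[2], 0.45 * fs), 4)
  ref <- bp(fetal_ref)
  if (sum(ref^2) == 0) stop("zero-power reference")
  snr_of <- function(v) {
    v <- bp(v)
    # project onto the reference: the in-line component is signal, the
    # orthogonal remainder is noise; invariant to global scaling of v
    a <- sum(v * ref) / sum(ref^2)
    orth <- v - a * ref
    10 * log10(a^2 * sum(ref^2) / sum(orth^2))
  }
  snr_of(extracted) - snr_of(raw)
}

#' Selection-strategy grid report
#'
#' Runs the extraction pipeline over a grid of (n1, n2) stage-wise IMF
#' selection counts on annotated synthetic cases and aggregates the
#' correlation coefficient, fetal R-peak F1 and SNR improvement as
#' mean +/- SD per cell. The (2, 1) cell is flagged as the reference
#' configuration.
#'
#' @param cases List of annotated `aecg` records (with `fetal_clean` and
#'   `fetal_rpeaks`).
#' @param models Either one trained `imf_classifier` or a named list of
#'   models keyed by `subject_id` (e.g. the per-fold models of [loso_cv()],
#'   so each case is scored by a model that never saw it). Ignored for
#'   non-CNN `selection_mode`.
#' @param grid A list of `c(n1, n2)` pairs.
#' @param cfg Base [extraction_config()]; `n1`/`n2` are overridden per cell.
#' @param tol_s R-peak matching tolerance in seconds.
#' @return List with `summary` (one row per cell: mean/SD of CC, F1,
#'   SNR improvement) and `per_case` (every case in every cell).
#' @export
selection_grid_report <- function(cases, models = NULL,
                                  grid = list(c(1, 1), c(2, 1), c(3, 1), c(2, 2)),
                                  cfg = extraction_config(), tol_s = 0.05) {
  per_case <- list()
  for (cell in grid) {
    cc_cfg <- cfg
    cc_cfg$n1 <- as.integer(cell[1])
    cc_cfg$n2 <- as.integer(cell[2])
    for (rec in cases) {
      model <- if (inherits(models, "imf_classifier")) models
               else models[[rec$subject_id]]
      res <- extract_fecg(rec, model = model, cfg = cc_cfg)
      ref <- butter_bandpass_zerophase(rec$fetal_clean, rec$fs,
                                       cfg$refine_band[1],
                                       min(cfg$refine_band[2], 0.45 * rec$fs), 4)
      cc <- abs(as.numeric(correlation_cc(ref, res$fecg, rec$fs)))
      m <- match_rpeaks(res$fetal_rpeaks, rec$fetal_rpeaks, rec$fs, tol_s)
      snr <- snr_improvement(rec$signal, res$fecg, rec$fetal_clean, rec$fs,
                             band = cfg$refine_band)
      per_case[[length(per_case) + 1L]] <- data.frame(
        n1 = cell[1], n2 = cell[2], subject_id = rec$subject_id, cc = cc,
        f1 = m$f1, snr_imp = snr, stringsAsFactors = FALSE)
    }
  }
  per_case <- do.call(rbind, per_case)
  agg <- do.call(rbind, lapply(split(per_case, list(per_case$n1, per_case$n2),
                                     drop = TRUE), function(d) {
    data.frame(n1 = d$n1[1], n2 = d$n2[1], cc_mean = mean(d$cc),
               cc_sd = sd(d$cc), f1_mean = mean(d$f1), f1_sd = sd(d$f1),
               snr_mean = mean(d$snr_imp), snr_sd = sd(d$snr_imp))
  }))
  agg$reference <- agg$n1 == 2 & agg$n2 == 1
  agg <- agg[order(agg$n1, agg$n2), ]
  rownames(agg) <- NULL
  list(summary = agg, per_case = per_case)
}
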