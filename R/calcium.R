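# Quantification and classification of Fluo-4 calcium-flux traces from the
# 30-minute high-frequency assay.

#' Normalize a raw calcium trace to F/F0
#'
#' `F0` is the median of the first `baseline_frames` frames; normalization
#' removes acquisition gain so classification is invariant to uniform
#' intensity scaling.
#'
#' @param time_s uniform time grid, seconds.
#' @param intensity raw fluorescence (a.u.), same length.
#' @param baseline_frames frames defining `F0` (default 5).
#' @return object of class `calcium_trace` with `time_s`, `raw`, `norm`,
#'   `F0` and a `valid` flag (`FALSE` when `F0 <= 0`).
#' @export
normalize_trace <- function(time_s, intensity, baseline_frames = 5L) {
  .assert(length(time_s) == length(intensity), "time and intensity must align")
  .assert(length(time_s) >= 6, "at least 6 frames required")
  dt <- diff(time_s)
  .assert(all(abs(dt - dt[1]) < 1e-6 * max(dt[1], 1)), "time grid must be uniform")
  F0 <- median(intensity[seq_len(min(baseline_frames, length(intensity)))])
  valid <- is.finite(F0) && F0 > 0
  structure(list(time_s = time_s, raw = intensity,
                 norm = if (valid) intensity / F0 else rep(NA_real_, length(intensity)),
                 F0 = F0, valid = valid),
            class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat(sprintf("Calcium trace: %d frames over %g s, F0 = %.4g%s\n",
              length(x$time_s), max(x$time_s) - min(x$time_s), x$F0,
              if (!x$valid) " (invalid)" else ""))
  invisible(x)
}

#' @export
plot.calcium_trace <- function(x, ...) {
  plot(x$time_s, x$norm, type = "l", xlab = "time (s)", ylab = "F/F0", ...)
  abline(h = 1, lty = 3, col = "grey50")
  invisible(x)
}

# Baseline model of a normalized trace. The trace is F/F0, so quiescent
# frames sit near 1; the frame-to-frame difference gives a robust noise
# estimate that ignores slow transients. A linear fit through the baseline
# frames (divided out, floored) is a conservative photobleach correction.
.baseline_info <- function(trace) {
  y <- trace$norm; tt <- trace$time_s
  noise <- max(mad(diff(y)) / sqrt(2), 1e-6)
  base_idx <- which(y <= 1 + 3 * noise)
  if (length(base_idx) < 5)
    base_idx <- order(y)[seq_len(max(5, length(y) %/% 10))]
  fit <- lm.fit(cbind(1, tt[base_idx]), y[base_idx])
  trend <- fit$coefficients[1] + fit$coefficients[2] * tt
  trend[trend <= 0.1] <- 0.1
  yd <- y / trend
  list(y = yd, base_idx = base_idx,
       baseline = median(yd[base_idx]),
       sd_b = max(sd(yd[base_idx]), noise, 1e-6))
}

#' Detect transient calcium peaks in a normalized trace
#'
#' Physiological activation transients are rise-and-return excursions above
#' baseline; a sustained step that never returns is not a transient (it is
#' handled as a plateau by [classify_trace()]). Peaks must exceed the
#' baseline by `sd_mult` baseline standard deviations and at least
#' `min_prominence` F/F0, and the trace must return to within
#' `return_frac` of the excursion after the peak.
#'
#' @param trace a [normalize_trace()] result.
#' @param sd_mult baseline-noise multiple for the detection threshold
#'   (default 2).
#' @param min_prominence minimum peak prominence in F/F0 units (default
#'   0.2).
#' @param return_frac fraction of the excursion to which the trace must
#'   return (default 0.25).
#' @return data.frame of peaks: `onset_s`, `peak_s`, `amplitude` (F/F0 above
#'   baseline), `duration_s` (width at half prominence).
#' @export
detect_transients <- function(trace, sd_mult = 2, min_prominence = 0.2,
                              return_frac = 0.25) {
  .assert(inherits(trace, "calcium_trace"), "trace must be a calcium_trace")
  empty <- data.frame(onset_s = numeric(0), peak_s = numeric(0),
                      amplitude = numeric(0), duration_s = numeric(0))
  if (!trace$valid) return(empty)
  bi <- .baseline_info(trace)
  y <- bi$y
  tt <- trace$time_s
  baseline <- bi$baseline
  sd_b <- bi$sd_b
  thr <- baseline + max(sd_mult * sd_b, min_prominence)

  dt <- tt[2] - tt[1]
  pk <- pracma::findpeaks(y, minpeakheight = thr,
                          minpeakdistance = max(3, round(60 / dt)))
  if (is.null(pk)) return(empty)
  pk <- pk[order(pk[, 2]), , drop = FALSE]
  idxs <- pk[, 2]
  keep <- logical(nrow(pk))
  dur <- onset <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    ip <- idxs[i]
    amp <- y[ip] - baseline
    # local prominence: height above the higher of the saddles towards the
    # neighbouring candidate peaks (rejects bumps on a decaying shoulder)
    lo_edge <- if (i > 1) idxs[i - 1] else 1L
    hi_edge <- if (i < nrow(pk)) idxs[i + 1] else length(y)
    saddle <- max(min(y[lo_edge:ip]), min(y[ip:hi_edge]))
    if (y[ip] - saddle < min_prominence) next
    # rise-and-return: the trace must come back towards baseline afterwards
    after_min <- min(y[ip:length(y)])
    keep[i] <- after_min <= baseline + return_frac * amp
    half <- baseline + amp / 2
    lo <- ip; while (lo > 1 && y[lo] > half) lo <- lo - 1
    hi <- ip; while (hi < length(y) && y[hi] > half) hi <- hi + 1
    dur[i] <- tt[hi] - tt[lo]
    on <- ip; while (on > 1 && y[on] > baseline + sd_b) on <- on - 1
    onset[i] <- tt[on]
  }
  if (!any(keep)) return(empty)
  data.frame(onset_s = onset[keep], peak_s = tt[idxs[keep]],
             amplitude = y[idxs[keep]] - baseline, duration_s = dur[keep])
}

#' Classify a calcium trace as responder, non-responder or death signature
#'
#' The death signature — a prolonged, stagnant high-intensity influx from a
#' compromised effector — is called when the fraction of frames above
#' `plateau_mult` times baseline is at least `plateau_frac` of the window
#' and the trace never returns to baseline. Otherwise a trace with at least
#' one detected transient is a responder; a flat trace is a non-responder.
#'
#' @param trace a [normalize_trace()] result.
#' @param plateau_mult plateau threshold in baseline multiples (default 2).
#' @param plateau_frac minimum fraction of the window above the plateau
#'   threshold (default 0.5).
#' @param ... passed to [detect_transients()].
#' @return one-row data.frame of class `trace_classification`: `label`,
#'   `baseline`, `peak_amplitude`, `peak_time_s`, `peak_duration_s`,
#'   `plateau_fraction`, `n_transients`, `valid`.
#' @export
classify_trace <- function(trace, plateau_mult = 2, plateau_frac = 0.5, ...) {
  .assert(inherits(trace, "calcium_trace"), "trace must be a calcium_trace")
  if (!trace$valid) {
    out <- data.frame(label = "unclassified", baseline = NA_real_,
                      peak_amplitude = NA_real_, peak_time_s = NA_real_,
                      peak_duration_s = NA_real_, plateau_fraction = NA_real_,
                      n_transients = NA_integer_, valid = FALSE,
                      reason = "non-positive F0", stringsAsFactors = FALSE)
    class(out) <- c("trace_classification", "data.frame")
    return(out)
  }
  y <- trace$norm
  # guard against baseline contamination: when the influx step falls inside
  # the F0 window, re-anchor on the lowest observed frames
  low <- median(sort(trace$raw)[seq_len(min(5, length(trace$raw)))])
  if (low > 0 && trace$F0 > 2 * low) y <- trace$raw / low
  above <- y > plateau_mult
  frac <- mean(above)
  no_return <- mean(tail(y, 3)) > 1 + 0.5 * (plateau_mult - 1)
  peaks <- detect_transients(trace, ...)
  label <- if (frac >= plateau_frac && no_return) "death_signature"
  else if (nrow(peaks) >= 1) "responder"
  else "non_responder"
  main <- if (nrow(peaks)) which.max(peaks$amplitude) else NA_integer_
  out <- data.frame(label = label, baseline = .baseline_info(trace)$baseline,
                    peak_amplitude = if (nrow(peaks)) peaks$amplitude[main] else 0,
                    peak_time_s = if (nrow(peaks)) peaks$peak_s[main] else NA_real_,
                    peak_duration_s = if (nrow(peaks)) peaks$duration_s[main] else NA_real_,
                    plateau_fraction = frac, n_transients = nrow(peaks),
                    valid = TRUE, reason = "", stringsAsFactors = FALSE)
  class(out) <- c("trace_classification", "data.frame")
  out
}

#' Classify every trace of a calcium trace set
#'
#' @param traces long data.frame (`trap`, `cell`, `time_s`, `intensity`) or
#'   a `calcium_trace_set` from [generate_calcium_traces()].
#' @param ... passed to [classify_trace()].
#' @return data.frame with one classified row per (trap, cell) trace.
#' @export
classify_traces <- function(traces, ...) {
  if (inherits(traces, "calcium_trace_set")) traces <- traces$traces
  key <- interaction(traces$trap, traces$cell, drop = TRUE)
  out <- do.call(rbind, lapply(split(traces, key), function(d) {
    d <- d[order(d$time_s), ]
    tr <- normalize_trace(d$time_s, d$intensity)
    cbind(data.frame(trap = d$trap[1], cell = d$cell[1]), classify_trace(tr, ...))
  }))
  rownames(out) <- NULL
  out
}

#' Per-condition response summary of classified calcium traces
#'
#' Reports, per condition, the number of traces, the fraction per label, the
#' responder fraction among non-compromised effectors (death-signature
#' traces are excluded from both numerator and denominator, mirroring the
#' exclusion of compromised effectors), the peak-time distribution, and the
#' within-trap discordance rate (traps containing both a responder and a
#' non-responder).
#'
#' @param classified output of [classify_traces()].
#' @param condition condition label per classified trace (recycled if length
#'   1).
#' @return object of class `response_summary`.
#' @export
summarize_responses <- function(classified, condition = "all") {
  .assert(nrow(classified) >= 1, "at least one classified trace required")
  condition <- rep_len(condition, nrow(classified))
  out <- do.call(rbind, lapply(split(seq_len(nrow(classified)), condition), function(ix) {
    d <- classified[ix, , drop = FALSE]
    n <- nrow(d)
    n_resp <- sum(d$label == "responder")
    n_non <- sum(d$label == "non_responder")
    n_death <- sum(d$label == "death_signature")
    pk <- d$peak_time_s[d$label == "responder"]
    disc <- tapply(d$label, d$trap, function(l)
      any(l == "responder") && any(l == "non_responder"))
    data.frame(condition = condition[ix[1]], n = n,
               responder_frac = n_resp / n,
               non_responder_frac = n_non / n,
               death_signature_frac = n_death / n,
               responder_frac_excl_death = if (n - n_death > 0) n_resp / (n - n_death) else NA_real_,
               peak_time_median_s = if (length(pk)) median(pk) else NA_real_,
               discordant_trap_frac = mean(unlist(disc)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("response_summary", "data.frame")
  out
}
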