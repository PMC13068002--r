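# Death calling and exclusion rules on per-trap time series.

#' Call death events from tracer/PI colocalization series
#'
#' Target death is strictly defined by spatial colocalization of the blue
#' tracer and the red PI signal: the j-th target death is called at the
#' first frame where at least `j` PI-positive components overlap the tracer
#' mask (at the overlap threshold applied during [extract_traces()]). A
#' PI-positive component without tracer is an effector death. Loss of GFP
#' intensity alone never produces a death call.
#'
#' @param series a `trap_timeseries` from [extract_traces()].
#' @return data.frame of events: `population`, `frame`, `time_h` (empty when
#'   no deaths occurred).
#' @export
call_death <- function(series) {
  .assert(inherits(series, "trap_timeseries"), "series must be a trap_timeseries")
  .assert(isTRUE(series$has_pi), "PI channel missing: death calling requires PI")
  ev <- list()
  step_events <- function(n_pi, population) {
    k <- max(n_pi)
    if (k == 0) return(NULL)
    frames <- vapply(seq_len(k), function(j) which(n_pi >= j)[1], integer(1))
    data.frame(population = population, frame = frames,
               time_h = series$frames_h[frames], stringsAsFactors = FALSE)
  }
  out <- rbind(step_events(series$n_pi_tgt, "target"),
               step_events(series$n_pi_eff, "effector"))
  if (is.null(out))
    out <- data.frame(population = character(0), frame = integer(0),
                      time_h = numeric(0))
  out
}

#' Apply the trap-exclusion rules to a per-trap time series
#'
#' A trap is excluded from fixed-ratio cohort statistics when any of the
#' following holds: a population's cell count increases and the increase is
#' sustained for at least two consecutive frames (`division`); a count
#' decreases with no new PI event in the surrounding frames (`escape`); a
#' PI-positive component is present at the first frame (`preloaded_dead`);
#' or counting was ambiguous in any frame (`ambiguous_count`). Flags
#' compose; a trap is excluded iff at least one reason applies.
#'
#' @param series a `trap_timeseries`.
#' @return object of class `exclusion_flags` with `excluded` and `reasons`.
#' @export
apply_exclusions <- function(series) {
  .assert(inherits(series, "trap_timeseries"), "series must be a trap_timeseries")
  reasons <- character(0)
  Tn <- nrow(series$counts)
  for (p in 1:2) {
    cts <- series$counts[, p]
    pi_series <- if (p == 1) series$n_pi_eff else series$n_pi_tgt
    for (t in 2:Tn) {
      if (cts[t] > cts[t - 1]) {
        sustained <- t == Tn || cts[t + 1] > cts[t - 1]
        if (sustained) reasons <- union(reasons, "division")
      }
      if (cts[t] < cts[t - 1]) {
        w0 <- max(1, t - 1); w1 <- min(Tn, t + 1)
        new_death <- max(pi_series[w0:w1]) > max(pi_series[seq_len(w0 - 1)], 0)
        if (!new_death) reasons <- union(reasons, "escape")
      }
    }
  }
  if (series$has_pi && (series$n_pi_tgt[1] > 0 || series$n_pi_eff[1] > 0))
    reasons <- union(reasons, "preloaded_dead")
  if (any(series$ambiguous)) reasons <- union(reasons, "ambiguous_count")
  structure(list(excluded = length(reasons) > 0, reasons = reasons),
            class = "exclusion_flags")
}

#' @export
print.exclusion_flags <- function(x, ...) {
  if (x$excluded) cat("excluded:", paste(x$reasons, collapse = ", "), "\n")
  else cat("retained\n")
  invisible(x)
}
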