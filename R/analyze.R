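#' End-to-end quantification of a trap-array time-lapse stack
#'
#' Convenience wrapper chaining the full pipeline: straighten and crop the
#' stitched stack, fit the per-trap ROI grid, extract counts, intensity
#' traces and PI colocalization series, apply the exclusion rules, and
#' summarise per-cohort cytotoxicity.
#'
#' @param stack an `image_stack` (rendered or read from TIFF + sidecar).
#' @param design the matching [trap_design()].
#' @param overlap_threshold PI/tracer overlap threshold for death calls.
#' @param ... further arguments to [extract_traces()].
#' @return list with `result` (a `cytotox_result`), `series`, `flags`,
#'   `roi_map` and `rotation_deg`.
#' @export
analyze_stack <- function(stack, design, overlap_threshold = 0.5, ...) {
  st <- straighten_and_crop(stack)
  roi <- split_traps(st$stack, design)
  series <- extract_traces(st$stack, roi, overlap_threshold = overlap_threshold, ...)
  flags <- lapply(series, apply_exclusions)
  res <- summarize_cytotoxicity(series, flags)
  list(result = res, series = series, flags = flags, roi_map = roi,
       rotation_deg = st$rotation_deg)
}
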