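# Per-trap cell counting and intensity-trace extraction.
#
# Convention: ROI boxes are half-open 0-based column intervals [x0, x1), so
# box columns in 1-based R indexing are (x0+1):x1; the ROI spans the full
# (cropped) band height, with the top and bottom rows serving as the local
# background ring.
#
# Cells are detected as bright spots: local maxima of the smoothed,
# background-subtracted image with a minimum mutual separation, which keeps
# touching-but-distinct cells countable. Targets come from the combined
# green/blue fluorescence (the blue tracer persists after death, so dead
# targets stay countable as debris); effectors come from the
# brightfield-proxy channel after removing spots that colocalize with the
# target mask.

# background statistics from the ROI/band border ring (top/bottom rows)
.ring_stats <- function(m, ring = 2L) {
  ring <- min(ring, max(1L, floor(nrow(m) / 3)))
  px <- c(m[seq_len(ring), ], m[(nrow(m) - ring + 1L):nrow(m), ])
  c(med = median(px), mad = max(mad(px), 1e-9))
}

#' Count cells of both populations in a single-trap ROI
#'
#' Spot-based counting: cell centres are local maxima of the smoothed,
#' background-subtracted image above a noise threshold, with a minimum
#' separation of half a cell diameter. Targets are detected in the combined
#' green/blue image; effector candidates in the brightfield-proxy channel,
#' discarding spots that fall on the target (tracer) mask.
#'
#' @param roi named list of channel matrices (`green`, `blue`, `red`, `bf`)
#'   for one trap at one frame.
#' @param um_per_pixel pixel size of the ROI.
#' @param cell_diameter_um nominal cell diameter (sets the spot separation).
#' @param thr_mult detection threshold in background-noise multiples.
#' @return list of class `cell_count` with `n_eff`, `n_tgt`, spot
#'   coordinates, the target mask and an `ambiguous` flag (saturated/merged
#'   ROI).
#' @export
count_cells <- function(roi, um_per_pixel = 3, cell_diameter_um = 14,
                        thr_mult = 8) {
  .assert(all(c("green", "blue", "bf") %in% names(roi)),
          "roi must provide green, blue and bf channels")
  min_sep <- max(3, cell_diameter_um / 2 / um_per_pixel)

  tgt_img <- pmax(roi$green, roi$blue)
  bg_t <- .ring_stats(tgt_img)
  spots_t <- .find_spots(tgt_img, bg_t["med"], bg_t["mad"], thr_mult, min_sep)
  mask_t <- tgt_img - bg_t["med"] > 6 * bg_t["mad"]

  bg_e <- .ring_stats(roi$bf)
  spots_e <- .find_spots(roi$bf, bg_e["med"], bg_e["mad"], thr_mult, min_sep)
  is_eff <- .not_colocalized(spots_e, spots_t)
  fore_frac <- mean(mask_t)
  structure(list(n_eff = sum(is_eff), n_tgt = nrow(spots_t),
                 spots_tgt = spots_t,
                 spots_eff = spots_e[is_eff, , drop = FALSE],
                 target_mask = mask_t,
                 ambiguous = fore_frac > 0.5),
            class = "cell_count")
}

# TRUE for candidate spots farther than `tol` px from every reference spot;
# a brightfield spot coinciding with a fluorescence spot is the same cell
.not_colocalized <- function(cand, ref, tol = 2.9) {
  if (nrow(cand) == 0) return(logical(0))
  if (nrow(ref) == 0) return(rep(TRUE, nrow(cand)))
  vapply(seq_len(nrow(cand)), function(i) {
    all((ref[, "row"] - cand[i, "row"])^2 +
          (ref[, "col"] - cand[i, "col"])^2 > tol^2)
  }, logical(1))
}

# map 1-based pixel columns to trap indices given the 0-based ROI boundaries
.col_to_trap <- function(cols, boxes) {
  edges <- c(boxes$x0[1], boxes$x1)
  i <- findInterval(cols - 1, edges)
  i[i < 1 | i > nrow(boxes)] <- NA_integer_
  i
}

#' Extract per-trap intensity traces, counts and PI colocalization series
#'
#' The whole-band analogue of per-ROI [count_cells()], run frame by frame:
#' background-subtracted mean intensity per trap and channel (border-ring
#' background), spot-based counts of both populations, and PI-positive
#' components split by tracer colocalization (the input to death calling).
#' Death discrimination is strictly dual-fluorescence: a PI component
#' overlapping the target mask by at least `overlap_threshold` is a target
#' death, a PI component without tracer is an effector death.
#'
#' @param aligned an aligned `image_stack`.
#' @param roi_map a [split_traps()] ROI map.
#' @param overlap_threshold minimum PI-mask/tracer-mask overlap fraction for
#'   a target-death call (default 0.5).
#' @param cell_diameter_um nominal cell diameter, um.
#' @param diameter_window_um admissible equivalent-diameter window for PI
#'   components, um.
#' @param thr_mult spot-detection threshold in noise multiples.
#' @return list of `trap_timeseries` objects (one per trap), each with
#'   `counts` (frames x 2: effector, target), `intensity` (frames x
#'   channels), `n_pi_tgt`/`n_pi_eff` colocalization series, `ambiguous`
#'   flags and the t = 0 cohort assignment.
#' @export
extract_traces <- function(aligned, roi_map, overlap_threshold = 0.5,
                           cell_diameter_um = 14, diameter_window_um = c(7, 25),
                           thr_mult = 8) {
  .assert(inherits(roi_map, "trap_roi_map"), "roi_map must be a trap_roi_map")
  d <- dim(aligned$data)
  Tn <- d[1]; H <- d[3]
  chans <- aligned$channels
  has_pi <- "red" %in% chans
  upp <- aligned$um_per_pixel
  boxes <- roi_map$boxes
  N <- roi_map$n_traps
  min_sep <- max(3, cell_diameter_um / 2 / upp)
  px_area <- upp^2
  min_area <- pi * (diameter_window_um[1] / 2)^2 / px_area
  max_area <- 4 * pi * (diameter_window_um[2] / 2)^2 / px_area
  widths <- boxes$x1 - boxes$x0

  counts_eff <- counts_tgt <- matrix(0L, Tn, N)
  n_pi_tgt <- n_pi_eff <- matrix(0L, Tn, N)
  ambiguous <- matrix(FALSE, Tn, N)
  intensity <- array(0, dim = c(Tn, N, length(chans)))

  trap_sums <- function(v) {
    # per-trap sums of a per-column vector via cumulative sums
    cs <- c(0, cumsum(v))
    cs[boxes$x1 + 1L] - cs[boxes$x0 + 1L]
  }

  for (ti in seq_len(Tn)) {
    planes <- lapply(seq_along(chans), function(ci) aligned$data[ti, ci, , ])
    names(planes) <- chans
    bg <- lapply(planes, .ring_stats)
    for (ci in seq_along(chans)) {
      clipped <- pmax(planes[[ci]] - bg[[ci]]["med"], 0)
      intensity[ti, , ci] <- trap_sums(colSums(clipped)) / (H * widths)
    }

    tp <- pmax(planes$green, planes$blue)
    bg_t <- .ring_stats(tp)
    mask_t <- tp - bg_t["med"] > 6 * bg_t["mad"]
    spots_t <- .find_spots(tp, bg_t["med"], bg_t["mad"], thr_mult, min_sep)
    tr <- .col_to_trap(spots_t[, "col"], boxes)
    counts_tgt[ti, ] <- tabulate(tr[!is.na(tr)], nbins = N)

    spots_e <- .find_spots(planes$bf, bg$bf["med"], bg$bf["mad"], thr_mult, min_sep)
    if (nrow(spots_e)) {
      is_eff <- .not_colocalized(spots_e, spots_t)
      tre <- .col_to_trap(spots_e[is_eff, "col"], boxes)
      counts_eff[ti, ] <- tabulate(tre[!is.na(tre)], nbins = N)
    }

    ambiguous[ti, ] <- trap_sums(colSums(mask_t)) / (H * widths) > 0.5

    if (has_pi) {
      sub_r <- planes$red - bg$red["med"]
      if (max(sub_r) > 8 * bg$red["mad"]) {
        mask_r <- sub_r > 6 * bg$red["mad"]
        lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask_r)))))
        n_comp <- max(lab)
        if (n_comp > 0) {
          areas <- tabulate(lab[lab > 0], nbins = n_comp)
          comp_idx <- which(lab > 0, arr.ind = TRUE)
          comp_id <- lab[lab > 0]
          on_tracer <- mask_t[lab > 0]
          overlap <- vapply(seq_len(n_comp), function(i)
            sum(on_tracer[comp_id == i]) / areas[i], numeric(1))
          cen_col <- vapply(seq_len(n_comp), function(i)
            mean(comp_idx[comp_id == i, 2]), numeric(1))
          keep <- areas >= min_area & areas <= max_area
          trc <- .col_to_trap(round(cen_col), boxes)
          for (i in which(keep & !is.na(trc))) {
            if (overlap[i] >= overlap_threshold)
              n_pi_tgt[ti, trc[i]] <- n_pi_tgt[ti, trc[i]] + 1L
            else
              n_pi_eff[ti, trc[i]] <- n_pi_eff[ti, trc[i]] + 1L
          }
        }
      }
    }
  }

  lapply(seq_len(N), function(t) {
    cts <- cbind(effector = counts_eff[, t], target = counts_tgt[, t])
    intens <- intensity[, t, , drop = TRUE]
    if (is.null(dim(intens))) intens <- matrix(intens, nrow = Tn)
    colnames(intens) <- chans
    cl <- classify_cohort(cts[1, 1], cts[1, 2])
    structure(list(trap = t, frames_h = aligned$frames_h,
                   counts = cts, intensity = intens,
                   n_pi_tgt = n_pi_tgt[, t], n_pi_eff = n_pi_eff[, t],
                   ambiguous = ambiguous[, t], has_pi = has_pi,
                   cohort_ratio = cl$ratio,
                   cohort_category = as.character(cl$category)),
              class = "trap_timeseries")
  })
}

#' @export
print.trap_timeseries <- function(x, ...) {
  cat(sprintf("Trap %d (%s at t=0): %d frames; deaths (PI): %d target, %d effector\n",
              x$trap, x$cohort_ratio, nrow(x$counts),
              max(x$n_pi_tgt), max(x$n_pi_eff)))
  invisible(x)
}
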