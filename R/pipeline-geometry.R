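# Geometric pre-processing of stitched trap-array stacks: straightening the
# array band and splitting it into per-trap ROIs.

# time/channel-mean reference image of a stack
.reference_image <- function(stack) {
  apply(stack$data, c(3, 4), mean)
}

#' Straighten a stitched trap-array stack and crop to the array band
#'
#' Estimates the global rotation of the (roughly horizontal) trap-array band
#' from the principal axis of the thresholded reference image, rotates every
#' plane to axis-aligned, and crops rows to the band extent.
#'
#' @param stack an `image_stack` (see [render_timelapse()] /
#'   [read_image_stack()]).
#' @param max_rotation_deg sanity bound on the detectable tilt (default 5).
#' @return list with `stack` (aligned, row-cropped `image_stack`),
#'   `rotation_deg` (estimated tilt, degrees) and `row_range`.
#' @export
straighten_and_crop <- function(stack, max_rotation_deg = 5) {
  .assert(inherits(stack, "image_stack"), "stack must be an image_stack")
  ref <- .reference_image(stack)
  med <- median(ref); madv <- mad(ref)
  mask <- ref > med + 8 * max(madv, 1e-9)
  .assert(sum(mask) >= 20, "no detectable trap-array band in the stack")
  # tilt of the band axis: the row profile of the rotated reference image is
  # sharpest (most concentrated) when the band is horizontal
  sub <- pmax(ref - med, 0) * mask
  sharpness <- function(a) {
    r <- if (abs(a) > 1e-6)
      t(EBImage::imageData(EBImage::rotate(EBImage::Image(t(sub)), -a, bg.col = 0)))
    else sub
    sum(rowMeans(r)^2)
  }
  coarse <- seq(-max_rotation_deg, max_rotation_deg, by = 0.25)
  a0 <- coarse[which.max(vapply(coarse, sharpness, numeric(1)))]
  opt <- optimize(sharpness, c(a0 - 0.3, a0 + 0.3), maximum = TRUE, tol = 0.01)
  ang <- opt$maximum
  if (abs(ang) < 0.03) ang <- 0
  .assert(abs(ang) <= max_rotation_deg,
          sprintf("estimated rotation %.2f deg exceeds the %.1f deg bound", ang,
                  max_rotation_deg))

  d <- dim(stack$data)
  out <- stack
  if (abs(ang) > 0.1) {
    for (ti in seq_len(d[1])) for (ci in seq_len(d[2])) {
      pl <- stack$data[ti, ci, , ]
      img <- EBImage::rotate(EBImage::Image(t(pl)), -ang,
                             output.dim = c(d[4], d[3]), bg.col = med)
      out$data[ti, ci, , ] <- t(EBImage::imageData(img))
    }
  }
  ref2 <- .reference_image(out)
  rp <- rowMeans(ref2)
  bg <- median(rp)
  thr <- bg + 0.1 * (max(rp) - bg)
  band <- which(rp > thr)
  .assert(length(band) > 0, "no detectable trap-array band after rotation")
  y0 <- max(1L, min(band) - 3L)
  y1 <- min(d[3], max(band) + 3L)
  out$data <- out$data[, , y0:y1, , drop = FALSE]
  out$rotation_applied <- ang
  list(stack = out, rotation_deg = ang, row_range = c(y0, y1))
}

#' Split an aligned stack into the per-trap ROI grid
#'
#' Fits the periodic trap grid to the column-intensity profile of the
#' aligned stack: the pitch is taken from the device design (and verified
#' against the profile's autocorrelation), and the grid phase is found by
#' maximising the comb correlation of the profile with the trap centres. ROI
#' boxes are half-open, non-overlapping column intervals of one pitch,
#' ordered along the array axis.
#'
#' @param aligned an aligned `image_stack` (output of
#'   [straighten_and_crop()]).
#' @param design the matching [trap_design()].
#' @param pitch_tolerance maximum relative deviation between fitted and
#'   design pitch (default 0.10).
#' @return object of class `trap_roi_map`: data.frame of boxes (`trap`,
#'   `x0`, `x1`, `center`) plus grid metadata.
#' @export
split_traps <- function(aligned, design, pitch_tolerance = 0.10) {
  .assert(inherits(aligned, "image_stack"), "aligned must be an image_stack")
  N <- design$N
  pitch <- design$trap_pitch / aligned$um_per_pixel
  ref <- .reference_image(aligned)
  prof <- colMeans(ref)
  prof <- prof - median(prof)
  W <- length(prof)

  # verify the periodicity against the design pitch
  lag_max <- min(W - 2L, ceiling(1.5 * pitch))
  ac <- stats::acf(prof, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  lo <- max(2L, floor(0.7 * pitch)); hi <- min(lag_max, ceiling(1.3 * pitch))
  win <- lo:hi
  fitted_pitch <- win[which.max(ac[win + 1L])]
  .assert(abs(fitted_pitch - pitch) / pitch <= pitch_tolerance,
          sprintf("fitted pitch %.1f px deviates more than %.0f%% from design %.1f px",
                  fitted_pitch, 100 * pitch_tolerance, pitch))
  .assert(W + 2 >= N * pitch, "stack narrower than the designed array")

  # grid phase from the Fourier fundamental at the pitch frequency: the
  # folded (period-pitch) intensity pattern peaks at the trap centres
  sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- 0
  sm <- pmax(sm, 0)
  x <- seq_along(sm) - 1  # 0-based pixel coordinates
  z <- sum(sm * exp(-2i * pi * x / pitch))
  .assert(Mod(z) > 0, "no periodic trap signal in the profile")
  c0 <- (-Arg(z) * pitch / (2 * pi)) %% pitch  # first trap centre (0-based)

  centers <- c0 + (seq_len(N) - 1L) * pitch
  b <- round(c0 - pitch / 2 + (0:N) * pitch)
  x0 <- pmax(b[-(N + 1L)], 0L)
  x1 <- pmin(b[-1L], W)
  .assert(all(x1 > x0), "degenerate ROI boxes")
  structure(list(boxes = data.frame(trap = seq_len(N), x0 = x0, x1 = x1,
                                    center = centers),
                 pitch = pitch, fitted_pitch = fitted_pitch, phase = c0,
                 n_traps = N, width = W),
            class = "trap_roi_map")
}

#' @export
print.trap_roi_map <- function(x, ...) {
  cat(sprintf("Trap ROI map: %d boxes, pitch %.2f px (fitted %.1f), phase %.2f px\n",
              x$n_traps, x$pitch, x$fitted_pitch, x$phase))
  invisible(x)
}
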