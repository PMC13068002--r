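# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

.is_count <- function(k) {
  is.numeric(k) && all(is.finite(k)) && all(k >= 0) && all(k == floor(k))
}

# conversion between SI volumetric flow and the bench unit
# 1 m^3/s = 1e9 uL/s = 6e10 uL/min
M3S_PER_ULMIN <- 1 / 6e10

#' Convert volumetric flow between SI and microlitres per minute
#'
#' @param q flow in m^3/s (`flow_to_uL_min`) or uL/min (`uL_min_to_flow`).
#' @return the converted flow.
#' @export
flow_to_uL_min <- function(q) q * 6e10

#' @rdname flow_to_uL_min
#' @export
uL_min_to_flow <- function(q) q * M3S_PER_ULMIN

# Otsu threshold on a numeric vector (256-bin histogram between finite range).
# Returns a value separating background and foreground; used with an explicit
# floor by the counting code so pure-noise ROIs do not produce spurious masks.
.otsu <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) <= 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = levels + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

# deterministic per-replicate seed streams below 2^31
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# 3x3 box blur with replicated edges (enough smoothing for blob-scale maxima)
.box_blur3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  p[1, ] <- p[2, ]; p[H + 2, ] <- p[H + 1, ]
  p[, 1] <- p[, 2]; p[, W + 2] <- p[, W + 1]
  (p[1:H, 1:W] + p[1:H, 2:(W + 1)] + p[1:H, 3:(W + 2)] +
     p[2:(H + 1), 1:W] + p[2:(H + 1), 2:(W + 1)] + p[2:(H + 1), 3:(W + 2)] +
     p[3:(H + 2), 1:W] + p[3:(H + 2), 2:(W + 1)] + p[3:(H + 2), 3:(W + 2)]) / 9
}

# detect bright spots (cell centres) as local maxima of the smoothed,
# background-subtracted image, with greedy minimum-separation suppression.
# Returns a matrix with columns row, col, value.
.find_spots <- function(m, bg_med, bg_mad, thr_mult = 8, min_sep = 4) {
  empty <- cbind(row = numeric(0), col = numeric(0), value = numeric(0))
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(empty)
  sm <- .box_blur3(m - bg_med)
  thr <- thr_mult * max(bg_mad, 1e-9)
  c0 <- sm[2:(H - 1), 2:(W - 1)]
  is_max <- c0 > thr &
    c0 >= sm[1:(H - 2), 2:(W - 1)] & c0 >= sm[3:H, 2:(W - 1)] &
    c0 >= sm[2:(H - 1), 1:(W - 2)] & c0 >= sm[2:(H - 1), 3:W] &
    c0 >= sm[1:(H - 2), 1:(W - 2)] & c0 >= sm[1:(H - 2), 3:W] &
    c0 >= sm[3:H, 1:(W - 2)] & c0 >= sm[3:H, 3:W]
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty)
  rows <- idx[, 1] + 1; cols <- idx[, 2] + 1
  vals <- sm[cbind(rows, cols)]
  o <- order(-vals)
  keep <- logical(length(o))
  kr <- kc <- numeric(0)
  for (i in o) {
    if (length(kr) == 0 ||
        all((kr - rows[i])^2 + (kc - cols[i])^2 >= min_sep^2)) {
      keep[i] <- TRUE
      kr <- c(kr, rows[i]); kc <- c(kc, cols[i])
    }
  }
  cbind(row = rows[keep], col = cols[keep], value = vals[keep])
}
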