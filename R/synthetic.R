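#' Scenario configuration for the synthetic trap-array generator
#'
#' Defines the ground-truthed synthetic experiment the generator emulates: a
#' two-population co-culture (population 1 = unlabeled effector, population 2
#' = target carrying a stable GFP plus a stable blue tracer) imaged every
#' `frame_interval_h` hours for `duration_h` hours, with propidium iodide
#' (PI) in the medium so any dead cell acquires a step-like red signal.
#' Target death is contact-dependent (only traps holding at least one
#' effector and one target draw from `death_prob`); single-population control
#' traps experience only the spontaneous baseline rates. Dead targets remain
#' in place as debris (dim green, persistent blue, strong red) because the
#' filter constrictions retain lysed material.
#'
#' @param design a [trap_design()]; the rendered stack has one ROI per trap.
#' @param occupancy occupancy source: a [loading_rate()] (per-trap Poisson
#'   draws), an [occupancy_table()] (tallies shuffled over traps), a
#'   [simulate_loading()] result, or a two-column matrix of per-trap
#'   `(k1, k2)`.
#' @param death_prob named probabilities of target death over the window,
#'   keyed by ratio string (`"1:1"`, `"1:2"`, `"2:1"`, ...) with a
#'   `"multiplet"` fallback for unlisted co-culture ratios. Defaults are the
#'   U87/NK dose-response values (1:1 = 0.215, 1:2 = 0.126, 2:1 = 0.267).
#' @param spontaneous_death baseline death probabilities
#'   `c(effector = , target = )` applied in control traps (defaults 0.01 and
#'   0.044).
#' @param death_time_dist named probability weights over hours on the frame
#'   grid; defaults weight 4-12 h.
#' @param division_rate,escape_rate per-cell probabilities of a division or
#'   an escape event during the window.
#' @param gfp_decay_halflife hours; post-death exponential decay of the
#'   target GFP signal.
#' @param photobleach_rate per-frame fractional loss of fluorescence.
#' @param noise_mean,noise_sd background level and noise per channel
#'   (16-bit-style arbitrary units).
#' @param amplitude peak cell intensity above background.
#' @param um_per_pixel spatial sampling of the rendered stack.
#' @param frame_interval_h,duration_h long-term imaging grid (default every
#'   2 h for 14 h).
#' @param ca_interval_s,ca_duration_min calcium imaging grid (default every
#'   10 s for 30 min).
#' @param ca_noise_sd,ca_bleach_frac calcium-trace noise (raw units) and
#'   total linear bleach fraction over the 30-min window.
#' @param rotation_deg global rotation applied to the rendered stack (to
#'   exercise the straightening step).
#' @param image_height_px height of the rendered band in pixels.
#' @param pixel_budget refuse to render scenes larger than this many pixels
#'   per plane.
#' @param cell_diameter_um rendered cell diameter (Gaussian blob FWHM).
#' @param seed integer seed; the generator is bit-deterministic given the
#'   configuration.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(design = trap_design(S = 8L),
                            occupancy = loading_rate(0.58, 0.83),
                            death_prob = c("1:1" = 0.215, "1:2" = 0.126,
                                           "2:1" = 0.267, "multiplet" = 0.215),
                            spontaneous_death = c(effector = 0.01, target = 0.044),
                            death_time_dist = c("2" = 0.05, "4" = 0.20, "6" = 0.175,
                                                "8" = 0.20, "10" = 0.175, "12" = 0.15,
                                                "14" = 0.05),
                            division_rate = 0.02, escape_rate = 0.02,
                            gfp_decay_halflife = 2, photobleach_rate = 0,
                            noise_mean = 100, noise_sd = 5, amplitude = 600,
                            um_per_pixel = 3, frame_interval_h = 2, duration_h = 14,
                            ca_interval_s = 10, ca_duration_min = 30,
                            ca_noise_sd = 3, ca_bleach_frac = 0.05,
                            rotation_deg = 0, image_height_px = 30L,
                            pixel_budget = 5e7, cell_diameter_um = 14,
                            seed = 1L) {
  probs <- c(death_prob, spontaneous_death, division_rate, escape_rate,
             photobleach_rate)
  .assert(all(probs >= 0 & probs <= 1), "all probabilities must lie in [0,1]")
  .assert(frame_interval_h > 0 && duration_h > 0 && ca_interval_s > 0 &&
            ca_duration_min > 0, "intervals and durations must be positive")
  .assert(all(names(death_time_dist) %in%
                as.character(seq(0, duration_h, by = frame_interval_h))),
          "death times must lie on the frame grid")
  structure(list(design = design, occupancy = occupancy, death_prob = death_prob,
                 spontaneous_death = spontaneous_death,
                 death_time_dist = death_time_dist / sum(death_time_dist),
                 division_rate = division_rate, escape_rate = escape_rate,
                 gfp_decay_halflife = gfp_decay_halflife,
                 photobleach_rate = photobleach_rate,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 amplitude = amplitude, um_per_pixel = um_per_pixel,
                 frame_interval_h = frame_interval_h, duration_h = duration_h,
                 ca_interval_s = ca_interval_s, ca_duration_min = ca_duration_min,
                 ca_noise_sd = ca_noise_sd, ca_bleach_frac = ca_bleach_frac,
                 rotation_deg = rotation_deg,
                 image_height_px = as.integer(image_height_px),
                 pixel_budget = pixel_budget,
                 cell_diameter_um = cell_diameter_um, seed = as.integer(seed)),
            class = "scenario_config")
}

# trap-local cell slots (um relative to trap centre); chosen so any two
# occupied slots are >= ~17 um apart and blobs stay inside the ROI
.CELL_SLOTS <- matrix(c(-12, -12,  12,  12,  12, -12, -12,  12,
                         0,   0,   0, -18,  0,  18, -15, 0),
                      ncol = 2, byrow = TRUE)

.resolve_occupancy <- function(occupancy, N) {
  if (inherits(occupancy, "loading_rate")) {
    k1 <- pmin(rpois(N, occupancy$lambda1), 3L)
    k2 <- pmin(rpois(N, occupancy$lambda2), 3L)
    return(cbind(k1 = k1, k2 = k2))
  }
  if (inherits(occupancy, "sim_result")) {
    .assert(nrow(occupancy$per_trap) == N, "simulation trap count mismatch")
    return(occupancy$per_trap)
  }
  if (inherits(occupancy, "occupancy_table")) {
    d <- as.data.frame(occupancy)
    d <- d[d$count > 0, , drop = FALSE]
    k1 <- rep(d$k1, d$count); k2 <- rep(d$k2, d$count)
    .assert(length(k1) == N, "occupancy table trap count mismatch")
    ord <- sample.int(N)
    return(cbind(k1 = k1[ord], k2 = k2[ord]))
  }
  occ <- as.matrix(occupancy)
  .assert(nrow(occ) == N && ncol(occ) == 2, "per-trap occupancy must be N x 2")
  colnames(occ) <- c("k1", "k2")
  occ
}

#' Generate the ground-truth event table for a synthetic experiment
#'
#' Draws per-trap occupancies, assigns trap-local cell positions, and draws
#' death, division and escape events per cell. Contact-dependent target
#' deaths occur only in traps holding both populations; control traps see
#' only the spontaneous baselines; dead cells never divide or escape; every
#' event time lies on the imaging frame grid.
#'
#' @param scenario a [scenario_config()].
#' @return object of class `ground_truth` with `cells` (one row per cell:
#'   trap, population, position, event times), `traps` (per-trap occupancy
#'   and cohort) and the frame grid.
#' @export
generate_ground_truth <- function(scenario) {
  .assert(inherits(scenario, "scenario_config"), "scenario must be a scenario_config")
  set.seed(scenario$seed)
  N <- scenario$design$N
  occ <- .resolve_occupancy(scenario$occupancy, N)
  frames_h <- seq(0, scenario$duration_h, by = scenario$frame_interval_h)
  cl <- classify_cohort(occ[, 1], occ[, 2])
  traps <- data.frame(trap = seq_len(N), k1 = occ[, 1], k2 = occ[, 2],
                      ratio = cl$ratio, category = as.character(cl$category),
                      stringsAsFactors = FALSE)

  death_times <- as.numeric(names(scenario$death_time_dist))
  draw_death_time <- function(n) {
    if (n == 0) return(numeric(0))
    death_times[sample.int(length(death_times), n, replace = TRUE,
                           prob = scenario$death_time_dist)]
  }
  # event-eligible interior grid for divisions/escapes
  mid_grid <- frames_h[frames_h > 0 & frames_h < scenario$duration_h]
  if (length(mid_grid) == 0) mid_grid <- frames_h[length(frames_h)]

  warned <- FALSE
  rows <- vector("list", N)
  for (t in seq_len(N)) {
    k1 <- occ[t, 1]; k2 <- occ[t, 2]
    n_cells <- k1 + k2
    if (n_cells == 0) next
    pop <- c(rep("effector", k1), rep("target", k2))
    slots <- .CELL_SLOTS[seq_len(min(n_cells, nrow(.CELL_SLOTS))), , drop = FALSE]
    if (n_cells > nrow(.CELL_SLOTS))
      slots <- rbind(slots, matrix(0, n_cells - nrow(.CELL_SLOTS), 2))
    jitter <- matrix(runif(2 * n_cells, -1, 1), ncol = 2)
    pos <- slots + jitter

    coculture <- k1 >= 1 && k2 >= 1
    p_tgt <- if (coculture) {
      ratio <- paste0(k1, ":", k2)
      if (!is.na(scenario$death_prob[ratio])) unname(scenario$death_prob[ratio])
      else if (!is.na(scenario$death_prob["multiplet"])) unname(scenario$death_prob["multiplet"])
      else {
        if (!warned) {
          warning("co-culture cohort ", ratio,
                  " missing from death_prob; treated as 0", call. = FALSE)
          warned <- TRUE
        }
        0
      }
    } else unname(scenario$spontaneous_death["target"])
    p_eff <- unname(scenario$spontaneous_death["effector"])

    dies <- ifelse(pop == "target", runif(n_cells) < p_tgt, runif(n_cells) < p_eff)
    death_h <- rep(NA_real_, n_cells)
    death_h[dies] <- draw_death_time(sum(dies))

    divides <- !dies & runif(n_cells) < scenario$division_rate
    division_h <- rep(NA_real_, n_cells)
    division_h[divides] <- sample(mid_grid, sum(divides), replace = TRUE)

    escapes <- !dies & !divides & runif(n_cells) < scenario$escape_rate
    escape_h <- rep(NA_real_, n_cells)
    escape_h[escapes] <- sample(mid_grid, sum(escapes), replace = TRUE)

    rows[[t]] <- data.frame(trap = t, cell = seq_len(n_cells), population = pop,
                            x_um = pos[, 1], y_um = pos[, 2],
                            death_h = death_h, division_h = division_h,
                            escape_h = escape_h, stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, rows)
  if (is.null(cells))
    cells <- data.frame(trap = integer(0), cell = integer(0),
                        population = character(0), x_um = numeric(0),
                        y_um = numeric(0), death_h = numeric(0),
                        division_h = numeric(0), escape_h = numeric(0))
  rownames(cells) <- NULL
  structure(list(cells = cells, traps = traps, frames_h = frames_h,
                 channels = c(green = "GFP", blue = "tracer", red = "PI",
                              bf = "brightfield_proxy"),
                 seed = scenario$seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d traps, %d cells, %d frames (%g h)\n",
              nrow(x$traps), nrow(x$cells), length(x$frames_h), max(x$frames_h)))
  cat(sprintf("  deaths: %d target, %d effector; divisions: %d; escapes: %d\n",
              sum(!is.na(x$cells$death_h) & x$cells$population == "target"),
              sum(!is.na(x$cells$death_h) & x$cells$population == "effector"),
              sum(!is.na(x$cells$division_h)), sum(!is.na(x$cells$escape_h))))
  invisible(x)
}

# add a Gaussian blob of peak `amp` and sd `sigma` px at (cx, cy) into `img`
.add_blob <- function(img, cx, cy, sigma, amp) {
  r <- ceiling(3 * sigma)
  x0 <- max(1L, floor(cx - r)); x1 <- min(ncol(img), ceiling(cx + r))
  y0 <- max(1L, floor(cy - r)); y1 <- min(nrow(img), ceiling(cy + r))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  g <- outer(exp(-(ys - cy)^2 / (2 * sigma^2)),
             exp(-(xs - cx)^2 / (2 * sigma^2)))
  img[ys, xs] <- img[ys, xs] + amp * g
  img
}

#' Render a multi-channel time-lapse image stack from ground truth
#'
#' Cells are rendered as Gaussian blobs on the 1-D trap-array band. Targets
#' carry green (GFP) and blue (tracer); effectors appear only in the
#' brightfield-proxy channel (all cells appear there). Target death adds a
#' step-like red PI blob at the death frame while the blue tracer persists
#' and the green decays exponentially; effector death adds red without blue.
#' Escaping cells shift half out of the band for one frame and then vanish;
#' divisions spawn an adjacent equal-intensity blob. An optional global
#' rotation emulates a tilted stitched acquisition.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param scenario the matching [scenario_config()].
#' @return object of class `image_stack`: `data` is a numeric array indexed
#'   `[frame, channel, row, column]`, plus the channel map, pixel size, frame
#'   grid and ROI grid metadata (pitch and trap centres before rotation).
#' @export
render_timelapse <- function(truth, scenario) {
  .assert(inherits(truth, "ground_truth"), "truth must be a ground_truth")
  des <- scenario$design
  upp <- scenario$um_per_pixel
  pitch_px <- des$trap_pitch / upp
  W <- as.integer(round(des$N * pitch_px))
  H <- scenario$image_height_px
  frames <- truth$frames_h
  Tn <- length(frames)
  chans <- c("green", "blue", "red", "bf")
  .assert(as.numeric(H) * W <= scenario$pixel_budget,
          "scene exceeds the configured pixel budget")

  set.seed(.derive_seeds(scenario$seed, 2L)[2L])
  sigma <- scenario$cell_diameter_um / 2.355 / upp
  A <- scenario$amplitude
  cy0 <- (H + 1) / 2
  centers_px <- (seq_len(des$N) - 0.5) * pitch_px
  cells <- truth$cells
  cx_px <- centers_px[cells$trap] + cells$x_um / upp
  cy_px <- cy0 + cells$y_um / upp

  # daughter-blob placement for dividing cells: pick, deterministically, the
  # candidate offset farthest from every other cell in the trap
  daughter_px <- matrix(NA_real_, nrow(cells), 2)
  cand <- matrix(c(18, 0, -18, 0, 0, 14, 0, -14, 13, 13, -13, 13,
                   13, -13, -13, -13), ncol = 2, byrow = TRUE)
  for (i in which(!is.na(cells$division_h))) {
    same <- which(cells$trap == cells$trap[i])
    best <- NULL; best_d <- -Inf
    for (k in seq_len(nrow(cand))) {
      px <- cells$x_um[i] + cand[k, 1]; py <- cells$y_um[i] + cand[k, 2]
      if (abs(px) > 20 || abs(py) > 20) next
      dmin <- min(sqrt((cells$x_um[same] - px)^2 + (cells$y_um[same] - py)^2))
      if (dmin > best_d) { best_d <- dmin; best <- c(px, py) }
    }
    if (is.null(best)) best <- c(cells$x_um[i] + 18, cells$y_um[i])
    daughter_px[i, ] <- c(centers_px[cells$trap[i]] + best[1] / upp,
                          cy0 + best[2] / upp)
  }

  rot <- scenario$rotation_deg
  # final canvas after optional rotation (EBImage enlarges to fit)
  if (abs(rot) > 1e-9) {
    th <- abs(rot) * pi / 180
    H_out <- ceiling(W * sin(th) + H * cos(th))
    W_out <- ceiling(W * cos(th) + H * sin(th))
  } else { H_out <- H; W_out <- W }

  data <- array(0, dim = c(Tn, length(chans), H_out, W_out))
  bleach <- (1 - scenario$photobleach_rate)^(seq_len(Tn) - 1L)

  for (ti in seq_len(Tn)) {
    t_h <- frames[ti]
    planes <- lapply(chans, function(ch) matrix(0, H, W))
    names(planes) <- chans
    for (i in seq_len(nrow(cells))) {
      esc <- cells$escape_h[i]
      gone <- !is.na(esc) && t_h > esc
      if (gone) next
      leaving <- !is.na(esc) && t_h == esc
      cy_i <- if (leaving) cy_px[i] + (H / 2) else cy_px[i]
      cx_i <- cx_px[i]
      dead <- !is.na(cells$death_h[i]) && t_h >= cells$death_h[i]
      is_target <- cells$population[i] == "target"
      if (is_target) {
        gfp <- A * bleach[ti]
        if (dead) gfp <- gfp * 2^(-(t_h - cells$death_h[i]) / scenario$gfp_decay_halflife)
        planes$green <- .add_blob(planes$green, cx_i, cy_i, sigma, gfp)
        planes$blue <- .add_blob(planes$blue, cx_i, cy_i, sigma, A * bleach[ti])
      }
      if (dead) planes$red <- .add_blob(planes$red, cx_i, cy_i, sigma, A)
      planes$bf <- .add_blob(planes$bf, cx_i, cy_i, sigma, 0.7 * A)
      div <- cells$division_h[i]
      if (!is.na(div) && t_h >= div) {
        dgt <- daughter_px[i, ]
        if (is_target) {
          planes$green <- .add_blob(planes$green, dgt[1], dgt[2], sigma, A * bleach[ti])
          planes$blue <- .add_blob(planes$blue, dgt[1], dgt[2], sigma, A * bleach[ti])
        }
        planes$bf <- .add_blob(planes$bf, dgt[1], dgt[2], sigma, 0.7 * A)
      }
    }
    for (ci in seq_along(chans)) {
      pl <- planes[[ci]]
      if (abs(rot) > 1e-9) {
        pl <- EBImage::imageData(EBImage::rotate(EBImage::Image(t(pl)), rot,
                                                 bg.col = 0))
        pl <- t(pl)
        # pad/trim to the common canvas
        ph <- nrow(pl); pw <- ncol(pl)
        out <- matrix(0, H_out, W_out)
        out[seq_len(min(H_out, ph)), seq_len(min(W_out, pw))] <-
          pl[seq_len(min(H_out, ph)), seq_len(min(W_out, pw))]
        pl <- out
      }
      noise_sd <- if (chans[ci] == "bf") 2 * scenario$noise_sd else scenario$noise_sd
      pl <- pl + matrix(rnorm(H_out * W_out, scenario$noise_mean, noise_sd), H_out, W_out)
      data[ti, ci, , ] <- pmax(pl, 0)
    }
  }
  structure(list(data = data, channels = chans, um_per_pixel = upp,
                 frames_h = frames, pitch_px = pitch_px,
                 trap_centers_px = centers_px, n_traps = des$N,
                 rotation_deg = rot, noise_mean = scenario$noise_mean,
                 noise_sd = scenario$noise_sd, seed = scenario$seed),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack: %d frames x %d channels x %d x %d px (%g um/px), %d traps\n",
              d[1], d[2], d[3], d[4], x$um_per_pixel, x$n_traps))
  cat("  channels:", paste(x$channels, collapse = ", "),
      sprintf("; rotation %g deg\n", x$rotation_deg))
  invisible(x)
}

#' Generate labelled synthetic calcium traces
#'
#' Emulates the 30-minute high-frequency Fluo-4 assay with three trace
#' archetypes: `responder` (1-3 gamma-shaped transient pulses on baseline
#' noise, the physiological activation flux), `non_responder` (flat baseline,
#' as in effector-only controls), and `death_signature` (an early step to a
#' sustained high plateau, the compromised-effector signature). A linear
#' photobleaching trend can be superimposed.
#'
#' @param scenario a [scenario_config()] (supplies grid, noise, bleach and
#'   seed).
#' @param n named counts per archetype.
#' @param baseline raw baseline fluorescence level.
#' @param pulse_amplitude range of responder pulse amplitudes, in multiples
#'   of baseline (drawn uniformly); a zero amplitude degenerates to a
#'   non-responder trace.
#' @param plateau_level range of death-plateau levels, in multiples of
#'   baseline.
#' @return object of class `calcium_trace_set`: `traces` (long data.frame
#'   trap, cell, time_s, intensity) and `labels` (per-trace ground truth with
#'   pulse times).
#' @export
generate_calcium_traces <- function(scenario,
                                    n = c(responder = 100, non_responder = 100,
                                          death_signature = 100),
                                    baseline = 100,
                                    pulse_amplitude = c(1.0, 2.0),
                                    plateau_level = c(2.5, 3.5)) {
  .assert(inherits(scenario, "scenario_config"), "scenario must be a scenario_config")
  set.seed(.derive_seeds(scenario$seed, 3L)[3L])
  tt <- seq(0, scenario$ca_duration_min * 60, by = scenario$ca_interval_s)
  n_frames <- length(tt)
  labels <- rep(names(n), n)
  n_tot <- length(labels)
  labels <- sample(labels)
  bleach <- 1 - scenario$ca_bleach_frac * tt / max(tt)

  traces <- vector("list", n_tot)
  meta <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    f <- rep(1, n_frames)
    first_peak <- NA_real_
    amp_used <- NA_real_
    if (labels[i] == "responder") {
      n_p <- sample(1:3, 1)
      onsets <- sort(runif(n_p, 60, 1200))
      amp_used <- runif(1, pulse_amplitude[1], pulse_amplitude[2])
      tau <- runif(1, 60, 120)
      for (t0 in onsets) {
        u <- (tt - t0) / tau
        pulse <- ifelse(u > 0, u * exp(1 - u), 0)  # gamma-shaped, peak 1 at u = 1
        f <- f + amp_used * pulse
      }
      first_peak <- onsets[1] + tau
    } else if (labels[i] == "death_signature") {
      t0 <- runif(1, 60, 300)
      lev <- runif(1, plateau_level[1], plateau_level[2])
      f <- f + (lev - 1) / (1 + exp(-(tt - t0) / 15))  # ~30 s logistic rise
      amp_used <- lev
      first_peak <- t0
    }
    raw <- baseline * f * bleach + rnorm(n_frames, 0, scenario$ca_noise_sd)
    traces[[i]] <- data.frame(trap = i, cell = 1L, time_s = tt, intensity = raw)
    meta[[i]] <- data.frame(trap = i, cell = 1L, label = labels[i],
                            amplitude = amp_used, first_event_s = first_peak,
                            stringsAsFactors = FALSE)
  }
  structure(list(traces = do.call(rbind, traces),
                 labels = do.call(rbind, meta),
                 interval_s = scenario$ca_interval_s,
                 baseline = baseline, seed = scenario$seed),
            class = "calcium_trace_set")
}

#' @export
print.calcium_trace_set <- function(x, ...) {
  cat(sprintf("Calcium trace set: %d traces, %d frames each (every %g s)\n",
              nrow(x$labels), length(unique(x$traces$time_s)), x$interval_s))
  print(table(x$labels$label))
  invisible(x)
}
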