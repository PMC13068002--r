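#' Geometry and topology of an S-stage bifurcated trap-array device
#'
#' The device splits an inlet channel into two at each of `S` bifurcation
#' stages; after the last stage each of the `2^S` channels opens into four
#' sub-channels terminating at cell traps, so the trap count is
#' `N = 4 * 2^S`. Each trap ends in 2-3 narrow filter channels whose cross
#' section is smaller than a cell diameter, so cells are retained while
#' medium passes.
#'
#' All dimensions are given in micrometres at the interface and converted to
#' SI internally. `H_c` is the nominal (mask) channel height; fabricated
#' devices are typically a few micrometres shallower, so a separate
#' `H_c_measured` is used for resistance estimates.
#'
#' @param S number of bifurcation stages (integer >= 0).
#' @param W_c,H_c main-channel width/height, um (defaults 30, 40).
#' @param H_c_measured as-fabricated channel height used in resistance
#'   calculations, um (default 35).
#' @param W_f,H_f filter-channel width/height, um (defaults 2, 4); must be
#'   smaller than the channel dimensions.
#' @param filters_per_trap 2 or 3 parallel filter channels per trap.
#' @param filter_length_um streamwise length of a filter constriction, um.
#' @param trap_pitch trap centre-to-centre spacing, um (default 60 = 30 um
#'   trap + 30 um gap).
#' @param array_span_mm length of the 1-D trap array, mm (default 61.44).
#' @param viscosity dynamic viscosity of the medium, Pa s.
#' @param density medium density, kg/m^3.
#' @param cell_diameter_um nominal diameter of the loaded cells, um.
#' @return object of class `trap_design`.
#' @examples
#' d <- trap_design(S = 8)
#' d$N  # 1024
#' @export
trap_design <- function(S = 8L, W_c = 30, H_c = 40, H_c_measured = 35,
                        W_f = 2, H_f = 4, filters_per_trap = 2L,
                        filter_length_um = 10, trap_pitch = 60,
                        array_span_mm = 61.44, viscosity = 1e-3,
                        density = 998, cell_diameter_um = 14) {
  .assert(.is_count(S), "S must be a non-negative integer")
  .assert(H_f < H_c && W_f < W_c, "filter cross-section must be smaller than the channel")
  .assert(filters_per_trap %in% c(2L, 3L), "filters_per_trap must be 2 or 3")
  N <- as.integer(4 * 2^S)
  structure(list(S = as.integer(S), N = N,
                 W_c = W_c, H_c = H_c, H_c_measured = H_c_measured,
                 W_f = W_f, H_f = H_f,
                 filters_per_trap = as.integer(filters_per_trap),
                 filter_length_um = filter_length_um,
                 trap_pitch = trap_pitch, array_span_mm = array_span_mm,
                 viscosity = viscosity, density = density,
                 cell_diameter_um = cell_diameter_um),
            class = "trap_design")
}

#' @export
print.trap_design <- function(x, ...) {
  cat(sprintf("Bifurcated trap-array design: S = %d stages, N = 4 x 2^%d = %d traps\n",
              x$S, x$S, x$N))
  cat(sprintf("  channel %g x %g um (measured height %g um), filter %g x %g um x%d\n",
              x$W_c, x$H_c, x$H_c_measured, x$W_f, x$H_f, x$filters_per_trap))
  cat(sprintf("  pitch %g um over %g mm span\n", x$trap_pitch, x$array_span_mm))
  invisible(x)
}

#' Hydrostatic inlet pressure P = rho * g * h
#'
#' Pressure at the device inlet from a liquid column of height `h` (e.g. a
#' filled pipette tip). With `density = 998` kg/m^3 and `column_height = 0.10`
#' m the standard gravity value gives 979 Pa; `gravity = 10` reproduces the
#' commonly quoted round figure of 998 Pa.
#'
#' @param density liquid density, kg/m^3.
#' @param gravity gravitational acceleration, m/s^2 (default 9.80665).
#' @param column_height liquid column height, m.
#' @return pressure in Pa.
#' @export
hydrostatic_pressure <- function(density = 998, gravity = 9.80665, column_height = 0.10) {
  .assert(density >= 0 && gravity >= 0 && column_height >= 0,
          "density, gravity and column height must be non-negative")
  density * gravity * column_height
}

#' Total device flow from the lumped Hagen-Poiseuille relation Q = P / R
#'
#' @param pressure driving pressure, Pa.
#' @param resistance aggregate hydraulic resistance, Pa s m^-3 (must be > 0).
#' @return total volumetric flow in m^3/s; convert with [flow_to_uL_min()].
#' @export
total_flow <- function(pressure, resistance) {
  .assert(is.numeric(resistance) && all(resistance > 0), "resistance must be > 0")
  pressure / resistance
}

#' Flow in one last-stage channel of the bifurcation tree
#'
#' The symmetric tree splits the total flow equally over the `2^S` channels
#' after the final bifurcation (each feeding four traps).
#'
#' @param total total device flow (any unit; the split is unit-preserving).
#' @param design a [trap_design()].
#' @return per-channel flow, `total / 2^S`.
#' @export
branch_flow <- function(total, design) {
  .assert(all(total >= 0), "total flow must be non-negative")
  total / 2^design$S
}

#' Hydraulic resistance of a rectangular channel segment
#'
#' Series approximation for fully developed laminar flow in a rectangular
#' duct: `R = 12 mu L / (w h^3 (1 - 0.63 h/w))` with the orientation
#' convention `h <= w` (arguments are swapped internally if needed). In the
#' wide-channel limit `h << w` this reduces to the parallel-plate result
#' `12 mu L / (w h^3)`.
#'
#' @param length segment length, m.
#' @param width,height cross-section dimensions, m.
#' @param viscosity dynamic viscosity, Pa s.
#' @return resistance in Pa s m^-3.
#' @export
segment_resistance <- function(length, width, height, viscosity = 1e-3) {
  .assert(all(length > 0) && all(width > 0) && all(height > 0) && all(viscosity > 0),
          "all dimensions and viscosity must be positive")
  h <- pmin(width, height)
  w <- pmax(width, height)
  12 * viscosity * length / (w * h^3 * (1 - 0.63 * h / w))
}

#' Wall shear stress estimate in a rectangular channel
#'
#' Parallel-plate estimate of the wall shear magnitude for volumetric flow
#' `Q`: `tau = 6 mu Q / (w h^2)` with `h <= w`.
#'
#' @param flow volumetric flow, m^3/s.
#' @param width,height channel cross-section, m.
#' @param viscosity dynamic viscosity, Pa s.
#' @return shear stress in Pa.
#' @export
wall_shear <- function(flow, width, height, viscosity = 1e-3) {
  .assert(all(width > 0) && all(height > 0), "dimensions must be positive")
  h <- pmin(width, height)
  w <- pmax(width, height)
  6 * viscosity * flow / (w * h^2)
}

#' Time to load a sample volume at a given flow rate
#'
#' @param sample_volume sample volume, uL.
#' @param total_flow flow rate, uL/min (must be > 0).
#' @return loading time in minutes.
#' @export
loading_time <- function(sample_volume, total_flow) {
  .assert(all(total_flow > 0), "flow must be > 0")
  .assert(all(sample_volume >= 0), "volume must be non-negative")
  sample_volume / total_flow
}
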