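#' Lumped hydraulic-resistance network of a bifurcated trap array
#'
#' Builds the series-parallel resistance network of a [trap_design()]: an
#' inlet segment, `S` generations of bifurcating channel segments whose
#' lengths halve per stage (distributing the array span), `2^S` last-stage
#' channels each feeding four trap sub-channels, and a terminal filter edge
#' per trap (2-3 filter channels in parallel). Because per-segment lengths of
#' a fabricated device are not part of the published geometry, the network is
#' calibrated by one global scale factor so that the empty-device aggregate
#' resistance equals `R_total` (default the bench-measured 1.48e13
#' Pa s m^-3).
#'
#' Trap occupancy is modelled as a multiplicative resistance penalty on the
#' trap's filter edge, `occupancy_multiplier^cells`; a captured cell blocks
#' most of the filter cross-section, so the default penalty is 10x per cell.
#'
#' @param design a [trap_design()].
#' @param R_total empty-device aggregate resistance to calibrate to,
#'   Pa s m^-3.
#' @param occupancy_multiplier default per-cell resistance penalty (>= 1).
#' @return object of class `hydraulic_network`.
#' @export
build_network <- function(design, R_total = 1.48e13, occupancy_multiplier = 10) {
  .assert(inherits(design, "trap_design"), "design must be a trap_design")
  .assert(R_total > 0, "R_total must be positive")
  .assert(occupancy_multiplier >= 1, "occupancy multiplier must be >= 1")
  S <- design$S
  mu <- design$viscosity
  span_m <- design$array_span_mm * 1e-3
  wc <- design$W_c * 1e-6
  hc <- design$H_c_measured * 1e-6
  # feeding-tree segment lengths halve per bifurcation stage
  L_inlet <- span_m / 2
  r_inlet <- segment_resistance(L_inlet, wc, hc, mu)
  r_stage <- if (S > 0) {
    vapply(seq_len(S), function(s)
      segment_resistance(span_m / 2^(s + 1), wc, hc, mu), numeric(1))
  } else numeric(0)
  r_sub <- segment_resistance(design$trap_pitch * 1e-6, wc, hc, mu)
  r_trap <- segment_resistance(design$filter_length_um * 1e-6,
                               design$W_f * 1e-6, design$H_f * 1e-6, mu) /
    design$filters_per_trap
  net <- list(design = design, S = S, N = design$N,
              r_inlet = r_inlet, r_stage = r_stage,
              r_sub = r_sub, r_trap = r_trap,
              occupancy_multiplier = occupancy_multiplier, scale = 1)
  class(net) <- "hydraulic_network"
  R0 <- .network_resistance(net, rep(0L, design$N))
  sc <- R_total / R0
  net$r_inlet <- net$r_inlet * sc
  net$r_stage <- net$r_stage * sc
  net$r_sub <- net$r_sub * sc
  net$r_trap <- net$r_trap * sc
  net$scale <- sc
  net$R_empty <- R_total
  net
}

#' @export
print.hydraulic_network <- function(x, ...) {
  cat(sprintf("Hydraulic network: S = %d stages, %d traps, empty-device R = %.3g Pa s m^-3\n",
              x$S, x$N, x$R_empty))
  cat(sprintf("  occupancy multiplier %gx per captured cell\n", x$occupancy_multiplier))
  invisible(x)
}

# aggregate resistance of the (possibly occupied) network; occ = cells/trap
.network_resistance <- function(net, occ, multiplier = net$occupancy_multiplier) {
  sol <- .collapse_tree(net, occ, multiplier)
  sol$R_device
}

# bottom-up series-parallel collapse of the symmetric binary tree.
# Heap node indexing: root junction = 1; children of i are 2i, 2i+1; leaves
# are at depth S (indices 2^S .. 2^(S+1)-1); leaf j feeds traps
# (j - 2^S)*4 + 1..4. Returns per-node effective resistances.
.collapse_tree <- function(net, occ, multiplier) {
  S <- net$S
  n_nodes <- 2L^(S + 1L) - 1L
  leaf0 <- 2L^S
  r_path <- net$r_sub + net$r_trap * multiplier^occ  # per-trap path to outlet
  R_eff <- numeric(n_nodes)
  for (j in leaf0:(2L * leaf0 - 1L)) {
    t0 <- (j - leaf0) * 4L
    R_eff[j] <- 1 / sum(1 / r_path[t0 + 1:4])
  }
  if (S > 0) {
    for (i in (leaf0 - 1L):1L) {
      d_child <- floor(log2(2 * i))  # depth of children = stage index
      Rb1 <- net$r_stage[d_child] + R_eff[2L * i]
      Rb2 <- net$r_stage[d_child] + R_eff[2L * i + 1L]
      R_eff[i] <- 1 / (1 / Rb1 + 1 / Rb2)
    }
  }
  list(R_eff = R_eff, r_path = r_path, R_device = net$r_inlet + R_eff[1L])
}

#' Solve the trap-array flow distribution for a given occupancy state
#'
#' Exact linear solution of the series-parallel network under either a fixed
#' inlet pressure (pipette/hydrostatic drive) or a fixed inlet flow (syringe
#' pump). Occupied traps carry a filter resistance scaled by
#' `multiplier^cells`, so under fixed pressure flow diverts away from
#' occupied traps towards empty ones, while under fixed flow the inlet
#' pressure rises to push the same total through.
#'
#' @param network a [build_network()] object.
#' @param boundary either `list(pressure = P)` (Pa) or `list(flow = Q)`
#'   (m^3/s).
#' @param occupancy integer vector of cells per trap (length `N`; default all
#'   empty).
#' @param multiplier per-cell resistance penalty (defaults to the network's).
#' @return object of class `flow_solution` with `total_flow` (m^3/s),
#'   `inlet_pressure` (Pa), `R_device`, per-trap `trap_flows`, per-leaf
#'   channel flows, `trap_shear` (Pa, per filter channel) and the boundary
#'   description.
#' @export
solve_flow <- function(network, boundary, occupancy = NULL,
                       multiplier = network$occupancy_multiplier) {
  .assert(inherits(network, "hydraulic_network"), "network must be a hydraulic_network")
  .assert(is.list(boundary) && length(boundary) == 1L &&
            names(boundary) %in% c("pressure", "flow"),
          "boundary must be list(pressure = ) or list(flow = )")
  N <- network$N
  if (is.null(occupancy)) occupancy <- rep(0L, N)
  .assert(length(occupancy) == N, "occupancy must have one entry per trap")
  .assert(all(occupancy >= 0), "occupancy must be non-negative")
  .assert(multiplier >= 1, "multiplier must be >= 1")

  col <- .collapse_tree(network, occupancy, multiplier)
  R_dev <- col$R_device
  .assert(is.finite(R_dev) && R_dev > 0, "singular network")

  if (names(boundary) == "pressure") {
    P_in <- boundary$pressure
    Q_tot <- P_in / R_dev
  } else {
    Q_tot <- boundary$flow
    P_in <- Q_tot * R_dev
  }

  S <- network$S
  leaf0 <- 2L^S
  n_nodes <- 2L * leaf0 - 1L
  Q_node <- numeric(n_nodes)
  P_node <- numeric(n_nodes)
  Q_node[1L] <- Q_tot
  P_node[1L] <- P_in - Q_tot * network$r_inlet
  if (S > 0) {
    for (i in 1L:(leaf0 - 1L)) {
      d_child <- floor(log2(2 * i))
      Rb1 <- network$r_stage[d_child] + col$R_eff[2L * i]
      Rb2 <- network$r_stage[d_child] + col$R_eff[2L * i + 1L]
      G1 <- 1 / Rb1; G2 <- 1 / Rb2
      Q_node[2L * i] <- Q_node[i] * G1 / (G1 + G2)
      Q_node[2L * i + 1L] <- Q_node[i] * G2 / (G1 + G2)
      P_node[2L * i] <- P_node[i] - Q_node[2L * i] * network$r_stage[d_child]
      P_node[2L * i + 1L] <- P_node[i] - Q_node[2L * i + 1L] * network$r_stage[d_child]
    }
  }
  trap_flows <- numeric(N)
  for (j in leaf0:n_nodes) {
    t0 <- (j - leaf0) * 4L
    trap_flows[t0 + 1:4] <- P_node[j] / col$r_path[t0 + 1:4]
  }
  des <- network$design
  shear <- wall_shear(trap_flows / des$filters_per_trap,
                      des$W_f * 1e-6, des$H_f * 1e-6, des$viscosity)
  structure(list(total_flow = Q_tot, inlet_pressure = P_in, R_device = R_dev,
                 trap_flows = trap_flows, leaf_flows = Q_node[leaf0:n_nodes],
                 node_flows = Q_node, node_pressures = P_node,
                 trap_shear = shear, occupancy = occupancy,
                 boundary = names(boundary), multiplier = multiplier),
            class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Flow solution (%s boundary): Q = %.4g m^3/s = %.4g uL/min, inlet P = %.4g Pa\n",
              x$boundary, x$total_flow, flow_to_uL_min(x$total_flow), x$inlet_pressure))
  cat(sprintf("  device R = %.4g Pa s m^-3; occupied traps: %d of %d\n",
              x$R_device, sum(x$occupancy > 0), length(x$occupancy)))
  cat(sprintf("  trap flow range: %.3g - %.3g uL/min; max filter shear %.3g Pa\n",
              flow_to_uL_min(min(x$trap_flows)), flow_to_uL_min(max(x$trap_flows)),
              max(x$trap_shear)))
  invisible(x)
}

#' @export
plot.flow_solution <- function(x, ...) {
  plot(seq_along(x$trap_flows), flow_to_uL_min(x$trap_flows), type = "h",
       xlab = "trap index", ylab = "trap flow (uL/min)",
       col = ifelse(x$occupancy > 0, "firebrick", "grey40"), ...)
  invisible(x)
}

#' Export a flow solution as a per-trap data.frame
#'
#' @param x a [solve_flow()] result.
#' @param ... unused.
#' @export
as.data.frame.flow_solution <- function(x, ...) {
  data.frame(trap = seq_along(x$trap_flows),
             occupancy = x$occupancy,
             flow_m3s = x$trap_flows,
             flow_uL_min = flow_to_uL_min(x$trap_flows),
             shear_Pa = x$trap_shear)
}
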