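#' A lot of cells introduced into the device
#'
#' @param population population index 1 or 2 (1 = effector by convention).
#' @param count number of cells in the lot.
#' @return object of class `cell_lot`.
#' @export
cell_lot <- function(population, count) {
  .assert(population %in% c(1L, 2L), "population must be 1 or 2")
  .assert(.is_count(count), "count must be a non-negative integer")
  structure(list(population = as.integer(population), count = as.integer(count)),
            class = "cell_lot")
}

#' Simulation controls for the Monte-Carlo loading model
#'
#' @param seed integer RNG seed; identical seed and configuration give a
#'   bit-identical result.
#' @param trap_capacity maximum total cells a trap can hold (default 6);
#'   cells arriving at a full trap are tallied as overflow and removed.
#' @param couple_hydraulics when `TRUE`, cells are routed down the
#'   bifurcation tree with branch probabilities proportional to the current
#'   branch flows from the occupied-network solution (flows are refreshed
#'   after every capture); when `FALSE` routing is uniform (equal split at
#'   every junction), the well-mixed limit.
#' @param occupancy_multiplier per-cell filter-resistance penalty forwarded
#'   to the hydraulic model.
#' @param mixing `"premixed"` (populations interleaved by a seeded
#'   permutation) or `"sequential"` (lots introduced in order).
#' @param replicates number of replicate loadings for
#'   [simulate_replicates()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, trap_capacity = 6L, couple_hydraulics = FALSE,
                       occupancy_multiplier = 10, mixing = c("premixed", "sequential"),
                       replicates = 1L) {
  .assert(trap_capacity >= 1, "trap capacity must be >= 1")
  .assert(replicates >= 1, "replicates must be >= 1")
  mixing <- match.arg(mixing)
  structure(list(seed = as.integer(seed), trap_capacity = as.integer(trap_capacity),
                 couple_hydraulics = isTRUE(couple_hydraulics),
                 occupancy_multiplier = occupancy_multiplier,
                 mixing = mixing, replicates = as.integer(replicates)),
            class = "sim_config")
}

# arrival sequence of population labels for the given lots
.arrival_sequence <- function(lots, mixing) {
  pops <- unlist(lapply(lots, function(l) rep(l$population, l$count)))
  if (length(pops) == 0L) return(integer(0))
  if (mixing == "premixed") pops <- sample(pops) else pops
}

#' Simulate sequential stochastic cell loading of a trap array
#'
#' Cells arrive one at a time and descend the bifurcation tree, choosing a
#' branch at every junction with probability proportional to the
#' instantaneous branch flow (equal splits when hydraulics are uncoupled).
#' A cell reaching a trap below capacity is captured with probability 1 (the
#' filter geometry guarantees capture); a cell reaching a full trap is
#' counted as overflow and removed. Occupancy — and, when coupled, the flow
#' field — is updated after every capture, so later cells are steered
#' towards emptier, lower-resistance traps.
#'
#' @param design a [trap_design()].
#' @param lots list of [cell_lot()]s (typically one per population).
#' @param config a [sim_config()].
#' @param network optional pre-built [build_network()] (rebuilt otherwise
#'   when hydraulic coupling is on).
#' @return object of class `sim_result`: `occupancy` (an
#'   [occupancy_table()]), `fill_order` (per-trap capture order as global
#'   cell indices), `overflow_count`, `lambda_realized`, `introduced`.
#' @export
simulate_loading <- function(design, lots, config = sim_config(), network = NULL) {
  .assert(inherits(design, "trap_design"), "design must be a trap_design")
  N <- design$N
  set.seed(config$seed)
  pops <- .arrival_sequence(lots, config$mixing)
  n_cells <- length(pops)
  cap <- config$trap_capacity

  n1 <- integer(N); n2 <- integer(N)
  fill_order <- vector("list", N)
  overflow <- 0L

  if (!config$couple_hydraulics) {
    # well-mixed limit: equal split at every junction == uniform trap choice
    traps <- if (n_cells > 0) sample.int(N, n_cells, replace = TRUE) else integer(0)
    tot <- integer(N)
    for (i in seq_len(n_cells)) {
      t <- traps[i]
      if (tot[t] >= cap) { overflow <- overflow + 1L; next }
      tot[t] <- tot[t] + 1L
      if (pops[i] == 1L) n1[t] <- n1[t] + 1L else n2[t] <- n2[t] + 1L
      fill_order[[t]] <- c(fill_order[[t]], i)
    }
  } else {
    if (is.null(network)) network <- build_network(design,
                                                   occupancy_multiplier = config$occupancy_multiplier)
    mult <- config$occupancy_multiplier
    S <- network$S
    leaf0 <- 2L^S
    col <- .collapse_tree(network, rep(0L, N), mult)
    R_eff <- col$R_eff
    r_path <- col$r_path
    tot <- integer(N)
    for (i in seq_len(n_cells)) {
      node <- 1L
      while (node < leaf0) {
        d_child <- floor(log2(2 * node))
        G1 <- 1 / (network$r_stage[d_child] + R_eff[2L * node])
        G2 <- 1 / (network$r_stage[d_child] + R_eff[2L * node + 1L])
        node <- if (runif(1) < G1 / (G1 + G2)) 2L * node else 2L * node + 1L
      }
      t0 <- (node - leaf0) * 4L
      g <- 1 / r_path[t0 + 1:4]
      t <- t0 + sample.int(4L, 1L, prob = g)
      if (tot[t] >= cap) { overflow <- overflow + 1L; next }
      tot[t] <- tot[t] + 1L
      if (pops[i] == 1L) n1[t] <- n1[t] + 1L else n2[t] <- n2[t] + 1L
      fill_order[[t]] <- c(fill_order[[t]], i)
      # incremental update of the occupied path, O(S)
      r_path[t] <- r_path[t] * mult
      R_eff[node] <- 1 / sum(1 / r_path[t0 + 1:4])
      a <- node
      while (a > 1L) {
        p <- a %/% 2L
        d_child <- floor(log2(2 * p))
        Rb1 <- network$r_stage[d_child] + R_eff[2L * p]
        Rb2 <- network$r_stage[d_child] + R_eff[2L * p + 1L]
        R_eff[p] <- 1 / (1 / Rb1 + 1 / Rb2)
        a <- p
      }
    }
  }

  kmax1 <- max(n1, 0L); kmax2 <- max(n2, 0L)
  counts <- matrix(0L, kmax1 + 1L, kmax2 + 1L)
  for (t in seq_len(N)) counts[n1[t] + 1L, n2[t] + 1L] <- counts[n1[t] + 1L, n2[t] + 1L] + 1L
  tab <- occupancy_table(counts)
  captured <- sum(n1) + sum(n2)
  .assert(captured + overflow == n_cells, "cell conservation violated")
  structure(list(occupancy = tab,
                 per_trap = cbind(k1 = n1, k2 = n2),
                 fill_order = fill_order,
                 overflow_count = overflow,
                 introduced = n_cells,
                 lambda_realized = c(sum(n1), sum(n2)) / N,
                 config = config),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Loading simulation: %d cells introduced, %d captured, %d overflow\n",
              x$introduced, x$introduced - x$overflow_count, x$overflow_count))
  cat(sprintf("  realized lambda: %.4g / %.4g over %d traps\n",
              x$lambda_realized[1], x$lambda_realized[2], x$occupancy$N_t))
  invisible(x)
}

#' Run replicate loading simulations with derived seed streams
#'
#' @inheritParams simulate_loading
#' @return list of [simulate_loading()] results, one per
#'   `config$replicates`.
#' @export
simulate_replicates <- function(design, lots, config = sim_config()) {
  seeds <- .derive_seeds(config$seed, config$replicates)
  net <- if (config$couple_hydraulics)
    build_network(design, occupancy_multiplier = config$occupancy_multiplier) else NULL
  lapply(seq_len(config$replicates), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    simulate_loading(design, lots, cfg, network = net)
  })
}

#' Cohort statistics across replicate loading simulations
#'
#' @param results list of [simulate_loading()] results.
#' @return object of class `sim_summary` with per-cohort mean and standard
#'   deviation of trap frequencies, the per-pair (1:1 etc.) frequencies, the
#'   realized-lambda distribution and overflow tallies.
#' @export
summarize_replicates <- function(results) {
  .assert(length(results) >= 1L, "at least one replicate required")
  .assert(all(vapply(results, inherits, logical(1), "sim_result")),
          "results must be sim_result objects")
  freq <- t(vapply(results, function(r)
    tabulate_cohorts(r$occupancy) / r$occupancy$N_t, numeric(length(COHORT_LEVELS))))
  colnames(freq) <- COHORT_LEVELS
  pair11 <- vapply(results, function(r) {
    ct <- r$occupancy$counts
    if (nrow(ct) >= 2 && ncol(ct) >= 2) ct[2, 2] / r$occupancy$N_t else 0
  }, numeric(1))
  lam <- t(vapply(results, function(r) r$lambda_realized, numeric(2)))
  csd <- if (nrow(freq) > 1L) apply(freq, 2, sd) else
    structure(rep(0, ncol(freq)), names = colnames(freq))
  structure(list(n_replicates = length(results),
                 cohort_mean = colMeans(freq),
                 cohort_sd = csd,
                 cohort_freq = freq,
                 pair_1to1 = pair11,
                 lambda = lam,
                 overflow = vapply(results, function(r) r$overflow_count, numeric(1))),
            class = "sim_summary")
}

#' @export
print.sim_summary <- function(x, ...) {
  cat(sprintf("Loading summary over %d replicates:\n", x$n_replicates))
  m <- rbind(mean = x$cohort_mean, sd = x$cohort_sd)
  print(round(m, 4))
  cat(sprintf("  1:1 singlet frequency: %.4f +/- %.4f (mean +/- sd)\n",
              mean(x$pair_1to1),
              if (length(x$pair_1to1) > 1) sd(x$pair_1to1) else 0))
  cat(sprintf("  realized lambda: %.3f / %.3f\n",
              mean(x$lambda[, 1]), mean(x$lambda[, 2])))
  invisible(x)
}
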