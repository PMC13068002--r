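#' Trap-occupancy table for a two-population pairing experiment
#'
#' An `occupancy_table` records how many of the `N_t` traps of a device hold
#' each combination `(k1, k2)` of cells from two co-seeded populations
#' (conventionally population 1 = effector, population 2 = target). It is the
#' common currency between the analytic Poisson model, the Monte-Carlo loading
#' simulator and the image-analysis pipeline.
#'
#' @param counts integer matrix of trap tallies; rows index `k1 = 0, 1, ...`,
#'   columns index `k2 = 0, 1, ...` (dimnames are set accordingly).
#' @param population_labels character vector of length 2 naming the two
#'   populations.
#' @return an object of class `occupancy_table`.
#' @examples
#' m <- matrix(0L, 3, 3)
#' m[1, 1] <- 900; m[2, 2] <- 100; m[3, 3] <- 24
#' tab <- occupancy_table(m)
#' estimate_lambda(tab, "effector")
#' @export
occupancy_table <- function(counts, population_labels = c("effector", "target")) {
  counts <- as.matrix(counts)
  .assert(all(counts >= 0) && all(counts == floor(counts)),
          "occupancy counts must be non-negative integers")
  .assert(length(population_labels) == 2L, "exactly two population labels required")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(k1 = 0:(nrow(counts) - 1L), k2 = 0:(ncol(counts) - 1L))
  structure(list(counts = counts,
                 N_t = sum(counts),
                 population_labels = as.character(population_labels)),
            class = "occupancy_table")
}

#' @export
print.occupancy_table <- function(x, ...) {
  cat("Trap occupancy table:", x$N_t, "traps\n")
  cat("populations:", paste(x$population_labels, collapse = " / "), "\n")
  print(x$counts)
  invisible(x)
}

#' @export
summary.occupancy_table <- function(object, ...) {
  lam <- c(estimate_lambda(object, 1L), estimate_lambda(object, 2L))
  names(lam) <- object$population_labels
  coh <- tabulate_cohorts(object)
  out <- list(N_t = object$N_t, lambda = lam, cohorts = coh)
  class(out) <- "summary.occupancy_table"
  out
}

#' @export
print.summary.occupancy_table <- function(x, ...) {
  cat("N_t =", x$N_t, "traps\n")
  cat("estimated loading rates (lambda = trapped cells / traps):\n")
  print(round(x$lambda, 4))
  cat("cohort tallies:\n")
  print(x$cohorts)
  invisible(x)
}

#' @export
as.data.frame.occupancy_table <- function(x, ...) {
  d <- as.data.frame.table(x$counts, stringsAsFactors = FALSE)
  names(d) <- c("k1", "k2", "count")
  d$k1 <- as.integer(d$k1)
  d$k2 <- as.integer(d$k2)
  d[order(d$k1, d$k2), , drop = FALSE]
}

.pop_index <- function(table, population) {
  if (is.numeric(population)) {
    .assert(population %in% c(1, 2), "population index must be 1 or 2")
    return(as.integer(population))
  }
  i <- match(population, table$population_labels)
  .assert(!is.na(i), paste0("unknown population label '", population, "'"))
  i
}

# marginal trap tallies n_t(k) for one population
.marginal_counts <- function(table, population) {
  i <- .pop_index(table, population)
  if (i == 1L) rowSums(table$counts) else colSums(table$counts)
}

#' Poisson probability of k cells in a trap
#'
#' Probability that a trap captures exactly `k` cells when the mean number of
#' cells per trap is `lambda`: `P(lambda, k) = lambda^k exp(-lambda) / k!`.
#'
#' @param lambda non-negative mean cells per trap.
#' @param k non-negative integer occupancy (vectorised).
#' @return probability (or vector of probabilities).
#' @export
poisson_pmf <- function(lambda, k) {
  .assert(is.numeric(lambda) && all(lambda >= 0), "lambda must be >= 0")
  .assert(.is_count(k), "k must be a non-negative integer")
  dpois(k, lambda)
}

#' Empirical loading frequency f(k) = n_t(k) / N_t
#'
#' @param table an [occupancy_table()].
#' @param k non-negative integer occupancy (vectorised).
#' @param population population label or index (1 or 2).
#' @return empirical frequency of traps holding exactly `k` cells of the
#'   population; 0 for `k` beyond the tabulated range.
#' @export
empirical_frequency <- function(table, k, population) {
  .assert(inherits(table, "occupancy_table"), "table must be an occupancy_table")
  .assert(.is_count(k), "k must be a non-negative integer")
  .assert(table$N_t > 0, "empty device: N_t = 0")
  n_k <- .marginal_counts(table, population)
  out <- numeric(length(k))
  inside <- k <= length(n_k) - 1L
  out[inside] <- n_k[k[inside] + 1L] / table$N_t
  out
}

#' Estimate the loading rate lambda = N_p / N_t from an occupancy table
#'
#' `N_p` is the total number of trapped cells of the population, i.e.
#' `sum_k k * n_t(k)`; flow-through (uncaptured) cells do not enter the
#' estimator.
#'
#' @inheritParams empirical_frequency
#' @return non-negative estimate of the mean cells per trap.
#' @export
estimate_lambda <- function(table, population) {
  .assert(inherits(table, "occupancy_table"), "table must be an occupancy_table")
  .assert(table$N_t > 0, "empty device: N_t = 0")
  n_k <- .marginal_counts(table, population)
  k <- seq_along(n_k) - 1L
  sum(k * n_k) / table$N_t
}

#' Loading rates for the two co-seeded populations
#'
#' @param lambda1,lambda2 non-negative mean cells per trap for populations 1
#'   and 2.
#' @return object of class `loading_rate`.
#' @export
loading_rate <- function(lambda1, lambda2) {
  .assert(is.numeric(lambda1) && lambda1 >= 0 && is.numeric(lambda2) && lambda2 >= 0,
          "loading rates must be non-negative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2), class = "loading_rate")
}

#' @export
print.loading_rate <- function(x, ...) {
  cat(sprintf("loading rates: lambda1 = %.4g, lambda2 = %.4g\n", x$lambda1, x$lambda2))
  invisible(x)
}

#' Double-Poisson co-occupancy probability P(k1 : k2) = P(k1) * P(k2)
#'
#' Joint probability that a trap holds `k1` cells of population 1 and `k2`
#' cells of population 2, under independent Poisson loading of the two
#' populations.
#'
#' @param rates a [loading_rate()] (or list with `lambda1`, `lambda2`).
#' @param k1,k2 non-negative integer occupancies (vectorised).
#' @return joint probability.
#' @examples
#' double_poisson(loading_rate(0.5, 0.5), 1, 1)    # ~0.092
#' double_poisson(loading_rate(0.83, 0.58), 1, 1)  # ~0.118
#' @export
double_poisson <- function(rates, k1, k2) {
  poisson_pmf(rates$lambda1, k1) * poisson_pmf(rates$lambda2, k2)
}

#' Empirical dual loading frequency f(k1 : k2) = f(k1) * f(k2)
#'
#' Product-rule estimate of the dual frequency from the two marginal
#' frequencies, assuming independent loading of the populations. The direct
#' tally `counts[k1, k2] / N_t` of an [occupancy_table()] is the alternative
#' estimator; both are exposed because printed dual counts in array
#' characterizations can be either.
#'
#' @param f1,f2 marginal frequencies in `[0, 1]`.
#' @return product frequency in `[0, 1]`.
#' @export
dual_frequency <- function(f1, f2) {
  .assert(is.numeric(f1) && all(f1 >= 0 & f1 <= 1), "f1 must lie in [0,1]")
  .assert(is.numeric(f2) && all(f2 >= 0 & f2 <= 1), "f2 must lie in [0,1]")
  f1 * f2
}

#' Cohort taxonomy of a trap occupancy pair
#'
#' Maps `(k1, k2)` to the standard pairing cohorts: `empty` (0:0),
#' `effector_only_control` (>=1:0), `target_only_control` (0:>=1),
#' `singlet_1to1` (1:1), and `multiplet` (>=1:>=1 except 1:1). Every lattice
#' pair maps to exactly one category.
#'
#' @param k1,k2 non-negative integer occupancies (vectorised, recycled).
#' @return data.frame with columns `k1`, `k2`, `ratio` (the literal "k1:k2"
#'   pair) and `category`.
#' @export
classify_cohort <- function(k1, k2) {
  .assert(.is_count(k1) && .is_count(k2), "occupancies must be non-negative integers")
  n <- max(length(k1), length(k2))
  k1 <- rep_len(k1, n); k2 <- rep_len(k2, n)
  category <- ifelse(k1 == 0 & k2 == 0, "empty",
              ifelse(k1 >= 1 & k2 == 0, "effector_only_control",
              ifelse(k1 == 0 & k2 >= 1, "target_only_control",
              ifelse(k1 == 1 & k2 == 1, "singlet_1to1", "multiplet"))))
  data.frame(k1 = as.integer(k1), k2 = as.integer(k2),
             ratio = paste0(k1, ":", k2),
             category = factor(category, levels = COHORT_LEVELS),
             stringsAsFactors = FALSE)
}

#' Cohort category levels used throughout the package
#' @export
COHORT_LEVELS <- c("empty", "effector_only_control", "target_only_control",
                   "singlet_1to1", "multiplet")

#' Observed trap tallies per cohort
#'
#' @param table an [occupancy_table()].
#' @return named integer vector of trap counts per cohort category.
#' @export
tabulate_cohorts <- function(table) {
  .assert(inherits(table, "occupancy_table"), "table must be an occupancy_table")
  d <- as.data.frame(table)
  cl <- classify_cohort(d$k1, d$k2)
  out <- tapply(d$count, cl$category, sum, default = 0L)
  out[is.na(out)] <- 0L
  out
}

#' Expected trap counts per (k1 : k2) pair and per cohort
#'
#' Evaluates `N_t * P(k1 : k2)` on the occupancy lattice, aggregating the
#' Poisson tail `k >= max_k` of each population into a single bin so the
#' expected counts sum to `N_t` exactly.
#'
#' @param rates a [loading_rate()].
#' @param N_t positive total trap count.
#' @param max_k tail-aggregation threshold (default 5, i.e. bins
#'   `0, 1, ..., 4, >=5`); must be >= 2.
#' @return list of class `cohort_expectation` with elements `pairs`
#'   (data.frame: `k1`, `k2`, labels, probability, expected count, cohort) and
#'   `cohorts` (named vector of expected counts per cohort).
#' @export
expected_cohort_counts <- function(rates, N_t, max_k = 5L) {
  .assert(is.numeric(N_t) && N_t > 0, "N_t must be positive")
  .assert(max_k >= 2, "max_k must be >= 2")
  max_k <- as.integer(max_k)
  tail_p <- function(lambda) {
    p <- dpois(0:(max_k - 1L), lambda)
    c(p, 1 - sum(p))  # aggregate >= max_k; conserves mass exactly
  }
  p1 <- tail_p(rates$lambda1)
  p2 <- tail_p(rates$lambda2)
  joint <- outer(p1, p2)
  ks <- 0:max_k
  lab <- c(as.character(0:(max_k - 1L)), paste0(">=", max_k))
  grid <- expand.grid(k1 = ks, k2 = ks)
  prob <- as.vector(joint[cbind(grid$k1 + 1L, grid$k2 + 1L)])
  cl <- classify_cohort(grid$k1, grid$k2)  # the >=max_k bin behaves as k = max_k (>1)
  pairs <- data.frame(k1 = grid$k1, k2 = grid$k2,
                      k1_label = lab[grid$k1 + 1L], k2_label = lab[grid$k2 + 1L],
                      probability = prob, expected = N_t * prob,
                      category = cl$category, stringsAsFactors = FALSE)
  cohorts <- tapply(pairs$expected, pairs$category, sum, default = 0)
  structure(list(pairs = pairs, cohorts = cohorts, N_t = N_t, rates = rates,
                 max_k = max_k),
            class = "cohort_expectation")
}

#' @export
print.cohort_expectation <- function(x, ...) {
  cat(sprintf("Expected cohort yields for N_t = %g traps (lambda1 = %.3g, lambda2 = %.3g):\n",
              x$N_t, x$rates$lambda1, x$rates$lambda2))
  print(round(x$cohorts, 1))
  invisible(x)
}

#' Chi-square goodness of fit of a marginal occupancy distribution to Poisson
#'
#' Compares the observed marginal tallies `n_t(k)` of one population with the
#' Poisson expectation at the rate estimated from the same table. Tail bins
#' are aggregated and bins with expected count < 5 are merged upward; degrees
#' of freedom are `bins - 1 - 1` (one for the estimated rate).
#'
#' @inheritParams empirical_frequency
#' @param min_expected merge threshold for expected bin counts (default 5).
#' @return object of class `poisson_gof` with `statistic`, `df`, `p.value`,
#'   `lambda_hat` and the merged `bins` table.
#' @export
goodness_of_fit <- function(table, population, min_expected = 5) {
  .assert(inherits(table, "occupancy_table"), "table must be an occupancy_table")
  n_k <- .marginal_counts(table, population)
  N_t <- table$N_t
  lambda_hat <- estimate_lambda(table, population)
  kmax <- length(n_k) - 1L
  .assert(kmax >= 1L, "fewer than 2 usable bins for goodness of fit")
  expected <- N_t * c(dpois(seq_len(kmax) - 1L, lambda_hat),
                      ppois(kmax - 1L, lambda_hat, lower.tail = FALSE))
  obs <- as.numeric(n_k)
  # merge sparse bins upward (from the tail towards k = 0)
  while (length(expected) > 1L && min(expected) < min_expected) {
    i <- length(expected)
    if (expected[i] < min_expected || expected[i - 1L] < min_expected) {
      expected[i - 1L] <- expected[i - 1L] + expected[i]
      obs[i - 1L] <- obs[i - 1L] + obs[i]
      expected <- expected[-i]; obs <- obs[-i]
    } else {
      j <- which.min(expected)
      expected[j + 1L] <- expected[j + 1L] + expected[j]
      obs[j + 1L] <- obs[j + 1L] + obs[j]
      expected <- expected[-j]; obs <- obs[-j]
    }
  }
  .assert(length(obs) >= 2L, "fewer than 2 usable bins for goodness of fit")
  stat <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 2L  # one df for totals, one for the estimated lambda
  p <- if (df >= 1L) pchisq(stat, df, lower.tail = FALSE) else NA_real_
  structure(list(statistic = stat, df = df, p.value = p,
                 lambda_hat = lambda_hat,
                 bins = data.frame(observed = obs, expected = expected)),
            class = "poisson_gof")
}

#' @export
print.poisson_gof <- function(x, ...) {
  cat(sprintf("Poisson goodness of fit: X^2 = %.3f, df = %d, p = %.4g (lambda_hat = %.4g)\n",
              x$statistic, x$df, x$p.value, x$lambda_hat))
  invisible(x)
}

#' @export
plot.poisson_gof <- function(x, ...) {
  b <- x$bins
  k <- seq_len(nrow(b)) - 1
  bp <- barplot(rbind(b$observed, b$expected), beside = TRUE,
                names.arg = k, col = c("grey30", "steelblue"),
                xlab = "occupancy bin", ylab = "traps", ...)
  legend("topright", legend = c("observed", "Poisson expectation"),
         fill = c("grey30", "steelblue"), bty = "n")
  invisible(bp)
}

.cohort_probability <- function(objective, lambda1, lambda2) {
  if (is.numeric(objective) && length(objective) == 2L) {
    return(dpois(objective[1], lambda1) * dpois(objective[2], lambda2))
  }
  p0_1 <- exp(-lambda1); p0_2 <- exp(-lambda2)
  p1_1 <- lambda1 * p0_1; p1_2 <- lambda2 * p0_2
  switch(objective,
         empty = p0_1 * p0_2,
         singlet_1to1 = p1_1 * p1_2,
         effector_only_control = (1 - p0_1) * p0_2,
         target_only_control = p0_1 * (1 - p0_2),
         multiplet = (1 - p0_1) * (1 - p0_2) - p1_1 * p1_2,
         stop("unknown cohort objective '", objective, "'"))
}

#' Choose loading rates to maximise or achieve a cohort probability
#'
#' Deterministic design helper for seeding-concentration planning: finds the
#' loading rate(s) that maximise the probability of a cohort (or explicit
#' `(k1, k2)` pair), or — when `target` is given — the smallest `lambda1`
#' achieving a stated probability at fixed `lambda2`. Search is a coarse grid
#' followed by golden-section refinement; the objective is smooth in 1 or 2
#' dimensions.
#'
#' @param objective a cohort category name (see [classify_cohort()]) or an
#'   integer pair `c(k1, k2)`.
#' @param target optional probability to achieve (rather than maximise).
#' @param lambda2 optional fixed rate for population 2; when `NULL` and
#'   `symmetric = TRUE` both rates are tied.
#' @param symmetric tie `lambda1 = lambda2` during maximisation (default when
#'   `lambda2` is not fixed).
#' @param upper upper bound of the search interval (default 5).
#' @param tol grid/refinement tolerance on lambda (default 1e-6).
#' @return list of class `lambda_design`: `rates` ([loading_rate()]),
#'   `value` (achieved probability), `feasible`.
#' @examples
#' optimize_lambda("singlet_1to1")$rates            # lambda = 1, value e^-2
#' optimize_lambda(c(1, 1), target = 0.092, lambda2 = 0.5)
#' @export
optimize_lambda <- function(objective, target = NULL, lambda2 = NULL,
                            symmetric = is.null(lambda2), upper = 5, tol = 1e-6) {
  obj1 <- function(l1, l2) .cohort_probability(objective, l1, l2)
  grid <- seq(0, upper, length.out = 201L)

  if (!is.null(target)) {
    .assert(!is.null(lambda2), "achieving a target probability requires a fixed lambda2")
    f <- function(l1) obj1(l1, lambda2) - target
    vals <- vapply(grid, function(g) obj1(g, lambda2), numeric(1))
    peak <- grid[which.max(vals)]
    if (max(vals) + 1e-12 < target) {
      return(structure(list(rates = NULL, value = max(vals), feasible = FALSE,
                            objective = objective),
                       class = "lambda_design"))
    }
    root <- if (f(0) >= 0) 0 else uniroot(f, c(0, peak), tol = tol)$root
    return(structure(list(rates = loading_rate(root, lambda2),
                          value = obj1(root, lambda2), feasible = TRUE,
                          objective = objective),
                     class = "lambda_design"))
  }

  if (symmetric) {
    vals <- vapply(grid, function(g) obj1(g, g), numeric(1))
    best <- grid[which.max(vals)]
    span <- grid[2] - grid[1]
    opt <- optimize(function(g) obj1(g, g),
                    c(max(0, best - span), min(upper, best + span)),
                    maximum = TRUE, tol = tol)
    cand <- rbind(c(best, max(vals)), c(opt$maximum, opt$objective))
    w <- which.max(cand[, 2])
    l <- cand[w, 1]
    return(structure(list(rates = loading_rate(l, l), value = cand[w, 2],
                          feasible = TRUE, objective = objective),
                     class = "lambda_design"))
  }

  if (!is.null(lambda2)) {
    vals <- vapply(grid, function(g) obj1(g, lambda2), numeric(1))
    best <- grid[which.max(vals)]
    span <- grid[2] - grid[1]
    opt <- optimize(function(g) obj1(g, lambda2),
                    c(max(0, best - span), min(upper, best + span)),
                    maximum = TRUE, tol = tol)
    cand <- rbind(c(best, max(vals)), c(opt$maximum, opt$objective))
    w <- which.max(cand[, 2])
    return(structure(list(rates = loading_rate(cand[w, 1], lambda2),
                          value = cand[w, 2], feasible = TRUE,
                          objective = objective),
                     class = "lambda_design"))
  }

  # free 2-D maximisation: coordinate-wise golden-section from the grid optimum
  g2 <- expand.grid(l1 = seq(0, upper, length.out = 51L),
                    l2 = seq(0, upper, length.out = 51L))
  vals <- mapply(obj1, g2$l1, g2$l2)
  l1 <- g2$l1[which.max(vals)]; l2 <- g2$l2[which.max(vals)]
  for (it in 1:4) {
    l1 <- optimize(function(g) obj1(g, l2), c(0, upper), maximum = TRUE, tol = tol)$maximum
    l2 <- optimize(function(g) obj1(l1, g), c(0, upper), maximum = TRUE, tol = tol)$maximum
  }
  structure(list(rates = loading_rate(l1, l2), value = obj1(l1, l2),
                 feasible = TRUE, objective = objective),
            class = "lambda_design")
}

#' @export
print.lambda_design <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("infeasible objective: maximum attainable probability %.4g\n", x$value))
  } else {
    cat(sprintf("lambda1 = %.4g, lambda2 = %.4g -> probability %.4g\n",
                x$rates$lambda1, x$rates$lambda2, x$value))
  }
  invisible(x)
}
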