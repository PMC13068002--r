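# Cohort-level cytotoxicity statistics and significance testing.

# cohort key for reporting: explicit k1:k2 ratio for co-culture traps,
# category name for empty/control traps
.cohort_key <- function(series) {
  if (series$cohort_category %in% c("singlet_1to1", "multiplet"))
    series$cohort_ratio else series$cohort_category
}

#' Summarise per-cohort cytotoxicity from analysed trap series
#'
#' Groups retained traps by their t = 0 effector-to-target cohort and
#' reports, per cohort: traps assigned/excluded/retained, the target and
#' effector death fractions (%), viability, and the normalized endpoint
#' green intensity (per-trap endpoint/initial, mean and sd). Control
#' cohorts (effector-only, target-only) report spontaneous death and
#' baseline viability. Cohorts with no retained traps are reported with
#' `n_retained = 0` and `NA` fractions.
#'
#' @param series_list list of `trap_timeseries` from [extract_traces()].
#' @param flags optional list of [apply_exclusions()] results (computed when
#'   omitted).
#' @return object of class `cytotox_result` with a per-cohort `cohorts`
#'   data.frame, per-trap detail, and exclusion tallies.
#' @export
summarize_cytotoxicity <- function(series_list, flags = NULL) {
  .assert(length(series_list) > 0, "no trap series supplied")
  if (is.null(flags)) flags <- lapply(series_list, apply_exclusions)
  .assert(length(flags) == length(series_list), "flags must match series")

  per_trap <- do.call(rbind, lapply(seq_along(series_list), function(i) {
    s <- series_list[[i]]
    deaths <- if (s$has_pi) call_death(s) else
      data.frame(population = character(0), frame = integer(0), time_h = numeric(0))
    n_tgt0 <- s$counts[1, "target"]
    n_eff0 <- s$counts[1, "effector"]
    init_g <- s$intensity[1, "green"]
    end_g <- s$intensity[nrow(s$intensity), "green"]
    data.frame(trap = s$trap, cohort = .cohort_key(s),
               category = s$cohort_category,
               n_eff = n_eff0, n_tgt = n_tgt0,
               tgt_deaths = sum(deaths$population == "target"),
               eff_deaths = sum(deaths$population == "effector"),
               norm_end_green = if (n_tgt0 > 0 && init_g > 0) end_g / init_g else NA_real_,
               excluded = flags[[i]]$excluded,
               reasons = paste(flags[[i]]$reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))

  keys <- unique(per_trap$cohort)
  cohorts <- do.call(rbind, lapply(keys, function(k) {
    d <- per_trap[per_trap$cohort == k, , drop = FALSE]
    r <- d[!d$excluded, , drop = FALSE]
    n_tgt <- sum(r$n_tgt); n_eff <- sum(r$n_eff)
    tgt_frac <- if (n_tgt > 0) 100 * sum(r$tgt_deaths) / n_tgt else NA_real_
    eff_frac <- if (n_eff > 0) 100 * sum(r$eff_deaths) / n_eff else NA_real_
    ng <- r$norm_end_green[!is.na(r$norm_end_green)]
    data.frame(cohort = k, category = d$category[1],
               n_assigned = nrow(d), n_excluded = sum(d$excluded),
               n_retained = nrow(r),
               target_death_pct = tgt_frac,
               effector_death_pct = eff_frac,
               target_viability_pct = if (is.na(tgt_frac)) NA_real_ else 100 - tgt_frac,
               effector_viability_pct = if (is.na(eff_frac)) NA_real_ else 100 - eff_frac,
               norm_end_green_mean = if (length(ng)) mean(ng) else NA_real_,
               norm_end_green_sd = if (length(ng) > 1) sd(ng) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(cohorts) <- NULL
  excl <- table(unlist(strsplit(per_trap$reasons[per_trap$excluded], ";")))
  structure(list(cohorts = cohorts, per_trap = per_trap,
                 exclusion_tally = excl),
            class = "cytotox_result")
}

#' @export
print.cytotox_result <- function(x, ...) {
  cat("Per-cohort cytotoxicity (retained traps):\n")
  d <- x$cohorts
  d$target_death_pct <- round(d$target_death_pct, 1)
  d$effector_death_pct <- round(d$effector_death_pct, 1)
  d$norm_end_green_mean <- round(d$norm_end_green_mean, 3)
  print(d[, c("cohort", "n_assigned", "n_excluded", "n_retained",
              "target_death_pct", "effector_death_pct", "norm_end_green_mean")],
        row.names = FALSE)
  if (length(x$exclusion_tally)) {
    cat("exclusions:\n"); print(x$exclusion_tally)
  }
  invisible(x)
}

#' @export
summary.cytotox_result <- function(object, ...) {
  print(object)
  invisible(object$cohorts)
}

# significance tier mapping at the conventional thresholds
.p_tier <- function(p) {
  ifelse(p < 0.0001, "****",
  ifelse(p < 0.0002, "***",
  ifelse(p < 0.0021, "**",
  ifelse(p < 0.0332, "*", "ns"))))
}

# Dunn's rank-based multiple-comparison z test after Kruskal-Wallis.
# z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T)(1/n_i + 1/n_j)),
# with tie correction T = sum(t^3 - t) / (12 (N - 1)).
.dunn_test <- function(values, groups, p.adjust.method = "bonferroni") {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  lev <- levels(groups)
  combs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / ns[a] + 1 / ns[b]))
    z[i] <- (rbar[a] - rbar[b]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  p_adj <- p.adjust(p, method = p.adjust.method)
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z,
             p = p_adj, stringsAsFactors = FALSE)
}

#' Pairwise cohort comparison with a normality-gated test choice
#'
#' One-way ANOVA followed by Tukey's HSD when every cohort passes a
#' Shapiro-Wilk normality check (alpha = 0.05), otherwise Kruskal-Wallis
#' followed by Dunn's multiple-comparison test with Bonferroni adjustment.
#' Significance tiers follow the conventional thresholds (* p < 0.0332,
#' ** p < 0.0021, *** p < 0.0002, **** p < 0.0001).
#'
#' @param values numeric per-trap outcome (e.g. per-trap target-death
#'   fraction or normalized endpoint intensity).
#' @param groups cohort label per value.
#' @param min_n cohorts with fewer observations are skipped with a notice
#'   (default 3).
#' @return object of class `cohort_comparison`: data.frame of pairs with
#'   `p`, `tier` and the `method` used, plus any skipped cohorts.
#' @export
compare_cohorts <- function(values, groups, min_n = 3L) {
  .assert(length(values) == length(groups), "values and groups must align")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  ns <- table(groups)
  skipped <- names(ns)[ns < min_n]
  if (length(skipped))
    message("cohorts skipped (n < ", min_n, "): ", paste(skipped, collapse = ", "))
  use <- groups %in% names(ns)[ns >= min_n]
  values <- values[use]; groups <- factor(groups[use])
  .assert(nlevels(groups) >= 2, "need at least two cohorts with sufficient n")

  normal <- all(vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(unique(v)) < 3 || length(v) < 3 || length(v) > 5000) return(FALSE)
    ok <- tryCatch(shapiro.test(v)$p.value >= 0.05, error = function(e) FALSE)
    ok
  }, logical(1)))

  if (normal) {
    fit <- aov(values ~ groups)
    tk <- TukeyHSD(fit)$groups
    pair <- rownames(tk)
    parts <- strsplit(pair, "-", fixed = TRUE)
    out <- data.frame(group1 = vapply(parts, `[`, "", 1),
                      group2 = vapply(parts, `[`, "", 2),
                      p = tk[, "p adj"], stringsAsFactors = FALSE)
    method <- "anova_tukey"
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
  } else {
    kw <- kruskal.test(values, groups)
    out <- .dunn_test(values, groups)[, c("group1", "group2", "p")]
    method <- "kruskal_dunn"
    omnibus <- kw$p.value
  }
  out$tier <- .p_tier(out$p)
  rownames(out) <- NULL
  structure(list(pairs = out, method = method, omnibus_p = omnibus,
                 skipped = skipped),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison (%s), omnibus p = %.4g\n", x$method, x$omnibus_p))
  d <- x$pairs
  d$p <- signif(d$p, 3)
  print(d, row.names = FALSE)
  if (length(x$skipped)) cat("skipped:", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
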