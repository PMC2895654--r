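# Kin-discrimination and dominance statistics from chimeric fruiting-body
# experiments, plus the pyrosequencing standard-curve calibration that
# turns peak heights into strain proportions.
#
# The published statistics are reconstructed from their verbal definitions
# and endpoint constraints (the displayed equations are unrendered in the
# source text): r_fb runs from 0 for random clustering to 1 for complete
# segregation; dominance d is the mean fruiting-body excess over the
# initial-mix proportion; LS is the mean absolute deviation from the mean.

#' Fit a pyrosequencing standard curve
#'
#' Ordinary least-squares regression of measured peak-height ratios on
#' known allele proportions (>= 3 distinct proportions spanning the mixes
#' of interest), used afterwards to invert measurements into proportions.
#'
#' @param known_proportions Numeric vector in `[0, 1]`.
#' @param peak_heights Measured response per mixture (replicates included
#'   as repeated proportions).
#' @return List of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_standard_curve <- function(known_proportions, peak_heights) {
  if (length(known_proportions) != length(peak_heights)) {
    stop("proportions and heights must have the same length", call. = FALSE)
  }
  if (length(unique(known_proportions)) < 3) {
    stop("need at least 3 distinct known proportions", call. = FALSE)
  }
  fit <- lm(peak_heights ~ known_proportions)
  sst <- sum((peak_heights - mean(peak_heights))^2)
  r2 <- if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2,
                 n = length(peak_heights)),
            class = "standard_curve")
}

#' Invert a standard curve into allele proportions
#'
#' Inverse regression `(height - intercept) / slope`; out-of-range values
#' are clipped to `[0, 1]` and counted in `attr(,"n_clipped")`.
#'
#' @param curve A [fit_standard_curve()] result with non-zero slope.
#' @param heights Measured peak heights.
#' @return Proportions in `[0, 1]`.
#' @export
estimate_proportions <- function(curve, heights) {
  if (curve$slope == 0) stop("standard curve has zero slope", call. = FALSE)
  p <- (heights - curve$intercept) / curve$slope
  clipped <- p < 0 | p > 1
  out <- pmin(pmax(p, 0), 1)
  attr(out, "n_clipped") <- sum(clipped)
  out
}

#' Fruiting-body relatedness r_fb
#'
#' For fruiting-body proportions \eqn{p_i} of a focal strain with sample
#' mean \eqn{\bar p}, each strain's relatedness in body i is its frequency
#' deviation scaled by the maximum possible deviation
#' (\eqn{r_i = (p_i - \bar p)/(1 - \bar p)} for the focal strain,
#' \eqn{r_i' = (\bar p - p_i)/\bar p} for the other). Weighting each body's
#' two relatedness values by the strain fractions and averaging over bodies
#' gives the global statistic
#' \deqn{r_{fb} = \frac{1}{N}\sum_i \left[ p_i\frac{p_i-\bar p}{1-\bar p}
#'   + (1-p_i)\frac{\bar p - p_i}{\bar p} \right],}
#' which is 0 for random clustering and 1 for complete segregation.
#'
#' @param p_list Fruiting-body proportions of the focal strain (>= 2
#'   bodies, values in `[0, 1]`).
#' @return r_fb, or `NA` with a warning when one strain is absent from
#'   every fruiting body (`mean(p)` is 0 or 1).
#' @export
fruiting_body_relatedness <- function(p_list) {
  if (length(p_list) < 2) stop("need at least 2 fruiting bodies", call. = FALSE)
  if (any(p_list < 0 | p_list > 1)) stop("proportions must lie in [0, 1]",
                                         call. = FALSE)
  pbar <- mean(p_list)
  if (pbar <= 0 || pbar >= 1) {
    warning("one strain absent from all fruiting bodies; r_fb undefined")
    return(NA_real_)
  }
  mean(p_list * (p_list - pbar) / (1 - pbar) +
         (1 - p_list) * (pbar - p_list) / pbar)
}

#' Dominance of a focal strain in chimeric fruiting bodies
#'
#' `d = mean(p_i) - p_o`: the excess of the strain's mean fruiting-body
#' proportion over its measured initial-mix proportion. Antisymmetric in
#' the focal strain.
#'
#' @param p_list Fruiting-body proportions of the focal strain (non-empty).
#' @param p_o Initial-mix proportion in `(0, 1)`.
#' @return List with `d` (signed) and `abs_d`.
#' @export
dominance <- function(p_list, p_o) {
  if (!length(p_list)) stop("empty fruiting-body list", call. = FALSE)
  if (p_o <= 0 || p_o >= 1) stop("p_o must lie strictly in (0, 1)", call. = FALSE)
  d <- mean(p_list) - p_o
  list(d = d, abs_d = abs(d))
}

#' Levene's statistic of individual deviation
#'
#' Mean absolute deviation of fruiting-body proportions from their mean.
#'
#' @param p_list Proportions (>= 2 values).
#' @return LS.
#' @export
levene_statistic <- function(p_list) {
  if (length(p_list) < 2) stop("need at least 2 values", call. = FALSE)
  mean(abs(p_list - mean(p_list)))
}

#' Variance of the arcsine square-root transform
#'
#' Sample variance (n - 1 denominator) of `asin(sqrt(x))` over
#' fruiting-body proportions; the variance-stabilized dispersion measure.
#'
#' @param p_list Proportions in `[0, 1]` (>= 2 values).
#' @return The variance.
#' @export
arcsine_variance <- function(p_list) {
  if (any(p_list < 0 | p_list > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (length(p_list) < 2) stop("need at least 2 values", call. = FALSE)
  var(asin(sqrt(p_list)))
}

#' Per-pair social statistics from a chimera experiment table
#'
#' Expects the long-format experiment table (columns `pair`, `marker`,
#' `replicate`, `fruiting_body`, `proportion`, `p_o`): computes r_fb,
#' signed and absolute dominance, LS and the arcsine variance per
#' marker x replicate, then averages marker-level values within pairs
#' (means with standard errors over marker x replicate cells).
#'
#' @param experiment Data frame as above (see [simulate_chimera()] and
#'   [read_chimera_csv()]).
#' @return Data frame of class `social_stats`, one row per pair: `r_fb`,
#'   `r_fb_se`, `d`, `abs_d`, `abs_d_se`, `levene`, `arcsine_var`,
#'   `n_cells`.
#' @export
social_statistics <- function(experiment) {
  need <- c("pair", "marker", "replicate", "fruiting_body", "proportion", "p_o")
  if (!all(need %in% names(experiment))) {
    stop("experiment table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  cells <- unique(experiment[c("pair", "marker", "replicate")])
  per_cell <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- merge(cells[i, , drop = FALSE], experiment)
    dom <- dominance(sub$proportion, sub$p_o[1])
    data.frame(cells[i, , drop = FALSE],
               r_fb = fruiting_body_relatedness(sub$proportion),
               d = dom$d, abs_d = dom$abs_d,
               levene = levene_statistic(sub$proportion),
               arcsine_var = arcsine_variance(sub$proportion))
  }))
  se <- function(x) sd(x) / sqrt(length(x))
  out <- do.call(rbind, lapply(split(per_cell, per_cell$pair), function(s) {
    data.frame(pair = s$pair[1],
               r_fb = mean(s$r_fb), r_fb_se = se(s$r_fb),
               d = mean(s$d),
               abs_d = mean(s$abs_d), abs_d_se = se(s$abs_d),
               levene = mean(s$levene),
               arcsine_var = mean(s$arcsine_var),
               n_cells = nrow(s))
  }))
  rownames(out) <- NULL
  attr(out, "per_cell") <- per_cell
  class(out) <- c("social_stats", "data.frame")
  out
}

#' Read a chimera experiment CSV
#'
#' Columns `pair`, `marker`, `replicate`, `fruiting_body`, `proportion`
#' (or `measurement` plus a standard curve applied upstream), `p_o`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_chimera_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pair", "marker", "replicate", "fruiting_body", "proportion", "p_o")
  if (!all(need %in% names(tab))) {
    stop("chimera CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab
}

#' Compare social statistics between strain-pair groups
#'
#' Three analyses over per-pair statistics: (1) a one-sided permutation
#' test of the sympatric minus allopatric difference in group means of
#' r_fb (and of |d|); (2) OLS regressions of r_fb and |d| on pairwise SNP
#' divergence, with R-squared; (3) a partition at the sample median
#' divergence into low/high groups with summaries.
#'
#' @param stats A [social_statistics()] data frame.
#' @param sympatric Logical vector per pair (`TRUE` = same collection site).
#' @param divergence Pairwise SNP divergence per pair (counts).
#' @param n_perm Permutations for the group test (default 1000).
#' @param seed RNG seed.
#' @return List of class `social_comparison`.
#' @export
compare_groups <- function(stats, sympatric, divergence, n_perm = 1000,
                           seed = NULL) {
  stopifnot(nrow(stats) == length(sympatric),
            nrow(stats) == length(divergence))
  if (!any(sympatric) || all(sympatric)) {
    stop("both sympatric and allopatric pairs are required", call. = FALSE)
  }
  perm_diff_test <- function(y) {
    obs <- mean(y[sympatric]) - mean(y[!sympatric])
    hits <- 0L
    for (k in seq_len(n_perm)) {
      g <- sample(sympatric)
      if (mean(y[g]) - mean(y[!g]) >= obs) hits <- hits + 1L
    }
    list(diff = obs, p_value = perm_pvalue(hits, n_perm),
         mean_sympatric = mean(y[sympatric]),
         mean_allopatric = mean(y[!sympatric]))
  }
  reg <- function(y) {
    fit <- lm(y ~ divergence)
    sst <- sum((y - mean(y))^2)
    list(slope = unname(coef(fit)[2]),
         r_squared = if (sst > 0) 1 - sum(fit$residuals^2) / sst else NA_real_)
  }
  med <- median(divergence)
  low <- divergence < med
  with_seed(seed, {
    structure(list(
      r_fb_test = perm_diff_test(stats$r_fb),
      abs_d_test = perm_diff_test(stats$abs_d),
      r_fb_regression = reg(stats$r_fb),
      abs_d_regression = reg(stats$abs_d),
      median_divergence = med,
      partition = data.frame(
        group = c("low", "high"),
        n = c(sum(low), sum(!low)),
        r_fb = c(mean(stats$r_fb[low]), mean(stats$r_fb[!low])),
        abs_d = c(mean(stats$abs_d[low]), mean(stats$abs_d[!low])))),
      class = "social_comparison")
  })
}
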