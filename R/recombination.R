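# Recombination inference: four-gamete incompatibilities and the
# Hudson-Kaplan minimum recombination count, a moment estimator of the
# population recombination parameter rho from the variance of pairwise
# differences, and a pairwise composite-likelihood estimator of rho backed
# by a Monte-Carlo two-locus sampling-probability table, with a likelihood
# permutation test of rho > 0.

# complete-case two-locus haplotype counts for all site pairs
pair_counts <- function(g) {
  M <- !is.na(g)
  g0 <- g; g0[!M] <- 0L
  n11 <- tcrossprod(g0)
  n1c <- tcrossprod(g0, M)
  nn <- tcrossprod(M * 1L)
  list(n11 = n11, n10 = n1c - n11, n01 = t(n1c) - n11,
       n00 = nn - n1c - t(n1c) + n11, nn = nn)
}

#' Four-gamete incompatibility between two sites
#'
#' TRUE iff all four haplotypes (00, 01, 10, 11) occur among complete-case
#' strains, which under infinite sites implies a recombination event
#' between the sites.
#'
#' @param matrix A [snp_matrix()].
#' @param site_i,site_j Site indices.
#' @return Logical.
#' @export
incompatible <- function(matrix, site_i, site_j) {
  stop_if_not_snp_matrix(matrix)
  pc <- pair_counts(matrix$geno[c(site_i, site_j), , drop = FALSE])
  pc$n00[1, 2] > 0 && pc$n01[1, 2] > 0 && pc$n10[1, 2] > 0 && pc$n11[1, 2] > 0
}

#' Minimum number of recombination events (Hudson-Kaplan Rm)
#'
#' Collects all four-gamete-incompatible site pairs as candidate
#' breakpoint intervals (per chromosome), discards intervals that contain
#' another, and greedily selects non-overlapping intervals scanning by
#' right endpoint. Rm is the number selected; disjoint intervals may share
#' an endpoint site because breakpoints fall strictly between sites.
#'
#' @param matrix A [snp_matrix()] (sites are coordinate-sorted by
#'   construction).
#' @return List of class `rm_result`: `rm` and `intervals` (data frame of
#'   chromosome, flanking site indices and bp positions).
#' @export
minimum_recombination_events <- function(matrix) {
  stop_if_not_snp_matrix(matrix)
  total <- 0L
  ivs <- list()
  for (ch in unique(matrix$chrom)) {
    idx <- which(matrix$chrom == ch)
    if (length(idx) < 2) next
    pc <- pair_counts(matrix$geno[idx, , drop = FALSE])
    inc <- pc$n00 > 0 & pc$n01 > 0 & pc$n10 > 0 & pc$n11 > 0
    pr <- which(inc & upper.tri(inc), arr.ind = TRUE)
    if (!nrow(pr)) next
    l <- pr[, 1]; r <- pr[, 2]
    # drop intervals containing another incompatible interval
    minimal <- vapply(seq_along(l), function(a) {
      !any(l >= l[a] & r <= r[a] & (l > l[a] | r < r[a]))
    }, logical(1))
    l <- l[minimal]; r <- r[minimal]
    ord <- order(r, l)
    l <- l[ord]; r <- r[ord]
    last <- -Inf; sel <- logical(length(l))
    for (a in seq_along(l)) {
      if (l[a] >= last) { sel[a] <- TRUE; last <- r[a] }
    }
    total <- total + sum(sel)
    ivs[[ch]] <- data.frame(chrom = ch,
                            left_site = idx[l[sel]], right_site = idx[r[sel]],
                            left_pos = matrix$pos[idx[l[sel]]],
                            right_pos = matrix$pos[idx[r[sel]]])
  }
  intervals <- if (length(ivs)) do.call(rbind, ivs) else
    data.frame(chrom = character(), left_site = integer(),
               right_site = integer(), left_pos = integer(),
               right_pos = integer())
  rownames(intervals) <- NULL
  structure(list(rm = total, intervals = intervals), class = "rm_result")
}

#' @export
print.rm_result <- function(x, ...) {
  cat(sprintf("<rm_result> Rm = %d (%d breakpoint interval(s))\n",
              x$rm, nrow(x$intervals)))
  invisible(x)
}

# Griffiths two-locus coalescence-time covariance for a pair of sequences
# at scaled recombination distance rho (Cov = Corr since Var(T) = 1).
two_locus_time_cov <- function(rho) (rho + 18) / (rho^2 + 13 * rho + 18)

#' Moment estimator of rho from the variance of pairwise differences
#'
#' Equates the observed sample variance of pairwise difference counts to
#' its coalescent expectation as a function of the region-wide rho:
#' \eqn{Var(K) = \bar K + \sum_s \theta_s^2 + \sum_{s \ne s'} \theta_s
#' \theta_{s'} C(\rho d_{ss'}/span)} with the standard two-locus
#' coalescence-time covariance \eqn{C(\rho) = (\rho+18)/(\rho^2+13\rho+18)}
#' and per-site rates \eqn{\theta_s = \bar K / S} spread over the observed
#' site positions (the distance-weighted summation). Solved by bisection;
#' boundary estimates are flagged.
#'
#' @param matrix A [snp_matrix()] on a single chromosome
#'   (n >= 4 strains, S >= 2 sites).
#' @param span Total span in bp that `rho` refers to.
#' @param rho_max Upper end of the bisection bracket (default 1e4).
#' @param tol Bisection tolerance on rho (default 1e-3).
#' @return List: `rho` (the estimate), `flag` (`"ok"`,
#'   `"no_recombination_signal"` when the observed variance reaches the
#'   rho = 0 expectation, or `"upper_boundary"`), `obs_var`.
#' @export
wakeley_rho <- function(matrix, span, rho_max = 1e4, tol = 1e-3) {
  stop_if_not_snp_matrix(matrix)
  if (length(unique(matrix$chrom)) > 1) {
    stop("moment estimator expects a single-chromosome matrix", call. = FALSE)
  }
  if (n_strains(matrix) < 4) stop("need n >= 4 strains", call. = FALSE)
  S <- n_sites(matrix)
  if (S < 2) return(list(rho = NA_real_, flag = "undefined", obs_var = NA_real_))
  pd <- pairwise_differences(matrix)
  K <- scaled_pair_diffs(pd, S)
  obs_var <- var(K)
  kbar <- mean(K)
  th <- kbar / S
  d <- abs(outer(matrix$pos, matrix$pos, "-"))
  dv <- d[upper.tri(d)]
  model_var <- function(rho) {
    kbar + th^2 * (S + 2 * sum(two_locus_time_cov(rho * dv / span)))
  }
  if (obs_var >= model_var(0)) {
    return(list(rho = 0, flag = "no_recombination_signal", obs_var = obs_var))
  }
  if (obs_var <= model_var(rho_max)) {
    return(list(rho = rho_max, flag = "upper_boundary", obs_var = obs_var))
  }
  lo <- 0; hi <- rho_max
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (model_var(mid) > obs_var) lo <- mid else hi <- mid
  }
  list(rho = (lo + hi) / 2, flag = "ok", obs_var = obs_var)
}

# Encode a 4-count configuration as a single integer and fold it over the
# 8 symmetries (allele swap at either locus, locus exchange).
config_codes <- function(cfg, n) {
  # cfg: matrix with columns n00, n01, n10, n11
  K <- n + 1
  enc <- function(a, b, c, d) ((a * K + b) * K + c) * K + d
  with(list(a = cfg[, 1], b = cfg[, 2], c = cfg[, 3], d = cfg[, 4]), {
    cand <- cbind(enc(a, b, c, d),  # identity
                  enc(c, d, a, b),  # swap allele at locus A
                  enc(b, a, d, c),  # swap allele at locus B
                  enc(d, c, b, a),  # swap both
                  enc(a, c, b, d),  # exchange loci
                  enc(b, d, a, c),
                  enc(c, a, d, b),
                  enc(d, b, c, a))
    do.call(pmin, as.data.frame(cand))
  })
}

decode_config <- function(code, n) {
  K <- n + 1
  d <- code %% K; code <- code %/% K
  c3 <- code %% K; code <- code %/% K
  b <- code %% K; a <- code %/% K
  cbind(n00 = a, n01 = b, n10 = c3, n11 = d)
}

#' Build a Monte-Carlo two-locus sampling-probability table
#'
#' For each grid value of the per-pair scaled recombination rate rho,
#' simulates two-locus genealogies, places one mutation per locus on the
#' marginal tree conditional on segregation, and tabulates folded
#' two-locus haplotype configuration frequencies. This table supplies the
#' per-pair likelihoods for [composite_rho()].
#'
#' @param n Sample size (4..64).
#' @param rho_grid Per-pair rho grid including 0 (default 21 points on
#'   `[0, 100]`).
#' @param n_sims Monte-Carlo replicates per grid point (default 1e5).
#' @param seed RNG seed.
#' @return Object of class `two_locus_table`: `n`, `rho_grid`, `codes`
#'   (folded configuration codes), `configs` (their canonical counts),
#'   `probs` (configurations x grid), `n_sims`, `seed`.
#' @export
build_two_locus_table <- function(n, rho_grid = seq(0, 100, length.out = 21),
                                  n_sims = 1e5, seed = NULL) {
  if (!0 %in% rho_grid) stop("rho_grid must include 0", call. = FALSE)
  rho_grid <- sort(unique(rho_grid))
  with_seed(seed, {
    counts <- list()
    for (gi in seq_along(rho_grid)) {
      cfg <- cpp_two_locus_configs(n, rho_grid[gi], as.integer(n_sims))
      codes <- config_codes(cfg, n)
      counts[[gi]] <- table(codes)
    }
    all_codes <- sort(unique(as.numeric(unlist(lapply(counts, names)))))
    probs <- matrix(0, length(all_codes), length(rho_grid))
    for (gi in seq_along(rho_grid)) {
      idx <- match(as.numeric(names(counts[[gi]])), all_codes)
      probs[idx, gi] <- as.numeric(counts[[gi]]) / n_sims
    }
    if (any(colSums(probs) == 0)) {
      warning("all-zero probability column(s) at grid point(s): ",
              paste(rho_grid[colSums(probs) == 0], collapse = ", "))
    }
    structure(list(n = n, rho_grid = rho_grid, codes = all_codes,
                   configs = decode_config(all_codes, n), probs = probs,
                   n_sims = n_sims, seed = seed),
              class = "two_locus_table")
  })
}

#' @export
print.two_locus_table <- function(x, ...) {
  cat(sprintf("<two_locus_table> n=%d, %d configurations, grid [%g, %g] (%d points), %g sims/point\n",
              x$n, length(x$codes), min(x$rho_grid), max(x$rho_grid),
              length(x$rho_grid), x$n_sims))
  invisible(x)
}

# Map observed complete-case pair configurations to table rows.
# Exact folded match when available; otherwise the configuration is scaled
# to the table's sample size and matched to the nearest stored canonical
# configuration (fallbacks counted).
match_configs <- function(cfg, table) {
  n <- table$n
  m <- rowSums(cfg)
  scaled <- cfg
  off <- which(m != n & m > 0)
  for (a in off) {
    v <- round(cfg[a, ] * n / m[a])
    excess <- sum(v) - n
    if (excess != 0) {
      j <- which.max(v)
      v[j] <- v[j] - excess
    }
    scaled[a, ] <- v
  }
  codes <- config_codes(scaled, n)
  idx <- match(codes, table$codes)
  fallback <- is.na(idx)
  if (any(fallback)) {
    canon <- decode_config(codes[fallback], n)
    tc <- table$configs
    for (a in seq_len(sum(fallback))) {
      dd <- rowSums((tc - matrix(canon[a, ], nrow(tc), 4, byrow = TRUE))^2)
      idx[which(fallback)[a]] <- which.min(dd)
    }
  }
  list(idx = idx, n_fallback = sum(fallback))
}

# log-likelihood interpolation over the table grid at per-pair rho values
interp_loglik <- function(LL, tg, rp) {
  i <- pmin(pmax(findInterval(rp, tg), 1L), length(tg) - 1L)
  w <- (rp - tg[i]) / (tg[i + 1] - tg[i])
  w <- pmin(pmax(w, 0), 1)
  rows <- seq_len(nrow(LL))
  LL[cbind(rows, i)] * (1 - w) + LL[cbind(rows, i + 1L)] * w
}

# Pairwise composite log-likelihood curve over a grid of region-level rho.
composite_curve <- function(LL, tg, dist, total_span, grid) {
  cap <- tg[length(tg)]
  vapply(grid, function(r) {
    sum(interp_loglik(LL, tg, pmin(r * dist / total_span, cap)))
  }, 0)
}

#' Composite-likelihood estimate of the population recombination rate
#'
#' Pairwise composite likelihood in the spirit of the Hudson/McVean
#' two-locus approach: each SNP pair contributes the log probability of
#' its folded haplotype configuration at per-pair rate
#' `rho_T * d_ij / total_span` (crossing-over linear in bp distance),
#' interpolated from a Monte-Carlo [build_two_locus_table()]. The estimate
#' is the grid argmax of the summed curve.
#'
#' @param matrix A MAF-filtered [snp_matrix()] on a single chromosome.
#' @param table A [build_two_locus_table()] result for the panel size.
#' @param total_span Span in bp that the region-level rho refers to; must
#'   be >= every pair distance.
#' @param grid Region-level rho grid (default 21 points on `[0, 100]`).
#' @return Object of class `rho_estimate`: `rho_hat`, `grid`, `loglik`
#'   (composite log-likelihood curve), `n_pairs`, `n_fallback`,
#'   `p_value` (NULL until [likelihood_permutation_test()] is run).
#' @export
composite_rho <- function(matrix, table, total_span,
                          grid = seq(0, 100, length.out = 21)) {
  stop_if_not_snp_matrix(matrix)
  if (length(unique(matrix$chrom)) > 1) {
    stop("composite likelihood expects a single-chromosome matrix", call. = FALSE)
  }
  S <- n_sites(matrix)
  if (S < 2) stop("need at least 2 sites", call. = FALSE)
  pc <- pair_counts(matrix$geno)
  up <- which(upper.tri(pc$nn), arr.ind = TRUE)
  cfg <- cbind(pc$n00[up], pc$n01[up], pc$n10[up], pc$n11[up])
  d <- abs(matrix$pos[up[, 2]] - matrix$pos[up[, 1]])
  if (any(d > total_span)) stop("pair distance exceeds total_span", call. = FALSE)
  # pairs monomorphic in complete cases carry no two-locus information
  poly <- (cfg[, 1] + cfg[, 2] > 0) & (cfg[, 3] + cfg[, 4] > 0) &
    (cfg[, 1] + cfg[, 3] > 0) & (cfg[, 2] + cfg[, 4] > 0)
  cfg <- cfg[poly, , drop = FALSE]; d <- d[poly]
  mm <- match_configs(cfg, table)
  floorp <- 0.5 / table$n_sims
  LL <- log(pmax(table$probs[mm$idx, , drop = FALSE], floorp))
  curve <- composite_curve(LL, table$rho_grid, d, total_span, grid)
  structure(list(rho_hat = grid[which.max(curve)], grid = grid,
                 loglik = curve, n_pairs = nrow(cfg),
                 n_fallback = mm$n_fallback,
                 table_grid = table$rho_grid,
                 pair_dist = d, pair_loglik = LL,
                 total_span = total_span, p_value = NULL),
            class = "rho_estimate")
}

#' @export
print.rho_estimate <- function(x, ...) {
  cat(sprintf("<rho_estimate> rho_hat = %.4g (%d pairs, %d table fallbacks)\n",
              x$rho_hat, x$n_pairs, x$n_fallback))
  if (!is.null(x$p_value)) cat(sprintf("  permutation p = %.4g\n", x$p_value))
  invisible(x)
}

#' Likelihood permutation test that rho exceeds zero
#'
#' Permutes SNP physical positions while holding genotype columns fixed
#' and re-maximizes the composite likelihood for each permutation. Under
#' no recombination the likelihood is independent of the physical
#' arrangement of sites, so the observed maximized composite likelihood
#' is exchangeable with the permuted ones; genuine distance-dependent LD
#' makes the observed arrangement fit better than permuted ones. The
#' default statistic is therefore the maximized composite log-likelihood,
#' \eqn{p = (1 + \#\{L_{perm} \ge L_{obs}\}) / (n_{perm}+1)}; the
#' re-maximized \eqn{\hat\rho} itself is available as an alternative
#' statistic (compared in the same direction), but permuting positions
#' tends to inflate \eqn{\hat\rho}, which leaves that variant with little
#' power against recombination.
#'
#' @param matrix The [snp_matrix()] passed to [composite_rho()].
#' @param table The same [build_two_locus_table()].
#' @param total_span Same span as in [composite_rho()].
#' @param n_perm Number of permutations (study default 1000).
#' @param seed RNG seed.
#' @param grid Region-level rho grid.
#' @param statistic `"likelihood"` (default) or `"rho"`.
#' @return The [composite_rho()] estimate with `p_value`, `perm_stat`
#'   (permuted statistics) and `statistic` filled in.
#' @export
likelihood_permutation_test <- function(matrix, table, total_span,
                                        n_perm = 1000, seed = NULL,
                                        grid = seq(0, 100, length.out = 21),
                                        statistic = c("likelihood", "rho")) {
  statistic <- match.arg(statistic)
  if (length(unique(matrix$pos)) < 2) {
    stop("permutation test undefined with fewer than 2 distinct positions",
         call. = FALSE)
  }
  est <- composite_rho(matrix, table, total_span, grid)
  pc <- pair_counts(matrix$geno)
  up <- which(upper.tri(pc$nn), arr.ind = TRUE)
  # recompute the polymorphic-pair index set exactly as composite_rho did
  cfg <- cbind(pc$n00[up], pc$n01[up], pc$n10[up], pc$n11[up])
  poly <- (cfg[, 1] + cfg[, 2] > 0) & (cfg[, 3] + cfg[, 4] > 0) &
    (cfg[, 1] + cfg[, 3] > 0) & (cfg[, 2] + cfg[, 4] > 0)
  ii <- up[poly, 1]; jj <- up[poly, 2]
  obs <- if (statistic == "likelihood") max(est$loglik) else est$rho_hat
  with_seed(seed, {
    hits <- 0L
    perm_stat <- numeric(n_perm)
    for (k in seq_len(n_perm)) {
      p <- sample(matrix$pos)
      d <- abs(p[jj] - p[ii])
      curve <- composite_curve(est$pair_loglik, est$table_grid, d,
                               total_span, grid)
      perm_stat[k] <- if (statistic == "likelihood") max(curve)
                      else grid[which.max(curve)]
      if (perm_stat[k] >= obs) hits <- hits + 1L
    }
    est$p_value <- perm_pvalue(hits, n_perm)
    est$perm_stat <- perm_stat
    est$statistic <- statistic
    est
  })
}
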