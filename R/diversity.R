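# Classical diversity statistics for haploid SNP panels.
#
# Missing-data policy: pairwise deletion for pi and pairwise differences
# (each pair's raw mismatch count is rescaled by S / jointly-callable
# sites); for theta_W, S counts sites biallelic among non-missing calls and
# L is the total surveyed length. Tajima's D constants use the panel n, not
# per-site n (a logged approximation, negligible at sporadic missingness).

#' Watterson's estimator of the scaled mutation rate
#'
#' \eqn{\theta_W = S / (a_n L)} per site, with
#' \eqn{a_n = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S Number of segregating sites.
#' @param n Number of strains (>= 2).
#' @param L Surveyed length in bp (> 0).
#' @return Per-site estimate (0 when `S = 0`).
#' @export
watterson_theta <- function(S, n, L) {
  if (n < 2) stop("need at least 2 strains", call. = FALSE)
  if (L <= 0) stop("surveyed length must be positive", call. = FALSE)
  S / (harmonic_a(n) * L)
}

#' Pairwise difference matrix
#'
#' Counts of differing sites for every strain pair over jointly non-missing
#' sites, plus the per-pair count of jointly callable sites. This houses the
#' pairwise SNP divergence `d` used when relating social statistics to
#' sequence divergence.
#'
#' @param matrix A [snp_matrix()].
#' @return List of class `pairwise_diff` with symmetric matrices `diff`
#'   (mismatch counts) and `callable` (jointly non-missing sites).
#' @export
pairwise_differences <- function(matrix) {
  stop_if_not_snp_matrix(matrix)
  g <- matrix$geno
  M <- !is.na(g)
  g0 <- g; g0[!M] <- 0L
  # mismatches = #[i=1,j=0] + #[i=0,j=1] over jointly called sites
  n11 <- crossprod(g0)
  n1c <- crossprod(g0, M)          # i minor, j called
  nn <- crossprod(M)
  d <- n1c + t(n1c) - 2 * n11
  diag(d) <- 0
  dimnames(d) <- dimnames(nn) <- list(matrix$strains, matrix$strains)
  structure(list(diff = d, callable = nn, strains = matrix$strains),
            class = "pairwise_diff")
}

# per-pair difference counts rescaled to the full site panel:
# d_ij * S / c_ij (equals raw counts when nothing is missing)
scaled_pair_diffs <- function(pd, S) {
  up <- upper.tri(pd$diff)
  d <- pd$diff[up]; cc <- pd$callable[up]
  bad <- cc == 0
  if (any(bad & S > 0)) {
    warning(sum(bad), " strain pair(s) with no jointly-callable sites excluded")
  }
  keep <- !bad | S == 0
  ifelse(cc[keep] > 0, d[keep] * S / cc[keep], 0)
}

#' Nucleotide diversity (pi)
#'
#' Mean over strain pairs of the per-pair difference count (missing data by
#' pairwise deletion, rescaled to the full site panel), divided by the
#' surveyed length `L`.
#'
#' @param matrix A [snp_matrix()].
#' @param L Surveyed length in bp.
#' @return Per-site pi.
#' @export
nucleotide_diversity <- function(matrix, L) {
  stop_if_not_snp_matrix(matrix)
  if (n_strains(matrix) < 2) stop("need at least 2 strains", call. = FALSE)
  S <- n_sites(matrix)
  if (S == 0) return(0)
  pd <- pairwise_differences(matrix)
  mean(scaled_pair_diffs(pd, S)) / L
}

# Tajima (1989) normalizing constants from the sample size alone.
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' \eqn{D = (\pi_{tot} - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} with the 1989
#' constants computed from the panel size; \eqn{\pi_{tot}} is the mean
#' pairwise difference count (not per site). Undefined (NA) when `S = 0`,
#' matching the convention that invariant fragments carry no D.
#'
#' @param matrix A [snp_matrix()].
#' @return Tajima's D, or `NA` if no site segregates.
#' @export
tajimas_d <- function(matrix) {
  stop_if_not_snp_matrix(matrix)
  S <- n_sites(matrix)
  if (S == 0) return(NA_real_)
  n <- n_strains(matrix)
  k <- tajima_constants(n)
  pd <- pairwise_differences(matrix)
  pi_tot <- mean(scaled_pair_diffs(pd, S))
  (pi_tot - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Hudson's Fst between two strain groups
#'
#' \eqn{F_{st} = 1 - H_w / H_b} where `H_w` is the mean within-group
#' per-pair diversity (the two group means averaged) and `H_b` the mean
#' between-group diversity, all from pairwise-deletion difference counts.
#'
#' @param matrix A [snp_matrix()].
#' @param group1,group2 Character vectors of strain ids (each >= 2 strains).
#' @return Fst, or `NA` (with a warning) when `H_b = 0`.
#' @export
hudson_fst <- function(matrix, group1, group2) {
  stop_if_not_snp_matrix(matrix)
  if (length(group1) < 2 || length(group2) < 2) {
    stop("each group needs at least 2 strains", call. = FALSE)
  }
  if (length(intersect(group1, group2))) stop("groups overlap", call. = FALSE)
  miss <- setdiff(c(group1, group2), matrix$strains)
  if (length(miss)) stop("unknown strains: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  S <- n_sites(matrix)
  pd <- pairwise_differences(matrix)
  rate <- function(i, j) {
    d <- pd$diff[i, j, drop = FALSE]; cc <- pd$callable[i, j, drop = FALSE]
    ifelse(cc > 0, d * ifelse(S > 0, S / cc, 0), NA)
  }
  within_mean <- function(g) {
    m <- rate(g, g)
    mean(m[upper.tri(m)], na.rm = TRUE)
  }
  hw <- (within_mean(group1) + within_mean(group2)) / 2
  hb <- mean(rate(group1, group2), na.rm = TRUE)
  if (!is.finite(hb) || hb == 0) {
    warning("between-group diversity is zero; Fst undefined")
    return(NA_real_)
  }
  1 - hw / hb
}

#' SNP spacing and expected genome-wide divergence
#'
#' Two headline summaries: the mean inter-SNP spacing `L/S` and the
#' expected number of genome-wide pairwise SNP differences
#' `pi * genome_size`.
#'
#' @param S Segregating sites in the surveyed region.
#' @param L Surveyed length in bp.
#' @param pi Per-site nucleotide diversity.
#' @param genome_size Genome length in bp (34 Mb for the amoeba assembly).
#' @return List with `snp_spacing_bp` (`NA` when `S = 0`) and
#'   `expected_genome_diff`.
#' @export
genome_summaries <- function(S, L, pi, genome_size) {
  list(snp_spacing_bp = if (S > 0) L / S else NA_real_,
       expected_genome_diff = pi * genome_size)
}

#' Pooled and per-fragment diversity summary
#'
#' Table-1-style pooled statistics (S, theta_W, pi, Tajima's D over the
#' whole panel) plus the per-fragment breakdown used for histogram-style
#' summaries. Both a pooled theta_W and the mean of per-fragment values are
#' reported, since either bookkeeping is defensible for multi-fragment
#' panels.
#'
#' @param fragments List of [fragment_alignment()] objects.
#' @return List of class `diversity_summary` with elements `pooled` and
#'   `per_fragment` (data frame).
#' @export
diversity_summary <- function(fragments) {
  mat <- call_snps(fragments)
  n <- n_strains(mat)
  L <- sum(vapply(fragments, `[[`, 0L, "length"))
  S <- n_sites(mat)
  per <- do.call(rbind, lapply(fragments, function(f) {
    m <- call_snps(list(f))
    s <- n_sites(m)
    # pairs missing a short fragment entirely are routine here; the
    # per-pair exclusion warning stays on the exported per-call surface
    suppressWarnings(data.frame(
      fragment_id = f$fragment_id,
      chromosome = f$chromosome,
      L = f$length, S = s,
      theta_w = watterson_theta(s, n, f$length),
      pi = nucleotide_diversity(m, f$length),
      tajima_d = if (s > 0) tajimas_d(m) else NA_real_))
  }))
  pooled <- list(n = n, L = L, S = S,
                 theta_w = watterson_theta(S, n, L),
                 theta_w_fragment_mean = mean(per$theta_w),
                 pi = nucleotide_diversity(mat, L),
                 tajima_d = tajimas_d(mat),
                 tajima_d_fragment_mean = mean(per$tajima_d, na.rm = TRUE))
  structure(list(pooled = pooled, per_fragment = per),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  p <- x$pooled
  cat(sprintf("<diversity_summary> n=%d  L=%d bp  S=%d\n", p$n, p$L, p$S))
  cat(sprintf("  theta_W=%.3g  pi=%.3g  Tajima's D=%.4f (fragment mean %.4f)\n",
              p$theta_w, p$pi, p$tajima_d, p$tajima_d_fragment_mean))
  invisible(x)
}
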