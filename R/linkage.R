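# Linkage disequilibrium: pairwise r2, distance-decay profiling against an
# interchromosomal baseline, and the distance-permutation decay test.
#
# Conventions: the MAF filter is applied once, globally, before pair
# formation; haplotype counts per pair are complete-case (pairwise
# deletion); distance bins are left-closed, right-open in bp.

#' Minor-allele-frequency filter
#'
#' Retains sites whose minor-allele frequency among non-missing calls is at
#' least `threshold` (the LD and recombination analyses use 10%).
#'
#' @param matrix A [snp_matrix()].
#' @param threshold Frequency in `[0, 0.5]`; default 0.10.
#' @return Filtered [snp_matrix()].
#' @export
maf_filter <- function(matrix, threshold = 0.10) {
  stop_if_not_snp_matrix(matrix)
  g <- matrix$geno
  called <- rowSums(!is.na(g))
  minor <- rowSums(g == 1L, na.rm = TRUE)
  maf <- pmin(minor, called - minor) / called
  subset_sites(matrix, which(maf >= threshold))
}

#' Pairwise linkage disequilibrium (r2) between all SNP pairs
#'
#' For each site pair, complete-case haplotype counts
#' (n00, n01, n10, n11) give \eqn{D = p_{11} - p_1 q_1} and
#' \eqn{r^2 = D^2 / (p_1(1-p_1) q_1(1-q_1))}. Pairs with a monomorphic
#' complete-case margin are dropped (their count is reported in
#' `attr(,"n_dropped_monomorphic")`). Same-chromosome pairs carry their bp
#' distance; cross-chromosome pairs are flagged unlinked (`linked = FALSE`,
#' `dist = NA`).
#'
#' @param matrix A [snp_matrix()] (usually MAF-filtered), >= 2 sites.
#' @return Data frame of class `ld_pairs`: `site_i`, `site_j`, `chrom_i`,
#'   `chrom_j`, `dist`, `linked`, `n` (complete cases), `r2`.
#' @export
pairwise_r2 <- function(matrix) {
  stop_if_not_snp_matrix(matrix)
  S <- n_sites(matrix)
  if (S < 2) stop("need at least 2 retained sites", call. = FALSE)
  g <- matrix$geno
  M <- !is.na(g)
  g0 <- g; g0[!M] <- 0L
  n11 <- tcrossprod(g0)                   # both minor among jointly called
  n1c <- tcrossprod(g0, M)                # i minor & j called
  nn <- tcrossprod(M * 1L)
  up <- which(upper.tri(nn), arr.ind = TRUE)
  i <- up[, 1]; j <- up[, 2]
  n <- nn[up]
  x11 <- n11[up]
  x1c <- n1c[up]                           # minor at i among joint
  xc1 <- t(n1c)[up]                        # minor at j among joint
  p <- x1c / n; q <- xc1 / n; p11 <- x11 / n
  keep <- n > 0 & p > 0 & p < 1 & q > 0 & q < 1
  D <- p11 - p * q
  r2 <- D^2 / (p * (1 - p) * q * (1 - q))
  chrom_i <- matrix$chrom[i]; chrom_j <- matrix$chrom[j]
  linked <- chrom_i == chrom_j
  dist <- ifelse(linked, abs(matrix$pos[j] - matrix$pos[i]), NA_real_)
  out <- data.frame(site_i = i, site_j = j,
                    chrom_i = chrom_i, chrom_j = chrom_j,
                    dist = dist, linked = linked, n = n,
                    r2 = r2)[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ld_pairs", "data.frame")
  attr(out, "n_dropped_monomorphic") <- sum(!keep)
  out
}

#' Distance-binned LD decay profile with unlinked baseline
#'
#' Bins same-chromosome pairs into the study's distance classes
#' (<0.1 kb, 0.1-0.5 kb, 0.5-10 kb, 10-25 kb, 25-50 kb, 50-100 kb, 100 kb
#' steps to 1 Mb, then 1 Mb windows), computes per-bin mean r2 and pair
#' counts, and estimates the baseline from cross-chromosome (unlinked)
#' pairs: their mean r2 and 80th percentile. A bin is flagged `elevated`
#' only if it holds more than 10 pairs and its mean exceeds the unlinked
#' 80th percentile; with no unlinked pairs the baseline is `NA` and the
#' flags are withheld.
#'
#' @param pairs An `ld_pairs` data frame from [pairwise_r2()].
#' @param bin_edges Optional numeric vector of bp bin edges (left-closed,
#'   right-open); defaults to the study scheme extended to the data's span.
#' @return List of class `ld_profile`: `bins` (data frame), `baseline_mean`,
#'   `baseline_q80`, `n_unlinked`.
#' @export
ld_profile <- function(pairs, bin_edges = NULL) {
  linked <- pairs[pairs$linked, , drop = FALSE]
  unlinked <- pairs[!pairs$linked, , drop = FALSE]
  if (is.null(bin_edges)) {
    top <- max(linked$dist, 1e6, 0, na.rm = TRUE) + 1
    edges <- c(0, 100, 500, 1e4, 2.5e4, 5e4, seq(1e5, 1e6, by = 1e5))
    if (top > 2e6) edges <- c(edges, seq(2e6, by = 1e6,
                                         length.out = ceiling((top - 2e6) / 1e6) + 1))
    bin_edges <- c(edges[edges < top], top)
  }
  cut_idx <- findInterval(linked$dist, bin_edges, rightmost.closed = FALSE)
  nb <- length(bin_edges) - 1L
  mean_r2 <- count <- numeric(nb)
  for (b in seq_len(nb)) {
    v <- linked$r2[cut_idx == b]
    count[b] <- length(v)
    mean_r2[b] <- if (length(v)) mean(v) else NA_real_
  }
  if (nrow(unlinked) > 0) {
    base_mean <- mean(unlinked$r2)
    base_q80 <- as.numeric(quantile(unlinked$r2, 0.80, type = 7))
    elevated <- count > 10 & !is.na(mean_r2) & mean_r2 > base_q80
  } else {
    base_mean <- base_q80 <- NA_real_
    elevated <- rep(NA, nb)
  }
  structure(list(
    bins = data.frame(lower = bin_edges[-(nb + 1L)], upper = bin_edges[-1L],
                      n_pairs = count, mean_r2 = mean_r2, elevated = elevated),
    baseline_mean = base_mean,
    baseline_q80 = base_q80,
    n_unlinked = nrow(unlinked)), class = "ld_profile")
}

#' @export
print.ld_profile <- function(x, ...) {
  cat(sprintf("<ld_profile> baseline mean r2 = %.4g (80th pct %.4g, %d unlinked pairs)\n",
              x$baseline_mean, x$baseline_q80, x$n_unlinked))
  print(utils::head(x$bins, 12))
  invisible(x)
}

#' Permutation test for LD decay with distance
#'
#' Statistic: rank (Spearman) correlation of r2 with bp distance over
#' linked pairs (Pearson available via `method`); the null is built by
#' permuting distances across pairs. One-sided for decay (negative
#' correlation), with the add-one rule
#' \eqn{p = (1 + \#\{stat_{perm} \le stat_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param pairs An `ld_pairs` data frame (needs >= 10 linked pairs).
#' @param n_perm Number of permutations (study default 1000).
#' @param seed RNG seed.
#' @param method `"spearman"` (default, robust to the skewed r2
#'   distribution) or `"pearson"`.
#' @return List: `statistic` (observed correlation), `p_value`, `n_pairs`.
#' @export
ld_decay_permutation_test <- function(pairs, n_perm = 1000, seed = NULL,
                                      method = c("spearman", "pearson")) {
  method <- match.arg(method)
  linked <- pairs[pairs$linked, , drop = FALSE]
  if (nrow(linked) < 10) stop("need at least 10 linked pairs", call. = FALSE)
  r2 <- linked$r2; d <- linked$dist
  if (sd(r2) == 0) {
    return(list(statistic = NA_real_, p_value = 1, n_pairs = nrow(linked)))
  }
  xf <- function(v) if (method == "spearman") rank(v) else v
  rr <- xf(r2)
  obs <- cor(rr, xf(d))
  with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      stat <- cor(rr, xf(sample(d)))
      if (stat <= obs) hits <- hits + 1L
    }
    list(statistic = obs, p_value = perm_pvalue(hits, n_perm),
         n_pairs = nrow(linked))
  })
}
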