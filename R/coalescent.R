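# Hudson-style coalescent with recombination over a continuous chromosome,
# infinite-sites mutation restricted to declared mutable windows (the
# sequenced fragments). Time is in units of N generations for a haploid
# population: pairwise coalescence rate 1, per-lineage recombination rate
# rho/2 across the span, per-site mutation rate theta_site/2 per lineage,
# so E[pairwise diff/site] = theta_site and rho = 2*N*r.
#
# Lineages carry their ancestral material as disjoint (a, b] segments, each
# with a descendant-set bitmask; segments that reach their MRCA are
# dropped. Descendant sets are integer bitmasks, which limits panels to 30
# strains (far above the 25-strain study design this emulates).

# coverage helpers for a set of mutable [start, end] bp intervals:
# cov(x) = mutable bp below continuous coordinate x; inv() its inverse.
make_coverage <- function(intervals, span) {
  iv <- intervals[order(intervals[, 1]), , drop = FALSE]
  s <- iv[, 1] - 1
  e <- pmin(iv[, 2], span)
  cum <- c(0, cumsum(e - s))
  list(
    cov = function(x) {
      idx <- findInterval(x, s)
      out <- numeric(length(x))
      hit <- idx > 0
      ih <- idx[hit]
      out[hit] <- cum[ih] + pmin(pmax(x[hit] - s[ih], 0), e[ih] - s[ih])
      out
    },
    inv = function(u) {
      i <- findInterval(u, cum, rightmost.closed = TRUE)
      i <- pmin(pmax(i, 1L), length(s))
      s[i] + (u - cum[i])
    },
    total = cum[length(cum)])
}

# OR-merge two lineages' segment matrices (cols a, b, mask); drop regions
# whose union mask is 0 (non-ancestral) or `full` (reached MRCA).
merge_segments <- function(s1, s2, full) {
  pts <- sort(unique(c(s1[, 1], s1[, 2], s2[, 1], s2[, 2])))
  mid <- (pts[-1] + pts[-length(pts)]) / 2
  cover <- function(s) {
    idx <- findInterval(mid, s[, 1])
    m <- integer(length(mid))
    hit <- idx > 0
    hi <- idx[hit]
    inside <- mid[hit] < s[hi, 2]
    m[hit][inside] <- as.integer(s[hi, 3][inside])
    m
  }
  m <- bitwOr(cover(s1), cover(s2))
  keep <- m != 0L & m != full
  if (!any(keep)) return(matrix(numeric(), 0, 3))
  a <- pts[-length(pts)][keep]; b <- pts[-1][keep]; mk <- m[keep]
  # collapse contiguous runs with identical masks
  if (length(a) > 1) {
    runs <- cumsum(c(TRUE, !(a[-1] == b[-length(b)] & mk[-1] == mk[-length(mk)])))
    a <- tapply(a, runs, min); b <- tapply(b, runs, max)
    mk <- tapply(mk, runs, `[`, 1)
  }
  cbind(as.numeric(a), as.numeric(b), as.numeric(mk))
}

#' Simulate haplotypes under the coalescent with recombination
#'
#' Standard neutral-equilibrium ancestral-recombination-graph simulation
#' with infinite-sites mutations placed uniformly, producing haploid 0/1
#' haplotypes with bp positions. Mutations can be confined to `mutable`
#' windows so that a whole chromosome's recombination history is simulated
#' while only sequenced fragments accumulate polymorphism.
#'
#' @param n Number of haploid strains (2..30).
#' @param theta_site Scaled mutation rate per bp (`2 N mu`).
#' @param rho_total Scaled recombination rate for the whole span (`2 N r`);
#'   crossover probability is linear in bp distance.
#' @param span Chromosome span in bp (> 0).
#' @param mutable Two-column matrix of 1-based inclusive `[start, end]` bp
#'   windows where mutations may fall; default the whole span.
#' @param seed RNG seed (`NULL` leaves the RNG stream alone).
#' @return List of class `coalescent_sim`: `positions` (sorted bp),
#'   `genotypes` (sites x strains 0/1 matrix, 0 = ancestral), `n`, `span`.
#' @export
simulate_coalescent <- function(n, theta_site, rho_total = 0, span,
                                mutable = NULL, seed = NULL) {
  if (span <= 0) stop("span must be positive", call. = FALSE)
  if (n < 2 || n > 30) stop("n must be in 2..30 (bitmask descendant sets)",
                            call. = FALSE)
  if (theta_site < 0 || rho_total < 0) stop("rates must be >= 0", call. = FALSE)
  mutable <- mutable %||% matrix(c(1, span), 1)
  cvg <- make_coverage(mutable, span)
  with_seed(seed, {
    lin <- vector("list", n)
    birth <- numeric(n)
    for (i in seq_len(n)) lin[[i]] <- cbind(0, span, bitwShiftL(1L, i - 1L))
    full <- bitwShiftL(1L, n) - 1L
    cap <- 1024L
    ra <- rb <- rw <- numeric(cap); rmask <- integer(cap); cnt <- 0L
    push <- function(a, b, mk, w) {
      m <- length(a)
      if (cnt + m > cap) {
        cap <<- max(cap * 2L, cnt + m)
        length(ra) <<- cap; length(rb) <<- cap
        length(rw) <<- cap; length(rmask) <<- cap
      }
      idx <- cnt + seq_len(m)
      ra[idx] <<- a; rb[idx] <<- b; rmask[idx] <<- as.integer(mk); rw[idx] <<- w
      cnt <<- cnt + m
    }
    flush <- function(i, t) {
      s <- lin[[i]]
      w <- (t - birth[i]) * (cvg$cov(s[, 2]) - cvg$cov(s[, 1]))
      ok <- w > 0
      if (any(ok)) push(s[ok, 1], s[ok, 2], s[ok, 3], w[ok])
    }
    t <- 0
    repeat {
      k <- length(lin)
      if (k < 2) break
      br <- vapply(lin, function(s) s[nrow(s), 2] - s[1, 1], 0)
      rate_r <- rho_total / (2 * span) * sum(br)
      rate_c <- k * (k - 1) / 2
      t <- t + rexp(1, rate_c + rate_r)
      if (runif(1) < rate_r / (rate_r + rate_c)) {
        i <- if (k == 1) 1L else sample.int(k, 1, prob = br)
        s <- lin[[i]]
        u <- runif(1, s[1, 1], s[nrow(s), 2])
        flush(i, t)
        la <- s[, 1] < u
        left <- s[la, , drop = FALSE]
        left[left[, 2] > u, 2] <- u
        ra_side <- s[s[, 2] > u, , drop = FALSE]
        ra_side[ra_side[, 1] < u, 1] <- u
        lin[[i]] <- left; birth[i] <- t
        lin[[length(lin) + 1L]] <- ra_side
        birth[length(lin)] <- t
      } else {
        pr <- sample.int(k, 2)
        flush(pr[1], t); flush(pr[2], t)
        merged <- merge_segments(lin[[pr[1]]], lin[[pr[2]]], full)
        lin[pr] <- NULL
        birth <- birth[-pr]
        if (nrow(merged) > 0) {
          lin[[length(lin) + 1L]] <- merged
          birth[length(lin)] <- t
        }
      }
    }
    # place mutations on the accumulated branch exposure
    W <- if (cnt > 0) sum(rw[seq_len(cnt)]) else 0
    nmut <- if (W > 0) rpois(1, theta_site / 2 * W) else 0L
    if (nmut == 0) {
      return(structure(list(
        positions = numeric(0),
        genotypes = matrix(integer(), 0, n,
                           dimnames = list(NULL, paste0("strain", seq_len(n)))),
        n = n, span = span), class = "coalescent_sim"))
    }
    idx <- sample.int(cnt, nmut, replace = TRUE, prob = rw[seq_len(cnt)])
    u <- runif(nmut, cvg$cov(ra[idx]), cvg$cov(rb[idx]))
    bp <- pmax(1, ceiling(cvg$inv(u)))
    masks <- rmask[idx]
    dup <- duplicated(bp)
    bp <- bp[!dup]; masks <- masks[!dup]
    ord <- order(bp)
    bp <- bp[ord]; masks <- masks[ord]
    geno <- t(vapply(masks, mask_to_bits, integer(n), n = n))
    colnames(geno) <- paste0("strain", seq_len(n))
    structure(list(positions = bp, genotypes = geno, n = n, span = span),
              class = "coalescent_sim")
  })
}
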