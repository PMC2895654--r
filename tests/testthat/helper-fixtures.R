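# Shared fixtures: all built in code at test time.

# SNP matrix from a genotype matrix (sites x strains), defaulting to one
# chromosome with 1 kb spacing.
make_mat <- function(geno, chrom = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  S <- nrow(geno)
  snp_matrix(geno,
             chrom %||% rep("chr1", S),
             pos %||% seq(1000, by = 1000, length.out = S))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One-chromosome region emulating the dense-chromosome design at reduced
# scale: 30 fragments of 500 bp spaced 40 kb (span ~1.3 Mb).
sim_region_matrix <- function(rho, seed, n = 25, n_frag = 30, frag_len = 500,
                              spacing = 4e4, theta = 8e-4) {
  starts <- 5e4 + (seq_len(n_frag) - 1) * spacing
  span <- starts[n_frag] + frag_len + 5e4
  sim <- simulate_coalescent(n, theta, rho, span,
                             mutable = cbind(starts, starts + frag_len - 1),
                             seed = seed)
  if (length(sim$positions) < 2) return(NULL)
  snp_matrix(sim$genotypes, rep("chr4", length(sim$positions)), sim$positions)
}

region_span <- function(n_frag = 30, frag_len = 500, spacing = 4e4) {
  5e4 + (n_frag - 1) * spacing + frag_len + 5e4
}

# Reduced Monte-Carlo two-locus table, built once per test session.
.fixture_env <- new.env()
get_two_locus_table <- function(n = 25) {
  key <- paste0("tab", n)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_two_locus_table(
      n, rho_grid = seq(0, 100, length.out = 9), n_sims = 2e4, seed = 4242)
  }
  .fixture_env[[key]]
}

# A small complete study design reused by several files.
get_small_design <- function() {
  if (is.null(.fixture_env$design)) {
    .fixture_env$design <- simulate_study_design(study_design_params(
      n = 8, n_frag_dense = 5, n_frag_other = 3, missing_rate = 0.05,
      theta_site = 5e-3, seed = 77))
  }
  .fixture_env$design
}

# Exhaustive-search oracle for the minimum recombination count: maximum
# number of pairwise-disjoint four-gamete-incompatible intervals (open
# intervals; sharing an endpoint site is allowed).
rm_oracle <- function(m) {
  S <- n_sites(m)
  iv <- NULL
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      if (incompatible(m, i, j)) iv <- rbind(iv, c(i, j))
    }
  }
  if (is.null(iv)) return(0L)
  best <- 0L
  nr <- nrow(iv)
  rec <- function(idx, chosen) {
    best <<- max(best, nrow(chosen))
    if (idx > nr) return()
    for (k in idx:nr) {
      ok <- nrow(chosen) == 0 ||
        all(iv[k, 1] >= chosen[, 2] | iv[k, 2] <= chosen[, 1])
      if (ok) rec(k + 1L, rbind(chosen, iv[k, ]))
    }
  }
  rec(1L, iv[0, , drop = FALSE])
  best
}

# Random biallelic toy matrix (every site carries both alleles).
random_toy_matrix <- function(S, n = 6) {
  geno <- matrix(0L, S, n)
  for (s in seq_len(S)) {
    repeat {
      g <- rbinom(n, 1, runif(1, 0.2, 0.8))
      if (any(g == 1) && any(g == 0)) break
    }
    geno[s, ] <- g
  }
  make_mat(geno)
}
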