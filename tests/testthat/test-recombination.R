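test_that("four-gamete incompatibility requires all four complete-case haplotypes", {
  g_all4 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  expect_true(incompatible(make_mat(g_all4), 1, 2))
  g_3 <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 1L, 1L))
  expect_false(incompatible(make_mat(g_3), 1, 2))
  # a missing call can reduce four observed gametes to three
  g_miss <- rbind(c(0L, 0L, 1L, 1L, 0L), c(0L, 1L, 0L, 1L, NA))
  g_miss2 <- g_miss; g_miss2[2, 3] <- NA
  expect_true(incompatible(make_mat(g_miss), 1, 2))
  expect_false(incompatible(make_mat(g_miss2), 1, 2))
})

test_that("Hudson-Kaplan Rm equals exhaustive interval search on toy matrices", {
  # a single incompatible pair: Rm = 1 with that interval
  g <- rbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  res <- minimum_recombination_events(make_mat(g))
  expect_equal(res$rm, 1)
  expect_equal(res$intervals$left_site, 1)
  expect_equal(res$intervals$right_site, 2)
  # no recombination: Rm = 0 on every tree-like simulation
  for (k in 1:10) {
    sim <- simulate_coalescent(12, 0.02, 0, 3000, seed = 600 + k)
    if (length(sim$positions) < 2) next
    expect_equal(minimum_recombination_events(make_mat(sim$genotypes))$rm, 0)
  }
  # random <= 8-site toys against the exhaustive-search oracle
  set.seed(1234)
  for (k in 1:25) {
    m <- random_toy_matrix(S = sample(4:8, 1), n = 6)
    expect_equal(minimum_recombination_events(m)$rm, rm_oracle(m),
                 info = paste("toy", k))
  }
  # Rm is invariant under coordinate translation
  m <- random_toy_matrix(6, 8)
  shifted <- snp_matrix(m$geno, m$chrom, m$pos + 12345L)
  expect_equal(minimum_recombination_events(shifted)$rm,
               minimum_recombination_events(m)$rm)
})

test_that("the moment estimator responds to LD structure and flags boundaries", {
  # one divergent strain carrying every variant: the pairwise-difference
  # variance exceeds its rho = 0 expectation -> estimate 0 with a flag
  singletons <- matrix(0L, 4, 6)
  singletons[, 1] <- 1L
  res0 <- wakeley_rho(make_mat(singletons), span = 1e5)
  expect_equal(res0$rho, 0)
  expect_equal(res0$flag, "no_recombination_signal")
  # perfectly correlated clade-split sites vs the same columns scrambled:
  # destroying LD lowers the difference variance and raises the estimate
  block <- matrix(rep(c(0L, 0L, 0L, 1L, 1L, 1L), 8), 8, 6, byrow = TRUE)
  resb <- wakeley_rho(make_mat(block), span = 1e5)
  set.seed(55)
  scr <- t(apply(block, 1, sample))
  ress <- wakeley_rho(make_mat(scr), span = 1e5)
  expect_gt(ress$rho, resb$rho)
  expect_error(wakeley_rho(make_mat(matrix(c(0L, 1L, 1L), 1)), 1e5), "n >= 4")
})

test_that("the moment estimator recovers rho within a factor of three on contiguous panels", {
  # n = 25, theta 0.0008/bp, 500 kb contiguous, true rho = 40
  wr <- vapply(1:30, function(k) {
    sim <- simulate_coalescent(25, 8e-4, 40, 5e5, seed = 32000 + k)
    if (length(sim$positions) < 2) return(NA_real_)
    m <- snp_matrix(sim$genotypes, rep("chr4", length(sim$positions)),
                    sim$positions)
    wakeley_rho(m, 5e5)$rho
  }, 0)
  med <- median(wr, na.rm = TRUE)
  expect_gt(med, 40 / 3)
  expect_lt(med, 40 * 3)
})

test_that("the two-locus table is normalized, folded, and tree-like at rho 0", {
  tab <- get_two_locus_table()
  expect_true(all(abs(colSums(tab$probs) - 1) < 1e-9))
  # stored codes are canonical under the 8-fold symmetry
  recoded <- ddpopgen:::config_codes(tab$configs, tab$n)
  expect_equal(recoded, tab$codes)
  # infinite sites on a single genealogy: no four-gamete configuration
  four <- rowSums(tab$configs > 0) == 4
  expect_equal(sum(tab$probs[four, which(tab$rho_grid == 0)]), 0)
  # recombination generates four-gamete mass
  expect_gt(sum(tab$probs[four, length(tab$rho_grid)]), 0.05)
})

test_that("composite rho is strain-order invariant and near zero without recombination", {
  tab <- get_two_locus_table()
  span <- region_span()
  mat <- sim_region_matrix(rho = 40, seed = 777)
  filt <- maf_filter(mat, 0.10)
  est <- composite_rho(filt, tab, span)
  perm <- snp_matrix(filt$geno[, rev(seq_len(ncol(filt$geno)))],
                     filt$chrom, filt$pos)
  est2 <- composite_rho(perm, tab, span)
  expect_equal(est2$loglik, est$loglik)
  expect_equal(est2$rho_hat, est$rho_hat)
  # rho = 0 simulations: argmax at or adjacent to the zero grid point
  hits <- 0L; tries <- 0L
  for (k in 1:50) {
    m0 <- sim_region_matrix(rho = 0, seed = 3200 + k)
    if (is.null(m0)) next
    f0 <- maf_filter(m0, 0.10)
    if (n_sites(f0) < 2) next
    tries <- tries + 1L
    e0 <- composite_rho(f0, tab, span)
    if (which.max(e0$loglik) <= 2) hits <- hits + 1L
  }
  expect_gte(hits / tries, 0.9)
})

test_that("the likelihood permutation test keeps its add-one floor and detects signal", {
  tab <- get_two_locus_table()
  span <- region_span()
  mat <- maf_filter(sim_region_matrix(rho = 80, seed = 808), 0.10)
  res <- likelihood_permutation_test(mat, tab, span, n_perm = 99, seed = 5)
  expect_gt(res$p_value, 0)                     # add-one rule
  expect_equal(res$p_value, 1 / 100)            # strong signal attains the floor
  expect_equal(length(res$perm_stat), 99)
  # single-position degenerate input is refused
  one_pos <- snp_matrix(rbind(c(0L, 1L, 0L, 1L), c(0L, 1L, 1L, 0L)),
                        c("chr4", "chr4"), c(100L, 101L))
  one_pos$pos <- c(100L, 100L)
  expect_error(likelihood_permutation_test(one_pos, tab, span, n_perm = 10),
               "fewer than 2 distinct")
})
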