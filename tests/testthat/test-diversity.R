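test_that("Watterson's theta follows the harmonic-number formula", {
  expect_equal(watterson_theta(0, 10, 1000), 0)
  # hand-summed harmonic number: a_4 = 1 + 1/2 + 1/3
  expect_equal(watterson_theta(3, 4, 100), 3 / ((1 + 1/2 + 1/3) * 100),
               tolerance = 1e-12)
  expect_equal(watterson_theta(3, 4, 100), 0.016364, tolerance = 1e-4)
  # the published panel: S=184, n=25, L=64.6 kb rounds to the printed value
  expect_lt(abs(watterson_theta(184, 25, 64600) - 0.00076), 1e-5)
  expect_error(watterson_theta(3, 1, 100), "at least 2")
})

test_that("nucleotide diversity matches brute force and is label-symmetric", {
  # no segregating sites: pi = 0
  empty <- snp_matrix(matrix(integer(), 0, 2), character(), integer(),
                      strains = c("a", "b"))
  expect_equal(nucleotide_diversity(empty, 100), 0)
  # one variant column A/A/T over L=1: pairwise diffs {0,1,1} -> 2/3
  m <- make_mat(matrix(c(0L, 0L, 1L), 1))
  expect_equal(nucleotide_diversity(m, 1), 2 / 3)
  # brute-force loop oracle with missing data
  set.seed(31)
  g <- matrix(rbinom(60, 1, 0.4), 12, 5)
  g[sample(60, 6)] <- NA
  keep <- rowSums(g == 1, na.rm = TRUE) >= 1 & rowSums(g == 0, na.rm = TRUE) >= 1
  g <- g[keep, ]
  m2 <- make_mat(g)
  S <- nrow(g)
  vals <- c()
  for (i in 1:4) for (j in (i + 1):5) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    vals <- c(vals, sum(g[ok, i] != g[ok, j]) * S / sum(ok))
  }
  L <- 500
  expect_equal(nucleotide_diversity(m2, L), mean(vals) / L)
  # invariant under strain relabeling
  m3 <- make_mat(g[, 5:1])
  expect_equal(nucleotide_diversity(m3, L), nucleotide_diversity(m2, L))
})

test_that("Tajima's D agrees with an independent 1989-constants oracle", {
  # n=4 with 8 singleton + 3 doubleton sites: pi_total = S/a1 exactly (both
  # equal 6), so the numerator and D are exactly zero
  g0 <- rbind(matrix(rep(c(1L, 0L, 0L, 0L), 2), 2, byrow = TRUE),
              matrix(rep(c(0L, 1L, 0L, 0L), 2), 2, byrow = TRUE),
              matrix(rep(c(0L, 0L, 1L, 0L), 2), 2, byrow = TRUE),
              matrix(rep(c(0L, 0L, 0L, 1L), 2), 2, byrow = TRUE),
              matrix(rep(c(1L, 1L, 0L, 0L), 3), 3, byrow = TRUE))
  expect_equal(tajimas_d(make_mat(g0)), 0)
  # independent computation straight from the published constants
  oracle_d <- function(g) {
    n <- ncol(g); S <- nrow(g)
    pi_tot <- mean(apply(combn(n, 2), 2, function(p) sum(g[, p[1]] != g[, p[2]])))
    a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
    (pi_tot - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  }
  g_singletons <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L))
  expect_equal(tajimas_d(make_mat(g_singletons)), oracle_d(g_singletons),
               tolerance = 1e-12)
  set.seed(8)
  g_rand <- matrix(rbinom(40, 1, 0.5), 8, 5)
  keep <- rowSums(g_rand) %in% 1:4
  g_rand <- g_rand[keep, ]
  expect_equal(tajimas_d(make_mat(g_rand)), oracle_d(g_rand), tolerance = 1e-12)
  # singleton-heavy -> negative; intermediate-frequency -> positive
  g_interm <- rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  expect_lt(tajimas_d(make_mat(g_singletons)), 0)
  expect_gt(tajimas_d(make_mat(g_interm)), 0)
  # no segregating sites: undefined
  empty <- snp_matrix(matrix(integer(), 0, 4), character(), integer())
  expect_true(is.na(tajimas_d(empty)))
})

test_that("pairwise differences equal a per-site loop and are symmetric", {
  set.seed(91)
  g <- matrix(rbinom(80, 1, 0.3), 16, 5)
  g[sample(80, 8)] <- NA
  keep <- rowSums(g == 1, na.rm = TRUE) >= 1 & rowSums(g == 0, na.rm = TRUE) >= 1
  g <- g[keep, ]
  pd <- pairwise_differences(make_mat(g))
  for (i in 1:5) for (j in 1:5) {
    ok <- !is.na(g[, i]) & !is.na(g[, j])
    expect_equal(unname(pd$diff[i, j]), sum(g[ok, i] != g[ok, j]))
    expect_equal(unname(pd$callable[i, j]), sum(ok))
  }
  expect_identical(pd$diff, t(pd$diff))
  expect_true(all(diag(pd$diff) == 0))
  expect_true(all(pd$diff <= pd$callable))
})

test_that("Hudson's Fst hits its endpoints and is near zero under panmixia", {
  # groups fixed for alternative alleles at every site -> Fst = 1
  g <- rbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  colnames(g) <- c("a1", "a2", "b1", "b2")
  expect_equal(hudson_fst(make_mat(g), c("a1", "a2"), c("b1", "b2")), 1)
  # hand computation on a 4-strain, 2-site toy
  g2 <- rbind(c(0L, 1L, 1L, 1L), c(0L, 0L, 0L, 1L))
  colnames(g2) <- c("a1", "a2", "b1", "b2")
  hw <- (1 + 1) / 2            # within-pair mismatch count in each group
  hb <- mean(c(sum(g2[, 1] != g2[, 3]), sum(g2[, 1] != g2[, 4]),
               sum(g2[, 2] != g2[, 3]), sum(g2[, 2] != g2[, 4])))
  expect_equal(hudson_fst(make_mat(g2), c("a1", "a2"), c("b1", "b2")),
               1 - hw / hb)
  # arbitrary split of one panmictic population: mean Fst ~ 0
  fsts <- vapply(1:200, function(k) {
    sim <- simulate_coalescent(8, 0.01, 0, 2000, seed = 5000 + k)
    if (length(sim$positions) < 2) return(NA_real_)
    m <- make_mat(sim$genotypes)
    hudson_fst(m, m$strains[1:4], m$strains[5:8])
  }, 0)
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.05)
})

test_that("genome summaries reproduce the worked spacing and divergence numbers", {
  gs <- genome_summaries(S = 184, L = 64600, pi = 0.0008, genome_size = 34e6)
  expect_equal(gs$snp_spacing_bp, 64600 / 184)
  expect_lt(abs(gs$snp_spacing_bp - 350), 2)
  expect_equal(gs$expected_genome_diff, 27200)
  expect_lt(abs(gs$expected_genome_diff - 27000), 300)
  expect_equal(genome_summaries(0, 100, 0, 34e6)$expected_genome_diff, 0)
  expect_true(is.na(genome_summaries(0, 100, 0, 34e6)$snp_spacing_bp))
})

test_that("pooled and per-fragment summaries are consistent", {
  des <- get_small_design()
  ds <- diversity_summary(des$fragments)
  expect_equal(ds$pooled$S, sum(ds$per_fragment$S))
  expect_equal(ds$pooled$L, sum(ds$per_fragment$L))
  expect_true(all(ds$per_fragment$theta_w >= 0))
  expect_true(all(is.na(ds$per_fragment$tajima_d) == (ds$per_fragment$S == 0)))
})
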