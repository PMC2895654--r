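make_concat <- function(seqs) list(sequences = seqs,
                                   length = nchar(seqs[[1]]))

test_that("K2P distances match the closed form", {
  same <- make_concat(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(unname(k2p_distance(same)["a", "b"]), 0)
  # P = 0.1, Q = 0: d = -0.5 log(0.8)
  s1 <- strrep("A", 10)
  s2 <- paste0("G", strrep("A", 9))   # one A->G transition in 10 sites
  d <- k2p_distance(make_concat(c(a = s1, b = s2)))
  expect_equal(unname(d["a", "b"]), -0.5 * log(1 - 2 * 0.1 - 0) - 0.25 * log(1),
               tolerance = 1e-10)
  expect_equal(unname(d["a", "b"]), 0.11157, tolerance = 1e-4)
  expect_identical(d["a", "b"], d["b", "a"])
})

test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  # constructed additive 4-taxon matrix: ((a,b),(c,d)) with internal edge 3
  el <- c(a = 2, b = 5, c = 4, d = 1); internal <- 3
  dm <- matrix(0, 4, 4, dimnames = list(names(el), names(el)))
  dm["a", "b"] <- dm["b", "a"] <- el["a"] + el["b"]
  dm["c", "d"] <- dm["d", "c"] <- el["c"] + el["d"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    dm[x, y] <- dm[y, x] <- el[x] + el[y] + internal
  }
  tr <- neighbor_joining(dm)
  expect_equal(unname(as.matrix(cophenetic(tr))[rownames(dm), colnames(dm)]),
               unname(dm), tolerance = 1e-10)
  # random additive matrices from known trees, 4-8 taxa: topology recovered
  set.seed(14)
  for (k in 1:20) {
    nt <- sample(4:8, 1)
    gen <- ape::rtree(nt, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.1, 1)
    dmat <- as.matrix(cophenetic(gen))
    rec <- neighbor_joining(dmat)
    expect_equal(phangorn::RF.dist(rec, gen), 0, info = paste("tree", k))
    expect_equal(as.matrix(cophenetic(rec))[rownames(dmat), colnames(dmat)],
                 dmat, tolerance = 1e-8)
  }
  # leaf-order permutation leaves the unrooted topology unchanged
  p <- c("c", "a", "d", "b")
  expect_equal(phangorn::RF.dist(neighbor_joining(dm[p, p]), tr), 0)
  # three taxa resolve as the unique star
  expect_equal(ape::Ntip(neighbor_joining(dm[1:3, 1:3])), 3)
  dm[1, 2] <- dm[2, 1] <- NA
  expect_error(neighbor_joining(dm), "undefined distances")
})

test_that("bootstrap supports identify a clean cherry and are reproducible", {
  set.seed(9)
  base <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  mutate <- function(s, idx, to) {
    v <- strsplit(s, "")[[1]]; v[idx] <- to; paste(v, collapse = "")
  }
  xx <- mutate(base, 200:215, "T")   # shared private mutations: a real clade
  seqs <- c(x1 = xx, x2 = xx,
            y1 = mutate(base, 1:30, "G"),
            z1 = mutate(base, 31:60, "C"),
            z2 = mutate(base, c(31:60, 90:110), "C"))
  concat <- make_concat(seqs)
  tr <- bootstrap_support(concat, replicates = 100, seed = 21)
  expect_true(all(tr$node.label >= 0 & tr$node.label <= 100, na.rm = TRUE))
  # identical pair (x1, x2) distinct from the rest: its bipartition at 100%
  nt <- ape::Ntip(tr)
  pair <- sort(c("x1", "x2"))
  rest <- sort(setdiff(names(seqs), pair))
  hit <- vapply(seq_len(tr$Nnode - 1) + nt + 1, function(nd) {
    tips <- sort(ape::extract.clade(tr, nd)$tip.label)
    identical(tips, pair) || identical(tips, rest)
  }, TRUE)
  support <- tr$node.label[-1][hit]
  expect_true(length(support) >= 1)
  expect_true(all(support == 100))
  tr2 <- bootstrap_support(concat, replicates = 100, seed = 21)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("geographic distances honor the within-site rule and the haversine form", {
  tab <- as_strain_table(data.frame(
    strain_id = c("s1", "s2", "s3", "s4"),
    site = c("dense", "dense", "north", "far"),
    lat = c(37.37, 37.37, 37.37, -37.37),
    lon = c(-80.52, -80.52, -80.52, 99.48),
    mating_type = "unknown"))
  d <- geographic_distances(tab)
  expect_equal(unname(d["s1", "s2"]), 1)      # shared site name -> 1 km
  expect_equal(unname(d["s1", "s3"]), 0)      # same coordinates, other site
  # s4 is antipodal to s1: half the great circle
  expect_equal(unname(d["s1", "s4"]), pi * 6378137 / 1000, tolerance = 1e-6)
  tab$lat[2] <- NA
  expect_error(geographic_distances(tab), "missing coordinates.*s2")
})

test_that("the Mantel test matches vegan and is exact for identical matrices", {
  set.seed(77)
  n <- 10
  m1 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(m1) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- mantel_test(m1, m1, n_perm = 500, seed = 2)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, 1 / 501)
  # observed statistic equals the independent vegan implementation
  skip_if_not_installed("vegan")
  m2 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dimnames(m2) <- dimnames(m1)
  res2 <- mantel_test(m1, m2, n_perm = 50, seed = 3)
  veg <- vegan::mantel(as.dist(m1), as.dist(m2), permutations = 10)
  expect_equal(res2$r, unname(veg$statistic), tolerance = 1e-12)
  expect_error(mantel_test(m1, matrix(1, n, n,
                                      dimnames = dimnames(m1)), n_perm = 10),
               "constant")
})
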