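# Strain clustering (K2P distances + neighbor joining with bootstrap) and
# geographic structure (great-circle distances, Mantel isolation-by-distance).

concat_to_dnabin <- function(concat) {
  m <- do.call(rbind, strsplit(tolower(concat$sequences), ""))
  rownames(m) <- names(concat$sequences)
  ape::as.DNAbin(m)
}

#' Kimura two-parameter distance matrix
#'
#' \eqn{d = -\frac{1}{2}\ln(1-2P-Q) - \frac{1}{4}\ln(1-2Q)} with transition
#' proportion P and transversion proportion Q over jointly non-missing
#' sites (pairwise deletion). Saturated pairs (non-positive log argument)
#' come back `NA` and are listed in `attr(,"undefined_pairs")`.
#'
#' @param concat A concatenation from [concatenate_alignments()] (or any
#'   named character vector of equal-length sequences).
#' @return Symmetric numeric matrix of class `dist_matrix` with
#'   `attr(,"metric") = "K2P"`.
#' @export
k2p_distance <- function(concat) {
  if (is.character(concat)) concat <- list(sequences = concat)
  dna <- concat_to_dnabin(concat)
  d <- as.matrix(ape::dist.dna(dna, model = "K80", pairwise.deletion = TRUE))
  und <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  d[!is.finite(d)] <- NA_real_
  diag(d) <- 0
  attr(d, "metric") <- "K2P"
  attr(d, "undefined_pairs") <- und
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a full distance matrix. Negative branch
#' lengths (an NJ artifact) are clamped to zero with the deficit moved to
#' the sibling edge, so path lengths through the parent are preserved.
#'
#' @param dist Symmetric distance matrix (>= 3 strains, no `NA`).
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 3) stop("need at least 3 strains", call. = FALSE)
  if (any(is.na(d))) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distances for pairs: ",
         paste(apply(bad, 1, function(r)
           paste(rownames(d)[r[1]], colnames(d)[r[2]], sep = "-")),
           collapse = ", "), call. = FALSE)
  }
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge[, 1]) != e)
    if (length(sib)) {
      tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    }
  }
  tr
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (fragment boundaries
#' ignored, mirroring a concatenated-data analysis), rebuilds the NJ tree
#' from K2P distances for each replicate, and scores each internal
#' bipartition of the original tree by the percentage of replicates that
#' contain it.
#'
#' @param concat A concatenation from [concatenate_alignments()].
#' @param replicates Bootstrap replicates (study default 1000).
#' @param seed RNG seed.
#' @return The NJ `phylo` tree with `node.label` set to supports in
#'   `[0, 100]` (root label `NA`).
#' @export
bootstrap_support <- function(concat, replicates = 1000, seed = NULL) {
  dna <- concat_to_dnabin(concat)
  build <- function(x) {
    d <- ape::dist.dna(x, model = "K80", pairwise.deletion = TRUE)
    m <- as.matrix(d)
    m[!is.finite(m)] <- max(m[is.finite(m)], 0) * 2
    ape::nj(as.dist(m))
  }
  tr <- build(dna)
  with_seed(seed, {
    bp <- ape::boot.phylo(tr, dna, build, B = replicates, rooted = FALSE,
                          quiet = TRUE)
    support <- 100 * bp / replicates
    support[1] <- NA  # root pseudo-node of an unrooted tree
    tr$node.label <- support
    tr
  })
}

#' Great-circle distance matrix between strain collection sites
#'
#' Haversine distances in km from decimal-degree coordinates; pairs of
#' strains sharing a site name get the fixed within-site distance instead
#' (the study design assigns 1 km within its densely sampled site).
#'
#' @param table A `strain_table` with `lat`/`lon` present for every strain.
#' @param within_site_km Distance assigned to same-site pairs (default 1).
#' @return Symmetric km matrix of class `dist_matrix`.
#' @export
geographic_distances <- function(table, within_site_km = 1) {
  bad <- table$strain_id[!is.finite(table$lat) | !is.finite(table$lon)]
  if (length(bad)) stop("missing coordinates for strains: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(table$strain_id, table$strain_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (table$site[i] == table$site[j]) {
        km <- within_site_km
      } else {
        km <- geosphere::distHaversine(c(table$lon[i], table$lat[i]),
                                       c(table$lon[j], table$lat[j])) / 1000
      }
      d[i, j] <- d[j, i] <- km
    }
  }
  attr(d, "metric") <- "geographic-km"
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Mantel test for isolation by distance
#'
#' Pearson correlation of the upper triangles of two strain-by-strain
#' distance matrices, with a null built by jointly permuting the rows and
#' columns (strain labels) of one matrix. One-sided for positive
#' association with the add-one rule.
#'
#' @param genetic,geographic Symmetric matrices over the same strains.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed.
#' @return List: `r` (observed correlation), `p_value`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 1000, seed = NULL) {
  g1 <- as.matrix(genetic); g2 <- as.matrix(geographic)
  if (!identical(dim(g1), dim(g2))) stop("matrix dimensions differ", call. = FALSE)
  if (!is.null(rownames(g1)) && !is.null(rownames(g2))) {
    if (!setequal(rownames(g1), rownames(g2))) {
      stop("strain sets differ between matrices", call. = FALSE)
    }
    g2 <- g2[rownames(g1), rownames(g1)]
  }
  up <- upper.tri(g1)
  if (sd(g1[up]) == 0 || sd(g2[up]) == 0) {
    stop("constant distance matrix; Mantel r undefined", call. = FALSE)
  }
  r_obs <- cor(g1[up], g2[up])
  n <- nrow(g1)
  with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      if (cor(g1[up], g2[p, p][up]) >= r_obs) hits <- hits + 1L
    }
    list(r = r_obs, p_value = perm_pvalue(hits, n_perm), n_perm = n_perm)
  })
}
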