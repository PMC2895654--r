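# Synthetic study-design generator: every analysis stage can be exercised
# end to end on data with the statistical structure the study assumes --
# 25 haploid strains, 137 gene fragments of 400-600 bp (94 on a densely
# sampled chromosome at a target mean spacing of 55.6 kb, the rest spread
# over the other five chromosomes), per-site diversity around 0.0008,
# recombination linear in bp, sporadic missing data.

# Approximate chromosome sizes (bp) for the six-chromosome, 34 Mb genome.
CHROM_SIZES <- c(chr1 = 4.9e6, chr2 = 8.5e6, chr3 = 6.5e6,
                 chr4 = 5.5e6, chr5 = 5.1e6, chr6 = 3.6e6)

#' Parameters of the emulated re-sequencing study design
#'
#' Defaults reproduce the study conditions: 25 strains, 137 fragments of
#' 400-600 bp with 94 on the dense chromosome (chr4) spaced 2.3-233.7 kb
#' apart with a 55.6 kb target mean, per-site theta 0.0008, a dense-
#' chromosome rho of 40 (other chromosomes scaled to the same per-bp
#' rate), and a 2% missing-call rate.
#'
#' @param n Number of strains.
#' @param theta_site Per-bp scaled mutation rate.
#' @param rho_dense Scaled recombination rate across the dense chromosome.
#' @param n_frag_dense,n_frag_other Fragment counts (dense chromosome /
#'   rest of genome).
#' @param frag_len Inclusive fragment length range in bp.
#' @param spacing_range Dense-chromosome start-to-start spacing range (bp).
#' @param spacing_mean Target mean spacing (bp).
#' @param missing_rate Per-call probability of a missing base.
#' @param seed RNG seed.
#' @return List of class `sim_params`.
#' @export
study_design_params <- function(n = 25, theta_site = 8e-4, rho_dense = 40,
                                n_frag_dense = 94, n_frag_other = 43,
                                frag_len = c(400, 600),
                                spacing_range = c(2300, 233700),
                                spacing_mean = 55600,
                                missing_rate = 0.02, seed = NULL) {
  stopifnot(n >= 2, theta_site >= 0, rho_dense >= 0,
            missing_rate >= 0, missing_rate <= 1)
  structure(list(n = n, theta_site = theta_site, rho_dense = rho_dense,
                 n_frag_dense = n_frag_dense, n_frag_other = n_frag_other,
                 frag_len = frag_len, spacing_range = spacing_range,
                 spacing_mean = spacing_mean, missing_rate = missing_rate,
                 seed = seed), class = "sim_params")
}

# Spacings from a shifted exponential truncated to the declared range,
# with the exponential mean solved so the truncated mean hits the target.
draw_spacings <- function(k, range, target_mean) {
  lo <- range[1]; hi <- range[2]
  cap <- hi - lo
  f <- function(m) lo + m * (1 - exp(-cap / m)) - target_mean
  m0 <- uniroot(f, c(1, 10 * target_mean))$root
  lo + pmin(rexp(k, 1 / m0), cap)
}

# 0/1 haplotypes -> nucleotide fragment alignments on an AT-rich background.
# Derived alleles are A -> G transitions at the mutated positions.
haplotypes_to_fragments <- function(sim, layout, strains) {
  lapply(seq_len(nrow(layout)), function(i) {
    st <- layout$start[i]; len <- layout$length[i]
    bg <- sample(c("A", "T", "C", "G"), len, replace = TRUE,
                 prob = c(0.39, 0.39, 0.11, 0.11))
    inside <- sim$positions >= st & sim$positions <= st + len - 1L
    cm <- matrix(bg, nrow = length(strains), ncol = len, byrow = TRUE)
    if (any(inside)) {
      off <- sim$positions[inside] - st + 1L
      bg[off] <- "A"
      cm <- matrix(bg, nrow = length(strains), ncol = len, byrow = TRUE)
      gsub <- sim$genotypes[inside, , drop = FALSE]
      for (s in seq_along(off)) {
        cm[gsub[s, ] == 1L, off[s]] <- "G"
      }
    }
    seqs <- setNames(apply(cm, 1, paste, collapse = ""), strains)
    fragment_alignment(layout$fragment_id[i], layout$chromosome[i], st, seqs)
  })
}

#' Simulate the full re-sequencing study design
#'
#' Simulates whole-chromosome coalescent histories with recombination
#' (mutations confined to the fragment windows), converts 0/1 haplotypes
#' to nucleotides (A/G transitions on a 78% AT background), lays the
#' fragments out per the declared design, assigns strains to synthetic
#' collection sites (one dense site holding about half the panel), and
#' sprinkles missing data.
#'
#' @param params A [study_design_params()] list.
#' @return List of class `study_design`: `fragments` (list of
#'   [fragment_alignment()]), `coords` (fragment coordinate table),
#'   `strains` (a `strain_table`), `params`.
#' @export
simulate_study_design <- function(params = study_design_params()) {
  with_seed(params$seed, {
    strains <- sprintf("SS%02d", seq_len(params$n))
    # dense-chromosome layout
    dense_size <- CHROM_SIZES[["chr4"]]
    lens <- sample(params$frag_len[1]:params$frag_len[2],
                   params$n_frag_dense, replace = TRUE)
    starts <- NULL
    for (try in 1:200) {
      sp <- draw_spacings(params$n_frag_dense - 1L, params$spacing_range,
                          params$spacing_mean)
      cand <- 50000 + cumsum(c(0, sp))
      if (cand[length(cand)] + lens[length(lens)] + 1000 < dense_size) {
        starts <- round(cand); break
      }
    }
    if (is.null(starts)) stop("fragment layout cannot fit in the chromosome span",
                              call. = FALSE)
    layout <- data.frame(fragment_id = sprintf("frag%03d", seq_len(params$n_frag_dense)),
                         chromosome = "chr4", start = as.integer(starts),
                         length = as.integer(lens))
    # remaining fragments spread over the other five chromosomes
    others <- setdiff(names(CHROM_SIZES), "chr4")
    och <- sample(others, params$n_frag_other, replace = TRUE,
                  prob = CHROM_SIZES[others])
    olen <- sample(params$frag_len[1]:params$frag_len[2],
                   params$n_frag_other, replace = TRUE)
    opos <- integer(params$n_frag_other)
    for (ch in unique(och)) {
      idx <- which(och == ch)
      taken <- numeric(0)
      for (i in idx) {
        for (try in 1:200) {
          cand <- round(runif(1, 1000, CHROM_SIZES[[ch]] - olen[i] - 1000))
          if (!length(taken) || min(abs(taken - cand)) > 2000) break
        }
        taken <- c(taken, cand)
        opos[i] <- cand
      }
    }
    layout <- rbind(layout, data.frame(
      fragment_id = sprintf("frag%03d",
                            params$n_frag_dense + seq_len(params$n_frag_other)),
      chromosome = och, start = as.integer(opos), length = olen))
    layout <- layout[order(match(layout$chromosome, CHROMOSOMES), layout$start), ]
    # per-chromosome coalescent simulation, constant per-bp rho
    rho_per_bp <- params$rho_dense / dense_size
    fragments <- list()
    for (ch in unique(layout$chromosome)) {
      sub <- layout[layout$chromosome == ch, , drop = FALSE]
      span <- CHROM_SIZES[[ch]]
      sim <- simulate_coalescent(
        n = params$n, theta_site = params$theta_site,
        rho_total = rho_per_bp * span, span = span,
        mutable = cbind(sub$start, sub$start + sub$length - 1L))
      fragments <- c(fragments, haplotypes_to_fragments(sim, sub, strains))
    }
    names(fragments) <- vapply(fragments, `[[`, "", "fragment_id")
    if (params$missing_rate > 0) {
      fragments <- inject_missing(fragments, params$missing_rate)
    }
    # strain metadata: one dense site holding about half the panel
    n_dense <- ceiling(params$n / 2)
    dense_lat <- 37.37; dense_lon <- -80.52
    n_other <- params$n - n_dense
    site <- c(rep("dense_site", n_dense), sprintf("site%02d", seq_len(n_other)))
    lat <- c(rep(dense_lat, n_dense), runif(n_other, 30, 45))
    lon <- c(rep(dense_lon, n_dense), runif(n_other, -95, -70))
    mt <- sample(c("matA1", "matA2", "matA3", "unknown"), params$n,
                 replace = TRUE, prob = c(4, 8, 6, 6) / 24)
    strain_tab <- as_strain_table(data.frame(
      strain_id = strains, site = site, lat = lat, lon = lon,
      mating_type = mt))
    structure(list(fragments = fragments,
                   coords = layout[c("fragment_id", "chromosome", "start", "length")],
                   strains = strain_tab, params = params),
              class = "study_design")
  })
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d fragments, %d strains, %d bp surveyed\n",
              length(x$fragments), nrow(x$strains),
              sum(vapply(x$fragments, `[[`, 0L, "length"))))
  invisible(x)
}

#' Write a simulated study design to disk
#'
#' One FASTA per fragment plus the coordinate and strain TSVs, in the
#' format [read_fragment_alignments()] and [read_strain_table()] consume.
#'
#' @param design A [simulate_study_design()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in design$fragments) {
    dna <- Biostrings::DNAStringSet(f$sequences)
    Biostrings::writeXStringSet(dna, file.path(dir, paste0(f$fragment_id, ".fasta")))
  }
  write.table(design$coords, file.path(dir, "coords.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(design$strains, file.path(dir, "strains.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Inject missing data
#'
#' Masks each call independently with probability `rate`: bases become `N`
#' in fragment alignments, genotypes become `NA` in a SNP matrix.
#'
#' @param x A [snp_matrix()], a [fragment_alignment()], or a list of
#'   fragment alignments.
#' @param rate Per-call missing probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return Object of the same shape with missing calls injected.
#' @export
inject_missing <- function(x, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]", call. = FALSE)
  if (rate == 0) return(x)
  with_seed(seed, {
    if (inherits(x, "snp_matrix")) {
      g <- x$geno
      mask <- matrix(runif(length(g)) < rate, nrow(g))
      g[mask] <- NA_integer_
      keep <- vapply(seq_len(nrow(g)), function(i) {
        sum(g[i, ] == 1L, na.rm = TRUE) >= 1 && sum(g[i, ] == 0L, na.rm = TRUE) >= 1
      }, logical(1))
      snp_matrix(g[keep, , drop = FALSE], x$chrom[keep], x$pos[keep],
                 x$major[keep], x$minor[keep], x$strains, x$n_multiallelic)
    } else if (inherits(x, "fragment_alignment")) {
      inject_fragment_missing(x, rate)
    } else {
      lapply(x, inject_fragment_missing, rate = rate)
    }
  })
}

inject_fragment_missing <- function(frag, rate) {
  cm <- frag_char_matrix(frag)
  mask <- matrix(runif(length(cm)) < rate, nrow(cm))
  cm[mask] <- "N"
  frag$sequences <- setNames(apply(cm, 1, paste, collapse = ""),
                             rownames(cm))
  frag
}

#' Parameters for the chimera-experiment generator
#'
#' Defaults mirror the assay design: a 50:50 intended mix, 16 fruiting
#' bodies from each of 3 replicate plates, 2 SNP markers read per pair.
#'
#' @param p_o Initial-mix proportion of the focal strain.
#' @param n_fb Fruiting bodies per replicate plate.
#' @param replicates Replicate plates.
#' @param n_markers SNP markers measured per pair.
#' @param segregation Segregation parameter s in `[0, 1]`: probability a
#'   fruiting body is clonal rather than mixed at the initial proportion.
#' @param noise Measurement noise SD applied to each proportion
#'   (truncated to `[0, 1]`).
#' @param seed RNG seed.
#' @return List of class `chimera_sim_params`.
#' @export
chimera_sim_params <- function(p_o = 0.5, n_fb = 16, replicates = 3,
                               n_markers = 2, segregation = 0.5,
                               noise = 0.02, seed = NULL) {
  stopifnot(p_o >= 0, p_o <= 1, segregation >= 0, segregation <= 1,
            noise >= 0)
  structure(list(p_o = p_o, n_fb = n_fb, replicates = replicates,
                 n_markers = n_markers, segregation = segregation,
                 noise = noise, seed = seed), class = "chimera_sim_params")
}

#' Simulate a chimeric fruiting-body experiment
#'
#' Clonal/mixed mixture model: with probability `s` a fruiting body is
#' clonal (all focal strain with probability `p_o`, otherwise none);
#' otherwise it reflects the initial mix (`p_i = p_o`). Truncated-Gaussian
#' measurement noise is then applied per marker. Under the implemented
#' r_fb the expectation of the statistic equals `s`, which makes recovery
#' checks directly interpretable.
#'
#' @param params A [chimera_sim_params()] list.
#' @param pair Pair label for the output table.
#' @return Long-format data frame (`pair`, `marker`, `replicate`,
#'   `fruiting_body`, `proportion`, `p_o`) consumable by
#'   [social_statistics()].
#' @export
simulate_chimera <- function(params = chimera_sim_params(), pair = "pair1") {
  with_seed(params$seed, {
    out <- list()
    for (rep in seq_len(params$replicates)) {
      clonal <- runif(params$n_fb) < params$segregation
      p_true <- ifelse(clonal,
                       as.numeric(runif(params$n_fb) < params$p_o),
                       params$p_o)
      for (mk in seq_len(params$n_markers)) {
        p_meas <- p_true
        if (params$noise > 0) {
          p_meas <- pmin(pmax(p_true + rnorm(params$n_fb, 0, params$noise), 0), 1)
        }
        out[[length(out) + 1L]] <- data.frame(
          pair = pair, marker = sprintf("snp%d", mk), replicate = rep,
          fruiting_body = seq_len(params$n_fb),
          proportion = p_meas, p_o = params$p_o)
      }
    }
    do.call(rbind, out)
  })
}
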