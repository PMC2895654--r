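# Orchestration: run every analysis stage over one input set and emit a
# machine-readable JSON summary plus a short human-readable report.

#' Assemble a run configuration
#'
#' @param fragments FASTA paths or a directory of per-fragment FASTAs.
#' @param coords Fragment coordinate TSV path (or data frame).
#' @param strains Strain metadata TSV path (or `strain_table`).
#' @param chimera Optional chimera CSV path (or data frame); when absent
#'   the social stage is skipped.
#' @param dense_chrom Chromosome used for LD/recombination profiling.
#' @param groups Optional named list of two character vectors of strain
#'   ids for the Fst contrast; default splits the dense collection site
#'   against the rest.
#' @param maf MAF threshold for LD and rho analyses.
#' @param n_perm Permutation count for all permutation tests.
#' @param n_boot Bootstrap replicates for the NJ tree.
#' @param rho_table A prebuilt [build_two_locus_table()] (or NULL to build
#'   a reduced one at run time).
#' @param genome_size Genome size in bp for the divergence projection.
#' @param seed Master seed; stage seeds are derived from it.
#' @param output_dir Where to write `summary.json` and `report.txt`.
#' @return List of class `run_config`.
#' @export
run_config <- function(fragments, coords, strains, chimera = NULL,
                       dense_chrom = "chr4", groups = NULL, maf = 0.10,
                       n_perm = 1000, n_boot = 100, rho_table = NULL,
                       genome_size = 34e6, seed = 1, output_dir = tempfile("ddpop")) {
  structure(list(fragments = fragments, coords = coords, strains = strains,
                 chimera = chimera, dense_chrom = dense_chrom,
                 groups = groups, maf = maf, n_perm = n_perm,
                 n_boot = n_boot, rho_table = rho_table,
                 genome_size = genome_size, seed = seed,
                 output_dir = output_dir), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Stage order: sequence loading and SNP calling, diversity summaries,
#' LD decay, recombination (Rm, moment rho, composite-likelihood rho with
#' permutation test), clustering and geographic structure, and - when
#' chimera data are supplied - the social statistics. A stage failure is
#' caught, recorded under `errors`, and later stages still run where their
#' inputs exist. The summary JSON is byte-stable for a fixed config and
#' seed.
#'
#' @param config A [run_config()].
#' @return List of class `run_report` with per-stage results; side effect:
#'   `summary.json` and `report.txt` under `config$output_dir`.
#' @export
run_full_analysis <- function(config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(config = list(maf = config$maf, n_perm = config$n_perm,
                            n_boot = config$n_boot, seed = config$seed,
                            dense_chrom = config$dense_chrom))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  frags <- stage("seqio", read_fragment_alignments(config$fragments, config$coords))
  strains <- stage("seqio", {
    if (is.character(config$strains)) read_strain_table(config$strains)
    else as_strain_table(config$strains)
  })
  if (is.null(frags)) {
    stop("sequence loading failed: ", errors$seqio, call. = FALSE)
  }
  mat <- call_snps(frags)
  L <- sum(vapply(frags, `[[`, 0L, "length"))

  div <- stage("diversity", {
    ds <- diversity_summary(frags)
    gs <- genome_summaries(ds$pooled$S, L, ds$pooled$pi, config$genome_size)
    list(n = ds$pooled$n, L = L, S = ds$pooled$S,
         theta_w = ds$pooled$theta_w, pi = ds$pooled$pi,
         tajima_d = ds$pooled$tajima_d,
         tajima_d_fragment_mean = ds$pooled$tajima_d_fragment_mean,
         snp_spacing_bp = gs$snp_spacing_bp,
         expected_genome_diff = gs$expected_genome_diff,
         mating_types = tally_mating_types(strains))
  })

  dense <- subset_sites(mat, which(mat$chrom == config$dense_chrom))
  filt <- maf_filter(dense, config$maf)
  ld <- stage("linkage", {
    pairs <- pairwise_r2(maf_filter(mat, config$maf))
    prof <- ld_profile(pairs)
    test <- ld_decay_permutation_test(pairs, n_perm = config$n_perm,
                                      seed = config$seed + 1L)
    list(n_sites = n_sites(filt), n_pairs = nrow(pairs),
         baseline_mean = prof$baseline_mean, baseline_q80 = prof$baseline_q80,
         decay_statistic = test$statistic, decay_p = test$p_value,
         profile = prof$bins)
  })

  recomb <- stage("recombination", {
    span <- CHROM_SIZES[[config$dense_chrom]]
    rm_res <- minimum_recombination_events(filt)
    wk <- wakeley_rho(dense, span)
    tab <- config$rho_table %||%
      build_two_locus_table(n_strains(mat), seq(0, 100, length.out = 9),
                            n_sims = 2e4, seed = config$seed + 2L)
    est <- likelihood_permutation_test(filt, tab, span,
                                       n_perm = config$n_perm,
                                       seed = config$seed + 3L)
    list(rm = rm_res$rm, moment_rho = wk$rho, moment_flag = wk$flag,
         rho_hat = est$rho_hat, rho_p = est$p_value,
         curve = data.frame(rho = est$grid, loglik = est$loglik))
  })

  clust <- stage("clustering_geo", {
    concat <- concatenate_alignments(frags)
    tree <- bootstrap_support(concat, replicates = config$n_boot,
                              seed = config$seed + 4L)
    gen_d <- pairwise_differences(mat)$diff
    geo_d <- geographic_distances(strains)
    ids <- intersect(rownames(gen_d), rownames(geo_d))
    mt <- mantel_test(gen_d[ids, ids], geo_d[ids, ids],
                      n_perm = config$n_perm, seed = config$seed + 5L)
    groups <- config$groups %||% {
      dense_site <- names(sort(table(strains$site), decreasing = TRUE))[1]
      list(dense = strains$strain_id[strains$site == dense_site],
           widespread = strains$strain_id[strains$site != dense_site])
    }
    fst <- hudson_fst(mat, groups[[1]], groups[[2]])
    list(newick = ape::write.tree(tree), mantel_r = mt$r,
         mantel_p = mt$p_value, fst = fst)
  })

  social <- NULL
  if (!is.null(config$chimera)) {
    social <- stage("social", {
      chim <- if (is.character(config$chimera)) read_chimera_csv(config$chimera)
              else config$chimera
      st <- social_statistics(chim)
      list(per_pair = st, mean_r_fb = mean(st$r_fb),
           mean_abs_d = mean(st$abs_d))
    })
  }

  report <- structure(list(config = res$config, diversity = div,
                           linkage = ld, recombination = recomb,
                           clustering = clust, social = social,
                           errors = errors), class = "run_report")
  jsonlite::write_json(report[!vapply(report, is.null, TRUE)],
                       file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  writeLines(format_report(report), file.path(config$output_dir, "report.txt"))
  report
}

format_report <- function(x) {
  lines <- c("ddpopgen analysis report", "========================")
  if (!is.null(x$diversity)) {
    d <- x$diversity
    lines <- c(lines, sprintf(
      "Diversity: n=%d  L=%d bp  S=%d  theta_W=%.3g  pi=%.3g  Tajima's D=%.4f",
      d$n, d$L, d$S, d$theta_w, d$pi, d$tajima_d))
    lines <- c(lines, sprintf(
      "  1 SNP every %.0f bp; expected genome-wide pairwise differences %.0f",
      d$snp_spacing_bp, d$expected_genome_diff))
  }
  if (!is.null(x$linkage)) {
    lines <- c(lines, sprintf(
      "LD: %d filtered pairs, baseline r2 %.3f (80th pct %.3f), decay p=%.4g",
      x$linkage$n_pairs, x$linkage$baseline_mean, x$linkage$baseline_q80,
      x$linkage$decay_p))
  }
  if (!is.null(x$recombination)) {
    lines <- c(lines, sprintf(
      "Recombination: Rm=%d, moment rho=%.2f (%s), composite rho_hat=%.2f (p=%.4g)",
      x$recombination$rm, x$recombination$moment_rho,
      x$recombination$moment_flag, x$recombination$rho_hat,
      x$recombination$rho_p))
  }
  if (!is.null(x$clustering)) {
    lines <- c(lines, sprintf("Structure: Mantel r=%.3f (p=%.4g), Fst=%.4f",
                              x$clustering$mantel_r, x$clustering$mantel_p,
                              x$clustering$fst))
  }
  if (!is.null(x$social)) {
    lines <- c(lines, sprintf("Social: mean r_fb=%.3f, mean |d|=%.3f over %d pairs",
                              x$social$mean_r_fb, x$social$mean_abs_d,
                              nrow(x$social$per_pair)))
  }
  if (length(x$errors)) {
    lines <- c(lines, paste("Stage errors:",
                            paste(names(x$errors), collapse = ", ")))
  }
  lines
}

#' @export
print.run_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
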