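test_that("fragment alignments round-trip through FASTA and reject malformed input", {
  des <- get_small_design()
  dir <- withr::local_tempdir()
  write_study_design(des, dir)
  frags <- read_fragment_alignments(dir, file.path(dir, "coords.tsv"))
  expect_length(frags, length(des$fragments))
  expect_equal(nrow(attr(frags, "rejected")), 0)
  # loader sorts by (chromosome, start); compare against the same ordering
  ord <- order(match(vapply(des$fragments, `[[`, "", "chromosome"), paste0("chr", 1:6)),
               vapply(des$fragments, `[[`, 0L, "start"))
  orig <- des$fragments[ord]
  expect_identical(lapply(frags, `[[`, "sequences"),
                   setNames(lapply(orig, `[[`, "sequences"),
                            vapply(orig, `[[`, "", "fragment_id")))
  # one sequence a bp short: fragment rejected, the rest still load
  bad <- file.path(dir, paste0(frags[[1]]$fragment_id, ".fasta"))
  seqs <- frags[[1]]$sequences
  seqs[1] <- substr(seqs[1], 1, nchar(seqs[1]) - 1)
  writeLines(c(rbind(paste0(">", names(seqs)), seqs)), bad)
  frags2 <- read_fragment_alignments(dir, file.path(dir, "coords.tsv"))
  expect_equal(attr(frags2, "rejected")$fragment_id, frags[[1]]$fragment_id)
  expect_length(frags2, length(frags) - 1)
  # unknown chromosome label is a hard error
  coords <- read.delim(file.path(dir, "coords.tsv"))
  coords$chromosome[1] <- "chr9"
  expect_error(read_fragment_alignments(dir, coords), "unknown chromosome")
})

test_that("strains absent from a fragment are harmonized to all-N", {
  dir <- withr::local_tempdir()
  writeLines(c(">s1", "ACGT", ">s2", "ACGA"), file.path(dir, "f1.fasta"))
  writeLines(c(">s1", "GGGG", ">s3", "GGGT"), file.path(dir, "f2.fasta"))
  coords <- data.frame(fragment_id = c("f1", "f2"), chromosome = "chr1",
                       start = c(100, 900), length = 4)
  frags <- read_fragment_alignments(
    file.path(dir, c("f1.fasta", "f2.fasta")), coords)
  expect_identical(names(frags[[1]]$sequences), c("s1", "s2", "s3"))
  expect_identical(frags[[1]]$sequences[["s3"]], "NNNN")
  expect_identical(frags[[2]]$sequences[["s2"]], "NNNN")
})

test_that("SNP calling matches a brute-force column scan and is order-invariant", {
  # single column A/A/A/T: one biallelic site, major A, minor T, count 1
  f <- fragment_alignment("t1", "chr1", 500,
                          c(a = "A", b = "A", c = "A", d = "T"))
  m <- call_snps(list(f))
  expect_equal(n_sites(m), 1)
  expect_equal(m$major, "A")
  expect_equal(m$minor, "T")
  expect_equal(sum(m$geno == 1L), 1)
  expect_equal(m$pos, 500L)
  # column A/C/G/T: excluded, multiallelic counter incremented
  f2 <- fragment_alignment("t2", "chr1", 600,
                           c(a = "A", b = "C", c = "G", d = "T"))
  m2 <- call_snps(list(f2))
  expect_equal(n_sites(m2), 0)
  expect_equal(m2$n_multiallelic, 1L)
  # simulated fragments: S equals an independent per-column scan
  des <- get_small_design()
  mat <- call_snps(des$fragments)
  scan_S <- 0L
  for (fr in des$fragments) {
    cm <- do.call(rbind, strsplit(fr$sequences, ""))
    for (j in seq_len(ncol(cm))) {
      obs <- cm[, j][!cm[, j] %in% c("N", "-")]
      if (length(unique(obs)) == 2) scan_S <- scan_S + 1L
    }
  }
  expect_equal(n_sites(mat), scan_S)
  # invariance under strain and fragment reordering
  shuf <- lapply(rev(des$fragments), function(fr) {
    fr$sequences <- fr$sequences[rev(names(fr$sequences))]
    fr
  })
  mat2 <- call_snps(shuf)
  expect_equal(n_sites(mat2), n_sites(mat))
  expect_equal(mat2$pos, mat$pos)
  expect_equal(mat2$geno[, mat$strains], mat$geno)
})

test_that("concatenation is length-preserving and invertible at boundaries", {
  f1 <- fragment_alignment("a", "chr1", 100,
                           c(s1 = strrep("A", 400), s2 = strrep("C", 400)))
  f2 <- fragment_alignment("b", "chr2", 900,
                           c(s1 = strrep("G", 600), s2 = strrep("T", 600)))
  cc <- concatenate_alignments(list(f1, f2))
  expect_equal(cc$length, 1000)
  expect_equal(cc$boundaries$end[1], 400)
  expect_equal(cc$boundaries$start[2], 401)
  back <- split_concatenation(cc)
  expect_identical(back[[1]]$sequences, f1$sequences)
  expect_identical(back[[2]]$sequences, f2$sequences)
  expect_identical(back[[2]]$start, f2$start)
  expect_error(concatenate_alignments(list()), "nothing to concatenate")
})

test_that("mating-type tallies match the printed strain panel", {
  tab <- read_strain_table(system.file("extdata", "mating_types.tsv",
                                       package = "ddpopgen"))
  tl <- tally_mating_types(tab)
  expect_equal(tl$assigned, 18)
  expect_equal(unname(tl$counts["unknown"]), 6L)
  expect_equal(unname(tl$counts["matA2"]), 8L)
  expect_equal(sum(tl$counts), nrow(tab))
  empty <- tab[0, ]
  expect_equal(sum(tally_mating_types(empty)$counts), 0L)
  tab$mating_type[1] <- "matB9"
  expect_error(tally_mating_types(tab), "unrecognized mating type")
})

test_that("haploid VCF export round-trips losslessly", {
  one <- make_mat(matrix(c(0L, 1L, NA), 1))
  p <- withr::local_tempfile(fileext = ".vcf")
  write_snps(one, p)
  expect_equal(sum(!startsWith(readLines(p), "#")), 1)
  des <- get_small_design()
  mat <- call_snps(des$fragments)
  write_snps(mat, p)
  mat2 <- read_snps(p)
  expect_equal(unname(mat2$geno), unname(mat$geno))
  expect_equal(mat2$pos, mat$pos)
  expect_equal(mat2$chrom, mat$chrom)
  expect_equal(mat2$major, mat$major)
  expect_equal(mat2$minor, mat$minor)
  # empty matrix: header-only file
  empty <- snp_matrix(matrix(integer(), 0, 3), character(), integer(),
                      strains = c("a", "b", "c"))
  write_snps(empty, p)
  expect_true(all(startsWith(readLines(p), "#")))
  # corrupted ordering refuses to serialize
  broken <- mat
  broken$pos[1:2] <- rev(broken$pos[1:2])
  expect_error(write_snps(broken, p), "strictly increasing")
})
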