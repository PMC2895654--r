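# seqio: external formats, SNP calling from fragment alignments, strain
# metadata. Coordinates are 1-based inclusive throughout the package.

#' Construct a fragment alignment
#'
#' One sequenced gene fragment: aligned sequences for a set of haploid
#' strains plus its genomic anchor (chromosome and 1-based start).
#' Gap (`-`) and `N` characters are treated as missing data everywhere
#' downstream; sequences are stored on the orientation given in the input.
#'
#' @param fragment_id Character scalar, fragment identifier.
#' @param chromosome One of `"chr1"`..`"chr6"`.
#' @param start 1-based start coordinate in bp.
#' @param sequences Named character vector (names are strain ids), all the
#'   same length, alphabet `A/C/G/T/N/-` (case-insensitive).
#' @return An object of class `fragment_alignment`.
#' @export
fragment_alignment <- function(fragment_id, chromosome, start, sequences) {
  if (!chromosome %in% CHROMOSOMES) {
    stop("unknown chromosome label: ", chromosome, call. = FALSE)
  }
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(len) != 1L || len == 0L) {
    stop("all sequences in fragment '", fragment_id,
         "' must have the same positive length", call. = FALSE)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop("sequences must be uniquely named by strain id", call. = FALSE)
  }
  structure(
    list(fragment_id = as.character(fragment_id),
         chromosome = chromosome,
         start = as.integer(start),
         length = as.integer(len),
         sequences = sequences),
    class = "fragment_alignment")
}

#' @export
print.fragment_alignment <- function(x, ...) {
  cat(sprintf("<fragment_alignment> %s  %s:%d-%d  %d strains\n",
              x$fragment_id, x$chromosome, x$start,
              x$start + x$length - 1L, length(x$sequences)))
  invisible(x)
}

#' Construct a biallelic SNP matrix
#'
#' The substrate of every statistic in the package: biallelic haploid
#' genotypes coded 0 (major allele), 1 (minor allele) or `NA` (missing),
#' with genomic positions. Sites must be strictly increasing within each
#' chromosome and every retained site must segregate (minor count >= 1)
#' among non-missing calls.
#'
#' @param geno Integer matrix, sites x strains, entries 0/1/`NA`.
#' @param chrom Character vector of chromosome labels per site.
#' @param pos Integer vector of 1-based coordinates per site.
#' @param major,minor Character vectors of major/minor nucleotides per site.
#' @param strains Character vector of strain ids (columns of `geno`).
#' @param n_multiallelic Count of sites excluded for >2 alleles.
#' @return An object of class `snp_matrix`.
#' @export
snp_matrix <- function(geno, chrom, pos, major = NULL, minor = NULL,
                       strains = NULL, n_multiallelic = 0L) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  S <- nrow(geno)
  strains <- strains %||% colnames(geno) %||% paste0("strain", seq_len(ncol(geno)))
  colnames(geno) <- strains
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(length(chrom) == S, length(pos) == S)
  major <- major %||% rep("A", S)
  minor <- minor %||% rep("G", S)
  ord <- order(match(chrom, CHROMOSOMES), pos)
  geno <- geno[ord, , drop = FALSE]
  chrom <- chrom[ord]; pos <- pos[ord]
  major <- major[ord]; minor <- minor[ord]
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (anyDuplicated(p)) stop("duplicated position on ", ch, call. = FALSE)
  }
  if (S > 0) {
    ok <- vapply(seq_len(S), function(i) {
      g <- geno[i, ]
      sum(g == 1L, na.rm = TRUE) >= 1L && sum(g == 0L, na.rm = TRUE) >= 1L
    }, logical(1))
    if (!all(ok)) stop("every site must be biallelic among non-missing calls",
                       call. = FALSE)
  }
  structure(
    list(geno = geno, chrom = chrom, pos = pos, major = major, minor = minor,
         strains = strains, n_multiallelic = as.integer(n_multiallelic)),
    class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d sites x %d strains (%d multiallelic excluded, %.1f%% missing)\n",
              nrow(x$geno), ncol(x$geno), x$n_multiallelic,
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Number of segregating sites
#' @param x A `snp_matrix`.
#' @return Integer count of retained biallelic sites.
#' @export
n_sites <- function(x) { stop_if_not_snp_matrix(x); nrow(x$geno) }

#' Number of strains
#' @param x A `snp_matrix`.
#' @return Integer strain count.
#' @export
n_strains <- function(x) { stop_if_not_snp_matrix(x); ncol(x$geno) }

#' Subset a SNP matrix by site
#' @param x A `snp_matrix`.
#' @param i Site index vector.
#' @return A `snp_matrix` with the selected sites.
#' @export
subset_sites <- function(x, i) {
  stop_if_not_snp_matrix(x)
  snp_matrix(x$geno[i, , drop = FALSE], x$chrom[i], x$pos[i],
             x$major[i], x$minor[i], x$strains, x$n_multiallelic)
}

#' Read a strain metadata table
#'
#' Tab-separated columns `strain_id`, `site`, `lat`, `lon`, `mating_type`.
#' Mating types are restricted to `matA1`, `matA2`, `matA3`, `unknown`.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` of class `strain_table`.
#' @export
read_strain_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("strain_id", "site", "lat", "lon", "mating_type")
  if (!all(need %in% names(tab))) {
    stop("strain table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  as_strain_table(tab)
}

#' Validate a strain metadata data.frame
#' @param tab Data frame with columns `strain_id`, `site`, `lat`, `lon`,
#'   `mating_type`.
#' @return The validated `strain_table`.
#' @export
as_strain_table <- function(tab) {
  if (anyDuplicated(tab$strain_id)) stop("strain ids must be unique", call. = FALSE)
  bad <- setdiff(unique(tab$mating_type), c("matA1", "matA2", "matA3", "unknown"))
  if (length(bad)) stop("unrecognized mating type label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  class(tab) <- c("strain_table", "data.frame")
  tab
}

#' Read per-fragment alignments and their coordinate table
#'
#' Each FASTA holds one fragment's aligned strain sequences; the coordinate
#' table (TSV: `fragment_id`, `chromosome`, `start`, `length`) anchors each
#' fragment to the genome. Fragments whose sequences disagree in length are
#' rejected (listed in `attr(,"rejected")`) rather than aborting the load;
#' an unknown chromosome label is an error. Strains are harmonized across
#' fragments: a strain absent from a fragment gets an all-`N` sequence.
#'
#' @param paths Character vector of FASTA paths, or a single directory
#'   containing `<fragment_id>.fasta` files.
#' @param coords Path to the coordinate TSV (or an equivalent data frame).
#' @return A list of [fragment_alignment()] objects sorted by
#'   (chromosome, start), with attributes `rejected` (data frame of
#'   rejected fragments and reasons) and `coords`.
#' @export
read_fragment_alignments <- function(paths, coords) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  }
  ctab <- if (is.character(coords)) read.delim(coords, stringsAsFactors = FALSE) else coords
  need <- c("fragment_id", "chromosome", "start", "length")
  if (!all(need %in% names(ctab))) {
    stop("coordinate table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad_chr <- setdiff(unique(ctab$chromosome), CHROMOSOMES)
  if (length(bad_chr)) stop("unknown chromosome label(s): ",
                            paste(bad_chr, collapse = ", "), call. = FALSE)
  frags <- list()
  rejected <- data.frame(fragment_id = character(), reason = character())
  for (p in paths) {
    fid <- sub("\\.(fa|fasta)$", "", basename(p))
    row <- ctab[ctab$fragment_id == fid, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("fragment '", fid, "' not found in the coordinate table", call. = FALSE)
    }
    dna <- Biostrings::readDNAStringSet(p)
    seqs <- setNames(as.character(dna), names(dna))
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      rejected <- rbind(rejected, data.frame(
        fragment_id = fid,
        reason = sprintf("sequence length mismatch (%s)",
                         paste(unique(lens), collapse = "/"))))
      next
    }
    frags[[fid]] <- fragment_alignment(fid, row$chromosome, row$start, seqs)
  }
  strains <- sort(unique(unlist(lapply(frags, function(f) names(f$sequences)))))
  frags <- lapply(frags, function(f) {
    missing <- setdiff(strains, names(f$sequences))
    if (length(missing)) {
      f$sequences <- c(f$sequences,
                       setNames(rep(strrep("N", f$length), length(missing)), missing))
    }
    f$sequences <- f$sequences[strains]
    f
  })
  ord <- order(match(vapply(frags, `[[`, "", "chromosome"), CHROMOSOMES),
               vapply(frags, `[[`, 0L, "start"))
  frags <- frags[ord]
  attr(frags, "rejected") <- rejected
  attr(frags, "coords") <- ctab
  frags
}

# character matrix (strains x L) view of a fragment
frag_char_matrix <- function(frag) {
  m <- do.call(rbind, strsplit(frag$sequences, ""))
  rownames(m) <- names(frag$sequences)
  m
}

#' Call biallelic SNPs from fragment alignments
#'
#' Scans every alignment column; `N` and `-` are missing. Columns with
#' exactly two observed alleles among non-missing calls become sites
#' (singletons retained; frequency filtering happens downstream with
#' [maf_filter()]); columns with more than two alleles are excluded and
#' counted in `n_multiallelic`. The major allele is the more frequent one
#' (ties broken alphabetically).
#'
#' @param fragments List of [fragment_alignment()] objects (>= 2 strains).
#' @return A [snp_matrix()]; zero usable sites give a valid empty matrix.
#' @export
call_snps <- function(fragments) {
  if (inherits(fragments, "fragment_alignment")) fragments <- list(fragments)
  strains <- names(fragments[[1]]$sequences)
  if (length(strains) < 2L) stop("need at least 2 strains", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  geno <- list(); chrom <- character(); pos <- integer()
  major <- character(); minor <- character(); n_multi <- 0L
  for (f in fragments) {
    if (!identical(sort(names(f$sequences)), sort(strains))) {
      stop("fragments must share the same strain set (use read_fragment_alignments)",
           call. = FALSE)
    }
    cm <- frag_char_matrix(f)[strains, , drop = FALSE]
    cnt <- vapply(bases, function(b) colSums(cm == b), numeric(ncol(cm)))
    if (is.null(dim(cnt))) cnt <- matrix(cnt, nrow = 1, dimnames = list(NULL, bases))
    nall <- rowSums(cnt > 0)
    n_multi <- n_multi + sum(nall > 2)
    for (j in which(nall == 2)) {
      cj <- cnt[j, ]
      two <- names(cj)[cj > 0]
      maj <- two[which.max(cj[two])]   # ties: first alphabetically (bases sorted)
      mnr <- setdiff(two, maj)
      col <- cm[, j]
      g <- ifelse(col == maj, 0L, ifelse(col == mnr, 1L, NA_integer_))
      geno[[length(geno) + 1L]] <- g
      chrom <- c(chrom, f$chromosome)
      pos <- c(pos, f$start + j - 1L)
      major <- c(major, maj); minor <- c(minor, mnr)
    }
  }
  if (!length(geno)) {
    g <- matrix(integer(), nrow = 0, ncol = length(strains),
                dimnames = list(NULL, strains))
    return(snp_matrix(g, character(), integer(), character(), character(),
                      strains, n_multi))
  }
  g <- do.call(rbind, geno)
  colnames(g) <- strains
  snp_matrix(g, chrom, pos, major, minor, strains, n_multi)
}

#' Concatenate fragment alignments
#'
#' Joins all fragments into one alignment (the substrate for distance-based
#' clustering), keeping an invertible boundary map back to per-fragment
#' coordinates.
#'
#' @param fragments List of [fragment_alignment()] objects with a shared
#'   strain set.
#' @return List with `sequences` (named character vector), `length`, and
#'   `boundaries` (data frame: fragment_id, start, end in concatenated
#'   coordinates plus genomic chromosome/start).
#' @export
concatenate_alignments <- function(fragments) {
  if (!length(fragments)) stop("nothing to concatenate", call. = FALSE)
  strains <- names(fragments[[1]]$sequences)
  lens <- vapply(fragments, `[[`, 0L, "length")
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- vapply(strains, function(s) {
    paste(vapply(fragments, function(f) f$sequences[[s]], ""), collapse = "")
  }, "")
  list(sequences = seqs,
       length = sum(lens),
       boundaries = data.frame(
         fragment_id = vapply(fragments, `[[`, "", "fragment_id"),
         start = starts, end = ends,
         chromosome = vapply(fragments, `[[`, "", "chromosome"),
         genomic_start = vapply(fragments, `[[`, 0L, "start")))
}

#' Split a concatenation back into fragments
#'
#' Inverse of [concatenate_alignments()] via its boundary map.
#' @param concat Result of [concatenate_alignments()].
#' @return List of [fragment_alignment()] objects.
#' @export
split_concatenation <- function(concat) {
  b <- concat$boundaries
  lapply(seq_len(nrow(b)), function(i) {
    fragment_alignment(b$fragment_id[i], b$chromosome[i], b$genomic_start[i],
                       substr(concat$sequences, b$start[i], b$end[i]))
  })
}

#' Tally mating types in a strain table
#'
#' @param table A `strain_table` (see [read_strain_table()]).
#' @return List with `counts` (named counts over the four labels),
#'   `assigned` (total minus unknown) and `total`.
#' @export
tally_mating_types <- function(table) {
  labels <- c("matA1", "matA2", "matA3", "unknown")
  bad <- setdiff(unique(table$mating_type), labels)
  if (length(bad)) stop("unrecognized mating type label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- vapply(labels, function(l) sum(table$mating_type == l), 0L)
  list(counts = counts,
       assigned = sum(counts) - counts[["unknown"]],
       total = sum(counts))
}

#' Write a SNP matrix as a haploid VCF
#'
#' Minimal VCF v4.2 export: REF is the major allele, ALT the minor, genotype
#' field is a single haploid GT (`0`, `1` or `.` for missing).
#'
#' @param matrix A [snp_matrix()]; positions must be sorted (they are by
#'   construction).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(matrix, path) {
  stop_if_not_snp_matrix(matrix)
  x <- matrix
  for (ch in unique(x$chrom)) {
    if (is.unsorted(x$pos[x$chrom == ch], strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosomes", call. = FALSE)
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=ddpopgen",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">',
           paste0("##contig=<ID=", CHROMOSOMES, ">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$strains), collapse = "\t"))
  lines <- hdr
  if (nrow(x$geno) > 0) {
    gt <- x$geno
    gtc <- matrix(as.character(gt), nrow = nrow(gt))
    gtc[is.na(gt)] <- "."
    body <- vapply(seq_len(nrow(gt)), function(i) {
      paste(c(x$chrom[i], x$pos[i], sprintf("snp%04d", i), x$major[i],
              x$minor[i], ".", "PASS", ".", "GT", gtc[i, ]), collapse = "\t")
    }, "")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a haploid VCF back into a SNP matrix
#'
#' Re-reader for [write_snps()] output (parsing via the vcfR package).
#' @param path VCF path.
#' @return A [snp_matrix()].
#' @export
read_snps <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    strains <- colnames(v@gt)[-1] %||% character()
    g <- matrix(integer(), 0, length(strains), dimnames = list(NULL, strains))
    return(snp_matrix(g, character(), integer(), character(), character(), strains))
  }
  gt <- vcfR::extract.gt(v)
  g <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  g[gt == "0"] <- 0L
  g[gt == "1"] <- 1L
  snp_matrix(g, fix$CHROM, as.integer(fix$POS), fix$REF, fix$ALT, colnames(gt))
}
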