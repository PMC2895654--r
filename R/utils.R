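# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG state for a single computation
#'
#' All stochastic functions in the package accept an explicit `seed`; a
#' `NULL` seed leaves the caller's RNG stream untouched.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# Declared chromosome set for the six-chromosome genome.
CHROMOSOMES <- paste0("chr", 1:6)

# Decode an integer bitmask into a 0/1 vector of length n (bit i = strain i).
mask_to_bits <- function(mask, n) {
  as.integer(bitwAnd(bitwShiftR(as.integer(mask), 0:(n - 1L)), 1L))
}

# Harmonic number a_n = sum_{i=1}^{n-1} 1/i used by Watterson's estimator.
harmonic_a <- function(n) sum(1 / seq_len(n - 1L))

# Add-one permutation p-value.
perm_pvalue <- function(n_extreme, n_perm) (1 + n_extreme) / (n_perm + 1)

stop_if_not_snp_matrix <- function(x) {
  if (!inherits(x, "snp_matrix")) stop("expected a 'snp_matrix' object", call. = FALSE)
}
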