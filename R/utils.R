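# Internal sequence and RNG helpers shared across modules.

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings GENETIC_CODE
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(ifelse(is.na(aa), "X", aa))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Deterministic 32-bit seed derived from a master seed and a string key.
# Used to split random streams per tree branch so that planting an event on
# one branch never perturbs the background process on another.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 1000000007
  as.integer((abs(seed) %% 65536 * 32749 + h) %% 2147483647)
}

# Run expr with a local RNG state seeded from `seed`, restoring the caller's
# stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1-based inclusive coordinates for reports; internal coordinates are
# 0-based half-open.
to_report_coord <- function(zero_based_start) zero_based_start + 1L
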