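# Shared helpers: amino-acid alphabet, genetic code, seeding, rounding.

#' The 20 proteinogenic amino acids (one-letter, alphabetical)
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Sequence-logo color classes: fixed partition of the 20 amino acids into
# hydrophobic / positively charged / negatively charged / polar uncharged.
AA_CLASS <- c(
  G = "hydrophobic", A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
  I = "hydrophobic", M = "hydrophobic", P = "hydrophobic", F = "hydrophobic",
  Y = "hydrophobic", W = "hydrophobic",
  R = "positive", K = "positive", H = "positive",
  D = "negative", E = "negative",
  C = "polar-uncharged", S = "polar-uncharged", T = "polar-uncharged",
  N = "polar-uncharged", Q = "polar-uncharged"
)

#' Round half away from zero at a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; printed ratio tables in the
#' antibody-engineering literature use conventional half-up rounding, so that
#' convention is applied when reproducing them.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic derivation of per-stage seeds from one master seed, so each
# simulation stage (library draw, each sort round, sequencing) has its own
# reproducible stream. Kept strictly below 2^31.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((abs(seed) * 48271 + stage * 7919) %% 2147483647)
}

# Run expr with a temporary RNG state seeded by `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Translate DNA strings in reading frame +1
#'
#' Standard genetic code; codons containing ambiguous bases translate to
#' \code{X}; stop codons to \code{*}. Input lengths must be divisible by 3
#' (use [translate_frame1()] for the rejection-aware pipeline step).
#'
#' @param dna character vector of DNA sequences (lengths divisible by 3)
#' @return character vector of amino-acid sequences
#' @export
translate_dna <- function(dna) {
  if (length(dna) == 0L) return(character(0))
  stopifnot(all(nchar(dna) %% 3L == 0L))
  out <- Biostrings::translate(
    Biostrings::DNAStringSet(dna),
    genetic.code = Biostrings::GENETIC_CODE,
    if.fuzzy.codon = "X",
    no.init.codon = TRUE
  )
  as.character(out)
}

# Codons encoded by the NNK degenerate codon (N = ACGT, K = G/T): 32 codons
# covering all 20 amino acids plus the amber stop TAG.
nnk_codons <- function() {
  as.vector(outer(
    as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
    c("G", "T"), paste0
  ))
}

# One deterministic NNK codon per amino acid (first in alphabetical codon
# order), used when building variant DNA in the simulator.
nnk_codon_for_aa <- function() {
  cods <- sort(nnk_codons())
  aas <- translate_dna(cods)
  keep <- !duplicated(aas) & aas != "*"
  stats::setNames(cods[keep], aas[keep])
}

# Vectorised Hamming distance between equal-length strings and one pattern.
hamming_to <- function(strings, pattern) {
  n <- nchar(pattern)
  mism <- integer(length(strings))
  for (i in seq_len(n)) {
    mism <- mism + (substr(strings, i, i) != substr(pattern, i, i))
  }
  mism
}
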