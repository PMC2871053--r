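# Internal string/number helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @keywords internal
rc_seq <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Normalize sequences to DNA space: uppercase, U -> T.
dna_norm <- function(x) {
  chartr("U", "T", toupper(x))
}

# Round half away from zero (the convention used by the report tables);
# base round() rounds half to even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage formatting rule for composition tables: one decimal, except
# values below 1% which carry two decimals (so small classes keep a
# significant figure).
round_pct <- function(x) {
  ifelse(x < 1, round_half_up(x, 2), round_half_up(x, 1))
}

# Count-weighted Shannon entropy (bits) of a categorical distribution.
shannon_entropy <- function(weights) {
  w <- weights[weights > 0]
  if (length(w) <= 1L) return(0)
  p <- w / sum(w)
  -sum(p * log2(p))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
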