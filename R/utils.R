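AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of a nucleotide string
#' @param x character vector of DNA sequences (A/C/G/T).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' G+C fraction of a nucleotide string
#' @param x character vector of DNA sequences.
#' @return numeric vector of G+C fractions in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  s <- Biostrings::DNAStringSet(x)
  f <- Biostrings::letterFrequency(s, letters = c("G", "C"))
  as.numeric(rowSums(f) / Biostrings::width(s))
}

# Translate in-frame CDS strings (no terminal stop handling; '*' retained).
translate_nt <- function(x) {
  gc <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    n <- nchar(s) - nchar(s) %% 3L
    if (n < 3L) return("")
    codons <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    aa <- unname(gc[toupper(codons)])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Translate a CDS as annotated (strand-adjusted, terminal stop removed).
translate_cds <- function(cds, strand = "+") {
  if (identical(strand, "-")) cds <- revcomp(cds)
  aa <- translate_nt(cds)
  sub("\\*$", "", aa)
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

random_protein <- function(len, start_met = TRUE) {
  len <- max(2L, as.integer(len))
  body <- sample(AA20, if (start_met) len - 1L else len, replace = TRUE)
  paste0(if (start_met) "M" else "", paste(body, collapse = ""))
}
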