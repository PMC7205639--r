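# Codon universe used throughout: the standard genetic code, with codons
# ordered TTT..GGG (first base slowest, bases in T, C, A, G order).

.BASES <- c("T", "C", "A", "G")

#' The 64 codons in fixed T/C/A/G order (TTT, TTC, ..., GGG)
#' @keywords internal
CODONS_64 <- paste0(
  rep(.BASES, each = 16L),
  rep(rep(.BASES, each = 4L), times = 4L),
  rep(.BASES, times = 16L)
)

#' Standard genetic code over `CODONS_64` (one-letter amino acids, `*` = stop)
#' @keywords internal
GENETIC_CODE_64 <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc[CODONS_64]), CODONS_64)
}

#' @keywords internal
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons in fixed order
#' @keywords internal
SENSE_CODONS <- CODONS_64[!CODONS_64 %in% STOP_CODONS]

#' The 59-codon RSCU universe: sense codons minus the single-codon families
#' Met (ATG) and Trp (TGG)
#' @keywords internal
RSCU_CODONS <- SENSE_CODONS[!SENSE_CODONS %in% c("ATG", "TGG")]

#' Synonymous families of the RSCU universe: amino acid -> codons (n >= 2)
#' @keywords internal
SYN_FAMILIES <- {
  aa <- GENETIC_CODE_64[RSCU_CODONS]
  split(RSCU_CODONS, aa)
}

# third base of each of the 64 codons, named by codon
.THIRD_BASE <- stats::setNames(substring(CODONS_64, 3L, 3L), CODONS_64)

#' Is the third codon position G or C?
#'
#' @param codons character vector of codons.
#' @return logical vector, TRUE where the third base is G or C.
#' @keywords internal
third_base_gc <- function(codons) {
  .THIRD_BASE[codons] %in% c("G", "C")
}

#' Split a coding sequence into consecutive codons
#'
#' @param sequence a nucleotide string whose length is a multiple of 3.
#' @return character vector of codons.
#' @keywords internal
split_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length must be a positive multiple of 3", call. = FALSE)
  }
  substring(sequence, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}
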