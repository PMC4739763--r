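#' Score the coding potential of a transcript sequence
#'
#' A lightweight coding-potential score over the three forward reading
#' frames. The score grows with the length of the longest open reading
#' frame (ATG to stop) and with the codon-usage bias inside that ORF
#' (entropy deficit relative to uniform usage of the sense codons):
#'
#' `score = 2.0 * min(L, 150) / 100 + bias - 2.8`
#'
#' with `L` the longest-ORF length in codons and `bias` in `[0, 1]`.
#' The scale is calibrated so a sequence without any ORF of at least
#' 100 codons scores below -0.5 (confidently non-coding, the cascade's
#' acceptance threshold) while full-length coding sequences of 150+
#' codons score above 0. A sequence with no ORF at all gets the floor
#' score of -2.8.
#'
#' @param sequence a nucleotide string (A/C/G/T), length >= 200.
#' @return A numeric score.
#' @examples
#' scoreCodingPotential(strrep("ACGT", 100)) < -0.5
#' @export
scoreCodingPotential <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (!grepl("^[ACGT]+$", sequence))
    stop("sequence must contain only A/C/G/T")
  orf <- longest_orf(sequence)
  if (orf$n_codons == 0L) return(-2.8)
  tab <- table(orf$codons[-1L])  # codon usage past the start codon
  if (!length(tab)) return(-2.8)
  p <- as.vector(tab) / sum(tab)
  hmax <- log2(min(61L, sum(tab)))
  bias <- if (hmax > 0) max(0, 1 + sum(p * log2(p)) / hmax) else 0
  2.0 * min(orf$n_codons, 150L) / 100 + bias - 2.8
}
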