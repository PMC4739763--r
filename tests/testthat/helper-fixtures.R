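# Shared fixtures, built in code at load time. Kept small so the whole
# suite stays fast; the heavier simulations live in test-acceptance.R.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# a hand-built two-gene genome with known exon structure
make_toy_annotation <- function() {
  set.seed(99)
  exon <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
  intron <- function(n) paste0("GT", exon(n - 4L), "AG")
  # gene X (+): 3 exons of 60 nt, introns 80 / 150 nt
  xe <- replicate(3, exon(60)); xi <- replicate(2, c(80, 150)) # lens
  x_parts <- c(xe[1], intron(80), xe[2], intron(150), xe[3])
  # gene Y (-): 2 exons of 70 nt (coding strand), intron 90 nt
  ye <- replicate(2, exon(70))
  y_parts <- c(ye[1], intron(90), ye[2])
  y_seq <- paste(y_parts, collapse = "")
  spacer <- function(n) exon(n)
  chrom <- paste0(spacer(200), paste(x_parts, collapse = ""), spacer(300),
                  as.character(Biostrings::reverseComplement(Biostrings::DNAString(y_seq))),
                  spacer(200))
  x_start <- 201L
  xs <- x_start + c(0L, 60L + 80L, 60L + 80L + 60L + 150L)
  y_start <- x_start + 60L * 3L + 80L + 150L + 300L
  # gene Y genomic: revcomp of y_seq, exon2 (transcription) comes first
  y_len <- nchar(y_seq)
  # coding-strand coords: exon1 1-70, intron 71-160, exon2 161-230
  y_e1 <- c(y_start + y_len - 70L, y_start + y_len - 1L)
  y_e2 <- c(y_start, y_start + 69L)
  ann <- GenomicRanges::GRanges("chr1",
                 IRanges::IRanges(c(xs, y_e2[1], y_e1[1]),
                         c(xs + 59L, y_e2[2], y_e1[2])),
                 strand = c("+", "+", "+", "-", "-"),
                 gene_id = c("gX", "gX", "gX", "gY", "gY"),
                 transcript_id = c("gX.t1", "gX.t1", "gX.t1",
                                   "gY.t1", "gY.t1"),
                 exon_rank = c(1L, 2L, 3L, 2L, 1L),
                 feature_type = "mRNA")
  list(genome = Biostrings::DNAStringSet(c(chr1 = chrom)), annotation = ann)
}

toy <- make_toy_annotation()

# brute-force mappability oracle: slide every junction-spanning window
# and string-search the whole reference set (genome both strands + all
# EEJ references), counting total occurrences
oracle_mappability <- function(lib, genome) {
  rd <- refData(lib)
  refs <- as.character(refSequences(lib))
  subjects <- c(as.character(genome),
                refs[rd$kind == "EEJ"])
  occurrences <- function(w) {
    p <- Biostrings::DNAString(w)
    rc <- Biostrings::reverseComplement(p)
    sum(vapply(subjects, function(s) {
      ss <- Biostrings::DNAString(s)
      Biostrings::countPattern(p, ss) + Biostrings::countPattern(rc, ss)
    }, numeric(1)))
  }
  out <- rep(NA_integer_, nrow(rd))
  for (i in seq_len(nrow(rd))) {
    if (!rd$kind[i] %in% c("EEJ", "EIJ5", "EIJ3")) next
    b <- rd$left_flank[i]; L <- b + rd$right_flank[i]
    o <- coenosplice:::span_offsets(b, L, lib@readLen, lib@minOverhang)
    if (o[1] > o[2]) { out[i] <- 0L; next }
    w <- substring(refs[i], o[1]:o[2], o[1]:o[2] + lib@readLen - 1L)
    out[i] <- sum(vapply(w, occurrences, numeric(1)) == 1)
  }
  out
}
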