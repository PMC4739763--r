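# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

# the 61 sense codons
sense_codons <- function() {
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all, STOP_CODONS)
}

#' @importFrom withr with_seed
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# random nucleotide string with a target GC fraction
random_seq <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all windows of width w, as a character vector (empty if too short)
seq_windows <- function(x, w) {
  n <- nchar(x)
  if (n < w) return(character(0))
  substring(x, seq_len(n - w + 1L), seq_len(n - w + 1L) + w - 1L)
}

# Longest open reading frame (ATG..stop, stop required) over the three
# forward frames. Returns codon count of the longest ORF (0 if none) and
# its codon strings.
longest_orf <- function(x) {
  n <- nchar(x)
  best <- 0L
  best_codons <- character(0)
  for (frame in 0:2) {
    m <- (n - frame) %/% 3L
    if (m < 2L) next
    starts <- frame + 3L * (seq_len(m) - 1L) + 1L
    codons <- substring(x, starts, starts + 2L)
    is_stop <- codons %in% STOP_CODONS
    is_atg <- codons == "ATG"
    stop_pos <- which(is_stop)
    for (s in which(is_atg)) {
      nxt <- stop_pos[stop_pos > s]
      if (!length(nxt)) next
      len <- nxt[1L] - s  # codons from ATG up to (excluding) the stop
      if (len > best) {
        best <- len
        best_codons <- codons[s:(nxt[1L] - 1L)]
      }
    }
  }
  list(n_codons = best, codons = best_codons)
}

# Rewrite a sequence so no forward-frame ORF reaches `max_codons` codons,
# by planting a stop codon in the middle of any offending ORF.
scrub_orfs <- function(x, max_codons = 60L) {
  repeat {
    n <- nchar(x)
    hit <- NULL
    for (frame in 0:2) {
      m <- (n - frame) %/% 3L
      if (m < 2L) next
      starts <- frame + 3L * (seq_len(m) - 1L) + 1L
      codons <- substring(x, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      stop_pos <- which(is_stop)
      for (s in which(codons == "ATG")) {
        nxt <- stop_pos[stop_pos > s]
        len <- if (length(nxt)) nxt[1L] - s else m - s + 1L
        if (len >= max_codons) {
          hit <- starts[s + len %/% 2L]
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) return(x)
    substr(x, hit, hit + 2L) <- "TAA"
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# uniform draw from an integer range, safe for degenerate lo == hi
sample_range <- function(rng, n = 1L) {
  if (rng[1L] == rng[2L]) rep(rng[1L], n)
  else sample(rng[1L]:rng[2L], n, replace = TRUE)
}
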