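#' Split reads into overlapping fixed-width read groups
#'
#' Each read is split into `windowLen`-nt sub-reads using a sliding
#' window advanced by `step` nt, so a read of length L yields
#' `floor((L - windowLen) / step) + 1` sub-reads (3 for 100 nt, 4 for
#' 125 nt at the 50/25 defaults). All sub-reads of one read form a "read
#' group"; downstream counting uses at most one sub-read per group.
#' Mates of a pair are pooled: pass them in the same read set.
#'
#' @param reads a [Biostrings::DNAStringSet] or named character vector.
#' @param windowLen sub-read length, nt.
#' @param step window step, nt.
#' @return Data frame with one row per sub-read: `group` (read id),
#'   `slot` (window index within the read), `seq`. Reads shorter than
#'   `windowLen` are skipped with a message.
#' @examples
#' nrow(splitReadGroups(c(r1 = strrep("A", 100))))  # 3
#' @export
splitReadGroups <- function(reads, windowLen = 50L, step = 25L) {
  nm <- names(reads)
  x <- as.character(reads)
  names(x) <- if (is.null(nm)) sprintf("read%d", seq_along(x)) else nm
  L <- nchar(x)
  short <- L < windowLen
  if (any(short))
    message(sum(short), " read(s) shorter than ", windowLen, " nt skipped")
  x <- x[!short]; L <- L[!short]
  n_sub <- (L - windowLen) %/% step + 1L
  group <- rep(names(x), n_sub)
  slot <- unlist(lapply(n_sub, seq_len), use.names = FALSE)
  start <- (slot - 1L) * step + 1L
  data.frame(group = group, slot = slot,
             seq = substring(rep(x, n_sub), start, start + windowLen - 1L),
             stringsAsFactors = FALSE)
}
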