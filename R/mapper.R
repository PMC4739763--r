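# Mapping subjects for a genome + junction library: chromosomes plus all
# EEJ-type references. EIJ and intron-body references are contiguous
# genome substrings, so they are never mapped against directly (they
# would make every such read multi-mapping); their support is counted
# from unique genome placements by coordinate overlap instead.
mapping_subjects <- function(genome, library) {
  rd <- library@refData
  eej <- which(rd$kind == "EEJ")
  c(stats::setNames(as.character(genome), names(genome)),
    stats::setNames(as.character(library@references)[eej], rd$id[eej]))
}

#' Map read groups uniquely to the genome plus junction library
#'
#' Places each sub-read against the combined reference set (all
#' chromosomes, both strands, plus every EEJ-type junction reference).
#' A sub-read is placed only when it has exactly one location in the
#' whole set within `maxMismatches`; multi-mapping and unmatched
#' sub-reads are returned unplaced with their location count.
#'
#' With `maxMismatches = 0` matching is exact and hash-based (suited to
#' large simulated read sets, which carry no sequencing errors). With
#' `maxMismatches > 0` an exact pigeonhole seed search is used: the
#' window is split into three disjoint trusted bands, so every location
#' with at most two mismatches is guaranteed to be found.
#'
#' @param groups data frame from [splitReadGroups()].
#' @param genome a [Biostrings::DNAStringSet].
#' @param library a [JunctionLibrary-class].
#' @param maxMismatches maximum mismatches per placement (0-2).
#' @return `groups` with added columns `subject`, `strand`, `pos`
#'   (NA when unplaced) and `n_loc` (number of candidate locations).
#' @export
mapReadGroups <- function(groups, genome, library, maxMismatches = 2L) {
  stopifnot(maxMismatches >= 0L, maxMismatches <= 2L)
  subjects <- mapping_subjects(genome, library)
  w <- library@readLen
  stopifnot(all(nchar(groups$seq) == w))
  if (maxMismatches == 0L) {
    hits <- map_exact(groups$seq, subjects, w)
  } else {
    hits <- map_pigeonhole(groups$seq, subjects, w, maxMismatches)
  }
  cbind(groups, hits)
}

map_exact <- function(qs, subjects, w) {
  win <- lapply(subjects, seq_windows, w = w)
  nwin <- lengths(win)
  subj_windows <- unlist(win, use.names = FALSE)
  subj_id <- rep(names(subjects), nwin)
  subj_pos <- unlist(lapply(nwin, seq_len), use.names = FALSE)
  uw <- unique(subj_windows)
  m <- match(subj_windows, uw)
  cnt <- tabulate(m, nbins = length(uw))
  first <- match(seq_along(uw), m)  # first occurrence per unique window

  uq <- unique(qs)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(uq)))
  fi <- match(uq, uw); ri <- match(rc, uw)
  nf <- ifelse(is.na(fi), 0L, cnt[fi])
  nr <- ifelse(is.na(ri), 0L, cnt[ri])
  n_loc <- nf + nr
  subject <- rep(NA_character_, length(uq))
  strand <- rep(NA_character_, length(uq))
  pos <- rep(NA_integer_, length(uq))
  one_f <- which(n_loc == 1L & nf == 1L)
  one_r <- which(n_loc == 1L & nr == 1L)
  subject[one_f] <- subj_id[first[fi[one_f]]]
  pos[one_f] <- subj_pos[first[fi[one_f]]]
  strand[one_f] <- "+"
  subject[one_r] <- subj_id[first[ri[one_r]]]
  pos[one_r] <- subj_pos[first[ri[one_r]]]
  strand[one_r] <- "-"
  i <- match(qs, uq)
  data.frame(subject = subject[i], strand = strand[i], pos = pos[i],
             n_loc = n_loc[i], stringsAsFactors = FALSE)
}

# Exact <=mm-mismatch location search via three disjoint trusted bands:
# any window with at most two mismatches is exact in at least one band.
map_pigeonhole <- function(qs, subjects, w, mm) {
  uq <- unique(qs)
  pats <- Biostrings::DNAStringSet(uq)
  bands <- list(c(1L, 17L), c(18L, 34L), c(35L, w))
  locs <- vector("list", length(uq))  # per pattern: "subj\tstrand\tpos"
  add_hits <- function(mi, subj_name, strand, subj_len) {
    st <- Biostrings::startIndex(mi)
    for (p in seq_along(st)) {
      s <- st[[p]]
      if (is.null(s) || !length(s)) next
      pos <- if (strand == "+") s else subj_len - s - w + 2L
      locs[[p]] <<- c(locs[[p]], paste(subj_name, strand, pos, sep = "\t"))
    }
  }
  for (si in seq_along(subjects)) {
    subj <- Biostrings::DNAString(subjects[[si]])
    subj_rc <- Biostrings::reverseComplement(subj)
    for (b in bands) {
      pd <- Biostrings::PDict(pats, tb.start = b[1L], tb.end = b[2L])
      add_hits(Biostrings::matchPDict(pd, subj, max.mismatch = mm),
               names(subjects)[si], "+", length(subj))
      add_hits(Biostrings::matchPDict(pd, subj_rc, max.mismatch = mm),
               names(subjects)[si], "-", length(subj))
    }
  }
  locs <- lapply(locs, unique)
  n_loc <- lengths(locs)
  subject <- rep(NA_character_, length(uq))
  strand <- rep(NA_character_, length(uq))
  pos <- rep(NA_integer_, length(uq))
  one <- which(n_loc == 1L)
  if (length(one)) {
    parts <- strsplit(unlist(locs[one]), "\t", fixed = TRUE)
    subject[one] <- vapply(parts, `[`, character(1), 1L)
    strand[one] <- vapply(parts, `[`, character(1), 2L)
    pos[one] <- as.integer(vapply(parts, `[`, character(1), 3L))
  }
  i <- match(qs, uq)
  data.frame(subject = subject[i], strand = strand[i], pos = pos[i],
             n_loc = n_loc[i], stringsAsFactors = FALSE)
}
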