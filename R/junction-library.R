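# Per-transcript structure from any genome + exon annotation: exon /
# intron sequences in transcription order plus their genomic intervals.
tx_structures <- function(genome, exons) {
  chroms <- stats::setNames(as.character(genome), names(genome))
  out <- list()
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx]
    strand <- as.character(BiocGenerics::strand(e))[1L]
    ord <- order(GenomicRanges::start(e), decreasing = identical(strand, "-"))
    e <- e[ord]
    chrom <- as.character(GenomicRanges::seqnames(e))[1L]
    cs <- chroms[[chrom]]
    st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    get <- function(a, b) {
      s <- substr(cs, a, b)
      if (strand == "-") revcomp(s) else s
    }
    n <- length(e)
    exseq <- unname(mapply(get, st, en))
    inseq <- character(0); irs <- integer(0); ire <- integer(0)
    if (n > 1L) for (k in seq_len(n - 1L)) {
      if (strand == "+") { a <- en[k] + 1L; b <- st[k + 1L] - 1L }
      else { a <- en[k + 1L] + 1L; b <- st[k] - 1L }
      if (a > b) stop("transcript ", tx, ": exons overlap or touch")
      irs <- c(irs, a); ire <- c(ire, b)
      inseq <- c(inseq, get(a, b))
    }
    out[[tx]] <- list(
      transcript_id = tx, gene_id = e$gene_id[1L], chrom = chrom,
      strand = strand, ex_gstart = st, ex_gend = en,
      exons = exseq, introns = inseq, in_gstart = irs, in_gend = ire)
  }
  out
}

# genomic read-start range equivalent to reference offsets [o1, o2] of a
# genome-contiguous reference (anchor = genomic coord of ref position 1)
genomic_window <- function(strand, anchor, o1, o2, readLen) {
  if (o1 > o2) return(c(NA_integer_, NA_integer_))
  if (strand == "+") c(anchor + o1 - 1L, anchor + o2 - 1L)
  else c(anchor - o2 - readLen + 2L, anchor - o1 - readLen + 2L)
}

# reference offsets of read starts that span the boundary at position b
# (last base of the left flank) with >= minOverhang on each side
span_offsets <- function(b, L, readLen, minOverhang) {
  o1 <- max(1L, b - (readLen - minOverhang - 1L))
  o2 <- min(L - readLen + 1L, b - minOverhang + 1L)
  c(o1, o2)
}

#' Build the junction reference library
#'
#' Constructs, for every transcript, all forward exon-exon junction
#' (EEJ) references -- one per (donor, downstream acceptor) pair in
#' transcriptional order -- and, per intron, the two exon-intron
#' junction references (EIJ5, EIJ3) plus an intron-body reference (the
#' whole intron when it is at most 200 nt, otherwise a centred 200-nt
#' mid-intron segment). Each junction flank holds up to
#' `readLen - minOverhang` nt, truncated at exon (or intron) boundaries.
#' Per-junction mappability is computed against the genome plus all EEJ
#' references (see [computeMappability()]).
#'
#' The default `minOverhang` of 8 nt makes the maximum mappability of a
#' 50-nt read 50 - 2*8 + 1 = 35 positions.
#'
#' @param annotation exon-level `GRanges` (metadata: `gene_id`,
#'   `transcript_id`; strand set), e.g. [annotationRanges()] output or an
#'   imported GTF.
#' @param genome a [Biostrings::DNAStringSet].
#' @param readLen mapped read (window) length, nt.
#' @param minOverhang minimum junction overhang, nt.
#' @param mappability compute the mappability table (default TRUE).
#' @param maxMismatches mismatch allowance for the mappability
#'   uniqueness check (0 = exact).
#' @return A [JunctionLibrary-class].
#' @examples
#' sg <- generateGenome(genomeSpec(nGenes = 2, nLincrna = 0, seed = 2))
#' lib <- buildJunctionLibrary(annotationRanges(sg), genomeSequences(sg))
#' lib
#' @export
buildJunctionLibrary <- function(annotation, genome, readLen = 50L,
                                 minOverhang = 8L, mappability = TRUE,
                                 maxMismatches = 0L) {
  readLen <- as.integer(readLen); minOverhang <- as.integer(minOverhang)
  flank <- readLen - minOverhang
  strs <- tx_structures(genome, annotation)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))

  ids <- character(0); kinds <- character(0); origins <- character(0)
  genesv <- character(0); txv <- character(0); units <- character(0)
  lfl <- integer(0); rfl <- integer(0); chv <- character(0)
  stv <- character(0); wlo <- integer(0); whi <- integer(0)
  seqs <- character(0)
  sites <- list()

  add_ref <- function(id, kind, origin, gene, tx, unit, lseq, rseq,
                      chrom, strand, win = c(NA_integer_, NA_integer_)) {
    ids <<- c(ids, id); kinds <<- c(kinds, kind); origins <<- c(origins, origin)
    genesv <<- c(genesv, gene); txv <<- c(txv, tx); units <<- c(units, unit)
    lfl <<- c(lfl, nchar(lseq)); rfl <<- c(rfl, nchar(rseq))
    chv <<- c(chv, chrom); stv <<- c(stv, strand)
    wlo <<- c(wlo, win[1L]); whi <<- c(whi, win[2L])
    seqs <<- c(seqs, paste0(lseq, rseq))
  }

  for (s in strs) {
    n <- length(s$exons)
    elen <- nchar(s$exons)
    if (any(s$ex_gend > chrom_len[[s$chrom]]))
      stop("transcript ", s$transcript_id, " extends beyond its chromosome")
    if (n < 2L) next
    # splice-site table (transcription order)
    for (k in seq_len(n - 1L)) {
      dpos <- if (s$strand == "+") s$ex_gend[k] else s$ex_gstart[k]
      apos <- if (s$strand == "+") s$ex_gstart[k + 1L] else s$ex_gend[k + 1L]
      sites[[length(sites) + 1L]] <- data.frame(
        chrom = s$chrom, position = c(dpos, apos),
        kind = c("donor", "acceptor"), strand = s$strand,
        origin = "annotated", support = NA_integer_,
        transcript_id = s$transcript_id, stringsAsFactors = FALSE)
    }
    lflank <- function(k) {
      b <- min(flank, elen[k]); substr(s$exons[k], elen[k] - b + 1L, elen[k])
    }
    rflank <- function(k) substr(s$exons[k], 1L, min(flank, elen[k]))
    # all forward EEJ combinations
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      add_ref(sprintf("%s.eej.%d_%d", s$transcript_id, i, j), "EEJ",
              "annotated", s$gene_id, s$transcript_id,
              sprintf("e%d-e%d", i, j), lflank(i), rflank(j),
              s$chrom, s$strand)
    # IR references per intron
    for (k in seq_len(n - 1L)) {
      iseq <- s$introns[k]; ilen <- nchar(iseq)
      unit <- sprintf("i%d", k)
      # EIJ5: exon k flank | intron start
      l5 <- lflank(k); r5 <- substr(iseq, 1L, min(flank, ilen))
      b <- nchar(l5); L <- b + nchar(r5)
      o <- span_offsets(b, L, readLen, minOverhang)
      anchor <- if (s$strand == "+") s$ex_gend[k] - b + 1L
                else s$ex_gstart[k] + b - 1L
      add_ref(sprintf("%s.eij5.%d", s$transcript_id, k), "EIJ5", "annotated",
              s$gene_id, s$transcript_id, unit, l5, r5, s$chrom, s$strand,
              genomic_window(s$strand, anchor, o[1L], o[2L], readLen))
      # EIJ3: intron end | exon k+1 flank
      bl <- min(flank, ilen)
      l3 <- substr(iseq, ilen - bl + 1L, ilen); r3 <- rflank(k + 1L)
      L <- bl + nchar(r3)
      o <- span_offsets(bl, L, readLen, minOverhang)
      anchor <- if (s$strand == "+") s$in_gend[k] - bl + 1L
                else s$in_gstart[k] + bl - 1L
      add_ref(sprintf("%s.eij3.%d", s$transcript_id, k), "EIJ3", "annotated",
              s$gene_id, s$transcript_id, unit, l3, r3, s$chrom, s$strand,
              genomic_window(s$strand, anchor, o[1L], o[2L], readLen))
      # intron body: whole intron, or a centred 200-nt mid-intron segment
      if (ilen <= 200L) { boff <- 1L; blen <- ilen }
      else { boff <- as.integer(floor(ilen / 2 - 100)) + 1L; blen <- 200L }
      bseq <- substr(iseq, boff, boff + blen - 1L)
      if (s$strand == "+") {
        bs <- s$in_gstart[k] + boff - 1L; be <- bs + blen - 1L
      } else {
        be <- s$in_gend[k] - boff + 1L; bs <- be - blen + 1L
      }
      win <- if (blen >= readLen) c(bs, be - readLen + 1L)
             else c(NA_integer_, NA_integer_)
      add_ref(sprintf("%s.body.%d", s$transcript_id, k), "body", "annotated",
              s$gene_id, s$transcript_id, unit, bseq, "", s$chrom, s$strand,
              win)
    }
  }

  refs <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  rd <- S4Vectors::DataFrame(
    id = ids, kind = kinds, origin = origins, gene_id = genesv,
    transcript_id = txv, unit = units, left_flank = lfl, right_flank = rfl,
    chrom = chv, strand = stv, win_lo = wlo, win_hi = whi)
  lib <- new("JunctionLibrary", references = refs, refData = rd,
             sites = if (length(sites)) do.call(rbind, sites)
                     else data.frame(),
             mappability = data.frame(), readLen = readLen,
             minOverhang = minOverhang)
  if (mappability)
    lib@mappability <- computeMappability(lib, genome,
                                          maxMismatches = maxMismatches)
  lib
}

#' Maximum junction mappability for a read length
#'
#' The number of start positions at which a read of length `readLen` can
#' span a junction while keeping at least `minOverhang` nt on each side:
#' `readLen - 2 * minOverhang + 1`.
#'
#' @param readLen read length, nt.
#' @param minOverhang minimum junction overhang, nt.
#' @return Integer count of positions (35 at the 50/8 defaults).
#' @export
maxMappability <- function(readLen = 50L, minOverhang = 8L) {
  as.integer(readLen - 2L * minOverhang + 1L)
}

#' Per-junction mappability
#'
#' For each EEJ / EIJ reference, counts the junction-spanning read-start
#' positions whose `readLen`-nt window maps back uniquely -- i.e. occurs
#' at no second location in the combined reference set (all chromosomes,
#' both strands, plus every EEJ-type reference) within `maxMismatches`.
#' Intron-body references are genome-contiguous and are not corrected,
#' so they get `NA`.
#'
#' @param library a [JunctionLibrary-class].
#' @param genome the genome `DNAStringSet` the library was built from.
#' @param maxMismatches 0 for exact uniqueness (fast, hash-based);
#'   positive values use exhaustive per-window matching and are intended
#'   for small fixtures.
#' @return Data frame: `id`, `kind`, `mappability`, `max_mappability`.
#' @export
computeMappability <- function(library, genome, maxMismatches = 0L) {
  readLen <- library@readLen; minOverhang <- library@minOverhang
  rd <- library@refData
  eej <- which(rd$kind == "EEJ")
  ref_chr <- as.character(library@references)
  subjects <- c(stats::setNames(as.character(genome), names(genome)),
                stats::setNames(ref_chr[eej], rd$id[eej]))

  count_occurrences <- if (maxMismatches == 0L) {
    subj_windows <- unlist(lapply(subjects, seq_windows, w = readLen),
                           use.names = FALSE)
    uw <- unique(subj_windows)
    cnt <- tabulate(match(subj_windows, uw), nbins = length(uw))
    function(w) {
      rc <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(w)))
      a <- cnt[match(w, uw)]; a[is.na(a)] <- 0L
      b <- cnt[match(rc, uw)]; b[is.na(b)] <- 0L
      a + b
    }
  } else {
    function(w) {
      vapply(w, function(x) {
        p <- Biostrings::DNAString(x)
        rc <- Biostrings::reverseComplement(p)
        sum(vapply(subjects, function(s) {
          ss <- Biostrings::DNAString(s)
          Biostrings::countPattern(p, ss, max.mismatch = maxMismatches) +
            Biostrings::countPattern(rc, ss, max.mismatch = maxMismatches)
        }, numeric(1)))
      }, numeric(1))
    }
  }

  n <- nrow(rd)
  mapp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!rd$kind[i] %in% c("EEJ", "EIJ5", "EIJ3")) next
    b <- rd$left_flank[i]
    L <- b + rd$right_flank[i]
    o <- span_offsets(b, L, readLen, minOverhang)
    if (o[1L] > o[2L]) { mapp[i] <- 0L; next }
    w <- substring(ref_chr[i], o[1L]:o[2L], o[1L]:o[2L] + readLen - 1L)
    mapp[i] <- sum(count_occurrences(w) == 1L)
  }
  data.frame(id = rd$id, kind = rd$kind, mappability = mapp,
             max_mappability = maxMappability(readLen, minOverhang),
             stringsAsFactors = FALSE)
}

#' Discover de novo splice sites from junction reads
#'
#' For every annotated donor, scans the two downstream introns for
#' candidate acceptors (AG motifs); for every annotated acceptor, the
#' two upstream introns for candidate donors (GT motifs). Each candidate
#' defines a novel EEJ joining the annotated site's exonic flank to the
#' contiguous genomic sequence beyond the candidate motif. A candidate
#' is accepted when at least `minSupport` read groups match its EEJ
#' across at least `minPositions` distinct junction-spanning start
#' positions.
#'
#' @param library a [JunctionLibrary-class] (provides readLen/overhang).
#' @param annotation,genome as for [buildJunctionLibrary()].
#' @param readGroups character vector of mapped 50-nt read-group
#'   sequences (e.g. `splitReadGroups(...)$seq`).
#' @param minSupport minimum supporting read groups (default 5).
#' @param minPositions minimum distinct start positions (default 2).
#' @return A list: `sites` (accepted novel splice sites), `references`
#'   (their novel EEJ sequences as a `DNAStringSet`), `candidates`
#'   (all scanned candidates with support counts).
#' @export
discoverDeNovoSpliceSites <- function(library, annotation, genome,
                                      readGroups, minSupport = 5L,
                                      minPositions = 2L) {
  readLen <- library@readLen; minOverhang <- library@minOverhang
  flank <- readLen - minOverhang
  strs <- tx_structures(genome, annotation)
  chroms <- stats::setNames(as.character(genome), names(genome))
  cand <- list()
  for (s in strs) {
    n <- length(s$exons)
    if (n < 2L) next
    cs <- chroms[[s$chrom]]
    elen <- nchar(s$exons)
    # contiguous genomic sequence in transcript orientation, from a
    # genomic coordinate, moving downstream (dir = +1) or upstream (-1)
    contig <- function(gpos, len, dir) {
      step <- if (s$strand == "+") dir else -dir
      a <- if (step > 0L) gpos else gpos - len + 1L
      b <- if (step > 0L) gpos + len - 1L else gpos
      x <- substr(cs, max(1L, a), min(nchar(cs), b))
      if (s$strand == "-") revcomp(x) else x
    }
    for (k in seq_len(n - 1L)) {
      # donor of intron k: scan introns k, k+1 for novel acceptors
      dflank <- substr(s$exons[k], elen[k] - min(flank, elen[k]) + 1L, elen[k])
      for (kk in k:min(k + 1L, n - 1L)) {
        iseq <- s$introns[kk]
        ag <- gregexpr("AG", iseq, fixed = TRUE)[[1L]]
        ag <- ag[ag > 0L & ag + 1L < nchar(iseq)]
        for (a in ag) {
          # genomic coordinate just after the AG, transcript orientation
          gpos <- if (s$strand == "+") s$in_gstart[kk] + a + 1L
                  else s$in_gend[kk] - a - 1L
          cand[[length(cand) + 1L]] <- list(
            tx = s$transcript_id, chrom = s$chrom, strand = s$strand,
            kind = "acceptor", position = gpos,
            left = dflank, right = contig(gpos, flank, +1L))
        }
      }
      # acceptor of intron k: scan introns k, k-1 for novel donors
      aflank <- substr(s$exons[k + 1L], 1L, min(flank, elen[k + 1L]))
      for (kk in max(k - 1L, 1L):k) {
        iseq <- s$introns[kk]
        gt <- gregexpr("GT", iseq, fixed = TRUE)[[1L]]
        gt <- gt[gt > 1L]
        for (g in gt) {
          gpos <- if (s$strand == "+") s$in_gstart[kk] + g - 2L
                  else s$in_gend[kk] - g + 2L
          cand[[length(cand) + 1L]] <- list(
            tx = s$transcript_id, chrom = s$chrom, strand = s$strand,
            kind = "donor", position = gpos,
            left = contig(gpos, flank, -1L), right = aflank)
        }
      }
    }
  }
  if (!length(cand))
    return(list(sites = data.frame(),
                references = Biostrings::DNAStringSet(), candidates = data.frame()))

  support <- integer(length(cand)); positions <- integer(length(cand))
  for (i in seq_along(cand)) {
    ref <- paste0(cand[[i]]$left, cand[[i]]$right)
    b <- nchar(cand[[i]]$left)
    o <- span_offsets(b, nchar(ref), readLen, minOverhang)
    if (o[1L] > o[2L]) next
    w <- substring(ref, o[1L]:o[2L], o[1L]:o[2L] + readLen - 1L)
    m <- table(factor(readGroups[readGroups %in% w], levels = w))
    support[i] <- sum(m)
    positions[i] <- sum(m > 0L)
  }
  cdf <- data.frame(
    transcript_id = vapply(cand, `[[`, character(1), "tx"),
    chrom = vapply(cand, `[[`, character(1), "chrom"),
    strand = vapply(cand, `[[`, character(1), "strand"),
    kind = vapply(cand, `[[`, character(1), "kind"),
    position = vapply(cand, function(x) x$position, numeric(1)),
    support = support, positions = positions, stringsAsFactors = FALSE)
  keep <- !duplicated(cdf[c("chrom", "strand", "kind", "position")])
  acc <- cdf$support >= minSupport & cdf$positions >= minPositions & keep
  refs <- vapply(cand[acc], function(x) paste0(x$left, x$right), character(1))
  names(refs) <- sprintf("denovo.%s.%s.%d", cdf$transcript_id[acc],
                         cdf$kind[acc], cdf$position[acc])
  sites <- cdf[acc, , drop = FALSE]
  if (nrow(sites)) sites$origin <- "de-novo"
  list(sites = sites, references = Biostrings::DNAStringSet(refs),
       candidates = cdf)
}

#' Discover microexon candidates inside annotated introns
#'
#' Scans every annotated intron for internal AG...GT-delimited segments
#' of `lenMin` to `lenMax` nt (default 3-15): a candidate microexon
#' preceded by a candidate acceptor and followed by a candidate donor,
#' which splits the intron into two GT..AG sub-introns. Each candidate
#' yields the two EEJ references joining it to its flanking exons.
#'
#' @param annotation,genome as for [buildJunctionLibrary()].
#' @param lenMin,lenMax microexon length bounds, nt.
#' @param readLen,minOverhang flank parameters for the emitted EEJs.
#' @return Data frame of candidates: transcript, intron index, segment
#'   offset within the intron, length, sequence, and the upstream /
#'   downstream EEJ reference sequences.
#' @export
discoverMicroexons <- function(annotation, genome, lenMin = 3L, lenMax = 15L,
                               readLen = 50L, minOverhang = 8L) {
  flank <- readLen - minOverhang
  strs <- tx_structures(genome, annotation)
  out <- list()
  for (s in strs) {
    n <- length(s$exons)
    if (n < 2L) next
    elen <- nchar(s$exons)
    for (k in seq_len(n - 1L)) {
      iseq <- s$introns[k]; ilen <- nchar(iseq)
      ag <- gregexpr("AG", iseq, fixed = TRUE)[[1L]]
      gt <- gregexpr("GT", iseq, fixed = TRUE)[[1L]]
      ag <- ag[ag > 2L]          # keep the intron's own GT start intact
      gt <- gt[gt > 0L & gt + 1L < ilen]  # and its own AG end
      for (a in ag) for (g in gt) {
        mlen <- g - (a + 2L)
        if (mlen < lenMin || mlen > lenMax) next
        mseq <- substr(iseq, a + 2L, g - 1L)
        lf <- substr(s$exons[k], elen[k] - min(flank, elen[k]) + 1L, elen[k])
        rf <- substr(s$exons[k + 1L], 1L, min(flank, elen[k + 1L]))
        up <- paste0(lf, substr(paste0(mseq, rf), 1L, flank))
        down <- paste0(substr(paste0(lf, mseq),
                              nchar(lf) + mlen - flank + 1L,
                              nchar(lf) + mlen), rf)
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = s$transcript_id, intron = k, offset = a + 2L,
          length = mlen, seq = mseq, eej_up = up, eej_down = down,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    data.frame(transcript_id = character(0), intron = integer(0),
               offset = integer(0), length = integer(0), seq = character(0),
               eej_up = character(0), eej_down = character(0))
  else do.call(rbind, out)
}

#' Export a junction library to FASTA + TSV
#'
#' @param library a [JunctionLibrary-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
exportJunctionLibrary <- function(library, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(library@references,
                              file.path(dir, "junctions.fa"))
  utils::write.table(as.data.frame(library@refData),
                     file.path(dir, "references.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(library@sites, file.path(dir, "sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(library@mappability, file.path(dir, "mappability.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
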