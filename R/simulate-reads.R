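# Decompose a fixture into per-transcript structures used by the read
# simulator: exon and intron sequences in transcription order.
transcript_structures <- function(sg) {
  chrom <- as.character(sg@genome[[1L]])
  ex <- sg@exons
  out <- list()
  for (tx in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == tx]
    strand <- as.character(BiocGenerics::strand(e))[1L]
    ord <- order(GenomicRanges::start(e),
                 decreasing = identical(strand, "-"))
    e <- e[ord]
    st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
    get <- function(a, b) {
      s <- substr(chrom, a, b)
      if (strand == "-") revcomp(s) else s
    }
    exseq <- mapply(get, st, en)
    n <- length(e)
    inseq <- character(0)
    if (n > 1L) {
      inseq <- vapply(seq_len(n - 1L), function(k) {
        if (strand == "+") get(en[k] + 1L, st[k + 1L] - 1L)
        else get(en[k + 1L] + 1L, st[k] - 1L)
      }, character(1))
    }
    out[[tx]] <- list(transcript_id = tx,
                      gene_id = e$gene_id[1L], strand = strand,
                      exons = unname(exseq), introns = unname(inseq),
                      exon_ids = sprintf("%s.e%d", tx, seq_len(n)),
                      intron_ids = if (n > 1L)
                        sprintf("%s.i%d", tx, seq_len(n - 1L)) else character(0))
  }
  out
}

build_isoform <- function(str, retained, included) {
  n <- length(str$exons)
  parts <- character(0)
  for (k in seq_len(n)) {
    if (included[k]) parts <- c(parts, str$exons[k])
    if (k < n && retained[k]) parts <- c(parts, str$introns[k])
  }
  paste(parts, collapse = "")
}

#' Simulate stranded RNA-seq reads for one stage
#'
#' Draws `librarySize` reads per replicate. Per-feature read counts are
#' multinomial with weights expression x mature length; each read picks
#' an isoform by Bernoulli draws against the stage's PIR / PSI truth
#' (a retained intron stays in with probability PIR/100, a cassette exon
#' is included with probability PSI/100; introns flanking a skipped exon
#' are always spliced), then a uniform start position along that isoform.
#' Reads report the transcript strand (stranded protocol) and carry no
#' sequencing errors. Deterministic for a fixed profile seed.
#'
#' @param sg a [SyntheticGenome-class].
#' @param profile a [StageProfile-class]; features named in its truth
#'   vectors must exist in the annotation.
#' @return Named list (one element per replicate) of
#'   [Biostrings::DNAStringSet] read sets.
#' @export
simulateStageReads <- function(sg, profile) {
  validObject(profile)
  strs <- transcript_structures(sg)
  by_gene <- stats::setNames(names(strs),
                             vapply(strs, `[[`, character(1), "gene_id"))
  expr <- profile@expression
  unknown <- setdiff(names(expr), names(by_gene))
  if (length(unknown))
    stop("expression truth names unknown features: ",
         paste(unknown, collapse = ", "))
  known_units <- unlist(lapply(strs, function(s) c(s$intron_ids, s$exon_ids)))
  bad <- setdiff(c(names(profile@pir), names(profile@psi)), known_units)
  if (length(bad))
    stop("PIR/PSI truth names unknown introns/exons: ",
         paste(bad, collapse = ", "))

  feats <- names(expr)[expr > 0]
  mat_len <- vapply(feats, function(f)
    sum(nchar(strs[[by_gene[[f]]]]$exons)), numeric(1))
  short <- feats[mat_len < profile@readLen]
  if (length(short))
    stop("read length ", profile@readLen,
         " exceeds the mature length of: ", paste(short, collapse = ", "))
  w <- expr[feats] * mat_len

  out <- list()
  for (r in seq_len(profile@replicates)) {
    reads <- with_seed_(profile@seed + 7919L * r, {
      n_per <- if (length(feats))
        as.vector(stats::rmultinom(1L, profile@librarySize, w)) else integer(0)
      acc <- character(0)
      for (fi in seq_along(feats)) {
        n <- n_per[fi]
        if (n == 0L) next
        str <- strs[[by_gene[[feats[fi]]]]]
        n_ex <- length(str$exons)
        p_ret <- profile@pir[str$intron_ids] / 100
        p_ret[is.na(p_ret)] <- 0
        p_inc <- profile@psi[str$exon_ids] / 100
        p_inc[is.na(p_inc)] <- 1
        ret <- matrix(stats::runif(n * max(n_ex - 1L, 0L)) <
                        rep(p_ret, each = n), nrow = n)
        inc <- matrix(stats::runif(n * n_ex) < rep(p_inc, each = n), nrow = n)
        # splice the introns flanking every skipped exon
        if (n_ex > 1L) for (k in seq_len(n_ex)) {
          skip <- !inc[, k]
          if (k > 1L) ret[skip, k - 1L] <- FALSE
          if (k < n_ex) ret[skip, k] <- FALSE
        }
        rkey <- if (ncol(ret)) apply(ret, 1L, paste, collapse = "")
                else rep("", n)
        key <- paste(rkey, apply(inc, 1L, paste, collapse = ""))
        rep_of <- vapply(split(seq_len(n), key), `[`, integer(1), 1L)
        iso_seq <- vapply(rep_of, function(j)
          build_isoform(str, ret[j, ], inc[j, ]), character(1))
        iso_len <- nchar(iso_seq)
        if (any(iso_len < profile@readLen))
          stop("isoform of ", feats[fi], " shorter than the read length")
        # fragments come from molecules in proportion to molarity x
        # length, so re-draw the per-pattern read counts with the
        # pattern frequencies tilted by isoform length
        freq <- tabulate(match(key, names(rep_of)), nbins = length(rep_of))
        n_u <- as.vector(stats::rmultinom(1L, n, freq * iso_len))
        starts <- unlist(mapply(function(m, len)
          if (m > 0L) sample.int(len - profile@readLen + 1L, m,
                                 replace = TRUE) else integer(0),
          n_u, iso_len, SIMPLIFY = FALSE), use.names = FALSE)
        acc <- c(acc, substring(rep(iso_seq, n_u), starts,
                                starts + profile@readLen - 1L))
      }
      acc
    })
    nm <- sprintf("%s_rep%d_read%06d", profile@stageName, r,
                  seq_along(reads))
    out[[sprintf("rep%d", r)]] <-
      Biostrings::DNAStringSet(stats::setNames(reads, nm))
  }
  out
}

#' Write simulated reads as FASTQ
#'
#' @param reads a named [Biostrings::DNAStringSet] (one replicate).
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeReadsFastq <- function(reads, path) {
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = qual)
  invisible(path)
}
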