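#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
NULL

# One protein-coding gene model on its coding strand.
# Exon lengths are padded so the mRNA is a whole number of codons and
# carries one full-length ORF (ATG ... sense codons ... stop); introns are
# GT..AG. Returns the genomic (coding-strand) sequence plus coding-strand
# exon/intron intervals in transcription order.
make_gene_model <- function(spec) {
  n_ex <- sample_range(spec@exonsPerGene)
  elens <- sample_range(spec@exonLen, n_ex)
  rem <- sum(elens) %% 3L
  if (rem) elens[n_ex] <- elens[n_ex] + (3L - rem)
  ncod <- sum(elens) %/% 3L
  mrna <- paste0("ATG",
                 paste(sample(sense_codons(), ncod - 2L, replace = TRUE),
                       collapse = ""),
                 sample(STOP_CODONS, 1L))
  ilens <- if (n_ex > 1L)
    sample_range(spec@intronLen, n_ex - 1L)
  else integer(0)
  introns <- vapply(ilens, function(l)
    paste0("GT", random_seq(l - 4L, spec@gcContent), "AG"), character(1))

  ce <- cumsum(elens)
  cs <- ce - elens + 1L
  exon_seqs <- substring(mrna, cs, ce)
  gseq <- exon_seqs[1L]
  pos <- elens[1L]
  ex_start <- integer(n_ex); ex_end <- integer(n_ex)
  ex_start[1L] <- 1L; ex_end[1L] <- elens[1L]
  in_start <- integer(length(ilens)); in_end <- integer(length(ilens))
  if (n_ex > 1L) for (k in 2:n_ex) {
    in_start[k - 1L] <- pos + 1L
    in_end[k - 1L] <- pos + ilens[k - 1L]
    gseq <- paste0(gseq, introns[k - 1L], exon_seqs[k])
    pos <- pos + ilens[k - 1L]
    ex_start[k] <- pos + 1L
    ex_end[k] <- pos + elens[k]
    pos <- pos + elens[k]
  }
  list(seq = gseq, len = nchar(gseq), n_ex = n_ex,
       ex_start = ex_start, ex_end = ex_end,
       in_start = in_start, in_end = in_end,
       strand = sample(c("+", "-"), 1L))
}

# Noncoding locus sequence: random at the target GC, stop-scrubbed so no
# forward-frame ORF reaches 60 codons (keeps the coding-potential score
# of planted noncoding loci confidently below the cascade threshold).
make_noncoding_seq <- function(len, gc) scrub_orfs(random_seq(len, gc), 60L)

# Greedy head-to-head / head-to-tail strand assignment for lincRNA loci.
# A locus on "+" is classified against the gene to its left, one on "-"
# against the gene to its right; head-to-head iff the strands differ.
assign_linc_strands <- function(sL, sR, mix) {
  n <- length(sL)
  strand <- character(n)
  cls <- character(n)
  quota <- round(mix * n)
  hh_opt <- function(i) if (sL[i] == "-") "+" else if (sR[i] == "+") "-" else NA
  ht_opt <- function(i) if (sL[i] == "+") "+" else if (sR[i] == "-") "-" else NA
  forced_hh <- vapply(seq_len(n), function(i) is.na(ht_opt(i)), logical(1))
  forced_ht <- vapply(seq_len(n), function(i) is.na(hh_opt(i)), logical(1))
  for (i in which(forced_hh)) { strand[i] <- hh_opt(i); cls[i] <- "head-to-head" }
  for (i in which(forced_ht)) { strand[i] <- ht_opt(i); cls[i] <- "head-to-tail" }
  quota <- quota - sum(forced_hh)
  for (i in which(!forced_hh & !forced_ht)) {
    if (quota > 0L) {
      strand[i] <- hh_opt(i); cls[i] <- "head-to-head"; quota <- quota - 1L
    } else {
      strand[i] <- ht_opt(i); cls[i] <- "head-to-tail"
    }
  }
  list(strand = strand, class = cls)
}

#' Generate a synthetic genome, annotation and truth tables
#'
#' Lays out a single toy chromosome: protein-coding genes with GT-AG
#' introns and full-length ORFs, intergenic spacers, and lincRNA loci
#' planted in the gaps between genes with a controlled head-to-head /
#' head-to-tail orientation mix. Optionally plants one decoy locus per
#' lincRNA-cascade failure mode. Per-stage truth (expression, intron
#' PIR, cassette-exon PSI) is drawn for two default stages "A" and "B".
#'
#' Exons of a gene are sorted and non-overlapping; every intron starts GT
#' and ends AG on the coding strand; lincRNA loci never overlap gene
#' bodies. Output is deterministic for a fixed spec + seed.
#'
#' @param spec a [GenomeSpec-class].
#' @return A [SyntheticGenome-class].
#' @examples
#' sg <- generateGenome(genomeSpec(nGenes = 3, nLincrna = 1, seed = 7))
#' sg
#' @export
generateGenome <- function(spec) {
  validObject(spec)
  with_seed_(spec@seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  gc <- spec@gcContent
  genes <- lapply(seq_len(spec@nGenes), function(i) make_gene_model(spec))
  gene_ids <- sprintf("g%03d", seq_len(spec@nGenes))

  # lincRNA loci (+ optional decoys), assigned round-robin to the gaps
  # between consecutive genes
  n_gap <- max(spec@nGenes - 1L, 0L)
  linc <- list()
  add_linc <- function(cls, len) {
    id <- sprintf("linc%03d", length(linc) + 1L)
    linc[[length(linc) + 1L]] <<- list(id = id, class = cls, len = len,
                                       seq = make_noncoding_seq(len, gc))
  }
  for (i in seq_len(spec@nLincrna))
    add_linc("lincRNA", sample_range(spec@lincrnaLen))
  if (spec@decoys) {
    add_linc("decoy_short", 150L)
    add_linc("decoy_ncrna", 500L)
    add_linc("decoy_repeat", 500L)
    add_linc("decoy_lowexpr", 500L)
    add_linc("decoy_utr_proximal", 500L)
  }
  n_linc <- length(linc)
  if (n_linc > 0L && n_gap == 0L && spec@nGenes > 1L)
    stop("cannot place lincRNA loci: no intergenic gap available")

  gap_of <- if (n_gap > 0L) rep(seq_len(n_gap), length.out = n_linc)
            else rep(0L, n_linc)
  # the UTR-proximal decoy needs a "+" gene on its left; pick such a gap
  utr_idx <- which(vapply(linc, function(l) l$class == "decoy_utr_proximal",
                          logical(1)))
  if (length(utr_idx) && n_gap > 0L) {
    plus_gaps <- which(vapply(seq_len(n_gap),
                              function(g) genes[[g]]$strand == "+", logical(1)))
    if (!length(plus_gaps)) { genes[[1L]]$strand <- "+"; plus_gaps <- 1L }
    gap_of[utr_idx] <- plus_gaps[1L]
  }

  # strand / orientation class per locus
  strand_linc <- rep("+", n_linc)
  class_linc <- rep(NA_character_, n_linc)
  real <- which(vapply(linc, function(l) l$class == "lincRNA", logical(1)))
  if (length(real) && n_gap > 0L) {
    sL <- vapply(gap_of[real], function(g) genes[[g]]$strand, character(1))
    sR <- vapply(gap_of[real], function(g) genes[[g + 1L]]$strand, character(1))
    asg <- assign_linc_strands(sL, sR, spec@orientationMix)
    strand_linc[real] <- asg$strand
    class_linc[real] <- asg$class
  }

  # assemble chromosome pieces in genomic order
  draw_spacer <- function()
    random_seq(sample_range(spec@intergenicLen), gc)
  pieces <- list()
  push <- function(kind, seq, meta = NULL)
    pieces[[length(pieces) + 1L]] <<- list(kind = kind, seq = seq, meta = meta)

  push("spacer", draw_spacer())
  push_linc <- function(j) {
    if (linc[[j]]$class == "decoy_utr_proximal")
      push("linc", linc[[j]]$seq, modifyList(linc[[j]], list(strand = "+")))
    else
      push("linc",
           if (strand_linc[j] == "+") linc[[j]]$seq else revcomp(linc[[j]]$seq),
           modifyList(linc[[j]], list(strand = strand_linc[j],
                                      orientation = class_linc[j])))
  }
  # Emits the whole intergenic gap after gene g, spacers included. A
  # lone lincRNA is placed nearer the flanking gene it is classified
  # against (left for "+" loci, right for "-"), so that gene is its
  # nearest neighbour; the UTR-proximal decoy sits 300 nt from the gene
  # on its left.
  emit_gap <- function(g) {
    members <- which(gap_of == g)
    members <- members[order(vapply(linc[members], function(l)
      l$class != "decoy_utr_proximal", logical(1)))]
    if (!length(members)) { push("spacer", draw_spacer()); return(invisible()) }
    for (mi in seq_along(members)) {
      j <- members[mi]
      if (linc[[j]]$class == "decoy_utr_proximal") {
        push("spacer", random_seq(300L, gc))
        push_linc(j)
        if (mi == length(members)) push("spacer", draw_spacer())
        next
      }
      d1 <- sample_range(spec@intergenicLen)
      d2 <- sample_range(spec@intergenicLen)
      lo <- min(d1, d2); hi <- max(d1, d2) + (d1 == d2)
      before <- if (strand_linc[j] == "+") lo else hi
      after <- if (strand_linc[j] == "+") hi else lo
      push("spacer", random_seq(before, gc))
      push_linc(j)
      if (mi == length(members)) push("spacer", random_seq(after, gc))
    }
  }
  if (spec@nGenes == 0L) {
    for (j in seq_len(n_linc)) {
      push("linc", linc[[j]]$seq, modifyList(linc[[j]], list(strand = "+")))
      push("spacer", draw_spacer())
    }
  } else {
    for (i in seq_len(spec@nGenes)) {
      gm <- genes[[i]]
      gseq <- if (gm$strand == "+") gm$seq else revcomp(gm$seq)
      push("gene", gseq, c(gm, list(id = gene_ids[i])))
      if (i < spec@nGenes) emit_gap(i)
    }
    push("spacer", draw_spacer())
  }

  lens <- vapply(pieces, function(p) nchar(p$seq), integer(1))
  offs <- c(0L, cumsum(lens))[seq_along(lens)]
  chrom_seq <- paste(vapply(pieces, `[[`, character(1), "seq"), collapse = "")

  # exon annotation + truth feature table
  ex_rows <- list(); feat_rows <- list(); rep_rows <- list()
  for (k in seq_along(pieces)) {
    p <- pieces[[k]]
    if (p$kind == "gene") {
      gm <- p$meta
      gs <- offs[k] + 1L
      L <- gm$len
      for (e in seq_len(gm$n_ex)) {
        if (gm$strand == "+") {
          st <- gs - 1L + gm$ex_start[e]; en <- gs - 1L + gm$ex_end[e]
        } else {
          st <- gs - 1L + (L - gm$ex_end[e] + 1L)
          en <- gs - 1L + (L - gm$ex_start[e] + 1L)
        }
        ex_rows[[length(ex_rows) + 1L]] <- data.frame(
          start = st, end = en, strand = gm$strand, gene_id = gm$id,
          transcript_id = paste0(gm$id, ".t1"), exon_rank = e,
          feature_type = "mRNA", stringsAsFactors = FALSE)
      }
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        id = gm$id, class = "coding", chrom = "chr1",
        start = gs, end = offs[k] + L, strand = gm$strand,
        length = sum(gm$ex_end - gm$ex_start + 1L), stringsAsFactors = FALSE)
    } else if (p$kind == "linc") {
      m <- p$meta
      st <- offs[k] + 1L; en <- offs[k] + nchar(p$seq)
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        start = st, end = en, strand = m$strand, gene_id = m$id,
        transcript_id = paste0(m$id, ".t1"), exon_rank = 1L,
        feature_type = "lincRNA", stringsAsFactors = FALSE)
      feat_rows[[length(feat_rows) + 1L]] <- data.frame(
        id = m$id, class = m$class, chrom = "chr1", start = st, end = en,
        strand = m$strand, length = m$len, stringsAsFactors = FALSE)
      if (m$class == "decoy_repeat")
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(start = st, end = en)
    }
  }
  exdf <- do.call(rbind, ex_rows)
  exons <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(exdf$start, exdf$end), strand = exdf$strand,
    type = "exon", gene_id = exdf$gene_id, transcript_id = exdf$transcript_id,
    exon_rank = exdf$exon_rank, feature_type = exdf$feature_type)
  feats <- do.call(rbind, feat_rows)
  reps <- if (length(rep_rows)) {
    rdf <- do.call(rbind, rep_rows)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(rdf$start, rdf$end))
  } else GenomicRanges::GRanges()

  truth <- default_truth(genes, gene_ids, feats)
  genome <- Biostrings::DNAStringSet(stats::setNames(chrom_seq, "chr1"))
  new("SyntheticGenome", genome = genome, exons = exons, repeats = reps,
      truth = c(list(features = feats), truth), spec = spec)
}

# Default two-stage truth: expression for every feature, PIR for every
# intron, PSI for each gene's designated cassette exon.
default_truth <- function(genes, gene_ids, feats) {
  stages <- c("A", "B")
  expr <- list(); pir <- list(); psi <- list()
  for (i in seq_along(genes)) {
    base <- 10^stats::runif(1, 0.7, 1.8)
    fb <- base * 2^stats::rnorm(1, 0, 0.5)
    expr[[length(expr) + 1L]] <- data.frame(
      feature = gene_ids[i], stage = stages, fpkm = c(base, fb))
    gm <- genes[[i]]
    if (gm$n_ex > 1L) for (k in seq_len(gm$n_ex - 1L)) {
      pa <- sample(c(0, 2, 10, 25, 50), 1L, prob = c(.4, .2, .2, .1, .1))
      pb <- if (stats::runif(1) < 0.2) min(100, pa + 35) else pa
      pir[[length(pir) + 1L]] <- data.frame(
        intron = sprintf("%s.t1.i%d", gene_ids[i], k), stage = stages,
        pir = c(pa, pb))
    }
    if (gm$n_ex >= 3L) {
      cass <- 1L + max(1L, (gm$n_ex - 1L) %/% 2L)  # an internal exon
      sa <- sample(c(100, 95, 80, 60), 1L, prob = c(.4, .3, .2, .1))
      sb <- if (stats::runif(1) < 0.2) max(0, sa - 40) else sa
      psi[[length(psi) + 1L]] <- data.frame(
        exon = sprintf("%s.t1.e%d", gene_ids[i], cass), stage = stages,
        psi = c(sa, sb))
    }
  }
  lincs <- feats[feats$class != "coding", , drop = FALSE]
  if (nrow(lincs)) for (j in seq_len(nrow(lincs))) {
    f <- if (lincs$class[j] == "decoy_lowexpr") c(0.3, 0.2)
         else c(stats::runif(1, 6, 12), stats::runif(1, 2, 6))
    expr[[length(expr) + 1L]] <- data.frame(
      feature = lincs$id[j], stage = stages, fpkm = f)
  }
  list(expression = do.call(rbind, expr),
       pir = if (length(pir)) do.call(rbind, pir)
             else data.frame(intron = character(0), stage = character(0),
                             pir = numeric(0)),
       psi = if (length(psi)) do.call(rbind, psi)
             else data.frame(exon = character(0), stage = character(0),
                             psi = numeric(0)))
}

#' Export a synthetic fixture to standard formats
#'
#' Writes `genome.fa` (FASTA), `annotation.gtf` (GTF, 1-based inclusive)
#' and the truth tables as TSV into `dir`. Identical fixtures write
#' byte-identical files.
#'
#' @param sg a [SyntheticGenome-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportSyntheticData <- function(sg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sg@genome, file.path(dir, "genome.fa"))
  gr <- sg@exons
  rtracklayer::export(gr, file.path(dir, "annotation.gtf"), format = "gtf")
  for (nm in names(sg@truth))
    utils::write.table(sg@truth[[nm]],
                       file.path(dir, sprintf("truth_%s.tsv", nm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Build default stage profiles from a fixture's truth tables
#'
#' @param sg a [SyntheticGenome-class].
#' @param librarySize reads per replicate.
#' @param readLen read length (nt).
#' @param replicates replicates per stage.
#' @param seed integer seed.
#' @return Named list of [StageProfile-class], one per truth stage.
#' @export
stageProfiles <- function(sg, librarySize = 50000L, readLen = 100L,
                          replicates = 3L, seed = 1L) {
  tt <- sg@truth
  stages <- unique(tt$expression$stage)
  out <- lapply(seq_along(stages), function(si) {
    s <- stages[si]
    e <- tt$expression[tt$expression$stage == s, ]
    p <- tt$pir[tt$pir$stage == s, ]
    q <- tt$psi[tt$psi$stage == s, ]
    stageProfile(s,
                 expression = stats::setNames(e$fpkm, e$feature),
                 pir = stats::setNames(p$pir, p$intron),
                 psi = stats::setNames(q$psi, q$exon),
                 replicates = replicates, librarySize = librarySize,
                 readLen = readLen, seed = seed + 1000L * si)
  })
  stats::setNames(out, stages)
}
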