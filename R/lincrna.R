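#' Classify a locus orientation against its adjacent gene
#'
#' The nearest protein-coding gene (by genomic distance, either side)
#' defines the orientation class: head-to-head when the locus and the
#' gene are on opposite strands (divergent pairs may share a
#' bidirectional promoter), head-to-tail when they run in the same
#' direction (the locus promoter lies downstream of the gene). Loci
#' with no gene on their chromosome are unclassified (`NA`); ties go to
#' the leftmost neighbour.
#'
#' @param loci `GRanges` of candidate loci (strand set).
#' @param genes `GRanges` of protein-coding gene bodies (strand set).
#' @return Data frame: `orientation` ("head-to-head" / "head-to-tail" /
#'   NA), `neighbor` (index into `genes`), `distance` (gap in nt; 0 for
#'   overlap).
#' @export
classifyOrientation <- function(loci, genes) {
  n <- length(loci)
  orientation <- rep(NA_character_, n)
  neighbor <- rep(NA_integer_, n)
  distance <- rep(NA_real_, n)
  if (!length(genes)) {
    return(data.frame(orientation = orientation, neighbor = neighbor,
                      distance = distance, stringsAsFactors = FALSE))
  }
  gs <- GenomicRanges::start(genes); ge <- GenomicRanges::end(genes)
  gchr <- as.character(GenomicRanges::seqnames(genes))
  gstr <- as.character(BiocGenerics::strand(genes))
  for (i in seq_len(n)) {
    chr <- as.character(GenomicRanges::seqnames(loci))[i]
    str <- as.character(BiocGenerics::strand(loci))[i]
    cand <- which(gchr == chr)
    if (!length(cand)) next
    ls <- GenomicRanges::start(loci)[i]; le <- GenomicRanges::end(loci)[i]
    gap <- pmax(0, pmax(gs[cand] - le, ls - ge[cand]) - 1L)
    nb <- cand[which.min(gap)]  # which.min takes the first = leftmost
    neighbor[i] <- nb
    distance[i] <- min(gap)
    orientation[i] <- if (gstr[nb] != str) "head-to-head" else "head-to-tail"
  }
  data.frame(orientation = orientation, neighbor = neighbor,
             distance = distance, stringsAsFactors = FALSE)
}

#' Run the lincRNA discovery filter cascade
#'
#' Applies, in order: (1) length over 200 nt; (2) no homology hit with
#' e-value below 1e-3; (3) no known ncRNA-family hit; (4) coding
#' potential score below -0.5; (5) no overlap with annotated gene
#' bodies + UTRs; (6) head-to-tail candidates closer than 1000 nt to
#' their upstream gene are flagged as possible mis-annotated UTRs and
#' dropped (kept with `keepFlagged = TRUE`); (7) no repeat overlap;
#' (8) surviving transcripts are collapsed into loci (same-strand
#' overlap); (9) locus expression of at least `exprHigh` FPKM in one
#' sample and above `exprLow` FPKM in all remaining samples. The audit
#' records the first rejecting step of every candidate; rejections plus
#' survivors always add up to the input.
#'
#' @param candidates `GRanges` of candidate transcripts with a
#'   metadata column `id`; multi-exon candidates are represented by
#'   their locus span.
#' @param evidence data frame keyed by `id` with columns
#'   `homology_evalue` (NA = no hit), `ncrna_hit` (logical),
#'   `coding_score`.
#' @param annotation `GRanges` of annotated protein-coding gene + UTR
#'   intervals (gene bodies).
#' @param repeats `GRanges` of repeat intervals (may be empty).
#' @param expression matrix of FPKM, rows = candidate ids, one column
#'   per sample.
#' @param minLen,eMax,codingMax,utrDist,exprHigh,exprLow thresholds as
#'   above.
#' @param exprRule `"all"` (default) requires every remaining sample
#'   above `exprLow`; `"any"` only one.
#' @param keepFlagged keep step-6 flagged candidates.
#' @return List: `loci` (`GRanges` of surviving loci with orientation
#'   class, neighbor distance and max FPKM), `audit` (data frame id,
#'   rejected_at -- `"none"` for survivors, with the locus id),
#'   `flagged` (ids flagged at step 6).
#' @export
runDiscoveryCascade <- function(candidates, evidence, annotation,
                                repeats = NULL, expression,
                                minLen = 200L, eMax = 1e-3,
                                codingMax = -0.5, utrDist = 1000L,
                                exprHigh = 5, exprLow = 1,
                                exprRule = c("all", "any"),
                                keepFlagged = FALSE) {
  exprRule <- match.arg(exprRule)
  ids <- candidates$id
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  missing <- setdiff(ids, evidence$id)
  if (length(missing))
    stop("candidates missing from evidence: ", paste(missing, collapse = ", "))
  missing <- setdiff(ids, rownames(expression))
  if (length(missing))
    stop("candidates missing from expression: ", paste(missing, collapse = ", "))
  ev <- evidence[match(ids, evidence$id), ]
  rejected <- rep(NA_character_, length(ids))
  flag <- function(step, bad) rejected[is.na(rejected) & bad] <<- step

  flag("length", GenomicRanges::width(candidates) <= minLen)
  flag("homology", !is.na(ev$homology_evalue) & ev$homology_evalue < eMax)
  flag("ncrna", ev$ncrna_hit)
  flag("coding_potential", ev$coding_score >= codingMax)
  ov <- IRanges::overlapsAny(candidates, annotation, ignore.strand = TRUE)
  flag("gene_overlap", ov)

  ori <- classifyOrientation(candidates, annotation)
  utr_flagged <- !is.na(ori$orientation) &
    ori$orientation == "head-to-tail" & ori$distance < utrDist
  flagged_ids <- ids[is.na(rejected) & utr_flagged]
  if (!keepFlagged) flag("utr_proximal", utr_flagged)

  if (!is.null(repeats) && length(repeats))
    flag("repeat", IRanges::overlapsAny(candidates, repeats,
                                        ignore.strand = TRUE))

  surv <- which(is.na(rejected))
  locus_of <- rep(NA_character_, length(ids))
  loci <- GenomicRanges::GRanges()
  if (length(surv)) {
    sc <- candidates[surv]
    red <- GenomicRanges::reduce(sc, ignore.strand = FALSE)
    hit <- GenomicRanges::findOverlaps(sc, red)
    locus_idx <- S4Vectors::subjectHits(hit)[match(seq_along(sc),
                                                   S4Vectors::queryHits(hit))]
    locus_ids <- sprintf("locus%03d", seq_along(red))
    locus_of[surv] <- locus_ids[locus_idx]
    # locus expression = per-sample max over member transcripts
    lex <- do.call(rbind, lapply(seq_along(red), function(li) {
      mem <- ids[surv][locus_idx == li]
      apply(expression[mem, , drop = FALSE], 2L, max)
    }))
    pass <- apply(lex, 1L, function(x) {
      hi <- which.max(x)
      rest <- x[-hi]
      max(x) >= exprHigh &&
        (if (exprRule == "all") all(rest > exprLow)
         else (!length(rest) || any(rest > exprLow)))
    })
    for (li in which(!pass))
      rejected[!is.na(locus_of) & locus_of == locus_ids[li]] <- "expression"
    keep <- which(pass)
    if (length(keep)) {
      loci <- red[keep]
      lori <- classifyOrientation(loci, annotation)
      S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
        locus_id = locus_ids[keep],
        n_transcripts = as.integer(table(factor(locus_idx,
                                                levels = seq_along(red)))[keep]),
        orientation = lori$orientation,
        neighbor_distance = lori$distance,
        max_fpkm = apply(lex[keep, , drop = FALSE], 1L, max))
    }
  }
  audit <- data.frame(id = ids,
                      rejected_at = ifelse(is.na(rejected), "none", rejected),
                      locus = locus_of, stringsAsFactors = FALSE)
  audit$locus[audit$rejected_at != "none"] <- NA_character_
  list(loci = loci, audit = audit, flagged = flagged_ids)
}

#' Expression correlation between loci and their neighbour genes
#'
#' Pearson correlation (with its two-sided p-value) of the expression
#' profiles of each (locus, neighbour gene) pair across samples.
#'
#' @param pairs data frame with columns `locus`, `gene` (row names of
#'   `expression`).
#' @param expression matrix, rows = features, columns = samples (>= 3).
#' @return `pairs` with added `r` and `p` (NA and a flag when a profile
#'   has zero variance).
#' @export
neighborExpressionCorrelation <- function(pairs, expression) {
  stopifnot(ncol(expression) >= 3L)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- expression[pairs$locus[i], ]
    y <- expression[pairs$gene[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(r = NA_real_, p = NA_real_, degenerate = TRUE))
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(r = unname(ct$estimate), p = ct$p.value, degenerate = FALSE)
  })
  cbind(pairs, do.call(rbind, res))
}

#' Chi-squared test of head-to-head over-representation
#'
#' One-degree-of-freedom goodness-of-fit test of the observed
#' head-to-head count against the 50 percent expected by chance, with
#' no continuity correction.
#'
#' @param nHeadToHead observed head-to-head pairs.
#' @param nTotal total classified pairs.
#' @return List: `statistic`, `p.value`.
#' @examples
#' orientationChi2(485, 692)$p.value < 3.6e-14
#' @export
orientationChi2 <- function(nHeadToHead, nTotal) {
  stopifnot(nTotal > 0, nHeadToHead >= 0, nHeadToHead <= nTotal)
  ht <- stats::chisq.test(c(nHeadToHead, nTotal - nHeadToHead),
                          p = c(0.5, 0.5), correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Fisher's exact test of lincRNA enrichment near a gene class
#'
#' Two-sided Fisher's exact test on the 2x2 table of genes with /
#' without a neighbouring lincRNA in a focal class (e.g. transcription
#' factors) versus all other genes.
#'
#' @param focalWith,focalTotal genes in the focal class with a
#'   neighbouring lincRNA, and the class total.
#' @param otherWith,otherTotal the same for the remaining genes.
#' @return List: `odds.ratio`, `p.value`.
#' @export
tfNeighborFisher <- function(focalWith, focalTotal, otherWith, otherTotal) {
  stopifnot(focalWith >= 0, otherWith >= 0,
            focalWith <= focalTotal, otherWith <= otherTotal)
  tab <- matrix(c(focalWith, focalTotal - focalWith,
                  otherWith, otherTotal - otherWith), nrow = 2L)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table: a margin is zero")
    return(list(odds.ratio = NA_real_, p.value = 1))
  }
  ht <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds.ratio = unname(ht$estimate), p.value = ht$p.value)
}
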