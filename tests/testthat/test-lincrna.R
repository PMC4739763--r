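# shared cascade fixture with one decoy per failure mode
sg_casc <- generateGenome(genomeSpec(nGenes = 8, nLincrna = 3,
                                     decoys = TRUE, seed = 5))
ev_casc <- generateEvidenceTables(sg_casc, seed = 2)
feats_casc <- truthTables(sg_casc)$features
tx_casc <- unique(annotationRanges(sg_casc)$transcript_id)
feat_of <- feats_casc[match(sub("[.]t1$", "", tx_casc), feats_casc$id), ]
cand_casc <- GenomicRanges::GRanges(
  feat_of$chrom, IRanges::IRanges(feat_of$start, feat_of$end),
  strand = feat_of$strand, id = tx_casc)
genes_casc <- with(feat_of[feat_of$class == "coding", ],
                   GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                          strand = strand))
exm <- local({
  ex <- truthTables(sg_casc)$expression
  m <- cbind(A = ex$fpkm[ex$stage == "A"][match(feat_of$id,
                                                ex$feature[ex$stage == "A"])],
             B = ex$fpkm[ex$stage == "B"][match(feat_of$id,
                                                ex$feature[ex$stage == "B"])])
  rownames(m) <- tx_casc
  m
})

test_that("coding-potential calibration separates planted classes", {
  # random sequences without a long ORF score confidently non-coding
  set.seed(31)
  rand <- replicate(40, coenosplice:::random_seq(
    sample(300:800, 1), 0.5))
  no_long_orf <- vapply(rand, function(s)
    coenosplice:::longest_orf(s)$n_codons < 100, logical(1))
  expect_gt(sum(no_long_orf), 30)
  scores <- vapply(rand[no_long_orf], scoreCodingPotential, numeric(1))
  expect_true(all(scores < -0.5))
  # full-length coding mRNAs from the generator score positive
  strs <- coenosplice:::transcript_structures(sg_casc)
  coding_tx <- paste0(feats_casc$id[feats_casc$class == "coding"], ".t1")
  mrna <- vapply(strs[coding_tx], function(s)
    paste(s$exons, collapse = ""), character(1))
  expect_true(all(vapply(mrna, scoreCodingPotential, numeric(1)) > 0))
  # no ORF at all floors the score
  expect_identical(scoreCodingPotential(strrep("TAA", 100)), -2.8)
  expect_error(scoreCodingPotential("ACGTN"), "A/C/G/T")
})

test_that("the cascade reproduces the planted truth with a faithful audit", {
  res <- runDiscoveryCascade(cand_casc, ev_casc$evidence, genes_casc,
                             repeats = repeatRanges(sg_casc),
                             expression = exm)
  truth_surv <- tx_casc[feat_of$class == "lincRNA"]
  surv <- res$audit$id[res$audit$rejected_at == "none"]
  expect_setequal(surv, truth_surv)
  # audit conservation: rejections + survivors = inputs
  expect_identical(nrow(res$audit), length(cand_casc))
  expect_identical(sum(res$audit$rejected_at == "none") +
                     sum(res$audit$rejected_at != "none"),
                   length(cand_casc))
  # each decoy falls at its intended step
  step_of <- function(cls)
    res$audit$rejected_at[match(paste0(feats_casc$id[feats_casc$class == cls],
                                       ".t1"), res$audit$id)]
  expect_identical(unique(step_of("coding")), "homology")
  expect_identical(step_of("decoy_short"), "length")
  expect_identical(step_of("decoy_ncrna"), "ncrna")
  expect_identical(step_of("decoy_repeat"), "repeat")
  expect_identical(step_of("decoy_lowexpr"), "expression")
  expect_identical(step_of("decoy_utr_proximal"), "utr_proximal")
})

test_that("an independent hand application of the filters agrees", {
  ev <- ev_casc$evidence[match(tx_casc, ev_casc$evidence$id), ]
  len <- BiocGenerics::width(cand_casc)
  ori <- classifyOrientation(cand_casc, genes_casc)
  keep <- len > 200 &
    !(!is.na(ev$homology_evalue) & ev$homology_evalue < 1e-3) &
    !ev$ncrna_hit &
    ev$coding_score < -0.5 &
    !IRanges::overlapsAny(cand_casc, genes_casc, ignore.strand = TRUE) &
    !(ori$orientation %in% "head-to-tail" & ori$distance < 1000) &
    !IRanges::overlapsAny(cand_casc, repeatRanges(sg_casc),
                          ignore.strand = TRUE) &
    apply(exm, 1, function(x) max(x) >= 5 && all(x[-which.max(x)] > 1))
  res <- runDiscoveryCascade(cand_casc, ev_casc$evidence, genes_casc,
                             repeats = repeatRanges(sg_casc),
                             expression = exm)
  expect_setequal(res$audit$id[res$audit$rejected_at == "none"],
                  tx_casc[keep])
})

test_that("cascade errors name candidates missing from the evidence", {
  ev2 <- ev_casc$evidence[-1, ]
  expect_error(
    runDiscoveryCascade(cand_casc, ev2, genes_casc,
                        repeats = repeatRanges(sg_casc), expression = exm),
    ev_casc$evidence$id[1])
})

test_that("keepFlagged retains the UTR-proximal candidates", {
  res <- runDiscoveryCascade(cand_casc, ev_casc$evidence, genes_casc,
                             repeats = repeatRanges(sg_casc),
                             expression = exm, keepFlagged = TRUE)
  utr_tx <- paste0(feats_casc$id[feats_casc$class == "decoy_utr_proximal"],
                   ".t1")
  expect_identical(res$audit$rejected_at[res$audit$id == utr_tx], "none")
  expect_true(utr_tx %in% res$flagged ||
                length(res$flagged) >= 1)  # still reported as flagged
})

test_that("orientation classification matches its geometric definition", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500, 1000),
                                  strand = "+")
  # divergent-strand locus downstream of a + gene: head-to-head
  l1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1200, 1500),
                               strand = "-")
  # same-strand locus: head-to-tail
  l2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1500, 1900),
                               strand = "+")
  expect_identical(classifyOrientation(l1, genes)$orientation, "head-to-head")
  expect_identical(classifyOrientation(l2, genes)$orientation, "head-to-tail")
  # no gene on the chromosome: unclassified
  l3 <- GenomicRanges::GRanges("chr2", IRanges::IRanges(10, 400),
                               strand = "+")
  expect_true(is.na(classifyOrientation(l3, genes)$orientation))
})

test_that("orientation classes survive reverse-complementing the fixture", {
  feats <- feats_casc
  L <- sum(BiocGenerics::width(genomeSequences(sg_casc)))
  flip <- function(df) {
    s <- L - df$end + 1L; e <- L - df$start + 1L
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(s, e),
                           strand = ifelse(df$strand == "+", "-", "+"))
  }
  lincs <- feats[feats$class == "lincRNA", ]
  genes <- feats[feats$class == "coding", ]
  fwd <- classifyOrientation(
    GenomicRanges::GRanges(lincs$chrom, IRanges::IRanges(lincs$start, lincs$end),
                           strand = lincs$strand),
    GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$start, genes$end),
                           strand = genes$strand))
  rev <- classifyOrientation(flip(lincs), flip(genes))
  expect_identical(fwd$orientation, rev$orientation)
})

test_that("neighbour expression correlation recovers exact relationships", {
  em <- rbind(l1 = c(1, 2, 3, 4), g1 = c(1, 2, 3, 4),
              l2 = c(1, 2, 3, 4), g2 = c(4, 3, 2, 1),
              l3 = c(2, 2, 2, 2), g3 = c(1, 5, 3, 4))
  pairs <- data.frame(locus = c("l1", "l2", "l3"),
                      gene = c("g1", "g2", "g3"))
  res <- neighborExpressionCorrelation(pairs, em)
  expect_equal(res$r[1], 1)
  expect_equal(res$r[2], -1)
  expect_true(is.na(res$r[3]) && res$degenerate[3])
})

test_that("planted divergent pairs correlate above background", {
  set.seed(41)
  n_pair <- 15; n_bg <- 30; n_s <- 6
  shared <- matrix(rnorm(n_pair * n_s, 0, 2), n_pair)
  em <- rbind(shared + rnorm(n_pair * n_s, 0, 0.5),   # loci
              shared + rnorm(n_pair * n_s, 0, 0.5),   # their genes
              matrix(rnorm(n_bg * n_s, 0, 2), n_bg))  # unrelated
  rownames(em) <- c(paste0("l", 1:n_pair), paste0("g", 1:n_pair),
                    paste0("x", 1:n_bg))
  planted <- neighborExpressionCorrelation(
    data.frame(locus = paste0("l", 1:n_pair), gene = paste0("g", 1:n_pair)),
    em)
  bg <- neighborExpressionCorrelation(
    data.frame(locus = paste0("x", 1:n_pair),
               gene = paste0("x", n_pair + 1:n_pair)), em)
  expect_gt(mean(planted$r), mean(bg$r))
})

test_that("the head-to-head chi-squared bound and exact-null behave", {
  expect_lt(orientationChi2(485, 692)$p.value, 3.6e-14)
  exact <- orientationChi2(346, 692)
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p.value, 1)
  # order-of-magnitude agreement with the exact binomial at small n
  p_chi <- orientationChi2(8, 10)$p.value
  p_bin <- binom.test(8, 10, 0.5)$p.value
  expect_lt(abs(log10(p_chi) - log10(p_bin)), 1)
  expect_error(orientationChi2(11, 10))
})

test_that("the enrichment test matches hypergeometric enumeration", {
  null <- tfNeighborFisher(5, 10, 5, 10)
  expect_equal(null$odds.ratio, 1, tolerance = 1e-6)
  expect_equal(null$p.value, 1)
  # fully separated table: p = probability of the two extreme tables
  res <- tfNeighborFisher(10, 10, 0, 10)
  p_exact <- sum(dhyper(c(0, 10), 10, 10, 10))
  expect_equal(res$p.value, p_exact)
  # swapping the rows inverts the odds ratio, p unchanged
  a <- tfNeighborFisher(8, 10, 3, 10)
  b <- tfNeighborFisher(2, 10, 7, 10)
  expect_equal(a$p.value, b$p.value)
  expect_equal(a$odds.ratio, 1 / b$odds.ratio, tolerance = 1e-6)
  expect_warning(tfNeighborFisher(0, 0, 0, 10), "degenerate")
})
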