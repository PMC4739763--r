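lib_toy <- buildJunctionLibrary(toy$annotation, toy$genome)

test_that("a 3-exon gene yields the 3 forward EEJs, a single-exon gene none", {
  rd <- refData(lib_toy)
  x_eej <- rd[rd$gene_id == "gX" & rd$kind == "EEJ", ]
  expect_setequal(x_eej$unit, c("e1-e2", "e2-e3", "e1-e3"))

  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 260), strand = "+", gene_id = "s",
                 transcript_id = "s.t1", exon_rank = 1L,
                 feature_type = "mRNA")
  lib1 <- buildJunctionLibrary(one, toy$genome, mappability = FALSE)
  expect_identical(sum(refData(lib1)$kind == "EEJ"), 0L)
})

test_that("EEJ counts match brute-force enumeration of ordered site pairs", {
  rd <- refData(lib_toy)
  expected <- sum(vapply(split(toy$annotation$exon_rank,
                               toy$annotation$transcript_id),
                         function(r) choose(length(r), 2), numeric(1)))
  expect_identical(sum(rd$kind == "EEJ"), as.integer(expected))
})

test_that("EEJ references concatenate the two exonic flanks", {
  rd <- refData(lib_toy)
  i <- which(rd$id == "gX.t1.eej.1_2")
  strs <- coenosplice:::tx_structures(toy$genome, toy$annotation)
  x <- strs[["gX.t1"]]
  # 60-nt exons truncate the 42-nt flanks to nothing less; flank = 42
  expect_identical(as.character(refSequences(lib_toy)[[i]]),
                   paste0(substring(x$exons[1], 60 - 42 + 1),
                          substr(x$exons[2], 1, 42)))
  expect_identical(rd$left_flank[i], 42L)
})

test_that("intron-body references follow the 200-nt mid-intron rule", {
  mk <- function(ilen) {
    set.seed(1)
    e1 <- coenosplice:::random_seq(80, 0.5)
    e2 <- coenosplice:::random_seq(80, 0.5)
    intr <- paste0("GT", coenosplice:::random_seq(ilen - 4, 0.5), "AG")
    g <- Biostrings::DNAStringSet(c(chr1 = paste0(e1, intr, e2)))
    ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 81 + ilen), c(80, 160 + ilen)),
                   strand = "+", gene_id = "g", transcript_id = "g.t1",
                   exon_rank = 1:2, feature_type = "mRNA")
    lib <- buildJunctionLibrary(ann, g, mappability = FALSE)
    rd <- refData(lib)
    BiocGenerics::width(refSequences(lib))[rd$kind == "body"]
  }
  expect_identical(mk(150), 150L)
  expect_identical(mk(200), 200L)
  expect_identical(mk(300), 200L)
  # centring: for a 300-nt intron the segment spans intron offsets 51-250
  set.seed(1)
  e1 <- coenosplice:::random_seq(80, 0.5)
  e2 <- coenosplice:::random_seq(80, 0.5)
  intr <- paste0("GT", coenosplice:::random_seq(296, 0.5), "AG")
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(e1, intr, e2)))
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 381), c(80, 460)), strand = "+",
                 gene_id = "g", transcript_id = "g.t1", exon_rank = 1:2,
                 feature_type = "mRNA")
  lib <- buildJunctionLibrary(ann, g, mappability = FALSE)
  rd <- refData(lib)
  body <- as.character(refSequences(lib)[[which(rd$kind == "body")]])
  expect_identical(body, substr(intr, 51, 250))
})

test_that("mappability equals 35 for unique flanks and matches the brute-force oracle", {
  mp <- mappabilityTable(lib_toy)
  expect_true(all(mp$max_mappability == 35L))
  eej <- mp[mp$kind == "EEJ", ]
  expect_true(all(eej$mappability == 35L))  # all toy flanks are unique
  oracle <- oracle_mappability(lib_toy, toy$genome)
  expect_identical(mp$mappability, oracle)
})

test_that("a duplicated flank lowers mappability below the maximum", {
  set.seed(5)
  e1 <- coenosplice:::random_seq(60, 0.5)
  e2 <- coenosplice:::random_seq(60, 0.5)
  e3 <- coenosplice:::random_seq(60, 0.5)
  i1 <- paste0("GT", coenosplice:::random_seq(96, 0.5), "AG")
  i2 <- paste0("GT", coenosplice:::random_seq(96, 0.5), "AG")
  # two genes share the first exon AND the first 20 nt of the second
  # exon, so junction windows with a right overhang of 8..20 nt are
  # identical between the two EEJs
  e3 <- paste0(substr(e2, 1, 20), coenosplice:::random_seq(40, 0.5))
  spacer <- coenosplice:::random_seq(150, 0.5)
  gA <- paste0(e1, i1, e2)
  gB <- paste0(e1, i2, e3)
  chrom <- paste0(spacer, gA, spacer, gB, spacer)
  oA <- 150L; oB <- 150L + nchar(gA) + 150L
  ann <- GenomicRanges::GRanges("chr1",
                 IRanges::IRanges(c(oA + 1, oA + 161, oB + 1, oB + 161),
                         c(oA + 60, oA + 220, oB + 60, oB + 220)),
                 strand = "+", gene_id = c("gA", "gA", "gB", "gB"),
                 transcript_id = c("gA.t1", "gA.t1", "gB.t1", "gB.t1"),
                 exon_rank = c(1L, 2L, 1L, 2L), feature_type = "mRNA")
  g <- Biostrings::DNAStringSet(c(chr1 = chrom))
  lib <- buildJunctionLibrary(ann, g)
  mp <- mappabilityTable(lib)
  eej <- mp[mp$kind == "EEJ", ]
  # the 13 windows with right overhang 8..20 are shared -> 35 - 13 = 22
  expect_identical(unname(eej$mappability), c(22L, 22L))
  expect_identical(mp$mappability, oracle_mappability(lib, g))
})

test_that("flank truncation at short exons bounds the spanning positions", {
  # 20-nt terminal exon: left flank 20 nt, so offsets span 20-8+1 = 13
  set.seed(6)
  e1 <- coenosplice:::random_seq(20, 0.5)
  e2 <- coenosplice:::random_seq(80, 0.5)
  intr <- paste0("GT", coenosplice:::random_seq(96, 0.5), "AG")
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(
    coenosplice:::random_seq(100, 0.5), e1, intr, e2,
    coenosplice:::random_seq(100, 0.5))))
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 221), c(120, 300)), strand = "+",
                 gene_id = "g", transcript_id = "g.t1", exon_rank = 1:2,
                 feature_type = "mRNA")
  lib <- buildJunctionLibrary(ann, g)
  mp <- mappabilityTable(lib)
  expect_lte(mp$mappability[mp$kind == "EEJ"], 20L - 8L + 1L)
})

test_that("library construction is deterministic and idempotent", {
  lib2 <- buildJunctionLibrary(toy$annotation, toy$genome)
  expect_identical(as.character(refSequences(lib_toy)),
                   as.character(refSequences(lib2)))
  expect_identical(mappabilityTable(lib_toy), mappabilityTable(lib2))
})

test_that("de novo sites require 5 reads over at least 2 start positions", {
  strs <- coenosplice:::tx_structures(toy$genome, toy$annotation)
  x <- strs[["gX.t1"]]
  # candidate acceptor: an AG inside intron 1 of gene X
  iseq <- x$introns[1]
  a <- regexpr("AG", substring(iseq, 3))[[1]] + 2L  # an internal AG
  expect_gt(a, 2)
  gpos <- x$in_gstart[1] + a + 1L
  chrom <- as.character(toy$genome[[1]])
  novel_ref <- paste0(substring(x$exons[1], nchar(x$exons[1]) - 41),
                      substr(chrom, gpos, gpos + 41L))
  support_reads <- function(offsets)
    substring(novel_ref, offsets, offsets + 49L)
  run <- function(reads)
    discoverDeNovoSpliceSites(lib_toy, toy$annotation, toy$genome, reads)
  hit <- function(res) any(res$sites$kind == "acceptor" &
                             res$sites$position == gpos)
  expect_true(hit(run(support_reads(c(1, 1, 10, 10, 20)))))   # 5 reads, 3 pos
  expect_false(hit(run(support_reads(c(1, 10, 20, 30)))))     # 4 reads
  expect_false(hit(run(support_reads(rep(10, 5)))))           # 1 position
})

test_that("accepted de novo acceptors carry the AG motif", {
  strs <- coenosplice:::tx_structures(toy$genome, toy$annotation)
  x <- strs[["gX.t1"]]
  iseq <- x$introns[1]
  a <- regexpr("AG", substring(iseq, 3))[[1]] + 2L
  gpos <- x$in_gstart[1] + a + 1L
  chrom <- as.character(toy$genome[[1]])
  novel_ref <- paste0(substring(x$exons[1], nchar(x$exons[1]) - 41),
                      substr(chrom, gpos, gpos + 41L))
  res <- discoverDeNovoSpliceSites(lib_toy, toy$annotation, toy$genome,
                                   substring(novel_ref, c(1, 5, 9, 13, 17),
                                             c(1, 5, 9, 13, 17) + 49L))
  acc <- res$sites[res$sites$kind == "acceptor", ]
  for (i in seq_len(nrow(acc)))
    expect_identical(substr(chrom, acc$position[i] - 2L, acc$position[i] - 1L),
                     "AG")
})

test_that("microexon scan respects the 3-15 nt length bounds", {
  set.seed(8)
  e1 <- coenosplice:::random_seq(80, 0.5)
  e2 <- coenosplice:::random_seq(80, 0.5)
  mk_intron <- function(mlen) {
    mid <- gsub("AG|GT", "CC",
                coenosplice:::random_seq(mlen, 0.5))  # clean segment
    mid <- substr(mid, 1, mlen)
    paste0("GT", gsub("AG|GT", "AA", coenosplice:::random_seq(40, 0.5)),
           "AG", mid, "GT",
           gsub("AG|GT", "TT", coenosplice:::random_seq(40, 0.5)), "AG")
  }
  run <- function(mlen) {
    intr <- mk_intron(mlen)
    g <- Biostrings::DNAStringSet(c(chr1 = paste0(e1, intr, e2)))
    ann <- GenomicRanges::GRanges("chr1",
                   IRanges::IRanges(c(1, 81 + nchar(intr)), c(80, 160 + nchar(intr))),
                   strand = "+", gene_id = "g", transcript_id = "g.t1",
                   exon_rank = 1:2, feature_type = "mRNA")
    discoverMicroexons(ann, g)
  }
  expect_true(9L %in% run(9)$length)
  # candidates outside the 3-15 nt bounds are never reported (the scan
  # may still find shifted in-bounds AG..GT pairs nearby)
  for (m in c(2, 9, 16)) {
    cand <- run(m)
    expect_true(all(cand$length >= 3L & cand$length <= 15L))
  }
  expect_false(2L %in% run(2)$length)
  expect_false(16L %in% run(16)$length)
})
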