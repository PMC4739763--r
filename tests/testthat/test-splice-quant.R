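lib_q <- buildJunctionLibrary(toy$annotation, toy$genome)

test_that("read splitting yields floor((L-50)/25)+1 windows per read", {
  reads <- c(a = strrep("A", 100), b = strrep("C", 125), c = strrep("G", 50))
  g <- splitReadGroups(reads)
  expect_identical(unname(table(g$group)[c("a", "b", "c")]),
                   table(c(rep(1, 3), rep(2, 4), 3))[1:3] |> unname())
  expect_identical(sum(g$group == "a"), 3L)
  expect_identical(sum(g$group == "b"), 4L)
  expect_identical(sum(g$group == "c"), 1L)
  # sub-reads tile the read at 25-nt steps
  expect_identical(g$seq[g$group == "b"],
                   substring(strrep("C", 125), c(1, 26, 51, 76),
                             c(50, 75, 100, 125)))
  expect_message(splitReadGroups(c(short = strrep("A", 49))), "skipped")
})

test_that("multi-mapping and over-mismatched sub-reads stay unplaced", {
  chrom <- as.character(toy$genome[[1]])
  dup <- substr(chrom, 1, 50)        # spacer sequence, could be unique
  g2 <- Biostrings::DNAStringSet(c(chr1 = chrom, chr2 = dup))  # duplicate it
  uniq <- substr(chrom, 301, 350)
  grp <- data.frame(group = c("r1", "r2"), slot = 1L,
                    seq = c(dup, uniq), stringsAsFactors = FALSE)
  pl <- mapReadGroups(grp, g2, lib_q, maxMismatches = 0)
  expect_identical(pl$n_loc, c(2L, 1L))
  expect_true(is.na(pl$subject[1]))
  expect_identical(pl$subject[2], "chr1")

  # three mismatches exceed the allowance; two are tolerated
  mut <- uniq
  substr(mut, 5, 5) <- if (substr(mut, 5, 5) == "A") "C" else "A"
  substr(mut, 25, 25) <- if (substr(mut, 25, 25) == "A") "C" else "A"
  substr(mut, 45, 45) <- if (substr(mut, 45, 45) == "A") "C" else "A"
  two <- uniq
  substr(two, 5, 5) <- if (substr(two, 5, 5) == "A") "C" else "A"
  substr(two, 25, 25) <- if (substr(two, 25, 25) == "A") "C" else "A"
  grp <- data.frame(group = c("m3", "m2"), slot = 1L, seq = c(mut, two),
                    stringsAsFactors = FALSE)
  pl <- mapReadGroups(grp, toy$genome, lib_q, maxMismatches = 2)
  expect_identical(pl$n_loc[pl$group == "m3"], 0L)
  expect_identical(pl$n_loc[pl$group == "m2"], 1L)
  expect_identical(pl$pos[pl$group == "m2"], 301L)
})

test_that("reverse-strand sub-reads are placed with minus orientation", {
  chrom <- as.character(toy$genome[[1]])
  w <- substr(chrom, 401, 450)
  rc <- coenosplice:::revcomp(w)
  grp <- data.frame(group = "r", slot = 1L, seq = rc,
                    stringsAsFactors = FALSE)
  pl <- mapReadGroups(grp, toy$genome, lib_q, maxMismatches = 0)
  expect_identical(pl$strand, "-")
  expect_identical(pl$pos, 401L)
})

test_that("junction counts match a brute-force string-matching oracle", {
  sg <- generateGenome(genomeSpec(nGenes = 3, nLincrna = 0,
                                  exonsPerGene = c(3, 3), seed = 23))
  gen <- genomeSequences(sg)
  lib <- buildJunctionLibrary(annotationRanges(sg), gen)
  txs <- sort(unique(annotationRanges(sg)$transcript_id))
  prof <- stageProfile("A",
                       expression = setNames(rep(20, 3), sub("[.]t1$", "", txs)),
                       pir = setNames(rep(30, 6),
                                      c(outer(txs, 1:2, function(t, k)
                                        sprintf("%s.i%d", t, k)))),
                       replicates = 1, librarySize = 5000, readLen = 100,
                       seed = 3)
  reads <- simulateStageReads(sg, prof)$rep1
  grp <- splitReadGroups(reads)
  pl <- mapReadGroups(grp, gen, lib, maxMismatches = 0)
  cnt <- countJunctionReads(pl, lib, seed = 4)

  # oracle: same counted slots, but counts recomputed by exhaustive
  # string matching of each counted sub-read against reference windows
  counted <- coenosplice:::choose_counted_slots(pl, seed = 4)
  rd <- refData(lib)
  refs <- as.character(refSequences(lib))
  for (i in which(rd$kind == "EEJ")) {
    b <- rd$left_flank[i]; L <- b + rd$right_flank[i]
    o <- coenosplice:::span_offsets(b, L, 50L, 8L)
    w <- substring(refs[i], o[1]:o[2], o[1]:o[2] + 49L)
    oracle <- sum(counted$seq %in% w & counted$subject == rd$id[i])
    expect_identical(cnt$raw[i], oracle)
  }
  # at most one count per original read
  expect_lte(max(table(counted$group)), 1L)
  expect_lte(sum(cnt$raw), length(reads))
})

test_that("mappability correction rescales and never shrinks counts", {
  expect_identical(correctJunctionCount(10, 35, 35), 10)
  expect_identical(correctJunctionCount(10, 20, 35), 17.5)
  expect_identical(correctJunctionCount(0, 7, 35), 0)
  expect_true(is.na(correctJunctionCount(3, 0, 35)))
  raw <- rpois(50, 10); mp <- sample(1:35, 50, TRUE)
  cc <- correctJunctionCount(raw, mp, 35)
  expect_true(all(cc >= raw))
  expect_identical(which(cc == raw & raw > 0), which(mp == 35 & raw > 0))
})

test_that("PSI follows the inclusion-mean formula with its coverage rule", {
  expect_identical(quantifyPSI(12, 8, 0)$psi, 100)
  expect_identical(quantifyPSI(10, 10, 10)$psi, 50)
  und <- quantifyPSI(0, 0, 0)
  expect_true(is.na(und$psi))
  expect_false(und$coverage_ok)
  expect_false(quantifyPSI(4, 4, 4)$coverage_ok)   # 4 + 4 = 8 < 20
  expect_true(quantifyPSI(10, 10, 15)$coverage_ok) # 10 + 15 = 25
})

test_that("PIR follows the EIJ-mean formula with balance checking", {
  expect_identical(quantifyPIR(0, 0, body = 0, eej = 30)$pir, 0)
  q <- quantifyPIR(10, 10, body = 4, eej = 10)
  expect_identical(q$pir, 50)
  expect_true(q$balance_ok)
  expect_false(quantifyPIR(20, 0, body = 4, eej = 10)$balance_ok)
  # retention support without body coverage fails the presence check
  expect_false(quantifyPIR(10, 10, body = 0, eej = 10)$balance_ok)
  expect_true(quantifyPIR(10, 10, body = NA, eej = 10)$balance_ok)
  und <- quantifyPIR(0, 0, body = 0, eej = 0)
  expect_true(is.na(und$pir))
  expect_false(und$coverage_ok)
})

test_that("event classification applies the retention and skipping thresholds", {
  ir <- data.frame(event = rep(c("i1", "i2", "i3"), each = 2),
                   pir = c(25, 10, 1.5, 1.0, 5, 10))
  es <- data.frame(event = rep(c("e1", "e2"), each = 2),
                   psi = c(95, 89, 98, 97))
  cl <- classifySpliceEvents(ir, es)
  expect_identical(cl$ir$retained, c(TRUE, FALSE, FALSE))
  expect_identical(cl$ir$constitutive, c(FALSE, TRUE, FALSE))
  expect_identical(cl$es$alternative, c(TRUE, FALSE))
})
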