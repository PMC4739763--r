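#' Generate evidence tables consistent with a fixture's truth
#'
#' Produces the tabular evidence the lincRNA cascade consumes, emulating
#' what external homology / ncRNA-family / coding-potential searches
#' would report on the fixture: coding transcripts receive a strong
#' homology hit (e-value <= 1e-3), planted known-ncRNA decoys one
#' ncRNA-family row, and every transcript a coding-potential score
#' computed from its own sequence.
#'
#' @param sg a [SyntheticGenome-class].
#' @param seed integer seed (e-value jitter only).
#' @return A list of data frames: `homology` (id, evalue), `ncrna`
#'   (id, family), `coding` (id, coding_score), and `evidence` -- the
#'   merged per-candidate table keyed by transcript id with columns
#'   `homology_evalue` (NA when no hit), `ncrna_hit`, `coding_score`.
#' @export
generateEvidenceTables <- function(sg, seed = 1L) {
  feats <- sg@truth$features
  strs <- transcript_structures(sg)
  tx <- vapply(strs, `[[`, character(1), "transcript_id")
  gene <- vapply(strs, `[[`, character(1), "gene_id")
  cls <- feats$class[match(gene, feats$id)]
  seqs <- vapply(strs, function(s) paste(s$exons, collapse = ""), character(1))

  with_seed_(seed, {
    ev <- 10^stats::runif(length(tx), -30, -4)   # strong hits for coding
    homology <- data.frame(id = tx[cls == "coding"],
                           evalue = ev[cls == "coding"],
                           stringsAsFactors = FALSE)
    ncrna <- data.frame(id = tx[cls == "decoy_ncrna"],
                        family = "RF-synthetic",
                        stringsAsFactors = FALSE)
    coding <- data.frame(id = unname(tx),
                         coding_score = vapply(unname(seqs),
                                               scoreCodingPotential,
                                               numeric(1)),
                         stringsAsFactors = FALSE)
    evidence <- data.frame(
      id = unname(tx),
      homology_evalue = ifelse(cls == "coding", ev, NA_real_),
      ncrna_hit = cls == "decoy_ncrna",
      coding_score = coding$coding_score,
      stringsAsFactors = FALSE)
    list(homology = homology, ncrna = ncrna, coding = coding,
         evidence = evidence)
  })
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
HYDROPHOBIC <- strsplit("AFILMVW", "")[[1]]
ER_MOTIFS <- c("KDEL", "HDEL", "HDEF")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

#' Generate proteins with planted secretion features
#'
#' Builds an amino-acid sequence set with known truth for the secretome
#' triage cascade, plus the predictor table an external signal-peptide /
#' transmembrane / targeting / GPI tool suite would produce for it.
#' Classes: `secreted` (signal peptide, D-score >= 0.45, no disqualifying
#' feature; some carry a tolerated TM segment within the first 60
#' residues), `no_signal`, `tm` (TM helix starting after residue 60),
#' `mito`, `er` (C-terminal KDEL / HDEL / HDEF), `gpi`.
#'
#' @param nPerClass named integer vector of class sizes; any subset of
#'   the classes above.
#' @param length protein length (residues).
#' @param seed integer seed.
#' @return A list: `proteins` ([Biostrings::AAStringSet]), `predictors`
#'   (data frame: id, signal_peptide_D, tm_starts as comma-separated
#'   string, targeting, gpi_anchored), `truth` (id, class).
#' @export
generateProteinSet <- function(nPerClass = c(secreted = 10, no_signal = 10,
                                             tm = 5, mito = 5, er = 5,
                                             gpi = 5),
                               length = 300L, seed = 1L) {
  stopifnot(!is.null(names(nPerClass)))
  with_seed_(seed, {
    rows <- list(); seqs <- character(0); ids <- character(0)
    k <- 0L
    for (cls in names(nPerClass)) for (i in seq_len(nPerClass[[cls]])) {
      k <- k + 1L
      id <- sprintf("prot%03d", k)
      s <- random_protein(length)
      d <- stats::runif(1, 0.55, 0.95)   # canonical signal peptide
      tm <- ""
      targeting <- "secretory"
      gpi <- FALSE
      if (cls %in% c("secreted", "tm", "mito", "er", "gpi")) {
        # plant an N-terminal hydrophobic signal-like stretch
        substr(s, 3L, 14L) <- paste(sample(HYDROPHOBIC, 12L, replace = TRUE),
                                    collapse = "")
      }
      if (cls == "no_signal") d <- stats::runif(1, 0.05, 0.44)
      if (cls == "tm") tm <- paste(sort(sample(61:(length - 30L), 2L)),
                                   collapse = ",")
      if (cls == "secreted" && i %% 2L == 0L)
        tm <- as.character(sample(20:55, 1L))  # tolerated, inside first 60 aa
      if (cls == "mito") targeting <- "mitochondrial"
      if (cls == "er")
        substr(s, length - 3L, length) <- sample(ER_MOTIFS, 1L)
      if (cls == "gpi") gpi <- TRUE
      if (cls != "er" && substr(s, length - 3L, length) %in% ER_MOTIFS)
        substr(s, length - 3L, length) <- "AAAA"
      ids <- c(ids, id); seqs <- c(seqs, s)
      rows[[k]] <- data.frame(id = id, class = cls, signal_peptide_D = d,
                              tm_starts = tm, targeting = targeting,
                              gpi_anchored = gpi, stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    list(proteins = Biostrings::AAStringSet(stats::setNames(seqs, ids)),
         predictors = tab[, c("id", "signal_peptide_D", "tm_starts",
                              "targeting", "gpi_anchored")],
         truth = tab[, c("id", "class")])
  })
}
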