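#' Scan for a C-terminal ER-retention motif
#'
#' TRUE iff the final four residues are exactly KDEL, HDEL or HDEF
#' (endoplasmic-reticulum retention signals); anywhere else in the
#' sequence the motif does not retain the protein.
#'
#' @param sequence amino-acid string(s).
#' @return Logical vector. Sequences shorter than 4 residues return
#'   FALSE with a warning.
#' @examples
#' scanERRetentionMotif(c("MAAKDEL", "MKDELA"))  # TRUE FALSE
#' @export
scanERRetentionMotif <- function(sequence) {
  sequence <- as.character(sequence)
  n <- nchar(sequence)
  if (any(n < 4L))
    warning(sum(n < 4L), " sequence(s) shorter than 4 residues")
  out <- substr(sequence, n - 3L, n) %in% ER_MOTIFS
  out[n < 4L] <- FALSE
  out
}

parse_tm_starts <- function(x) {
  if (is.list(x)) return(lapply(x, as.numeric))
  lapply(strsplit(ifelse(is.na(x) | x == "", "", as.character(x)), ","),
         as.numeric)
}

#' In-silico secretome triage cascade
#'
#' Orders every protein through the prediction cascade: (1) require a
#' canonical signal peptide (D-score >= `dCutoff`, default 0.450,
#' boundary inclusive); (2) reject proteins with a transmembrane helix
#' starting after residue `tmLimit` (default 60; a TM segment inside
#' the signal region is tolerated); (3) reject mitochondrial targeting;
#' (4) reject a C-terminal KDEL / HDEL / HDEF ER-retention motif;
#' (5) reject GPI-anchored proteins. The first failing step is
#' recorded; survivors are called secreted. The final secreted set is
#' unchanged under reordering of steps 2-5 (conjunctive predicates).
#'
#' @param proteins named [Biostrings::AAStringSet] or character vector.
#' @param predictors data frame with one row per protein: `id`,
#'   `signal_peptide_D` in `[0, 1]`, `tm_starts` (comma-separated
#'   residue positions or list column; empty = none), `targeting`
#'   (`"secretory"` / `"mitochondrial"` / `"other"`), `gpi_anchored`.
#' @param dCutoff signal-peptide D-score cutoff.
#' @param tmLimit TM helices starting after this residue disqualify.
#' @return Data frame: `id`, `decision` ("secreted" / "rejected"),
#'   `rejecting_step` ("none", "signal", "tm", "mito", "er_retention",
#'   "gpi"). Every input protein appears exactly once.
#' @export
triageSecretome <- function(proteins, predictors, dCutoff = 0.450,
                            tmLimit = 60L) {
  seqs <- stats::setNames(as.character(proteins), names(proteins))
  missing <- setdiff(names(seqs), predictors$id)
  if (length(missing))
    stop("no predictor row for: ", paste(missing, collapse = ", "))
  pr <- predictors[match(names(seqs), predictors$id), ]
  tm <- parse_tm_starts(pr$tm_starts)
  step <- rep("none", length(seqs))
  hit <- function(bad, label) step[step == "none" & bad] <<- label
  hit(pr$signal_peptide_D < dCutoff, "signal")
  hit(vapply(tm, function(x) any(x > tmLimit), logical(1)), "tm")
  hit(pr$targeting == "mitochondrial", "mito")
  hit(scanERRetentionMotif(seqs), "er_retention")
  hit(as.logical(pr$gpi_anchored), "gpi")
  data.frame(id = names(seqs),
             decision = ifelse(step == "none", "secreted", "rejected"),
             rejecting_step = step, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Overlap of in-silico and in-vivo protein sets
#'
#' Three-way partition of two id sets; counts conserve
#' (`|A| = common + A_only`).
#'
#' @param inSilico,inVivo character id vectors.
#' @return List: `common`, `silico_only`, `vivo_only` (counts) and the
#'   corresponding id vectors `common_ids`, `silico_only_ids`,
#'   `vivo_only_ids`.
#' @examples
#' summarizeOverlap(letters[1:5], letters[4:8])$common  # 2
#' @export
summarizeOverlap <- function(inSilico, inVivo) {
  inSilico <- unique(inSilico); inVivo <- unique(inVivo)
  common <- intersect(inSilico, inVivo)
  list(common = length(common),
       silico_only = length(setdiff(inSilico, inVivo)),
       vivo_only = length(setdiff(inVivo, inSilico)),
       common_ids = common,
       silico_only_ids = setdiff(inSilico, inVivo),
       vivo_only_ids = setdiff(inVivo, inSilico))
}
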