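#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Specification of a synthetic genome fixture
#'
#' A `GenomeSpec` describes the layout of a toy single-chromosome genome:
#' how many protein-coding genes and lincRNA loci to plant, the exon /
#' intron / intergenic size ranges, the background GC content and the
#' fraction of lincRNA loci placed head-to-head (divergent) with their
#' upstream protein-coding neighbour. All generation is deterministic for
#' a fixed `seed`.
#'
#' @slot nGenes number of protein-coding genes.
#' @slot exonsPerGene integer range (min, max) of exons per gene.
#' @slot exonLen integer range (min, max) of exon length in nt.
#' @slot intronLen integer range (min, max) of intron length in nt.
#' @slot gcContent target GC fraction in (0, 1) for non-coding sequence.
#' @slot nLincrna number of true lincRNA loci.
#' @slot lincrnaLen integer range of lincRNA locus length in nt.
#' @slot intergenicLen integer range of intergenic spacer length in nt.
#' @slot orientationMix fraction of lincRNA loci planted head-to-head.
#' @slot decoys logical; also plant one decoy locus per lincRNA-cascade
#'   failure mode (short, known ncRNA family, repeat overlap, low
#'   expression, UTR-proximal head-to-tail).
#' @slot seed integer seed.
#' @exportClass GenomeSpec
setClass("GenomeSpec", representation(
  nGenes = "integer",
  exonsPerGene = "integer",
  exonLen = "integer",
  intronLen = "integer",
  gcContent = "numeric",
  nLincrna = "integer",
  lincrnaLen = "integer",
  intergenicLen = "integer",
  orientationMix = "numeric",
  decoys = "logical",
  seed = "integer"
))

setValidity("GenomeSpec", function(object) {
  msg <- character(0)
  rng <- function(x, nm, lo = 1L) {
    if (length(x) != 2L || any(is.na(x)) || x[1L] > x[2L] || x[1L] < lo)
      msg <<- c(msg, sprintf("%s must be a nonempty range with min >= %d", nm, lo))
  }
  rng(object@exonsPerGene, "exonsPerGene")
  rng(object@exonLen, "exonLen")
  rng(object@intronLen, "intronLen", lo = 10L)
  rng(object@lincrnaLen, "lincrnaLen")
  rng(object@intergenicLen, "intergenicLen")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msg <- c(msg, "gcContent must lie in (0, 1)")
  if (object@orientationMix < 0 || object@orientationMix > 1)
    msg <- c(msg, "orientationMix must lie in [0, 1]")
  if (object@nGenes < 0L || object@nLincrna < 0L)
    msg <- c(msg, "nGenes and nLincrna must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeSpec
#'
#' @param nGenes,nLincrna counts of planted protein-coding genes and
#'   lincRNA loci.
#' @param exonsPerGene,exonLen,intronLen,lincrnaLen,intergenicLen
#'   length-2 integer ranges (min, max).
#' @param gcContent target GC fraction of non-coding sequence.
#' @param orientationMix fraction of lincRNA loci planted head-to-head
#'   with their upstream neighbour.
#' @param decoys plant one decoy locus per cascade failure mode.
#' @param seed integer seed; the same spec and seed reproduce the fixture
#'   byte for byte.
#' @return A [GenomeSpec-class] object.
#' @examples
#' gs <- genomeSpec(nGenes = 4, nLincrna = 2, seed = 1)
#' @export
genomeSpec <- function(nGenes = 20L,
                       exonsPerGene = c(3L, 7L),
                       exonLen = c(150L, 350L),
                       intronLen = c(80L, 300L),
                       gcContent = 0.5,
                       nLincrna = 8L,
                       lincrnaLen = c(400L, 900L),
                       intergenicLen = c(1200L, 2500L),
                       orientationMix = 0.7,
                       decoys = FALSE,
                       seed = 1L) {
  new("GenomeSpec",
      nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      exonLen = as.integer(exonLen),
      intronLen = as.integer(intronLen),
      gcContent = as.numeric(gcContent),
      nLincrna = as.integer(nLincrna),
      lincrnaLen = as.integer(lincrnaLen),
      intergenicLen = as.integer(intergenicLen),
      orientationMix = as.numeric(orientationMix),
      decoys = isTRUE(decoys),
      seed = as.integer(seed))
}

#' A synthetic genome with annotation and planted truth
#'
#' Container for one generated fixture: the chromosome sequence(s), the
#' exon-level annotation, planted repeat intervals, and the truth tables
#' (per-feature class, per-stage expression, per-intron PIR and per-exon
#' PSI) that downstream tests compare against.
#'
#' @slot genome a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot exons a [GenomicRanges::GRanges] of exon records with metadata
#'   columns `type` ("exon"), `gene_id`, `transcript_id`, `exon_rank` (in
#'   transcription order) and `feature_type` ("mRNA" or "lincRNA").
#' @slot repeats a `GRanges` of planted repeat intervals.
#' @slot truth a named list of data frames: `features` (id, class,
#'   coordinates), `expression` (feature, stage, fpkm), `pir` (intron,
#'   stage, pir), `psi` (exon, stage, psi).
#' @slot spec the generating [GenomeSpec-class].
#' @exportClass SyntheticGenome
setClass("SyntheticGenome", representation(
  genome = "DNAStringSet",
  exons = "GRanges",
  repeats = "GRanges",
  truth = "list",
  spec = "GenomeSpec"
))

setValidity("SyntheticGenome", function(object) {
  need <- c("features", "expression", "pir", "psi")
  if (!all(need %in% names(object@truth)))
    return(sprintf("truth must contain: %s", paste(need, collapse = ", ")))
  TRUE
})

#' @describeIn SyntheticGenome-class chromosome sequences.
#' @param x a `SyntheticGenome`.
#' @export
genomeSequences <- function(x) x@genome

#' @describeIn SyntheticGenome-class exon annotation as `GRanges`.
#' @export
annotationRanges <- function(x) x@exons

#' @describeIn SyntheticGenome-class planted repeat intervals.
#' @export
repeatRanges <- function(x) x@repeats

#' @describeIn SyntheticGenome-class named list of truth tables.
#' @export
truthTables <- function(x) x@truth

setMethod("show", "SyntheticGenome", function(object) {
  cat("SyntheticGenome:",
      sum(Biostrings::width(object@genome)), "nt on",
      length(object@genome), "chromosome(s);",
      length(unique(object@exons$transcript_id)), "transcripts (",
      sum(object@truth$features$class == "coding"), "coding,",
      sum(object@truth$features$class == "lincRNA"), "lincRNA )\n")
})

#' A stage expression / splicing profile for read simulation
#'
#' Defines one "cell stage": per-feature target expression (FPKM scale),
#' per-intron retention truth (PIR, percent), per-exon inclusion truth
#' (PSI, percent), the per-replicate library size and read length.
#'
#' @slot stageName label.
#' @slot replicates number of replicates.
#' @slot expression named numeric vector, feature id -> target FPKM.
#' @slot pir named numeric vector, intron id -> percent in [0, 100].
#' @slot psi named numeric vector, exon id -> percent in [0, 100].
#' @slot librarySize reads per replicate.
#' @slot readLen read length in nt.
#' @slot seed integer seed.
#' @exportClass StageProfile
setClass("StageProfile", representation(
  stageName = "character",
  replicates = "integer",
  expression = "numeric",
  pir = "numeric",
  psi = "numeric",
  librarySize = "integer",
  readLen = "integer",
  seed = "integer"
))

setValidity("StageProfile", function(object) {
  msg <- character(0)
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (any(object@expression < 0)) msg <- c(msg, "expression must be >= 0")
  if (length(object@pir) && (any(object@pir < 0) || any(object@pir > 100)))
    msg <- c(msg, "PIR truth must lie in [0, 100]")
  if (length(object@psi) && (any(object@psi < 0) || any(object@psi > 100)))
    msg <- c(msg, "PSI truth must lie in [0, 100]")
  if (object@librarySize < 1L) msg <- c(msg, "librarySize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StageProfile
#'
#' @param stageName stage label.
#' @param expression named numeric vector of target FPKM per feature.
#' @param pir,psi named numeric percent-truth vectors (intron / exon ids).
#' @param replicates replicates per stage.
#' @param librarySize simulated reads per replicate.
#' @param readLen read length (nt).
#' @param seed integer seed.
#' @return A [StageProfile-class].
#' @export
stageProfile <- function(stageName, expression, pir = numeric(0),
                         psi = numeric(0), replicates = 3L,
                         librarySize = 50000L, readLen = 100L, seed = 1L) {
  new("StageProfile", stageName = stageName, replicates = as.integer(replicates),
      expression = expression, pir = pir, psi = psi,
      librarySize = as.integer(librarySize), readLen = as.integer(readLen),
      seed = as.integer(seed))
}

setMethod("show", "StageProfile", function(object) {
  cat("StageProfile", sQuote(object@stageName), ":",
      object@replicates, "replicates x", object@librarySize,
      "reads of", object@readLen, "nt;",
      length(object@expression), "features,",
      length(object@pir), "PIR truths,",
      length(object@psi), "PSI truths\n")
})

#' Junction reference library
#'
#' The set of exon-exon junction (EEJ), exon-intron junction (EIJ5 /
#' EIJ3) and intron-body reference sequences for a genome + annotation,
#' together with the splice-site table and per-junction mappability.
#' EEJ references concatenate two exonic flanks of up to
#' `readLen - minOverhang` nt each, truncated at exon boundaries; intron
#' bodies hold at most 200 nt (a centred mid-intron segment for longer
#' introns).
#'
#' @slot references [Biostrings::DNAStringSet] of reference sequences,
#'   named by junction id.
#' @slot refData a [S4Vectors::DataFrame] with one row per reference:
#'   `id`, `kind` (EEJ / EIJ5 / EIJ3 / body), `origin` (annotated /
#'   de-novo / microexon), parent `gene_id` / `transcript_id`, `unit`
#'   (intron or exon-pair label), flank lengths, and the genomic window
#'   `chrom` / `strand` / `win_lo` / `win_hi` of valid read starts for
#'   genome-contiguous (EIJ / body) references.
#' @slot sites data frame of splice sites (chrom, position, kind, strand,
#'   origin, support).
#' @slot mappability data frame: `id`, `mappability`, `max_mappability`.
#' @slot readLen,minOverhang library parameters (nt).
#' @exportClass JunctionLibrary
setClass("JunctionLibrary", representation(
  references = "DNAStringSet",
  refData = "DataFrame",
  sites = "data.frame",
  mappability = "data.frame",
  readLen = "integer",
  minOverhang = "integer"
))

setValidity("JunctionLibrary", function(object) {
  if (anyDuplicated(object@refData$id)) return("reference ids must be unique")
  if (length(object@references) != nrow(object@refData))
    return("references and refData must be parallel")
  TRUE
})

#' @describeIn JunctionLibrary-class reference sequences.
#' @param x a `JunctionLibrary`.
#' @export
refSequences <- function(x) x@references

#' @describeIn JunctionLibrary-class per-reference metadata.
#' @export
refData <- function(x) x@refData

#' @describeIn JunctionLibrary-class splice-site table.
#' @export
siteTable <- function(x) x@sites

#' @describeIn JunctionLibrary-class per-junction mappability table.
#' @export
mappabilityTable <- function(x) x@mappability

setMethod("show", "JunctionLibrary", function(object) {
  k <- table(object@refData$kind)
  cat("JunctionLibrary:", length(object@references), "references (",
      paste(names(k), k, sep = "=", collapse = ", "),
      ") readLen", object@readLen, "minOverhang", object@minOverhang, "\n")
})
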