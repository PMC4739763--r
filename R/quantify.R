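#' Mappability-correct a raw junction count
#'
#' Scales the raw read-group count of a junction to what it would be if
#' all spanning positions were uniquely mappable:
#' `corrected = raw * max_mappability / mappability`. Junctions with
#' zero mappable positions cannot be quantified and return `NA`.
#'
#' @param raw raw read-group count(s).
#' @param mappability uniquely mappable spanning positions per junction.
#' @param maxMappability library-wide maximum (see [maxMappability()]).
#' @return Corrected count(s); never smaller than `raw`.
#' @examples
#' correctJunctionCount(10, 20, 35)  # 17.5
#' @export
correctJunctionCount <- function(raw, mappability, maxMappability = 35L) {
  out <- ifelse(mappability > 0, raw * maxMappability / mappability, NA_real_)
  out[raw == 0] <- 0
  out
}

# One counted sub-read per read group, chosen uniformly among ALL the
# group's sub-reads before looking at placements, so every (read,
# window) combination is counted with the same probability and a
# junction is never counted twice for the same original read. The
# chosen sub-read contributes only if it is uniquely placed.
choose_counted_slots <- function(placements, seed = 1L) {
  if (!nrow(placements))
    return(placements[!is.na(placements$subject), , drop = FALSE])
  chosen <- with_seed_(seed, {
    perm <- sample.int(nrow(placements))
    x <- placements[perm, , drop = FALSE]
    x[!duplicated(x$group), , drop = FALSE]
  })
  chosen[!is.na(chosen$subject), , drop = FALSE]
}

#' Count junction-supporting read groups
#'
#' Applies the one-random-count-per-read-group rule to unique
#' placements, then tallies per-reference support: EEJ references by
#' direct sense placements; EIJ references by genome placements whose
#' window covers the exon-intron boundary with the library's minimum
#' overhang on each side; intron-body references by genome placements
#' falling entirely inside the body segment.
#'
#' @param placements output of [mapReadGroups()].
#' @param library a [JunctionLibrary-class].
#' @param seed seed for the counted-slot choice (recorded in the output
#'   attributes).
#' @return Data frame: `id`, `kind`, `raw` count per reference.
#' @export
countJunctionReads <- function(placements, library, seed = 1L) {
  rd <- library@refData
  counted <- choose_counted_slots(placements, seed = seed)
  raw <- integer(nrow(rd))

  is_eej <- rd$kind == "EEJ"
  eej_hits <- counted$subject[counted$strand %in% "+" &
                                counted$subject %in% rd$id[is_eej]]
  tab <- table(eej_hits)
  raw[is_eej] <- as.integer(tab[rd$id[is_eej]])
  raw[is.na(raw)] <- 0L

  gen <- counted[!(counted$subject %in% rd$id), , drop = FALSE]
  key <- paste(gen$subject, gen$strand)
  pos_by <- split(gen$pos, key)
  for (i in which(rd$kind %in% c("EIJ5", "EIJ3", "body"))) {
    if (is.na(rd$win_lo[i])) {
      # a body segment shorter than the read window cannot be observed
      if (rd$kind[i] == "body") raw[i] <- NA_integer_
      next
    }
    p <- pos_by[[paste(rd$chrom[i], rd$strand[i])]]
    if (is.null(p)) next
    raw[i] <- sum(p >= rd$win_lo[i] & p <= rd$win_hi[i])
  }
  out <- data.frame(id = rd$id, kind = rd$kind, raw = raw,
                    stringsAsFactors = FALSE)
  attr(out, "count_seed") <- seed
  out
}

#' Percent spliced in (PSI) from junction counts
#'
#' `PSI = 100 * I / (I + S)` with `I` the mean of the two
#' mappability-corrected inclusion junction counts (upstream and
#' downstream) and `S` the corrected skipping junction count.
#' `coverage_ok` requires the mean raw inclusion count plus the raw
#' skipping count to reach `minCoverage` (default 20 reads per splice
#' junction). `I + S = 0` leaves PSI undefined.
#'
#' @param up,down,skip corrected inclusion / skipping counts (vectors).
#' @param rawUp,rawDown,rawSkip raw counts (default: the corrected ones).
#' @param minCoverage minimum junction read support.
#' @return Data frame: `psi`, `coverage_ok`.
#' @examples
#' quantifyPSI(10, 10, 10)$psi  # 50
#' @export
quantifyPSI <- function(up, down, skip, rawUp = up, rawDown = down,
                        rawSkip = skip, minCoverage = 20) {
  inc <- (up + down) / 2
  tot <- inc + skip
  psi <- ifelse(tot > 0, 100 * inc / tot, NA_real_)
  cov <- (rawUp + rawDown) / 2 + rawSkip
  data.frame(psi = psi,
             coverage_ok = !is.na(psi) & cov >= minCoverage)
}

#' Percent intron retention (PIR) from junction counts
#'
#' `PIR = 100 * R / (R + EEJ)` with `R` the mean of the corrected 5'
#' and 3' exon-intron junction counts and `EEJ` the corrected count of
#' the junction formed by intron removal. Retention support must be
#' balanced: a two-sided exact binomial test of the raw EIJ5 vs EIJ3
#' counts (null p = 0.5) must not reject at `balanceAlpha`, and the
#' intron body must have read support whenever `R > 0` (body counts are
#' a presence check only). `coverage_ok` requires the mean raw EIJ
#' count plus the raw EEJ count to reach `minCoverage`.
#'
#' @param eij5,eij3,eej corrected junction counts (vectors).
#' @param body raw intron-body counts (`NA` = body shorter than the
#'   read window; the presence check is then skipped).
#' @param rawEij5,rawEij3,rawEej raw counts (default: corrected).
#' @param minCoverage minimum junction read support.
#' @param balanceAlpha significance level of the balance test.
#' @return Data frame: `pir`, `coverage_ok`, `balance_ok`.
#' @examples
#' quantifyPIR(10, 10, body = 5, eej = 10)$pir  # 50
#' @export
quantifyPIR <- function(eij5, eij3, body, eej, rawEij5 = eij5,
                        rawEij3 = eij3, rawEej = eej, minCoverage = 20,
                        balanceAlpha = 0.05) {
  r <- (eij5 + eij3) / 2
  tot <- r + eej
  pir <- ifelse(tot > 0, 100 * r / tot, NA_real_)
  cov <- (rawEij5 + rawEij3) / 2 + rawEej
  n5 <- round(rawEij5); n3 <- round(rawEij3)
  bal_p <- mapply(function(a, b) {
    if (a + b == 0) return(1)
    stats::binom.test(a, a + b, p = 0.5)$p.value
  }, n5, n3)
  body_ok <- is.na(body) | body > 0 | r == 0
  data.frame(pir = pir,
             coverage_ok = !is.na(pir) & cov >= minCoverage,
             balance_ok = bal_p >= balanceAlpha & body_ok)
}

# intron / cassette-exon event scaffolds from the library's reference ids
ir_event_index <- function(library) {
  rd <- library@refData
  ir <- rd[rd$kind == "EIJ5", c("transcript_id", "unit")]
  if (!nrow(ir)) return(NULL)
  k <- as.integer(sub("^i", "", ir$unit))
  data.frame(event = sprintf("%s.%s", ir$transcript_id, ir$unit),
             eij5 = sprintf("%s.eij5.%d", ir$transcript_id, k),
             eij3 = sprintf("%s.eij3.%d", ir$transcript_id, k),
             body = sprintf("%s.body.%d", ir$transcript_id, k),
             eej = sprintf("%s.eej.%d_%d", ir$transcript_id, k, k + 1L),
             stringsAsFactors = FALSE)
}

es_event_index <- function(library) {
  rd <- library@refData
  out <- list()
  for (tx in unique(rd$transcript_id[rd$kind == "EIJ5"])) {
    n_in <- sum(rd$kind == "EIJ5" & rd$transcript_id == tx)
    n_ex <- n_in + 1L
    if (n_ex < 3L) next
    for (k in 2:(n_ex - 1L))
      out[[length(out) + 1L]] <- data.frame(
        event = sprintf("%s.e%d", tx, k),
        up = sprintf("%s.eej.%d_%d", tx, k - 1L, k),
        down = sprintf("%s.eej.%d_%d", tx, k, k + 1L),
        skip = sprintf("%s.eej.%d_%d", tx, k - 1L, k + 1L),
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

#' Quantify intron retention and exon skipping across samples
#'
#' Full junction pipeline for a set of read sets: split into read
#' groups, map uniquely against genome + junction library, count with
#' the one-count-per-group rule, mappability-correct, and compute
#' per-intron PIR and per-internal-exon PSI for every sample.
#'
#' @param readSets named list of read sets (character or
#'   `DNAStringSet`), one per sample.
#' @param genome a [Biostrings::DNAStringSet].
#' @param library a [JunctionLibrary-class] with a mappability table.
#' @param windowLen,step read-group parameters (see
#'   [splitReadGroups()]).
#' @param maxMismatches mapping mismatch allowance (see
#'   [mapReadGroups()]).
#' @param minCoverage,balanceAlpha see [quantifyPIR()] /
#'   [quantifyPSI()].
#' @param seed seed for the counted-slot choice.
#' @return List of two data frames, `ir` and `es`, one row per event x
#'   sample with counts, PIR / PSI and flags.
#' @export
quantifySplicing <- function(readSets, genome, library, windowLen = 50L,
                             step = 25L, maxMismatches = 0L,
                             minCoverage = 20, balanceAlpha = 0.05,
                             seed = 1L) {
  stopifnot(!is.null(names(readSets)))
  mp <- library@mappability
  if (!nrow(mp)) stop("library has no mappability table")
  iri <- ir_event_index(library)
  esi <- es_event_index(library)
  ir_out <- list(); es_out <- list()
  for (sm in names(readSets)) {
    grp <- splitReadGroups(readSets[[sm]], windowLen, step)
    pl <- mapReadGroups(grp, genome, library, maxMismatches)
    cnt <- countJunctionReads(pl, library, seed = seed)
    raw <- stats::setNames(cnt$raw, cnt$id)
    corr <- stats::setNames(
      correctJunctionCount(cnt$raw, mp$mappability[match(cnt$id, mp$id)],
                           mp$max_mappability[match(cnt$id, mp$id)]),
      cnt$id)
    if (!is.null(iri)) {
      q <- quantifyPIR(corr[iri$eij5], corr[iri$eij3],
                       body = unname(raw[iri$body]),
                       eej = corr[iri$eej],
                       rawEij5 = raw[iri$eij5], rawEij3 = raw[iri$eij3],
                       rawEej = raw[iri$eej],
                       minCoverage = minCoverage, balanceAlpha = balanceAlpha)
      ir_out[[sm]] <- data.frame(
        event = iri$event, sample = sm,
        eij5 = unname(corr[iri$eij5]), eij3 = unname(corr[iri$eij3]),
        body = unname(raw[iri$body]), eej = unname(corr[iri$eej]), q,
        stringsAsFactors = FALSE, row.names = NULL)
    }
    if (!is.null(esi)) {
      q <- quantifyPSI(corr[esi$up], corr[esi$down], corr[esi$skip],
                       rawUp = raw[esi$up], rawDown = raw[esi$down],
                       rawSkip = raw[esi$skip], minCoverage = minCoverage)
      es_out[[sm]] <- data.frame(
        event = esi$event, sample = sm,
        up = unname(corr[esi$up]), down = unname(corr[esi$down]),
        skip = unname(corr[esi$skip]), q,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  list(ir = if (length(ir_out)) do.call(rbind, c(ir_out, make.row.names = FALSE))
            else NULL,
       es = if (length(es_out)) do.call(rbind, c(es_out, make.row.names = FALSE))
            else NULL)
}

#' Classify quantified events across samples
#'
#' Applies the event-level thresholds: an intron is a positive
#' retention event when PIR >= 20 in at least one sample and
#' constitutively spliced when PIR < 2 in all samples; an exon is
#' alternative when its skipping rate is below 90 percent inclusion
#' (PSI <= 90) in at least one sample.
#'
#' @param ir,es long event tables from [quantifySplicing()].
#' @return List of per-event summaries with logical flags `retained` /
#'   `constitutive` (IR) and `alternative` (ES).
#' @export
classifySpliceEvents <- function(ir = NULL, es = NULL) {
  out <- list()
  if (!is.null(ir)) {
    sp <- split(ir$pir, ir$event)
    out$ir <- data.frame(
      event = names(sp),
      retained = vapply(sp, function(x) any(x >= 20, na.rm = TRUE), logical(1)),
      constitutive = vapply(sp, function(x)
        all(!is.na(x)) && all(x < 2), logical(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (!is.null(es)) {
    sp <- split(es$psi, es$event)
    out$es <- data.frame(
      event = names(sp),
      alternative = vapply(sp, function(x) any(x <= 90, na.rm = TRUE), logical(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
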