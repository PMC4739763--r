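#' Expression in FPKM and mappability-corrected cRPKM
#'
#' `FPKM = 1e9 * count / (length * total_mapped)` (fragments per
#' kilobase of exon per million mapped fragments) and
#' `cRPKM = 1e9 * count / (mappable_positions * total_unique)` (reads
#' per 1000 uniquely mappable positions per million uniquely mapped
#' reads). FPKM is invariant to scaling counts and library size by the
#' same factor; when a feature's mappable-position count equals its
#' length, cRPKM equals RPKM.
#'
#' @param counts feature x sample matrix of raw counts.
#' @param lengths feature lengths, nt (> 0).
#' @param librarySizes per-sample totals (default: column sums).
#' @param mappablePositions per-feature uniquely mappable positions;
#'   `NULL` skips cRPKM, zeros yield `NA`.
#' @return List of matrices: `fpkm`, and `crpkm` when requested.
#' @examples
#' computeExpression(matrix(10), lengths = 1000, librarySizes = 1e6)$fpkm
#' @export
computeExpression <- function(counts, lengths, librarySizes = colSums(counts),
                              mappablePositions = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(lengths > 0), all(librarySizes > 0),
            length(lengths) == nrow(counts))
  fpkm <- 1e9 * sweep(counts / lengths, 2L, librarySizes, "/")
  out <- list(fpkm = fpkm)
  if (!is.null(mappablePositions)) {
    mp <- ifelse(mappablePositions > 0, mappablePositions, NA_real_)
    out$crpkm <- 1e9 * sweep(counts / mp, 2L, librarySizes, "/")
  }
  out
}

#' Call differential splicing between two stages
#'
#' An event is called differential when the absolute difference of its
#' stage-mean PIR / PSI exceeds `deltaMin` (default over 15 points),
#' every stage's replicate standard deviation stays below `sdMax`
#' (default under 10), and coverage is adequate in all samples.
#'
#' @param events long table with columns `event`, `sample`, `stage`, a
#'   value column (`pir` or `psi`, auto-detected via `value`), and
#'   `coverage_ok`.
#' @param value name of the value column; default picks `pir` or `psi`.
#' @param deltaMin minimum |stage-mean difference|, percentage points.
#' @param sdMax maximum per-stage replicate standard deviation.
#' @return Data frame per event: stage means, `delta` (second stage
#'   minus first), per-stage SDs, `called`. Events with missing
#'   replicate values are skipped with a message.
#' @export
callDiffSplicing <- function(events, value = NULL, deltaMin = 15,
                             sdMax = 10) {
  value <- value %||% intersect(c("pir", "psi"), names(events))[1L]
  stopifnot(!is.na(value), "stage" %in% names(events))
  stages <- sort(unique(events$stage))
  if (length(stages) != 2L)
    stop("exactly two stages are required, got: ",
         paste(stages, collapse = ", "))
  out <- list(); skipped <- 0L
  for (ev in unique(events$event)) {
    d <- events[events$event == ev, ]
    v1 <- d[[value]][d$stage == stages[1L]]
    v2 <- d[[value]][d$stage == stages[2L]]
    if (length(v1) < 2L || length(v2) < 2L || anyNA(c(v1, v2))) {
      skipped <- skipped + 1L
      next
    }
    m1 <- mean(v1); m2 <- mean(v2)
    s1 <- stats::sd(v1); s2 <- stats::sd(v2)
    out[[ev]] <- data.frame(
      event = ev, mean1 = m1, mean2 = m2, delta = m2 - m1,
      sd1 = s1, sd2 = s2,
      coverage_ok = all(d$coverage_ok),
      called = abs(m2 - m1) > deltaMin & s1 < sdMax & s2 < sdMax &
        all(d$coverage_ok),
      stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " event(s) skipped for missing replicate values")
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation-based differential expression (plumbing stand-in)
#'
#' A self-contained two-stage caller used to exercise downstream
#' plumbing: the statistic is the log2 fold change of stage means (with
#' a pseudocount of 1); its null distribution pools the statistics of
#' all genes over balanced relabelings of the replicates, giving
#' fine-grained permutation p-values even at n = 3 vs 3; BH adjustment
#' controls FDR. Deterministic under `seed` when relabelings are
#' subsampled.
#'
#' @param counts gene x sample matrix.
#' @param stages factor/character of length `ncol(counts)` with exactly
#'   two levels, at least two replicates each.
#' @param nPermutations maximum relabelings (all are enumerated when
#'   fewer exist).
#' @param seed integer seed.
#' @param qThreshold BH-adjusted significance threshold.
#' @return Data frame: `gene`, `log2fc`, `p`, `q`, `called`.
#' @export
callDiffExpression <- function(counts, stages, nPermutations = 1000L,
                               seed = 1L, qThreshold = 0.05) {
  counts <- as.matrix(counts)
  stages <- as.character(stages)
  lv <- unique(stages)
  stopifnot(length(lv) == 2L)
  i1 <- which(stages == lv[1L]); i2 <- which(stages == lv[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("at least two replicates per stage are required")
  stat <- function(a, b)
    log2((rowMeans(counts[, b, drop = FALSE]) + 1) /
           (rowMeans(counts[, a, drop = FALSE]) + 1))
  obs <- stat(i1, i2)

  n <- ncol(counts)
  combos <- utils::combn(n, length(i1), simplify = FALSE)
  # mixed relabelings only: the observed labeling and its mirror carry
  # the signal itself and do not belong in the null pool
  combos <- Filter(function(a) !setequal(a, i1) && !setequal(a, i2), combos)
  if (length(combos) > nPermutations)
    combos <- with_seed_(seed, sample(combos, nPermutations))
  null <- unlist(lapply(combos, function(a) stat(a, setdiff(seq_len(n), a))))
  null <- abs(null)
  # pooled empirical p-value, add-one corrected
  p <- (1 + vapply(abs(obs), function(x) sum(null >= x), numeric(1))) /
    (1 + length(null))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             log2fc = unname(obs), p = unname(p), q = unname(q),
             called = unname(q <= qThreshold), stringsAsFactors = FALSE)
}
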