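#' Normalize an ortholog expression matrix
#'
#' Entrywise `log2(x + 1)` transform followed by column quantile
#' normalization (every column's sorted values are replaced by the
#' cross-column rank means; tied ranks share their mean). After the
#' step all columns have identical sorted values.
#'
#' @param m genes x samples matrix of non-negative expression values
#'   (cRPKM or FPKM scale).
#' @return The normalized matrix, with attribute
#'   `normalization = "quantile"`.
#' @export
normalizeMatrix <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("expression matrix must be non-negative")
  out <- limma::normalizeQuantiles(log2(m + 1), ties = TRUE)
  dimnames(out) <- dimnames(m)
  attr(out, "normalization") <- "quantile"
  out
}

#' Pairwise Spearman correlation distances between samples
#'
#' `d(i, j) = 1 - rho(column i, column j)` with average-rank tie
#' handling; symmetric with a zero diagonal, entries in `[0, 2]`.
#'
#' @param m genes x samples matrix (>= 3 genes).
#' @return samples x samples distance matrix.
#' @export
spearmanDistances <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 3L)
  const <- apply(m, 2L, function(x) stats::sd(x) == 0)
  if (any(const))
    warning("constant column(s): ", paste(colnames(m)[const], collapse = ", "),
            "; their correlations are undefined")
  d <- 1 - suppressWarnings(stats::cor(m, method = "spearman"))
  diag(d) <- 0
  d
}

#' Cluster samples by expression distance
#'
#' Complete-linkage hierarchical clustering and a neighbor-joining tree
#' from the same Spearman correlation distance matrix. Bootstrap
#' support resamples genes (rows) with replacement, recomputes the
#' distances and the NJ tree, and reports the percentage of replicates
#' containing each internal bipartition.
#'
#' @param m normalized genes x samples matrix (used for the gene
#'   bootstrap; may be `NULL` when `distances` is supplied and
#'   `nBootstrap = 0`).
#' @param distances samples x samples distance matrix; defaults to
#'   [spearmanDistances()] of `m`.
#' @param nBootstrap bootstrap replicates (default 100; 0 skips).
#' @param seed integer seed.
#' @return List: `distances`, `hclust`, `nj` (an [ape::phylo] with
#'   bootstrap percentages in `node.label`), `support`.
#' @export
clusterSamples <- function(m = NULL, distances = NULL, nBootstrap = 100L,
                           seed = 1L) {
  if (is.null(distances)) distances <- spearmanDistances(m)
  hc <- stats::hclust(stats::as.dist(distances), method = "complete")
  if (ncol(distances) < 3L)
    return(list(distances = distances, hclust = hc, nj = NULL,
                support = NULL))
  tr <- ape::nj(stats::as.dist(distances))
  support <- NULL
  if (nBootstrap > 0L) {
    stopifnot(!is.null(m))
    m <- as.matrix(m)
    nj_fun <- function(x)  # x: samples x genes
      ape::nj(stats::as.dist(1 - stats::cor(t(x), method = "spearman")))
    bp <- with_seed_(seed,
      ape::boot.phylo(tr, t(m), nj_fun, B = nBootstrap, quiet = TRUE,
                      trees = FALSE))
    support <- 100 * bp / nBootstrap
    tr$node.label <- support
  }
  list(distances = distances, hclust = hc, nj = tr, support = support)
}

#' PCA of sample expression profiles with top-loading gene extraction
#'
#' Principal component analysis of the samples (genes centred across
#' samples, no rescaling -- quantile normalization already equalizes
#' the distributions). Component signs are fixed so each component's
#' largest-magnitude gene loading is positive, making "loading above
#' threshold" gene selections reproducible.
#'
#' @param m normalized genes x samples matrix.
#' @param loadingThreshold select genes with loading above this value
#'   on `component`.
#' @param component which component to extract the gene set from.
#' @return List: `scores` (samples x components), `loadings` (genes x
#'   components), `var_explained` (fractions), `genes` (selected ids).
#' @export
pcaWithLoadings <- function(m, loadingThreshold = 0.03, component = 2L) {
  m <- as.matrix(m)
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(pr$rotation))) {
    if (pr$rotation[which.max(abs(pr$rotation[, k])), k] < 0) {
      pr$rotation[, k] <- -pr$rotation[, k]
      pr$x[, k] <- -pr$x[, k]
    }
  }
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  component <- min(component, ncol(pr$rotation))
  sel <- rownames(pr$rotation)[pr$rotation[, component] > loadingThreshold]
  if (!length(sel))
    warning("no gene loading exceeds ", loadingThreshold,
            " on component ", component)
  list(scores = pr$x, loadings = pr$rotation, var_explained = ve,
       genes = sel)
}

#' Co-regulation of a gene module
#'
#' Full pairwise Pearson correlation matrix over the module's genes,
#' summarized as the mean off-diagonal correlation, and compared with a
#' resampled background of size-matched random gene sets.
#'
#' @param m genes x samples matrix (>= 3 samples).
#' @param moduleGenes character ids (rows of `m`).
#' @param nBackground random size-matched gene sets (default 1000).
#' @param seed integer seed.
#' @return List: `cor` (module correlation matrix), `mean_r`,
#'   `background` (vector of background mean correlations),
#'   `percentile` (of `mean_r` in the background), `degenerate`
#'   (zero-variance module genes).
#' @export
moduleCoregulation <- function(m, moduleGenes, nBackground = 1000L,
                               seed = 1L) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 3L, all(moduleGenes %in% rownames(m)))
  mean_offdiag <- function(genes) {
    cc <- suppressWarnings(stats::cor(t(m[genes, , drop = FALSE])))
    mean(cc[upper.tri(cc)], na.rm = TRUE)
  }
  sds <- apply(m[moduleGenes, , drop = FALSE], 1L, stats::sd)
  degenerate <- moduleGenes[sds == 0]
  cc <- suppressWarnings(stats::cor(t(m[moduleGenes, , drop = FALSE])))
  mean_r <- mean(cc[upper.tri(cc)], na.rm = TRUE)
  bg <- with_seed_(seed, vapply(seq_len(nBackground), function(i)
    mean_offdiag(sample(rownames(m), length(moduleGenes))), numeric(1)))
  list(cor = cc, mean_r = mean_r, background = bg,
       percentile = mean(bg <= mean_r), degenerate = degenerate)
}
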