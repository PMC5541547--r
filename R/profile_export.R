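#' Z-linked log2 expression matrix for heatmap rendering
#'
#' Exports every Z-linked gene's log2 FPKM across samples — including genes
#' with zero FPKM, which are floored rather than dropped, so the profile
#' shows the whole chromosome. Display-only: the floored values never feed
#' the ratio statistics.
#'
#' @param x a \linkS4class{DosageExperiment} with unit \code{fpkm}.
#' @param map named chromosome map (see
#'   \code{\link{readGeneChromosomeMap}}).
#' @param zChromosome the Z chromosome number (default 1).
#' @param floor small positive value substituted for zero FPKM before
#'   log2 (default \code{2^-10}, i.e. a floored value of -10).
#' @param sampleOrder optional character vector giving the column order
#'   (stage/sex order for the plot).
#' @return numeric gene x sample matrix of log2 values over all Z-linked
#'   genes.
#' @export
zProfileMatrix <- function(x, map, zChromosome = 1L, floor = 2^-10,
                           sampleOrder = NULL) {
  stopifnot(is(x, "DosageExperiment"))
  if (exprUnit(x) != "fpkm")
    stop("zProfileMatrix expects unit 'fpkm', got '", exprUnit(x), "'")
  if (floor <= 0) stop("floor must be positive")
  chrom <- unname(map[rownames(x)])
  chromNum <- suppressWarnings(as.numeric(chrom))
  isZ <- !is.na(chromNum) & chromNum == zChromosome
  if (!any(isZ)) stop("no Z-linked genes in the matrix")
  vals <- assay(x, 1L)[isZ, , drop = FALSE]
  if (!is.null(sampleOrder)) {
    miss <- setdiff(sampleOrder, colnames(vals))
    if (length(miss))
      stop("unknown sample(s) in sampleOrder: ",
           paste(sQuote(miss), collapse = ", "))
    vals <- vals[, sampleOrder, drop = FALSE]
  }
  log2(pmax(vals, floor))
}

#' Deterministic hierarchical clustering of gene expression profiles
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson r across samples), cut into k clusters. Rows with zero
#' variance (e.g. all-floored silent genes) are handled by a defined
#' fallback: two constant rows are at distance 0 when identical and 1
#' otherwise, and a constant row is at distance 1 from any varying row.
#' Cluster labels are canonicalised — clusters are numbered by the
#' lexicographically smallest gene id they contain — so the labelling is
#' invariant to the input row order.
#'
#' @param mat numeric gene x sample matrix (e.g. from
#'   \code{\link{zProfileMatrix}}).
#' @param k number of clusters, \code{2 <= k <= nrow(mat)}.
#' @return named integer vector gene -> cluster label in 1..k.
#' @export
clusterGenes <- function(mat, k) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (is.null(rownames(mat))) stop("matrix must have gene ids as rownames")
  if (k < 2L || k > n)
    stop("k must be between 2 and the number of genes (", n, "), got ", k)
  v <- apply(mat, 1L, stats::var)
  const <- v < .Machine$double.eps
  d <- matrix(1, n, n)
  if (any(!const)) {
    cc <- suppressWarnings(stats::cor(t(mat[!const, , drop = FALSE])))
    d[!const, !const] <- 1 - cc
  }
  if (any(const)) {
    ci <- which(const)
    for (i in ci) for (j in ci)
      d[i, j] <- if (isTRUE(all.equal(mat[i, ], mat[j, ]))) 0 else 1
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  raw <- stats::cutree(hc, k = k)
  # canonical labels: order clusters by their smallest member gene id
  first <- vapply(seq_len(k), function(cl) min(names(raw)[raw == cl]),
                  character(1L))
  relabel <- match(seq_len(k), order(first))
  stats::setNames(relabel[raw], names(raw))
}
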