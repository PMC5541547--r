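#' Derive FPKM from raw counts
#'
#' FPKM(g, s) = 1e9 * count(g, s) / (length(g) * N(s)), with N(s) the
#' library size of sample s. Gene lengths must be attached to the object
#' (merged-exon length when derived from annotation, otherwise a supplied
#' length column).
#'
#' @param x a \linkS4class{DosageExperiment} with unit \code{raw_counts}
#'   and gene lengths.
#' @param librarySizes per-sample library sizes: \code{"from_column_sums"}
#'   (default) or a named/positional numeric vector of positive totals.
#' @return a \linkS4class{DosageExperiment} with unit \code{fpkm}.
#' @examples
#' m <- matrix(c(10L, 0L), 1, 2,
#'             dimnames = list("g1", c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1","s2"), sex = c("male","female"),
#'                  stage = "78h", replicate = 1L)
#' de <- DosageExperiment(m, "raw_counts", md, geneLengths = c(g1 = 1000))
#' # assay(computeFpkm(de, c(1e6, 1e6)))  ->  10, 0
#' @export
computeFpkm <- function(x, librarySizes = "from_column_sums") {
  stopifnot(is(x, "DosageExperiment"))
  if (exprUnit(x) != "raw_counts")
    stop("computeFpkm expects unit 'raw_counts', got '", exprUnit(x), "'")
  len <- geneLengths(x)
  if (is.null(len))
    stop("missing gene lengths: attach a gene_length column")
  if (anyNA(len))
    stop("missing gene length for gene '",
         rownames(x)[which(is.na(len))[1L]], "'")
  counts <- assay(x, 1L)
  if (identical(librarySizes, "from_column_sums")) {
    N <- colSums(counts)
  } else {
    N <- librarySizes
    if (!is.null(names(N))) N <- N[colnames(counts)]
    if (length(N) != ncol(counts))
      stop("librarySizes must cover every sample")
  }
  if (any(N <= 0)) stop("library sizes must be positive")
  fpkm <- 1e9 * sweep(counts / as.numeric(len), 2L, N, "/")
  out <- x
  SummarizedExperiment::assay(out, 1L) <- fpkm
  out@unit <- "fpkm"
  validObject(out)
  out
}

#' Average technical replicates
#'
#' Collapses replicate columns to one column per (sex, stage) group by the
#' per-gene arithmetic mean. Singleton groups pass through unchanged. The
#' collapsed columns are named \code{<sex>_<stage>} (\code{<stage>} for
#' sexless samples) and ordered by first appearance.
#'
#' @param x a \linkS4class{DosageExperiment} (any unit; replicates within a
#'   group share it by construction).
#' @return a \linkS4class{DosageExperiment} with one column per group and
#'   \code{replicate = 1}.
#' @export
averageReplicates <- function(x) {
  stopifnot(is(x, "DosageExperiment"))
  cd <- colData(x)
  key <- ifelse(cd$sex == "none", as.character(cd$stage),
                paste(cd$sex, cd$stage, sep = "_"))
  groups <- unique(key)
  vals <- assay(x, 1L)
  out <- vapply(groups, function(g) {
    cols <- which(key == g)
    if (!length(cols)) stop("empty replicate group: ", g)
    rowMeans(vals[, cols, drop = FALSE])
  }, numeric(nrow(vals)))
  if (nrow(vals) == 1L) out <- matrix(out, 1L, dimnames = list(rownames(vals), groups))
  md <- data.frame(
    sample_id = groups,
    sex = cd$sex[match(groups, key)],
    stage = cd$stage[match(groups, key)],
    replicate = 1L
  )
  de <- DosageExperiment(out, unit = exprUnit(x), sampleData = md,
                         geneLengths = geneLengths(x))
  if ("chromosome" %in% colnames(rowData(x)))
    rowData(de)$chromosome <- rowData(x)$chromosome
  de
}

#' Restrict to the "true expression" gene set (FPKM != 0)
#'
#' All ratio statistics are computed on genes that actually show expression.
#' Two universes are used: per sample (each sample keeps its own positive
#' genes; the universe of Z:A analysis) and per stage requiring expression
#' in \emph{both} the male and the female column (the universe of M:F
#' analysis).
#'
#' @param x a \linkS4class{DosageExperiment} with unit \code{fpkm}.
#' @param mode \code{"per_sample"} or \code{"both_sexes"}.
#' @return for \code{per_sample}, a named list (one element per sample) of
#'   named numeric vectors holding that sample's positive FPKM values; for
#'   \code{both_sexes}, a named list (one element per stage present in both
#'   sexes) of row/column-subset \code{DosageExperiment}s with exactly the
#'   male and female columns and the genes positive in both.
#' @export
filterTrueExpression <- function(x, mode = c("per_sample", "both_sexes")) {
  stopifnot(is(x, "DosageExperiment"))
  if (exprUnit(x) != "fpkm")
    stop("filterTrueExpression expects unit 'fpkm', got '", exprUnit(x), "'")
  mode <- match.arg(mode)
  vals <- assay(x, 1L)
  if (mode == "per_sample") {
    out <- lapply(colnames(vals), function(s) {
      v <- vals[, s]
      v[v > 0]
    })
    names(out) <- colnames(vals)
    return(out)
  }
  cd <- colData(x)
  stages <- unique(as.character(cd$stage[cd$sex %in% c("male", "female")]))
  out <- list()
  for (st in stages) {
    mcol <- which(cd$stage == st & cd$sex == "male")
    fcol <- which(cd$stage == st & cd$sex == "female")
    if (!length(mcol) || !length(fcol)) next
    if (length(mcol) > 1L || length(fcol) > 1L)
      stop("stage '", st, "' has multiple columns per sex; ",
           "average replicates first")
    keep <- vals[, mcol] > 0 & vals[, fcol] > 0
    out[[st]] <- x[keep, c(mcol, fcol)]
  }
  if (!length(out))
    stop("no stage with both a male and a female sample")
  out
}

#' Remove genes with low raw counts in a four-sample comparison
#'
#' A gene is retained iff its raw count is at least \code{minCount} in
#' \emph{all} four comparison samples (2 male x 2 female technical
#' replicates of one stage); a count below the threshold in any one of the
#' four removes the gene. Applied before TMM normalization of the M:F
#' analysis.
#'
#' @param x a \linkS4class{DosageExperiment} with unit \code{raw_counts}.
#' @param comparisonSamples character vector of exactly 4 sample ids.
#' @param minCount minimum raw count (default 4; a count of exactly 4 is
#'   kept — the rule removes genes with \emph{less than} four).
#' @return the row-filtered \code{DosageExperiment} (all columns kept).
#' @export
filterLowCounts <- function(x, comparisonSamples, minCount = 4L) {
  stopifnot(is(x, "DosageExperiment"))
  if (exprUnit(x) != "raw_counts")
    stop("filterLowCounts expects unit 'raw_counts', got '", exprUnit(x), "'")
  if (length(comparisonSamples) != 4L)
    stop("comparisonSamples must name exactly 4 samples, got ",
         length(comparisonSamples))
  miss <- setdiff(comparisonSamples, colnames(x))
  if (length(miss))
    stop("unknown sample(s): ", paste(sQuote(miss), collapse = ", "))
  sub <- assay(x, 1L)[, comparisonSamples, drop = FALSE]
  keep <- rowSums(sub >= minCount) == 4L
  x[keep, ]
}

#' TMM between-sample scaling factors
#'
#' Computes trimmed-mean-of-M-values scaling factors for a raw-count
#' matrix. For each sample k against the reference r, over the genes with
#' positive counts in both libraries:
#' \deqn{M_g = \log_2\frac{x_{gk}/N_k}{x_{gr}/N_r}, \qquad
#'       A_g = \tfrac12 \log_2\left(\frac{x_{gk}}{N_k}\cdot
#'             \frac{x_{gr}}{N_r}\right)}
#' The genes in the top/bottom \code{logratioTrim} fraction by M and the
#' top/bottom \code{intensityTrim} fraction by A are dropped (intersection
#' of survivors), and the factor is
#' \eqn{2^{\sum w_g M_g / \sum w_g}} with inverse-variance (delta-method
#' binomial) weights
#' \eqn{w_g = 1/\left(\frac{N_k - x_{gk}}{N_k x_{gk}} +
#' \frac{N_r - x_{gr}}{N_r x_{gr}}\right)}. Factors are rescaled so their
#' geometric mean is 1 (their product is 1).
#'
#' @param x a \linkS4class{DosageExperiment} with unit \code{raw_counts}
#'   and at least two samples.
#' @param reference reference sample id, or \code{"auto"}: the sample whose
#'   75th-percentile count fraction is closest to the mean of those
#'   fractions.
#' @param logratioTrim fraction trimmed from each tail of the M
#'   distribution (default 0.30).
#' @param intensityTrim fraction trimmed from each tail of the A
#'   distribution (default 0.05).
#' @return list of class \code{"TmmFactors"}: \code{factors} (named, product
#'   1), \code{reference}, \code{logratio_trim}, \code{intensity_trim}.
#' @references Robinson MD, Oshlack A (2010). A scaling normalization
#'   method for differential expression analysis of RNA-seq data.
#'   Genome Biology 11:R25.
#' @export
tmmFactors <- function(x, reference = "auto", logratioTrim = 0.30,
                       intensityTrim = 0.05) {
  stopifnot(is(x, "DosageExperiment"))
  if (exprUnit(x) != "raw_counts")
    stop("tmmFactors expects unit 'raw_counts', got '", exprUnit(x), "'")
  counts <- assay(x, 1L)
  if (ncol(counts) < 2L) stop("TMM needs at least two samples")
  if (any(colSums(counts) <= 0)) stop("every sample needs a positive count")
  N <- colSums(counts)
  if (identical(reference, "auto")) {
    f75 <- apply(counts, 2L, function(v) stats::quantile(v / sum(v), 0.75))
    reference <- colnames(counts)[which.min(abs(f75 - mean(f75)))]
  } else if (!reference %in% colnames(counts)) {
    stop("unknown reference sample: ", reference)
  }
  ref <- counts[, reference]
  Nr <- N[[reference]]
  factors <- vapply(colnames(counts), function(k) {
    if (k == reference) return(1)
    .tmmPairFactor(counts[, k], ref, N[[k]], Nr,
                   logratioTrim, intensityTrim, k)
  }, numeric(1L))
  factors <- factors / exp(mean(log(factors)))
  structure(list(factors = factors, reference = reference,
                 logratio_trim = logratioTrim,
                 intensity_trim = intensityTrim),
            class = "TmmFactors")
}

.tmmPairFactor <- function(obs, ref, Nk, Nr, logratioTrim, intensityTrim,
                           label) {
  use <- obs > 0 & ref > 0
  if (!any(use))
    stop("sample '", label, "' shares no co-expressed gene with the ",
         "reference")
  o <- obs[use]; r <- ref[use]
  M <- log2((o / Nk) / (r / Nr))
  A <- 0.5 * log2((o / Nk) * (r / Nr))
  w <- 1 / ((Nk - o) / (Nk * o) + (Nr - r) / (Nr * r))
  n <- length(M)
  # drop the top and bottom `trim` fraction on each axis; keep the
  # intersection of survivors (rank-based, average ranks on ties)
  loM <- floor(n * logratioTrim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * intensityTrim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    warning("no genes survive TMM trimming for sample '", label,
            "'; factor set to 1")
    return(1)
  }
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' @export
print.TmmFactors <- function(x, ...) {
  cat("TMM scaling factors (reference:", x$reference, ")\n")
  print(round(x$factors, 6))
  invisible(x)
}
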