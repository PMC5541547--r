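#' Bootstrap percentile confidence interval for the median Z:A ratio
#'
#' Nonparametric bootstrap of the ratio of class medians: each replicate
#' resamples the autosomal vector (size |A|, with replacement) and the
#' Z-linked vector (size |Z|, with replacement) independently and computes
#' median(Z*)/median(A*). The reported point estimate is the median of the
#' bootstrap distribution and the interval its empirical percentile bounds
#' (linear interpolation). Resampling is on the linear FPKM scale; for odd
#' resample sizes this is identical to bootstrapping log values and
#' back-transforming.
#'
#' @param fpkmA,fpkmZ positive FPKM vectors of expressed autosomal and
#'   Z-linked genes.
#' @param nBoot number of bootstrap replicates (default 10000).
#' @param ciLevel confidence level (default 0.95).
#' @param seed integer seed; the result is fully reproducible from it.
#' @return list of class \code{"BootstrapResult"}: \code{point},
#'   \code{ci_low}, \code{ci_high}, \code{n_boot}, \code{ci_level},
#'   \code{seed}.
#' @examples
#' bootstrapZaMedian(c(2, 2, 2, 2), c(1, 1, 1, 1), nBoot = 100,
#'                   seed = 1)  # point 0.5, zero-width CI
#' @export
bootstrapZaMedian <- function(fpkmA, fpkmZ, nBoot = 10000L,
                              ciLevel = 0.95, seed) {
  if (!length(fpkmA) || !length(fpkmZ))
    stop("bootstrapZaMedian needs non-empty A and Z vectors")
  if (nBoot < 1L) stop("nBoot must be at least 1")
  if (missing(seed)) stop("an explicit seed is required")
  nA <- length(fpkmA); nZ <- length(fpkmZ)
  stat <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      mz <- stats::median(fpkmZ[sample.int(nZ, nZ, replace = TRUE)])
      ma <- stats::median(fpkmA[sample.int(nA, nA, replace = TRUE)])
      mz / ma
    }, numeric(1L))
  })
  alpha <- (1 - ciLevel) / 2
  ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha), type = 7))
  structure(list(point = stats::median(stat),
                 ci_low = ci[1L], ci_high = ci[2L],
                 n_boot = as.integer(nBoot), ci_level = ciLevel,
                 seed = as.integer(seed)),
            class = "BootstrapResult")
}

#' @export
print.BootstrapResult <- function(x, ...) {
  cat(sprintf("bootstrap median Z:A = %.6f, %g%% CI [%.6f, %.6f] (%d reps)\n",
              x$point, 100 * x$ci_level, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

# Evaluate an expression under a local RNG state restored on exit.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
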