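#' Z:A expression summary for one sample
#'
#' Core dosage estimate: mean- and median-based ratios of Z-linked to
#' autosomal expression within one sample, on the linear FPKM scale,
#' together with a two-sided rank-sum comparison of the two gene classes on
#' log2 values. A ratio near 1 means the average Z-linked gene is expressed
#' like the average autosomal gene; near 0.5, at half that level.
#'
#' @param fpkmA positive FPKM vector of expressed autosomal genes.
#' @param fpkmZ positive FPKM vector of expressed Z-linked genes.
#' @param label sample label carried into the output row.
#' @return one-row data.frame: \code{label}, \code{mean_A}, \code{mean_Z},
#'   \code{mean_za}, \code{median_A}, \code{median_Z}, \code{median_za},
#'   \code{n_A}, \code{n_Z}, \code{p_A_vs_Z}.
#' @examples
#' zaSummary(c(1, 2, 4), c(1, 2), "toy")  # median_za = 1.5/2 = 0.75
#' @export
zaSummary <- function(fpkmA, fpkmZ, label = "") {
  if (!length(fpkmA) || !length(fpkmZ))
    stop("zaSummary needs non-empty A and Z vectors")
  if (any(fpkmA <= 0) || any(fpkmZ <= 0))
    stop("zaSummary expects strictly positive FPKM ",
         "(apply the true-expression filter first)")
  p <- mwuTest(log2(fpkmA), log2(fpkmZ), alternative = "two_sided")$p_value
  data.frame(
    label = label,
    mean_A = mean(fpkmA), mean_Z = mean(fpkmZ),
    mean_za = mean(fpkmZ) / mean(fpkmA),
    median_A = stats::median(fpkmA), median_Z = stats::median(fpkmZ),
    median_za = stats::median(fpkmZ) / stats::median(fpkmA),
    n_A = length(fpkmA), n_Z = length(fpkmZ),
    p_A_vs_Z = p,
    stringsAsFactors = FALSE
  )
}

#' Per-gene male:female expression ratios
#'
#' @param male,female positive FPKM vectors aligned by gene (genes already
#'   filtered to expression in both sexes).
#' @return list with \code{ratio} (M/F per gene) and \code{log2_ratio};
#'   names are taken from \code{male}.
#' @export
mfRatios <- function(male, female) {
  if (length(male) != length(female))
    stop("male and female vectors differ in length (",
         length(male), " vs ", length(female), ")")
  if (!length(male)) stop("empty input")
  if (any(male <= 0) || any(female <= 0))
    stop("mfRatios expects strictly positive FPKM in both sexes")
  r <- male / female
  list(ratio = r, log2_ratio = log2(r))
}

#' Class-level summary of male:female ratio distributions for one stage
#'
#' Summarises sex-biased expression per gene class: the medians of the
#' per-gene M:F ratios for Z-linked and autosomal genes and their quotient
#' (the "Z:A ratio of medians" — about 1 when the Z chromosome is no more
#' sex-biased than autosomes), plus three two-sided rank-sum tests: male vs
#' female log2 expression within each class (when the per-sex expression
#' vectors are supplied) and the Z vs A comparison of the log2-ratio
#' distributions.
#'
#' @param ratiosZ,ratiosA per-gene M/F ratio vectors for Z-linked and
#'   autosomal genes (see \code{\link{mfRatios}}).
#' @param stage stage label carried into the output row.
#' @param log2FpkmZ,log2FpkmA optional lists with elements \code{male} and
#'   \code{female}: the classes' log2 FPKM vectors used for the
#'   within-class male-vs-female tests. When omitted those p-values are NA
#'   (they are not derivable from the ratios alone).
#' @return one-row data.frame: \code{stage}, \code{n_Z}, \code{n_A},
#'   \code{median_mf_Z}, \code{median_mf_A}, \code{za_ratio_of_medians},
#'   \code{p_Z_MvsF}, \code{p_A_MvsF}, \code{p_AvsZ_dist}.
#' @export
mfSummary <- function(ratiosZ, ratiosA, stage = "",
                      log2FpkmZ = NULL, log2FpkmA = NULL) {
  if (!length(ratiosZ) || !length(ratiosA))
    stop("mfSummary needs non-empty Z and A ratio vectors")
  medZ <- stats::median(ratiosZ)
  medA <- stats::median(ratiosA)
  sexP <- function(l) {
    if (is.null(l)) return(NA_real_)
    mwuTest(l$male, l$female, alternative = "two_sided")$p_value
  }
  data.frame(
    stage = stage,
    n_Z = length(ratiosZ), n_A = length(ratiosA),
    median_mf_Z = medZ, median_mf_A = medA,
    za_ratio_of_medians = medZ / medA,
    p_Z_MvsF = sexP(log2FpkmZ),
    p_A_MvsF = sexP(log2FpkmA),
    p_AvsZ_dist = mwuTest(log2(ratiosZ), log2(ratiosA),
                          alternative = "two_sided")$p_value,
    stringsAsFactors = FALSE
  )
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' U counts the pairs with \eqn{x_i > y_j}, ties counting one half. The
#' p-value is exact when \code{min(|x|, |y|) <= 8} — from the exact
#' Wilcoxon distribution when the pooled values are tie-free, and by full
#' enumeration of the \eqn{\binom{n_1+n_2}{n_1}} group assignments over the
#' observed midranks when ties are present — and otherwise uses the normal
#' approximation with tie and continuity corrections. Two-sided exact
#' p-values double the smaller tail, capped at 1.
#'
#' @param x,y numeric vectors (non-empty).
#' @param alternative \code{"two_sided"}, \code{"less"} or
#'   \code{"greater"} (of x relative to y).
#' @return list of class \code{"mwu_test"}: \code{U}, \code{p_value},
#'   \code{method} (\code{"exact"} or \code{"normal_approx"}),
#'   \code{alternative}.
#' @examples
#' mwuTest(c(1, 2), c(3, 4))$p_value        # 1/3
#' mwuTest(c(1, 3, 5), c(2, 4, 6))$p_value  # 0.7
#' @export
mwuTest <- function(x, y, alternative = c("two_sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("mwuTest needs non-empty inputs")
  if (anyNA(x) || anyNA(y)) stop("mwuTest inputs must not contain NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (min(n1, n2) <= 8L) {
    if (!ties) {
      pLess <- stats::pwilcox(U, n1, n2)
      pGreater <- 1 - stats::pwilcox(U - 1, n1, n2)
    } else {
      tails <- .enumTails(r, n1, U)
      pLess <- tails[1L]; pGreater <- tails[2L]
    }
    p <- switch(alternative,
                two_sided = min(1, 2 * min(pLess, pGreater)),
                less = pLess,
                greater = pGreater)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    Ntot <- n1 + n2
    tieTab <- table(pooled)
    sigma2 <- n1 * n2 / 12 *
      ((Ntot + 1) - sum(tieTab^3 - tieTab) / (Ntot * (Ntot - 1)))
    sigma <- sqrt(sigma2)
    cc <- 0.5  # continuity correction toward the null
    z <- U - mu
    p <- switch(alternative,
      two_sided = {
        zc <- (z - sign(z) * min(cc, abs(z))) / sigma
        min(1, 2 * stats::pnorm(-abs(zc)))
      },
      less = stats::pnorm((z + cc) / sigma),
      greater = stats::pnorm(-(z - cc) / sigma))
    method <- "normal_approx"
  }
  structure(list(U = U, p_value = max(p, .Machine$double.xmin),
                 method = method, alternative = alternative),
            class = "mwu_test")
}

# Exact conditional tails under ties: enumerate every assignment of n1 of
# the pooled midranks to group x. Only reached for min(n) <= 8, where
# choose(n1+n2, n1) stays small for the sizes this package meets.
.enumTails <- function(r, n1, U) {
  n <- length(r)
  offset <- n1 * (n1 + 1) / 2
  idx <- utils::combn(n, n1)
  Uall <- colSums(matrix(r[idx], nrow = n1)) - offset
  eps <- 1e-9
  c(mean(Uall <= U + eps), mean(Uall >= U - eps))
}

#' @export
print.mwu_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.6g (%s, %s)\n",
              x$U, x$p_value, x$method, x$alternative))
  invisible(x)
}

#' qRT-PCR delta-Ct fold change (male relative to female)
#'
#' Relative quantification against an endogenous reference gene with the
#' female sample as calibrator (female fold change is 1 by construction):
#' \eqn{\Delta Ct_m = Ct^{target}_m - Ct^{ref}_m},
#' \eqn{\Delta Ct_f = Ct^{target}_f - Ct^{ref}_f},
#' fold \eqn{= 2^{-(\Delta Ct_m - \Delta Ct_f)}}.
#'
#' @param ctTargetM,ctRefM,ctTargetF,ctRefF cycle-threshold values for the
#'   target and reference gene in the male and female sample.
#' @return fold change of the male sample relative to the female sample.
#' @examples
#' deltaCtFold(20, 18, 21, 18)  # 2
#' @export
deltaCtFold <- function(ctTargetM, ctRefM, ctTargetF, ctRefF) {
  stopifnot(is.finite(ctTargetM), is.finite(ctRefM),
            is.finite(ctTargetF), is.finite(ctRefF))
  dM <- ctTargetM - ctRefM
  dF <- ctTargetF - ctRefF
  2^(-(dM - dF))
}
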