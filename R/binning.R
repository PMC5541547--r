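#' Split expression values into quartile bins (independent binning)
#'
#' Sorts the values in descending order (stable; ties broken by gene id,
#' ascending) and splits them into four contiguous bins as equal in size as
#' possible, the higher-expression bins taking any remainder first. The
#' first (highest-expression) bin is Q4 and the last Q1, so Q4 = high,
#' Q3 = medium, Q2 = low, Q1 = very low expression.
#'
#' @param values named numeric vector (names are gene ids); length >= 4.
#' @return named list \code{Q4}, \code{Q3}, \code{Q2}, \code{Q1} of named
#'   numeric vectors partitioning the input.
#' @examples
#' independentQuartiles(setNames(1:8, paste0("g", 1:8)))
#' @export
independentQuartiles <- function(values) {
  n <- length(values)
  if (n < 4L) stop("need at least 4 values to form quartiles, got ", n)
  if (is.null(names(values)) || any(names(values) == ""))
    stop("values must be named by gene id")
  ord <- order(-values, names(values))
  sizes <- .quartileSizes(n)
  bins <- split(values[ord], rep(c("Q4", "Q3", "Q2", "Q1"), sizes))
  bins[c("Q4", "Q3", "Q2", "Q1")]
}

# near-equal contiguous sizes, remainder to the higher-expression bins
.quartileSizes <- function(n) {
  base <- n %/% 4L
  rem <- n %% 4L
  base + as.integer(seq_len(4L) <= rem)
}

#' Split per-gene (male, female) pairs into quartiles by max of the pair
#'
#' Gene-wise paired variant: pairs are ranked by \code{max(male, female)}
#' descending (ties broken by gene id) and split exactly as
#' \code{\link{independentQuartiles}}; each gene's male and female values
#' stay together in one bin.
#'
#' @param pairs data.frame with columns \code{gene_id}, \code{male},
#'   \code{female}; at least 4 rows.
#' @return named list \code{Q4}..\code{Q1} of row-subset data.frames.
#' @export
pairedMaxQuartiles <- function(pairs) {
  pairs <- as.data.frame(pairs)
  need <- c("gene_id", "male", "female")
  miss <- setdiff(need, colnames(pairs))
  if (length(miss))
    stop("pairs lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(pairs)
  if (n < 4L) stop("need at least 4 pairs to form quartiles, got ", n)
  key <- pmax(pairs$male, pairs$female)
  ord <- order(-key, pairs$gene_id)
  sizes <- .quartileSizes(n)
  lab <- rep(c("Q4", "Q3", "Q2", "Q1"), sizes)
  out <- lapply(c("Q4", "Q3", "Q2", "Q1"), function(q) {
    df <- pairs[ord[lab == q], , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- c("Q4", "Q3", "Q2", "Q1")
  out
}

#' Per-quartile male vs female rank-sum comparison
#'
#' For each quartile, compares the male and female log2 expression values
#' by a two-sided Mann-Whitney test and reports the per-sex medians.
#' Accepts either two independently binned value sets (male and female
#' bins from \code{\link{independentQuartiles}}) or one set of paired bins
#' from \code{\link{pairedMaxQuartiles}}.
#'
#' @param binsMale for mode \code{"independent"}, the male quartile bins;
#'   for mode \code{"paired_max"}, the paired bins (and \code{binsFemale}
#'   is omitted).
#' @param binsFemale the female quartile bins (independent mode only).
#' @param mode \code{"independent"} or \code{"paired_max"}.
#' @param label optional label (e.g. the stage) carried into the output.
#' @return data.frame with one row per quartile (Q4 first): \code{label},
#'   \code{quartile}, \code{binning_mode}, \code{n_male}, \code{n_female},
#'   \code{median_male}, \code{median_female}, \code{p_value}.
#' @export
quartileCompare <- function(binsMale, binsFemale = NULL,
                            mode = c("independent", "paired_max"),
                            label = "") {
  mode <- match.arg(mode)
  qs <- c("Q4", "Q3", "Q2", "Q1")
  rows <- lapply(qs, function(q) {
    if (mode == "independent") {
      if (is.null(binsFemale))
        stop("independent mode needs both male and female bins")
      m <- unname(binsMale[[q]]); f <- unname(binsFemale[[q]])
    } else {
      m <- binsMale[[q]]$male; f <- binsMale[[q]]$female
    }
    data.frame(label = label, quartile = q, binning_mode = mode,
               n_male = length(m), n_female = length(f),
               median_male = stats::median(m),
               median_female = stats::median(f),
               p_value = mwuTest(m, f, "two_sided")$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
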