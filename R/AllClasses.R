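#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assays colData rowData rowData<-
#' @importFrom S4Vectors DataFrame metadata
NULL

.EXPR_UNITS <- c("raw_counts", "fpkm", "log2_fpkm")

#' DosageExperiment: a gene x sample expression matrix with dosage metadata
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one
#' expression assay together with the metadata the dosage-compensation
#' statistics need: a unit tag (\code{raw_counts}, \code{fpkm} or
#' \code{log2_fpkm}), per-sample sex/stage/replicate annotation in
#' \code{colData}, and optional per-gene lengths (bp) and chromosome
#' assignments in \code{rowData}.
#'
#' Validity rules: gene ids (rownames) are unique and non-empty; values are
#' finite and non-negative for \code{raw_counts} and \code{fpkm}; raw counts
#' are whole numbers; \code{colData} carries \code{sex} (one of
#' \code{"male"}, \code{"female"}, \code{"none"}), \code{stage} and a
#' positive integer \code{replicate}; gene lengths, when present, are
#' strictly positive.
#'
#' @slot unit single character string, one of \code{"raw_counts"},
#'   \code{"fpkm"}, \code{"log2_fpkm"}.
#'
#' @seealso \code{\link{readExpressionTable}}, \code{\link{computeFpkm}},
#'   \code{\link{assignLinkage}}
#' @export
setClass("DosageExperiment",
  contains = "SummarizedExperiment",
  slots = c(unit = "character")
)

setValidity("DosageExperiment", function(object) {
  msg <- character()
  if (length(object@unit) != 1L || !object@unit %in% .EXPR_UNITS)
    msg <- c(msg, sprintf("unit must be one of: %s",
                          paste(.EXPR_UNITS, collapse = ", ")))
  gid <- rownames(object)
  if (is.null(gid) || anyNA(gid) || any(gid == ""))
    msg <- c(msg, "gene ids (rownames) must be present and non-empty")
  else if (anyDuplicated(gid))
    msg <- c(msg, sprintf("duplicate gene id: '%s'",
                          gid[anyDuplicated(gid)]))
  if (length(SummarizedExperiment::assays(object)) >= 1L) {
    x <- assay(object, 1L)
    if (any(!is.finite(x)))
      msg <- c(msg, "expression values must be finite")
    else if (length(object@unit) == 1L && object@unit %in% c("raw_counts", "fpkm")) {
      if (any(x < 0))
        msg <- c(msg, "expression values must be non-negative")
      if (object@unit == "raw_counts" && any(abs(x - round(x)) > 1e-8)) {
        bad <- which(abs(x - round(x)) > 1e-8, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf(
          "non-integer count %g at gene '%s', sample '%s'",
          x[bad[1L], bad[2L]], rownames(x)[bad[1L]], colnames(x)[bad[2L]]))
      }
    }
  }
  cd <- colData(object)
  for (f in c("sex", "stage", "replicate"))
    if (!f %in% colnames(cd))
      msg <- c(msg, sprintf("colData must contain '%s'", f))
  if ("sex" %in% colnames(cd) &&
      !all(cd$sex %in% c("male", "female", "none")))
    msg <- c(msg, "sex must be one of 'male', 'female', 'none'")
  if ("replicate" %in% colnames(cd)) {
    r <- cd$replicate
    if (anyNA(r) || any(r < 1) || any(r != round(r)))
      msg <- c(msg, "replicate must be a positive integer")
  }
  if ("gene_length" %in% colnames(rowData(object))) {
    len <- rowData(object)$gene_length
    if (anyNA(len) || any(len <= 0))
      msg <- c(msg, "gene lengths must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DosageExperiment
#'
#' @param values numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids).
#' @param unit one of \code{"raw_counts"}, \code{"fpkm"}, \code{"log2_fpkm"}.
#' @param sampleData data.frame (or DataFrame) with one row per sample and
#'   columns \code{sample_id}, \code{sex}, \code{stage}, \code{replicate}.
#'   Rows are matched to matrix columns by \code{sample_id}.
#' @param geneLengths optional named numeric vector of per-gene lengths in bp
#'   (names matched against gene ids) or unnamed vector in row order.
#' @param chromosome optional per-gene chromosome labels (same matching).
#'
#' @return a validated \linkS4class{DosageExperiment}.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), sex = c("male", "female"),
#'                  stage = "78h", replicate = 1L)
#' DosageExperiment(m, "fpkm", md)
#' @export
DosageExperiment <- function(values, unit, sampleData, geneLengths = NULL,
                             chromosome = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("'values' must have gene ids as rownames")
  if (is.null(colnames(values)))
    stop("'values' must have sample ids as colnames")
  sampleData <- as.data.frame(sampleData)
  if (!"sample_id" %in% colnames(sampleData))
    stop("sampleData must contain a 'sample_id' column")
  missing <- setdiff(colnames(values), sampleData$sample_id)
  if (length(missing))
    stop("sample column without metadata: ",
         paste(sQuote(missing), collapse = ", "))
  sampleData <- sampleData[match(colnames(values), sampleData$sample_id), ,
                           drop = FALSE]
  cd <- DataFrame(sampleData, row.names = colnames(values))
  rd <- DataFrame(row.names = rownames(values))
  if (!is.null(geneLengths))
    rd$gene_length <- .matchGeneVector(geneLengths, rownames(values),
                                       "geneLengths")
  if (!is.null(chromosome))
    rd$chromosome <- .matchGeneVector(chromosome, rownames(values),
                                      "chromosome")
  se <- SummarizedExperiment(assays = list(exprs = values),
                             colData = cd, rowData = rd)
  new("DosageExperiment", se, unit = unit)
}

.matchGeneVector <- function(v, ids, what) {
  if (!is.null(names(v))) {
    miss <- setdiff(ids, names(v))
    if (length(miss))
      stop(what, " missing for gene ", sQuote(miss[1L]))
    v <- v[ids]
  } else if (length(v) != length(ids)) {
    stop(what, " must be named or match the number of genes")
  }
  unname(v)
}

#' @describeIn DosageExperiment the unit tag of the expression values.
#' @param x a DosageExperiment.
#' @export
exprUnit <- function(x) {
  stopifnot(is(x, "DosageExperiment"))
  x@unit
}

#' @describeIn DosageExperiment per-gene lengths (bp), or NULL when absent.
#' @export
geneLengths <- function(x) {
  stopifnot(is(x, "DosageExperiment"))
  rd <- rowData(x)
  if ("gene_length" %in% colnames(rd)) {
    len <- rd$gene_length
    names(len) <- rownames(x)
    len
  } else NULL
}

#' @describeIn DosageExperiment per-sample sex labels, named by sample id.
#' @export
sampleSex <- function(x) stats::setNames(colData(x)$sex, colnames(x))

#' @describeIn DosageExperiment per-sample stage labels, named by sample id.
#' @export
sampleStage <- function(x) stats::setNames(colData(x)$stage, colnames(x))

setMethod("show", "DosageExperiment", function(object) {
  cat(sprintf("DosageExperiment [%s]: %d genes x %d samples\n",
              object@unit, nrow(object), ncol(object)))
  cd <- colData(object)
  if (nrow(cd)) {
    grp <- paste(cd$sex, cd$stage, sep = " ")
    cat("samples:", paste(sprintf("%s (%s, rep %d)", rownames(cd), grp,
                                  cd$replicate), collapse = "; "), "\n")
  }
  rd <- rowData(object)
  extras <- intersect(c("gene_length", "chromosome"), colnames(rd))
  if (length(extras))
    cat("rowData:", paste(extras, collapse = ", "), "\n")
})
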