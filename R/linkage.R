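#' Split genes into autosomal and Z-linked sets
#'
#' Partitions the genes of a \linkS4class{DosageExperiment} by chromosome:
#' genes on the configured Z chromosome form the Z set, genes on any other
#' numbered chromosome the autosomal (A) set, and genes labelled
#' \code{"unplaced"} or absent from the map are dropped — unmapped genes are
#' excluded from all downstream dosage statistics. The annotation carries no
#' W chromosome; any non-numeric label other than the Z chromosome ends up
#' in the dropped set.
#'
#' @param x a \linkS4class{DosageExperiment}.
#' @param map named character vector gene_id -> chromosome label, as
#'   returned by \code{\link{readGeneChromosomeMap}}.
#' @param zChromosome integer chromosome number that is the Z chromosome
#'   (1 in \emph{Bombyx mori}).
#'
#' @return list with elements \code{A} and \code{Z} (row-subset
#'   \code{DosageExperiment}s, original gene order preserved, with a
#'   \code{chromosome} column in rowData) and \code{dropped} (character
#'   vector of excluded gene ids).
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("g1","g2","g3"), c("s1","s2")))
#' md <- data.frame(sample_id = c("s1","s2"), sex = c("male","female"),
#'                  stage = "78h", replicate = 1L)
#' de <- DosageExperiment(m, "raw_counts", md)
#' assignLinkage(de, c(g1 = "1", g2 = "5", g3 = "unplaced"), 1)
#' @export
assignLinkage <- function(x, map, zChromosome = 1L) {
  stopifnot(is(x, "DosageExperiment"))
  gid <- rownames(x)
  chrom <- unname(map[gid])
  chrom[is.na(chrom)] <- "unplaced"
  chromNum <- suppressWarnings(as.numeric(chrom))
  isZ <- !is.na(chromNum) & chromNum == zChromosome
  isA <- !is.na(chromNum) & chromNum != zChromosome
  if (!any(isZ) && !any(isA))
    stop("no genes assigned to either A or Z: ",
         "expression matrix and chromosome map do not overlap")
  subsetWithChrom <- function(keep) {
    out <- x[keep, ]
    rowData(out)$chromosome <- chrom[keep]
    out
  }
  list(A = subsetWithChrom(isA),
       Z = subsetWithChrom(isZ),
       dropped = gid[!isZ & !isA])
}
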