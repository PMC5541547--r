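#' Read a gene x sample expression table
#'
#' Reads a TSV with a \code{gene_id} column followed by one numeric column
#' per sample, and attaches per-sample metadata (sex, stage, replicate).
#' Parsing is locale-independent (decimal point). An optional
#' \code{gene_length} column (bp) is picked up when present; a length table
#' can also be supplied separately.
#'
#' @param path path to the expression TSV (header:
#'   \code{gene_id<TAB>sample1<TAB>...}; an optional \code{gene_length}
#'   column is recognised by name).
#' @param unit unit of the values: \code{"raw_counts"}, \code{"fpkm"} or
#'   \code{"log2_fpkm"}.
#' @param metadata path to a sample-metadata TSV with columns
#'   \code{sample_id}, \code{sex}, \code{stage}, \code{replicate}, or a
#'   data.frame of the same shape. Every sample column must be covered.
#'
#' @return a \linkS4class{DosageExperiment}; row order follows the file.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"), tsv)
#' md <- data.frame(sample_id = c("s1", "s2"), sex = c("male", "female"),
#'                  stage = "78h", replicate = 1L)
#' readExpressionTable(tsv, "fpkm", md)
#' @export
readExpressionTable <- function(path, unit, metadata) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (!"gene_id" %in% colnames(tab))
    stop("expression table must have a 'gene_id' column: ", path)
  gid <- as.character(tab$gene_id)
  dup <- gid[duplicated(gid)]
  if (length(dup))
    stop("duplicate gene id: '", dup[1L], "'")
  lengths <- NULL
  if ("gene_length" %in% colnames(tab)) {
    lengths <- stats::setNames(as.numeric(tab$gene_length), gid)
    tab$gene_length <- NULL
  }
  sampleCols <- setdiff(colnames(tab), "gene_id")
  if (!length(sampleCols)) stop("no sample columns in ", path)
  vals <- as.matrix(tab[, sampleCols, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric value at row %d, column '%s'",
                   bad[1L, 1L], sampleCols[bad[1L, 2L]]))
    vals <- matrix(as.numeric(vals), nrow(vals),
                   dimnames = dimnames(vals))
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("missing value at row %d, column '%s'",
                 bad[1L, 1L], sampleCols[bad[1L, 2L]]))
  }
  if (unit %in% c("raw_counts", "fpkm") && any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)
    stop(sprintf("negative value at row %d, column '%s'",
                 bad[1L, 1L], sampleCols[bad[1L, 2L]]))
  }
  if (unit == "raw_counts" && any(abs(vals - round(vals)) > 1e-8)) {
    bad <- which(abs(vals - round(vals)) > 1e-8, arr.ind = TRUE)
    stop(sprintf("non-integer count %g at row %d, column '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 sampleCols[bad[1L, 2L]]))
  }
  rownames(vals) <- gid
  md <- if (is.character(metadata)) readSampleMetadata(metadata) else metadata
  DosageExperiment(vals, unit = unit, sampleData = md,
                   geneLengths = lengths)
}

#' Read a sample-metadata TSV
#'
#' @param path TSV with columns \code{sample_id}, \code{sex}, \code{stage},
#'   \code{replicate}.
#' @return a data.frame.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("sample metadata not found: ", path)
  md <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "stage", "replicate")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: '",
         md$sample_id[duplicated(md$sample_id)][1L], "'")
  md$replicate <- as.integer(md$replicate)
  md
}

#' Read a scaffold-to-chromosome mapping table
#'
#' Two-column TSV (\code{scaffold_id}, \code{chromosome}); chromosome is an
#' integer 1-28 or the literal \code{"unplaced"}. Lines may be in any order;
#' a header row is optional (detected by the literal column names).
#'
#' @param path path to the TSV.
#' @return named character vector scaffold -> chromosome label.
#' @export
readScaffoldMap <- function(path) {
  if (!file.exists(path)) stop("scaffold map not found: ", path)
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("^scaffold_id\t", first)
  tab <- utils::read.delim(path, header = hasHeader, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("scaffold_id", "chromosome"))
  if (!nrow(tab)) stop("empty scaffold map: ", path)
  if (anyDuplicated(tab$scaffold_id))
    stop("scaffold mapped twice: '",
         tab$scaffold_id[duplicated(tab$scaffold_id)][1L], "'")
  stats::setNames(as.character(tab$chromosome), tab$scaffold_id)
}

#' Assign each annotated gene to a chromosome via its scaffold
#'
#' Reads gene features from a GFF3 file and a scaffold-to-chromosome table,
#' and labels every gene with the chromosome of the scaffold it resides on.
#' Genes on scaffolds absent from the map are labelled \code{"unplaced"}
#' (they are dropped later by \code{\link{assignLinkage}}, mirroring the
#' exclusion of unmapped genes from the analysis). Coordinates are 1-based
#' inclusive per the GFF3 standard but are not otherwise used.
#'
#' @param gffPath GFF3 file; features with type \code{gene} are keyed on
#'   their \code{ID} attribute. (Loci whose isoforms were merged upstream
#'   are expected to appear as single gene features.)
#' @param scaffoldMapPath two-column scaffold map TSV
#'   (see \code{\link{readScaffoldMap}}).
#' @return named character vector gene_id -> chromosome label, one entry per
#'   gene feature in the GFF.
#' @export
readGeneChromosomeMap <- function(gffPath, scaffoldMapPath) {
  if (!file.exists(gffPath)) stop("GFF file not found: ", gffPath)
  .validateGffLines(gffPath)
  smap <- readScaffoldMap(scaffoldMapPath)
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  if (!length(gr)) stop("no gene features in GFF: ", gffPath)
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids))
    stop("gene feature without an ID attribute in ", gffPath)
  scaf <- as.character(GenomicRanges::seqnames(gr))
  chrom <- unname(smap[scaf])
  chrom[is.na(chrom)] <- "unplaced"
  stats::setNames(chrom, as.character(ids))
}

# Cheap structural check so malformed lines are reported with a line number
# before rtracklayer parses the file.
.validateGffLines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    nf <- length(strsplit(ln, "\t", fixed = TRUE)[[1L]])
    if (nf != 9L)
      stop(sprintf("malformed GFF line %d (%d fields, expected 9) in %s",
                   i, nf, path))
  }
  invisible(TRUE)
}

#' Write result tables and a run manifest
#'
#' Writes one TSV per summary type with a fixed, documented column order
#' (mirroring the per-sample Z:A table, the bootstrap table and the
#' per-stage M:F table), plus a JSON sidecar recording the run
#' configuration and seed.
#'
#' @param results named list; recognised elements are \code{dosage}
#'   (data.frame of \code{\link{zaSummary}} rows), \code{bootstrap}
#'   (data.frame of \code{\link{bootstrapZaMedian}} rows), \code{mf}
#'   (data.frame of \code{\link{mfSummary}} rows), \code{quartile}
#'   (data.frame of \code{\link{quartileCompare}} rows) and
#'   \code{profile} (numeric matrix from \code{\link{zProfileMatrix}}).
#' @param outDir output directory (created if needed).
#' @param config optional list serialised into \code{manifest.json}.
#' @return invisibly, the paths written.
#' @export
writeResultTables <- function(results, outDir, config = list()) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("output directory is not writable: ", outDir)
  columns <- list(
    dosage = c("label", "mean_A", "mean_Z", "mean_za", "median_A",
               "median_Z", "median_za", "n_A", "n_Z", "p_A_vs_Z"),
    bootstrap = c("label", "point", "ci_low", "ci_high", "n_boot",
                  "ci_level", "seed"),
    mf = c("stage", "n_Z", "n_A", "median_mf_Z", "median_mf_A",
           "za_ratio_of_medians", "p_Z_MvsF", "p_A_MvsF", "p_AvsZ_dist"),
    quartile = c("label", "quartile", "binning_mode", "n_male", "n_female",
                 "median_male", "median_female", "p_value")
  )
  paths <- character()
  for (nm in names(columns)) {
    f <- file.path(outDir, paste0(nm, ".tsv"))
    df <- results[[nm]]
    if (is.null(df)) df <- data.frame()
    df <- as.data.frame(df)
    for (col in setdiff(columns[[nm]], colnames(df)))
      df[[col]] <- if (nrow(df)) NA else logical(0)
    df <- df[, columns[[nm]], drop = FALSE]
    utils::write.table(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, f)
  }
  if (!is.null(results$profile)) {
    f <- file.path(outDir, "z_profile.tsv")
    prof <- as.data.frame(results$profile)
    prof <- cbind(gene_id = rownames(results$profile), prof)
    utils::write.table(prof, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
  }
  mf <- file.path(outDir, "manifest.json")
  manifest <- list(
    package = "zdosage",
    version = as.character(utils::packageVersion("zdosage")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config
  )
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(c(paths, mf))
}

#' Write a DosageExperiment back to TSV
#'
#' Round-trip companion of \code{\link{readExpressionTable}}: writes the
#' expression matrix (with a \code{gene_length} column when lengths are
#' attached) and, optionally, the sample metadata.
#'
#' @param x a \linkS4class{DosageExperiment}.
#' @param path output TSV path.
#' @param metadataPath optional path for the sample-metadata TSV.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTable <- function(x, path, metadataPath = NULL) {
  stopifnot(is(x, "DosageExperiment"))
  df <- data.frame(gene_id = rownames(x), check.names = FALSE)
  len <- geneLengths(x)
  if (!is.null(len)) df$gene_length <- unname(len)
  vals <- assay(x, 1L)
  for (s in colnames(vals)) df[[s]] <- vals[, s]
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(metadataPath))
    utils::write.table(as.data.frame(colData(x)), metadataPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
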