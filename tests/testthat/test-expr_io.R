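test_that("expression tables round-trip through TSV", {
  f <- writeTsv(c("gene_id\ts1\ts2", "g1\t1\t2", "g2\t3\t4"))
  de <- readExpressionTable(f, "fpkm", toyMeta(c("s1", "s2")))
  expect_s4_class(de, "DosageExperiment")
  expect_identical(dim(de), c(2L, 2L))
  expect_identical(exprUnit(de), "fpkm")
  expect_equal(assay(de)["g1", "s2"], 2)
  expect_identical(rownames(de), c("g1", "g2"))

  # exact round-trip for counts, near-exact for fpkm
  cnt <- toyExperiment(matrix(c(5L, 0L, 12L, 7L), 2, 2,
                              dimnames = list(c("ga", "gb"),
                                              c("s1", "s2"))),
                       unit = "raw_counts")
  out <- tempfile(fileext = ".tsv")
  writeExpressionTable(cnt, out)
  back <- readExpressionTable(out, "raw_counts", toyMeta(c("s1", "s2")))
  expect_identical(assay(back), assay(cnt))

  fp <- toyExperiment(matrix(c(pi, exp(1), 1 / 3, 1e-7), 2, 2,
                             dimnames = list(c("ga", "gb"),
                                             c("s1", "s2"))))
  writeExpressionTable(fp, out)
  back <- readExpressionTable(out, "fpkm", toyMeta(c("s1", "s2")))
  expect_equal(assay(back), assay(fp), tolerance = 1e-9)
})

test_that("malformed expression input is rejected with a useful message", {
  dup <- writeTsv(c("gene_id\ts1", "g1\t1", "g1\t2"))
  expect_error(readExpressionTable(dup, "fpkm", toyMeta("s1")), "g1")

  frac <- writeTsv(c("gene_id\ts1\ts2", "g1\t2.5\t1"))
  expect_error(readExpressionTable(frac, "raw_counts",
                                   toyMeta(c("s1", "s2"))),
               "non-integer count 2.5")
  # the same file is fine as fpkm
  expect_s4_class(readExpressionTable(frac, "fpkm",
                                      toyMeta(c("s1", "s2"))),
                  "DosageExperiment")

  neg <- writeTsv(c("gene_id\ts1", "g1\t-3"))
  expect_error(readExpressionTable(neg, "fpkm", toyMeta("s1")),
               "negative value")

  ok <- writeTsv(c("gene_id\ts1\ts2", "g1\t1\t2"))
  expect_error(readExpressionTable(ok, "fpkm", toyMeta("s1")),
               "s2")
})

test_that("gene lengths travel with the table when present", {
  f <- writeTsv(c("gene_id\tgene_length\ts1", "g1\t1000\t5",
                  "g2\t250\t0"))
  de <- readExpressionTable(f, "raw_counts", toyMeta("s1"))
  expect_equal(geneLengths(de), c(g1 = 1000, g2 = 250))
})

test_that("genes are assigned chromosomes via their scaffold", {
  gff <- writeTsv(c(
    "##gff-version 3",
    "nscaf2828\tsrc\tgene\t100\t2100\t.\t+\t.\tID=BGIBMGA000001",
    "nscaf0002\tsrc\tgene\t1\t900\t.\t-\t.\tID=BGIBMGA000002",
    "nscaf9999\tsrc\tgene\t5\t505\t.\t+\t.\tID=BGIBMGA000003"))
  smap <- writeTsv(c("scaffold_id\tchromosome", "nscaf2828\t1",
                     "nscaf0002\t7"))
  map <- readGeneChromosomeMap(gff, smap)
  # total: one entry per gene feature
  expect_length(map, 3L)
  expect_identical(map[["BGIBMGA000001"]], "1")
  expect_identical(map[["BGIBMGA000002"]], "7")
  expect_identical(map[["BGIBMGA000003"]], "unplaced")
})

test_that("malformed GFF and empty scaffold maps are hard errors", {
  bad <- writeTsv(c("##gff-version 3",
                    "nscaf1\tsrc\tgene\t1\t10\t.\t+",
                    "nscaf1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1"))
  smap <- writeTsv(c("scaffold_id\tchromosome", "nscaf1\t2"))
  expect_error(readGeneChromosomeMap(bad, smap), "line 2")

  gff <- writeTsv(c("##gff-version 3",
                    "nscaf1\tsrc\tgene\t1\t10\t.\t+\t.\tID=g1"))
  empty <- writeTsv("scaffold_id\tchromosome")
  expect_error(readGeneChromosomeMap(gff, empty), "empty scaffold map")
})

test_that("result tables are written with fixed headers and survive a round trip", {
  outDir <- file.path(tempfile(), "results")
  dosage <- zaSummary(c(1, 2, 4), c(1, 2), "toy")
  paths <- writeResultTables(list(dosage = dosage), outDir,
                             config = list(seed = 7))
  tab <- read.delim(file.path(outDir, "dosage.tsv"))
  expect_identical(colnames(tab),
                   c("label", "mean_A", "mean_Z", "mean_za", "median_A",
                     "median_Z", "median_za", "n_A", "n_Z", "p_A_vs_Z"))
  expect_equal(tab$median_za, 0.75, tolerance = 1e-6)
  # empty summaries give header-only files, no error
  mf <- read.delim(file.path(outDir, "mf.tsv"))
  expect_identical(nrow(mf), 0L)
  manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"))
  expect_equal(manifest$config$seed, 7)
})
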