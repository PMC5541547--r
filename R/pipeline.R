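#' Run the full dosage-compensation analysis
#'
#' Orchestrates the whole pipeline: read inputs, assign chromosome linkage,
#' derive FPKM from counts, average technical replicates, apply the
#' true-expression filters (per sample for Z:A, both sexes for M:F),
#' compute Z:A summaries with bootstrap confidence intervals, M:F
#' summaries under both FPKM and TMM normalization (the TMM path applies
#' the four-sample low-count filter first), quartile-stratified
#' comparisons (independent binning for the Z:A universe, max-of-pair for
#' the M:F universe), and the Z-linked profile matrix. Optionally writes
#' all result tables plus a JSON manifest.
#'
#' @param config a list. Input either as paths —
#'   \code{expression_path}, \code{metadata_path}, \code{unit}
#'   (\code{"raw_counts"} or \code{"fpkm"}), \code{gff_path},
#'   \code{scaffold_map_path} — or in-memory as \code{experiment}
#'   (a \linkS4class{DosageExperiment}) and \code{linkage_map} (named
#'   gene -> chromosome vector). Optional keys (defaults in parentheses):
#'   \code{z_chromosome} (1), \code{min_count} (4), \code{logratio_trim}
#'   (0.30), \code{intensity_trim} (0.05), \code{tmm_reference}
#'   ("auto"), \code{n_boot} (10000), \code{ci_level} (0.95),
#'   \code{seed} (1), \code{floor} (2^-10), \code{out_dir} (NULL),
#'   \code{cluster_k} (NULL: no clustering).
#' @return list: \code{dosage} (data.frame, one \code{\link{zaSummary}}
#'   row per sample), \code{bootstrap} (data.frame, one row per sample),
#'   \code{mf} (data.frame, one \code{\link{mfSummary}} row per stage,
#'   FPKM-normalized), \code{mf_tmm} (same under TMM, stages with a full
#'   2x2 replicate design only), \code{quartile} (data.frame of
#'   \code{\link{quartileCompare}} rows, both binning modes),
#'   \code{profile} (Z-linked log2 matrix), \code{clusters} (when
#'   \code{cluster_k} given), \code{dropped} (unmapped gene ids),
#'   \code{config} (the config as applied).
#' @export
runDosageAnalysis <- function(config) {
  cfg <- .applyConfigDefaults(config)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  de <- stage("read", {
    if (!is.null(cfg$experiment)) cfg$experiment
    else readExpressionTable(cfg$expression_path, cfg$unit,
                             cfg$metadata_path)
  })
  map <- stage("read", {
    if (!is.null(cfg$linkage_map)) cfg$linkage_map
    else readGeneChromosomeMap(cfg$gff_path, cfg$scaffold_map_path)
  })

  rawCounts <- if (exprUnit(de) == "raw_counts") de else NULL
  fpkm <- stage("fpkm", {
    if (exprUnit(de) == "raw_counts") computeFpkm(de) else de
  })
  avg <- stage("average_replicates", averageReplicates(fpkm))
  message(sprintf("INFO %d genes x %d samples after replicate averaging",
                  nrow(avg), ncol(avg)))

  link <- stage("linkage", assignLinkage(avg, map, cfg$z_chromosome))
  message(sprintf("INFO linkage: %d A-linked, %d Z-linked, %d dropped",
                  nrow(link$A), nrow(link$Z), length(link$dropped)))

  # --- Z:A universe: per-sample true expression ------------------------
  exprA <- stage("true_expression", filterTrueExpression(link$A,
                                                         "per_sample"))
  exprZ <- stage("true_expression", filterTrueExpression(link$Z,
                                                         "per_sample"))
  dosage <- NULL; boots <- NULL
  quartiles <- list()
  for (i in seq_along(exprA)) {
    s <- names(exprA)[i]
    a <- exprA[[s]]; z <- exprZ[[s]]
    message(sprintf("INFO sample %s: %d A + %d Z expressed genes",
                    s, length(a), length(z)))
    dosage <- rbind(dosage, stage("za_summary", zaSummary(a, z, s)))
    b <- stage("bootstrap",
               bootstrapZaMedian(a, z, nBoot = cfg$n_boot,
                                 ciLevel = cfg$ci_level,
                                 seed = cfg$seed + i))
    boots <- rbind(boots, data.frame(label = s, point = b$point,
                                     ci_low = b$ci_low,
                                     ci_high = b$ci_high,
                                     n_boot = b$n_boot,
                                     ci_level = b$ci_level,
                                     seed = b$seed))
  }

  # independent-binning quartiles of the Z-linked Z:A universe, per stage
  cd <- colData(avg)
  stages <- unique(as.character(cd$stage[cd$sex %in% c("male", "female")]))
  for (st in stages) {
    ms <- rownames(cd)[cd$stage == st & cd$sex == "male"]
    fs <- rownames(cd)[cd$stage == st & cd$sex == "female"]
    if (length(ms) != 1L || length(fs) != 1L) next
    zm <- log2(exprZ[[ms]]); zf <- log2(exprZ[[fs]])
    if (length(zm) < 4L || length(zf) < 4L) next
    quartiles[[paste0(st, "_independent")]] <- stage("quartiles",
      quartileCompare(independentQuartiles(zm), independentQuartiles(zf),
                      mode = "independent", label = st))
  }

  # --- M:F universe: genes expressed in both sexes ---------------------
  mf <- NULL; mfTmm <- NULL
  bothA <- stage("true_expression", filterTrueExpression(link$A,
                                                         "both_sexes"))
  bothZ <- stage("true_expression", filterTrueExpression(link$Z,
                                                         "both_sexes"))
  for (st in intersect(names(bothA), names(bothZ))) {
    ratios <- lapply(list(Z = bothZ[[st]], A = bothA[[st]]), function(sub) {
      sx <- sampleSex(sub)
      m <- assay(sub, 1L)[, names(sx)[sx == "male"]]
      f <- assay(sub, 1L)[, names(sx)[sx == "female"]]
      list(mf = mfRatios(m, f), male = m, female = f)
    })
    message(sprintf("INFO stage %s: %d Z + %d A genes expressed in both sexes",
                    st, length(ratios$Z$mf$ratio), length(ratios$A$mf$ratio)))
    mf <- rbind(mf, stage("mf_summary", mfSummary(
      ratios$Z$mf$ratio, ratios$A$mf$ratio, stage = st,
      log2FpkmZ = list(male = log2(ratios$Z$male),
                       female = log2(ratios$Z$female)),
      log2FpkmA = list(male = log2(ratios$A$male),
                       female = log2(ratios$A$female)))))
    zdf <- data.frame(gene_id = rownames(bothZ[[st]]),
                      male = log2(ratios$Z$male),
                      female = log2(ratios$Z$female))
    if (nrow(zdf) >= 4L)
      quartiles[[paste0(st, "_paired_max")]] <- stage("quartiles",
        quartileCompare(pairedMaxQuartiles(zdf), mode = "paired_max",
                        label = st))
    if (!is.null(rawCounts))
      mfTmm <- rbind(mfTmm, stage("mf_tmm",
        .mfUnderTmm(rawCounts, map, st, cfg,
                    universe = c(rownames(bothZ[[st]]),
                                 rownames(bothA[[st]])))))
  }

  profile <- stage("profile", zProfileMatrix(avg, map, cfg$z_chromosome,
                                             floor = cfg$floor))
  clusters <- NULL
  if (!is.null(cfg$cluster_k))
    clusters <- stage("cluster", clusterGenes(profile, cfg$cluster_k))

  results <- list(dosage = dosage, bootstrap = boots, mf = mf,
                  mf_tmm = mfTmm,
                  quartile = do.call(rbind, unname(quartiles)),
                  profile = profile, clusters = clusters,
                  dropped = link$dropped, config = cfg)
  if (!is.null(cfg$out_dir))
    stage("write", writeResultTables(results, cfg$out_dir,
                                     config = .serializableConfig(cfg)))
  results
}

# M:F medians and tests for one stage under TMM normalization: subset the
# raw counts to the stage's 2x2 replicate design, drop genes below the
# count threshold in any of the four libraries, scale by TMM factors and
# effective library sizes, average replicates per sex.
.mfUnderTmm <- function(rawCounts, map, st, cfg, universe) {
  cd <- colData(rawCounts)
  ms <- rownames(cd)[cd$stage == st & cd$sex == "male"]
  fs <- rownames(cd)[cd$stage == st & cd$sex == "female"]
  if (length(ms) != 2L || length(fs) != 2L) {
    message("INFO stage ", st, ": no 2x2 replicate design, ",
            "skipping the TMM M:F path")
    return(NULL)
  }
  four <- c(ms, fs)
  sub <- rawCounts[rownames(rawCounts) %in% universe, four]
  kept <- filterLowCounts(sub, comparisonSamples = four,
                          minCount = cfg$min_count)
  message(sprintf("INFO stage %s: %d of %d genes pass the %d-count filter",
                  st, nrow(kept), nrow(sub), cfg$min_count))
  tmm <- tmmFactors(kept, reference = cfg$tmm_reference,
                    logratioTrim = cfg$logratio_trim,
                    intensityTrim = cfg$intensity_trim)
  counts <- assay(kept, 1L)
  eff <- colSums(counts) * tmm$factors[colnames(counts)]
  norm <- sweep(counts, 2L, eff, "/") * 1e6
  m <- rowMeans(norm[, ms, drop = FALSE])
  f <- rowMeans(norm[, fs, drop = FALSE])
  ok <- m > 0 & f > 0
  chrom <- suppressWarnings(as.numeric(map[rownames(counts)]))
  isZ <- ok & !is.na(chrom) & chrom == cfg$z_chromosome
  isA <- ok & !is.na(chrom) & chrom != cfg$z_chromosome
  mfSummary(m[isZ] / f[isZ], m[isA] / f[isA], stage = st,
            log2FpkmZ = list(male = log2(m[isZ]), female = log2(f[isZ])),
            log2FpkmA = list(male = log2(m[isA]), female = log2(f[isA])))
}

.applyConfigDefaults <- function(config) {
  defaults <- list(z_chromosome = 1L, min_count = 4L,
                   logratio_trim = 0.30, intensity_trim = 0.05,
                   tmm_reference = "auto", n_boot = 10000L,
                   ci_level = 0.95, seed = 1L, floor = 2^-10,
                   out_dir = NULL, cluster_k = NULL)
  cfg <- utils::modifyList(defaults, config)
  hasPaths <- !is.null(cfg$expression_path)
  if (is.null(cfg$experiment) && !hasPaths)
    stop("config needs either 'experiment' or 'expression_path'")
  if (hasPaths) {
    for (p in c("expression_path", "metadata_path"))
      if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]]))
        stop("missing input file (", p, "): ", cfg[[p]])
    if (is.null(cfg$unit))
      stop("config key 'unit' is required with expression_path")
  }
  if (is.null(cfg$linkage_map)) {
    for (p in c("gff_path", "scaffold_map_path")) {
      if (is.null(cfg[[p]]))
        stop("config needs either 'linkage_map' or '", p, "'")
      if (!file.exists(cfg[[p]]))
        stop("missing input file (", p, "): ", cfg[[p]])
    }
  }
  cfg
}

.serializableConfig <- function(cfg) {
  cfg$experiment <- NULL
  if (!is.null(cfg$linkage_map))
    cfg$linkage_map <- sprintf("<in-memory map of %d genes>",
                               length(cfg$linkage_map))
  cfg
}
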