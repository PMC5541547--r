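#' Simulation parameters for a synthetic dosage dataset
#'
#' Describes a negative-binomial RNA-seq count simulation with known
#' dosage truth, shaped like a silkworm embryonic time course: ~450
#' Z-linked genes on chromosome 1 and ~9600 autosomal genes on
#' chromosomes 2-28, gene-wise lognormal baseline expression, overdispersed
#' counts, technical duplicates, and a fraction of silent genes per sex.
#'
#' Per stage s, autosomal genes have mean factor 1 and Z-linked genes the
#' dose factor d_sex,s (Z:A < 1 is a reduced Z dose in both sexes); male
#' samples are additionally scaled by the global male bias b_s. The
#' implied truths are: autosomal M:F = b_s, Z-linked M:F = d_male,s * b_s /
#' d_female,s, and per-sex Z:A factors d_male,s and d_female,s.
#'
#' @param nGenesZ number of Z-linked (chromosome 1) genes (default 450).
#' @param nGenesA number of autosomal genes spread over chromosomes 2-28
#'   (default 9600).
#' @param stages list of per-stage parameter lists, each with \code{name},
#'   \code{male_bias} (b_s), \code{z_dose_male} and \code{z_dose_female};
#'   the default is a single unbiased, fully compensated "null" stage
#'   (b = 1, d = 1).
#' @param baselineMeanLog2,baselineSdLog2 gene baseline log2-mean
#'   expression ~ Normal(3, 2).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param librarySize expected reads per sample (default 1e7).
#' @param silentFraction probability a gene is off in a given sex
#'   (default 0.05).
#' @param biasedFraction fraction of genes (by number; the lowest-expressed
#'   ones) that carry the male bias b_s (default 0.8). A bias applied to
#'   every gene would cancel exactly under library-size normalization
#'   (FPKM), so the generator biases the many low/moderately expressed
#'   genes and leaves the few top-expressed genes as the unbiased
#'   read-mass reservoir; the applied factor is solved so the expected
#'   observed M:F of a biased gene is exactly b_s after normalization.
#' @param nTechReps technical replicates per (sex, stage) (default 2).
#' @param geneLengthMeanLog,geneLengthSdLog gene length ~ LogNormal
#'   (default median 1500 bp, sdlog 0.5).
#' @param seed integer seed.
#' @return list of class \code{"SimParams"}.
#' @seealso \code{\link{scenarioPresets}}, \code{\link{generateDataset}}
#' @export
simParams <- function(nGenesZ = 450L, nGenesA = 9600L,
                      stages = list(list(name = "null", male_bias = 1,
                                         z_dose_male = 1,
                                         z_dose_female = 1)),
                      baselineMeanLog2 = 3, baselineSdLog2 = 2,
                      dispersion = 10, librarySize = 1e7,
                      silentFraction = 0.05, biasedFraction = 0.8,
                      nTechReps = 2L,
                      geneLengthMeanLog = log(1500),
                      geneLengthSdLog = 0.5, seed = 1L) {
  stopifnot(nGenesZ >= 1L, nGenesA >= 1L, length(stages) >= 1L,
            baselineSdLog2 > 0, dispersion > 0, librarySize > 0,
            silentFraction >= 0, silentFraction < 1,
            biasedFraction > 0, biasedFraction <= 1, nTechReps >= 1L,
            geneLengthSdLog > 0)
  for (st in stages)
    stopifnot(!is.null(st$name), st$male_bias > 0, st$z_dose_male > 0,
              st$z_dose_female > 0)
  structure(list(
    n_genes_z = as.integer(nGenesZ), n_genes_a = as.integer(nGenesA),
    stages = stages,
    baseline_mean_log2 = baselineMeanLog2,
    baseline_sd_log2 = baselineSdLog2,
    dispersion = dispersion, library_size = librarySize,
    silent_fraction = silentFraction,
    biased_fraction = biasedFraction,
    n_tech_reps = as.integer(nTechReps),
    gene_length_meanlog = geneLengthMeanLog,
    gene_length_sdlog = geneLengthSdLog,
    seed = as.integer(seed)
  ), class = "SimParams")
}

#' Named simulation scenarios
#'
#' Canned parameter sets tracing the biology the analysis is built for:
#' \describe{
#'   \item{uncompensated_early}{one early embryonic stage with a global
#'     male bias (autosomal M:F truth 1.35) and a stronger male Z dose
#'     (Z-linked M:F truth 1.5) — the uncompensated state.}
#'   \item{compensated_head}{one head-like stage with no sex bias (both
#'     M:F truths 1.0) and a reduced Z dose in both sexes (Z:A factor
#'     0.6) — complete but unconventional compensation.}
#'   \item{bombyx_like_timecourse}{four stages with monotone decreasing
#'     Z-linked M:F truth (1.5, 1.4, 1.1, 1.0): male-biased early stages
#'     relaxing into the compensated state.}
#' }
#'
#' @param name one of \code{"uncompensated_early"},
#'   \code{"compensated_head"}, \code{"bombyx_like_timecourse"}.
#' @param ... overrides passed on to \code{\link{simParams}} (e.g.
#'   \code{nGenesA}, \code{seed}).
#' @return a \code{SimParams} object.
#' @export
scenarioPresets <- function(name = c("uncompensated_early",
                                     "compensated_head",
                                     "bombyx_like_timecourse"), ...) {
  name <- match.arg(name)
  stages <- switch(name,
    uncompensated_early = list(
      list(name = "78h", male_bias = 1.35,
           z_dose_male = 0.5, z_dose_female = 0.45)),
    compensated_head = list(
      list(name = "head", male_bias = 1,
           z_dose_male = 0.6, z_dose_female = 0.6)),
    bombyx_like_timecourse = list(
      list(name = "78h", male_bias = 1.35,
           z_dose_male = 0.5, z_dose_female = 0.45),
      list(name = "96h", male_bias = 1.2,
           z_dose_male = 0.525, z_dose_female = 0.45),
      list(name = "120h", male_bias = 1,
           z_dose_male = 0.55, z_dose_female = 0.5),
      list(name = "head", male_bias = 1,
           z_dose_male = 0.6, z_dose_female = 0.6))
  )
  simParams(stages = stages, ...)
}

#' Ground truth implied by simulation parameters
#'
#' @param params a \code{SimParams} object.
#' @return data.frame with one row per stage: \code{stage},
#'   \code{expected_mf_Z} (= d_m * b / d_f), \code{expected_mf_A} (= b),
#'   \code{za_factor_male}, \code{za_factor_female}.
#' @export
simTruth <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  do.call(rbind, lapply(params$stages, function(st) data.frame(
    stage = st$name,
    expected_mf_Z = st$z_dose_male * st$male_bias / st$z_dose_female,
    expected_mf_A = st$male_bias,
    za_factor_male = st$z_dose_male,
    za_factor_female = st$z_dose_female,
    stringsAsFactors = FALSE
  )))
}

#' Generate a synthetic count dataset with known dosage truth
#'
#' Draws counts(g, s) ~ NegBin(mean, size = dispersion) with mean equal to
#' the library-size-scaled gene baseline times the class/sex/stage factors
#' of \code{\link{simParams}}; technical replicates are independent draws.
#' Genes silenced in a sex (probability \code{silent_fraction}, fixed per
#' gene and sex across stages and replicates) get mean 0. Fully
#' reproducible from the seed.
#'
#' @param params a \code{SimParams} object.
#' @param dir optional directory: when given, the expression TSV
#'   (\code{expression.tsv}, with a \code{gene_length} column), sample
#'   metadata (\code{samples.tsv}), gene annotation (\code{genes.gff3})
#'   and scaffold map (\code{scaffold_map.tsv}) are written there in the
#'   formats \code{\link{readExpressionTable}} and
#'   \code{\link{readGeneChromosomeMap}} read.
#' @return list: \code{counts} (\linkS4class{DosageExperiment},
#'   \code{raw_counts}, with gene lengths and chromosomes), \code{linkage}
#'   (data.frame \code{gene_id}, \code{chromosome}, \code{scaffold_id}),
#'   \code{truth} (see \code{\link{simTruth}}), \code{params}, and
#'   \code{files} (named paths when \code{dir} was given).
#' @examples
#' d <- generateDataset(simParams(nGenesZ = 40, nGenesA = 200, seed = 7))
#' d$counts
#' @export
generateDataset <- function(params, dir = NULL) {
  stopifnot(inherits(params, "SimParams"))
  nZ <- params$n_genes_z; nA <- params$n_genes_a
  n <- nZ + nA
  withSeed(params$seed, {
    geneIds <- sprintf("BMSYN%06d", seq_len(n))
    chrom <- c(rep(1L, nZ),
               sort(rep_len(2:28, nA)))
    # ~50 genes per scaffold, scaffolds nested within chromosomes
    scafIdx <- integer(n)
    off <- 0L
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      scafIdx[i] <- off + (seq_along(i) - 1L) %/% 50L + 1L
      off <- max(scafIdx[i])
    }
    scaffold <- sprintf("nscaf%04d", scafIdx)
    lengths <- pmax(200, round(stats::rlnorm(n, params$gene_length_meanlog,
                                             params$gene_length_sdlog)))
    baseline <- 2^stats::rnorm(n, params$baseline_mean_log2,
                               params$baseline_sd_log2)
    silent <- matrix(stats::runif(2L * n) < params$silent_fraction,
                     nrow = n, dimnames = list(NULL, c("male", "female")))
    wBase <- baseline * lengths
    biased <- wBase < stats::quantile(wBase, params$biased_fraction)
    cols <- list(); meta <- list()
    for (st in params$stages) {
      classW <- function(sex) {
        dose <- if (sex == "male") st$z_dose_male else st$z_dose_female
        w <- wBase * ifelse(chrom == 1L, dose, 1)
        w[silent[, sex]] <- 0
        w
      }
      wf <- classW("female")
      wm <- classW("male")
      # male bias applied to the biased gene set with the factor solved so
      # that the expected observed (library-normalized) M:F of a biased
      # gene is exactly b: beta * sum(wf) / T_m = b with
      # T_m = beta * S_biased + S_unbiased
      b <- st$male_bias
      if (abs(b - 1) > 1e-12) {
        Sb <- sum(wm[biased]); Su <- sum(wm[!biased])
        beta <- b * Su / (sum(wf) - b * Sb)
        if (!is.finite(beta) || beta <= 0)
          stop("male_bias ", b, " is not attainable: the biased gene set ",
               "holds too large a share of the library ",
               "(lower biasedFraction)")
        wm[biased] <- wm[biased] * beta
      }
      for (sex in c("male", "female")) {
        w <- if (sex == "male") wm else wf
        mu <- params$library_size * w / sum(w)
        for (rep in seq_len(params$n_tech_reps)) {
          sid <- sprintf("%s_%s_r%d", sex, st$name, rep)
          cols[[sid]] <- as.integer(stats::rnbinom(n, mu = mu,
                                                   size = params$dispersion))
          meta[[sid]] <- data.frame(sample_id = sid, sex = sex,
                                    stage = st$name, replicate = rep,
                                    stringsAsFactors = FALSE)
        }
      }
    }
    counts <- do.call(cbind, cols)
    rownames(counts) <- geneIds
    md <- do.call(rbind, meta)
    de <- DosageExperiment(counts, unit = "raw_counts", sampleData = md,
                           geneLengths = stats::setNames(lengths, geneIds),
                           chromosome = as.character(chrom))
    linkTab <- data.frame(gene_id = geneIds,
                          chromosome = as.character(chrom),
                          scaffold_id = scaffold,
                          stringsAsFactors = FALSE)
    files <- NULL
    if (!is.null(dir)) files <- .writeSimFixtures(de, linkTab, lengths, dir)
    list(counts = de, linkage = linkTab, truth = simTruth(params),
         params = params, files = files)
  })
}

.writeSimFixtures <- function(de, linkTab, lengths, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  exprPath <- file.path(dir, "expression.tsv")
  metaPath <- file.path(dir, "samples.tsv")
  writeExpressionTable(de, exprPath, metadataPath = metaPath)
  # one gene feature per gene; consecutive genes tile their scaffold
  starts <- stats::ave(seq_len(nrow(linkTab)), linkTab$scaffold_id,
                       FUN = seq_along)
  start <- (starts - 1L) * 5000L + 1L
  gffPath <- file.path(dir, "genes.gff3")
  writeLines(c("##gff-version 3",
               sprintf("%s\tzdosage_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       linkTab$scaffold_id, start,
                       start + as.integer(lengths) - 1L,
                       linkTab$gene_id)),
             gffPath)
  mapPath <- file.path(dir, "scaffold_map.tsv")
  scafMap <- unique(linkTab[, c("scaffold_id", "chromosome")])
  utils::write.table(scafMap, mapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("scaffold_id",
                                                      "chromosome"))
  c(expression = exprPath, metadata = metaPath, gff = gffPath,
    scaffold_map = mapPath)
}
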