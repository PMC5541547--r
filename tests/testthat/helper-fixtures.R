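# Shared fixtures and independent oracles for the test suite.

suppressPackageStartupMessages(library(SummarizedExperiment))

toyMeta <- function(ids, sex = rep(c("male", "female"), length.out =
                                     length(ids)),
                    stage = "78h", replicate = 1L) {
  data.frame(sample_id = ids, sex = sex, stage = stage,
             replicate = replicate, stringsAsFactors = FALSE)
}

toyExperiment <- function(values, unit = "fpkm", ...) {
  DosageExperiment(values, unit = unit,
                   sampleData = toyMeta(colnames(values), ...))
}

writeTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# --- Mann-Whitney oracle: full enumeration of group assignments ---------
# Independent of the implementation's stats::pwilcox path: builds the exact
# conditional U distribution by listing every choice of which pooled values
# belong to x, computing U by direct pair counting.
mwuOracle <- function(x, y, alternative = "two_sided") {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  countU <- function(xs, ys)
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  Uobs <- countU(x, y)
  sets <- utils::combn(n1 + n2, n1)
  Uall <- apply(sets, 2L, function(i) countU(pooled[i], pooled[-i]))
  eps <- 1e-9
  pl <- mean(Uall <= Uobs + eps)
  pg <- mean(Uall >= Uobs - eps)
  switch(alternative,
         two_sided = min(1, 2 * min(pl, pg)),
         less = pl,
         greater = pg)
}

# --- TMM oracle: sort-based survivor selection, direct weighted mean ----
# Recomputes one pairwise TMM factor from scratch. Survivors are picked by
# explicit positions in the sorted order (valid for tie-free M and A, as in
# the continuous simulations used in tests), not by rank().
tmmOracle <- function(obs, ref, Nk, Nr, logratioTrim = 0.30,
                      intensityTrim = 0.05) {
  use <- obs > 0 & ref > 0
  o <- obs[use]; r <- ref[use]
  M <- log2((o / Nk) / (r / Nr))
  A <- 0.5 * log2((o / Nk) * (r / Nr))
  w <- 1 / ((Nk - o) / (Nk * o) + (Nr - r) / (Nr * r))
  n <- length(M)
  lo <- function(trim) floor(n * trim) + 1
  survM <- order(M)[seq(lo(logratioTrim), n + 1 - lo(logratioTrim))]
  survA <- order(A)[seq(lo(intensityTrim), n + 1 - lo(intensityTrim))]
  keep <- intersect(survM, survA)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

# Two-library count pair with a known fraction of genes upregulated in the
# second library; continuous-ish counts drawn once per seed.
simCountPair <- function(nGenes = 1000, deFraction = 0.05, fold = 4,
                         seed = 42) {
  set.seed(seed)
  base <- rpois(nGenes, lambda = exp(rnorm(nGenes, 5, 1))) + 1L
  up <- seq_len(round(nGenes * deFraction))
  lib2 <- base
  lib2[up] <- lib2[up] * fold
  m <- cbind(s1 = base, s2 = as.integer(lib2))
  rownames(m) <- sprintf("g%04d", seq_len(nGenes))
  m
}
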