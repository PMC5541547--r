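test_that("independent binning sorts descending into near-equal quartiles", {
  v <- setNames(1:8, paste0("g", 1:8))
  q <- independentQuartiles(v)
  expect_identical(names(q), c("Q4", "Q3", "Q2", "Q1"))
  expect_equal(unname(q$Q4), c(8, 7))
  expect_equal(unname(q$Q1), c(2, 1))

  # remainder goes to the higher-expression bins first
  q10 <- independentQuartiles(setNames(1:10, sprintf("g%02d", 1:10)))
  expect_identical(unname(lengths(q10)), c(3L, 3L, 2L, 2L))

  # boundary: 4 values give 4 singleton bins
  q4 <- independentQuartiles(setNames(4:1, paste0("g", 1:4)))
  expect_true(all(lengths(q4) == 1L))

  expect_error(independentQuartiles(setNames(1:3, paste0("g", 1:3))),
               "at least 4")
})

test_that("binning partitions the input and ignores monotone rescaling", {
  set.seed(4)
  for (i in 1:5) {
    n <- sample(5:40, 1)
    v <- setNames(rlnorm(n), sprintf("g%03d", 1:n))
    q <- independentQuartiles(v)
    expect_identical(sort(unlist(lapply(q, names), use.names = FALSE)),
                     sort(names(v)))
    expect_lte(diff(range(lengths(q))), 1L)
    # membership unchanged under any order-preserving transform
    qLog <- independentQuartiles(log2(v))
    expect_identical(lapply(q, names), lapply(qLog, names))
  }
})

test_that("paired-max binning keeps gene pairs intact", {
  pairs <- data.frame(gene_id = c("a", "b", "c", "d"),
                      male = c(10, 1, 5, 2), female = c(1, 9, 5, 2))
  q <- pairedMaxQuartiles(pairs)
  expect_identical(vapply(q, function(b) b$gene_id, character(1)),
                   c(Q4 = "a", Q3 = "b", Q2 = "c", Q1 = "d"))

  # all pairs equal: membership is decided by the gene-id tie-break alone
  tied <- data.frame(gene_id = c("d", "b", "a", "c"),
                     male = 2, female = 2)
  qt <- pairedMaxQuartiles(tied)
  expect_identical(vapply(qt, function(b) b$gene_id, character(1)),
                   c(Q4 = "a", Q3 = "b", Q2 = "c", Q1 = "d"))

  set.seed(6)
  big <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    male = rlnorm(100), female = rlnorm(100))
  qb <- pairedMaxQuartiles(big)
  genes <- unlist(lapply(qb, function(b) b$gene_id), use.names = FALSE)
  expect_identical(sort(genes), sort(big$gene_id))   # exactly one bin each
  for (b in qb) {                                     # pairs never separate
    m <- match(b$gene_id, big$gene_id)
    expect_equal(b$male, big$male[m])
    expect_equal(b$female, big$female[m])
  }
})

test_that("quartileCompare delegates to the rank-sum test per bin", {
  v <- setNames(rlnorm(20, 2, 1), sprintf("g%02d", 1:20))
  same <- quartileCompare(independentQuartiles(v),
                          independentQuartiles(v), mode = "independent")
  expect_equal(same$p_value, rep(1, 4))
  expect_identical(same$quartile, c("Q4", "Q3", "Q2", "Q1"))

  # p equals a direct mwuTest call on the same vectors
  m <- setNames(rlnorm(24, 1, 0.3), sprintf("g%02d", 1:24))
  f <- m / 2
  rep <- quartileCompare(independentQuartiles(m),
                         independentQuartiles(f), mode = "independent")
  qm <- independentQuartiles(m); qf <- independentQuartiles(f)
  for (i in 1:4)
    expect_equal(rep$p_value[i],
                 mwuTest(unname(qm[[rep$quartile[i]]]),
                         unname(qf[[rep$quartile[i]]]))$p_value)
  expect_true(all(rep$median_male > rep$median_female))
})
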