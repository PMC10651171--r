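test_that("signed-rank Z matches closed form and sign conventions", {
  r <- medianVsZeroTest(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$Z, 2.2014, tolerance = 1e-4)     # (21 - 10.5)/sqrt(22.75)
  expect_equal(r$Z, (21 - 10.5) / sqrt(6 * 7 * 13 / 24), tolerance = 1e-10)
  rn <- medianVsZeroTest(-c(1.5, 2.5, 3, 4, 5.5))
  expect_lt(rn$Z, 0)
  expect_error(medianVsZeroTest(rep(0, 6)), "zero")
  expect_error(medianVsZeroTest(c(1, 2, 3)), "at least 5")
  # sign-test mode reduces to a binomial test
  rs <- medianVsZeroTest(c(1, 2, 3, 4, 5, -1), mode = "sign")
  expect_equal(rs$p, min(1, 2 * pbinom(1, 6, 0.5)))
})

test_that("rank statistics agree with exhaustive-permutation exact nulls (n <= 8)", {
  # exact p from enumerating the package statistic over all partitions / sign
  # flips must equal the independent oracle's exact p exactly
  pkgExactRankSumP <- function(a, b) {
    pooled <- c(a, b)
    zObs <- abs(rankSumZ(a, b)$Z)
    sets <- combn(length(pooled), length(a))
    zs <- vapply(seq_len(ncol(sets)), function(k)
      abs(rankSumZ(pooled[sets[, k]], pooled[-sets[, k]])$Z), 0)
    mean(zs >= zObs - 1e-9)
  }
  pkgExactSignedRankP <- function(v) {
    zObs <- abs(signedRankZ(v)$Z)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(v))))
    zs <- vapply(seq_len(nrow(signs)), function(k)
      abs(signedRankZ(abs(v) * signs[k, ])$Z), 0)
    mean(zs >= zObs - 1e-9)
  }
  set.seed(14)
  for (i in 1:5) {
    a <- round(rnorm(4), 2); b <- round(rnorm(4, 1), 2)
    expect_equal(pkgExactRankSumP(a, b), oracleExactRankSumP(a, b))
    # normal approximation tracks the exact p loosely at these tiny n
    expect_lt(abs(rankSumZ(a, b)$p - oracleExactRankSumP(a, b)), 0.15)
    v <- round(rnorm(6, 0.8), 2); v <- v[v != 0]
    if (length(v) >= 5) {
      expect_equal(pkgExactSignedRankP(v), oracleExactSignedRankP(v))
      expect_lt(abs(signedRankZ(v)$p - oracleExactSignedRankP(v)), 0.15)
    }
  }
  # the statistic itself matches the oracle exactly
  expect_equal(rankSumZ(c(1, 2, 3), c(4, 5, 6))$Z, oracleRankSumZ(1:3, 4:6))
})

test_that("Spearman association handles monotone extremes and null calibration", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearmanAssoc(x, exp(x))$R, 1)
  expect_equal(spearmanAssoc(x, -x^3)$R, -1)
  expect_error(spearmanAssoc(x, rep(2, 6)), "constant")
  expect_error(spearmanAssoc(x, x[-1]), "unequal")
  # invariance under strictly monotone transforms
  set.seed(15)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearmanAssoc(a, b)$R, spearmanAssoc(exp(a), qnorm(pnorm(b)))$R)
  # null rejection rate at the n = 40 critical value ~ 5%
  hits <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    abs(spearmanAssoc(rnorm(40), rnorm(40))$R) > 0.312
  }, logical(1))
  expect_gte(mean(hits), 0.02)
  expect_lte(mean(hits), 0.10)
  # R agrees with stats::cor(method = "spearman")
  expect_equal(spearmanAssoc(a, b)$R, cor(a, b, method = "spearman"))
})

test_that("Bonferroni control flags the corrected family", {
  fam <- data.frame(p = c(0.005, 0.028, 0.0054, 0.0482))
  out <- bonferroniAdjust(fam, m = 8)
  expect_identical(out$significant, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$alpha_corrected[1], 0.00625)
  one <- bonferroniAdjust(data.frame(p = 0.04), m = 1)
  expect_true(one$significant)
  lst <- bonferroniAdjust(list(list(p = 0.001), list(p = 0.02)), m = 8)
  expect_true(lst[[1]]$significant && !lst[[2]]$significant)
})
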