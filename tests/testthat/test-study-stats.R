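test_that("replicate summaries follow the n = 5 convention", {
  s5 <- summarizeValues(c(1, 2, 3, 4, 100))
  expect_equal(s5$summaryType, "mean +/- SD")
  expect_equal(s5$center, 22)
  expect_equal(s5$spread, sqrt(7610 / 4), tolerance = 1e-12)
  s6 <- summarizeValues(1:6)
  expect_equal(s6$summaryType, "median (IQR)")
  expect_equal(s6$center, 3.5)
  expect_equal(c(s6$q25, s6$q75), c(2.25, 4.75))
  sc <- summarizeValues(rep(7, 8))
  expect_equal(sc$spread, 0)
  expect_error(summarizeValues(3), "at least 2")
})

test_that("identically distributed groups are not flagged", {
  x <- c(2.3, 4.1, 1.7, 3.3, 2.9, 3.8, 2.2, 3.1, 4.4)
  g <- rep(c("p1", "p2", "p3"), 3)
  rep_ <- compareGroups(x, g, metric = "null")
  expect_false(any(rep_@dunn$significant))
  expect_equal(unname(rep_@kruskalH),
               unname(stats::kruskal.test(x, factor(g))$statistic))
})

test_that("a 3-sigma shifted group is flagged against both others", {
  set.seed(4)
  x <- c(rnorm(10, 0, 1), rnorm(10, 0, 1), rnorm(10, 3, 1))
  g <- rep(c("a", "b", "shift"), each = 10)
  rep_ <- compareGroups(x, g, metric = "power")
  d <- rep_@dunn
  hit <- d$group1 == "shift" | d$group2 == "shift"
  expect_true(all(d$significant[hit]))
  expect_false(any(d$significant[!hit]))
  expect_lt(rep_@kruskalP, 0.05)
})

test_that("Kruskal-Wallis H matches the exhaustive-permutation oracle", {
  vals <- c(3.1, 4.2, 2.8, 3.9, 7.7, 8.1, 6.9, 4.5, 5.2, 4.8)
  g <- rep(c("a", "b", "c"), c(4, 3, 3))
  # independent oracle: H from first principles on ranks
  Hof <- function(gg) {
    r <- rank(vals); Nn <- length(vals)
    tie <- table(r)
    corr <- 1 - sum(tie^3 - tie) / (Nn^3 - Nn)
    Rj <- tapply(r, gg, sum); nj <- tapply(r, gg, length)
    (12 / (Nn * (Nn + 1)) * sum(Rj^2 / nj) - 3 * (Nn + 1)) / corr
  }
  rep_ <- compareGroups(vals, g, metric = "fixture")
  expect_equal(unname(rep_@kruskalH), Hof(g), tolerance = 1e-12)
  # exhaustive relabelling: all 10! / (4! 3! 3!) = 4200 assignments
  Hobs <- Hof(g)
  aIdx <- utils::combn(10, 4)
  tot <- 0L; ge <- 0L
  for (i in seq_len(ncol(aIdx))) {
    rest <- setdiff(1:10, aIdx[, i])
    bIdx <- utils::combn(rest, 3)
    for (j in seq_len(ncol(bIdx))) {
      gg <- character(10)
      gg[aIdx[, i]] <- "a"; gg[bIdx[, j]] <- "b"
      gg[setdiff(rest, bIdx[, j])] <- "c"
      tot <- tot + 1L
      if (Hof(gg) >= Hobs - 1e-12) ge <- ge + 1L
    }
  }
  expect_equal(tot, 4200L)
  pPerm <- ge / tot
  # both routes reject the null at alpha = 0.05 on this fixture
  expect_lt(pPerm, 0.05)
  expect_lt(rep_@kruskalP, 0.05)
})

test_that("Bonferroni correction dominates raw p and alpha is monotone", {
  set.seed(7)
  x <- c(rnorm(8), rnorm(8, 1), rnorm(8, 2), rnorm(8, 3))
  g <- rep(letters[1:4], each = 8)
  r5 <- compareGroups(x, g, alpha = 0.05)
  expect_true(all(r5@dunn$pBonferroni >= r5@dunn$pRaw - 1e-15))
  expect_true(all(r5@dunn$pBonferroni <= 1))
  r1 <- compareGroups(x, g, alpha = 0.01)
  r10 <- compareGroups(x, g, alpha = 0.10)
  expect_true(all(which(r1@dunn$significant) %in%
                    which(r5@dunn$significant)))
  expect_true(all(which(r5@dunn$significant) %in%
                    which(r10@dunn$significant)))
})

test_that("undersized groups are dropped with a warning", {
  x <- c(rnorm(5), rnorm(5, 1), rnorm(2))
  g <- rep(c("a", "b", "tiny"), c(5, 5, 2))
  expect_warning(r <- compareGroups(x, g), "tiny")
  expect_equal(sort(unique(r@groupSummary$group)), c("a", "b"))
  expect_error(suppressWarnings(
    compareGroups(rnorm(4), rep(c("a", "b"), each = 2))), "at least 2")
})

test_that("normality and variance screens are reported but do not gate", {
  set.seed(2)
  x <- c(rexp(10), rexp(10, 0.2))
  g <- rep(c("a", "b"), each = 10)
  r <- compareGroups(x, g)
  expect_length(r@shapiroP, 2)
  expect_true(is.finite(r@leveneP))
  expect_true(is.finite(r@kruskalP))  # omnibus ran regardless of screens
})
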