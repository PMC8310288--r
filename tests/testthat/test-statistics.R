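test_that("Friedman statistic follows its closed forms", {
  expect_equal(friedman_test(matrix(5, 4, 3))$statistic, 0)   # constant table

  # perfect concordance, no ties: n(k-1)
  pc <- matrix(rep(1:3, each = 5), 5, 3)
  expect_equal(friedman_test(pc)$statistic, 10)
  expect_equal(friedman_test(rbind(c(1, 2), c(1, 2)))$statistic, 2)

  f <- friedman_test(pc)
  n <- 5; k <- 3
  expect_equal(sum(f$rank_sums), n * k * (k + 1) / 2)
  expect_equal(f$df, k - 1)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("Friedman is invariant to monotone transforms and matches stats::friedman.test", {
  withr::with_seed(501, y <- matrix(rnorm(28), 7, 4))
  a <- friedman_test(y)
  b <- friedman_test(exp(y))                    # strictly monotone transform
  expect_equal(a$statistic, b$statistic)

  ref <- stats::friedman.test(y)
  expect_equal(a$statistic, unname(ref$statistic))
  expect_equal(a$p_value, ref$p.value)

  # with ties
  withr::with_seed(503, yt <- matrix(sample(1:3, 24, TRUE), 6, 4))
  expect_equal(friedman_test(yt)$statistic,
               unname(stats::friedman.test(yt)$statistic))
})

test_that("Dunn post hoc standardizes rank-sum differences with Bonferroni control", {
  const <- dunn_posthoc(matrix(2, 5, 3))
  expect_true(all(const$p_adjusted == 1))
  expect_equal(nrow(const), 3)                  # k(k-1)/2 pairs

  pc <- matrix(rep(1:3, each = 5), 5, 3)
  d <- dunn_posthoc(pc)
  extreme <- d[d$treatment_1 == "1" & d$treatment_2 == "3" |
               d$treatment_1 == "3" & d$treatment_2 == "1", ]
  expect_equal(abs(extreme$rank_sum_diff), 10)  # n(k-1)

  withr::with_seed(505, y <- matrix(rnorm(40), 10, 4))
  dd <- dunn_posthoc(y)
  expect_true(all(dd$p_adjusted >= dd$p_raw - 1e-15))
  # z antisymmetry: swapping the pair order flips the sign
  dswap <- dunn_posthoc(y[, c(2, 1, 3, 4)])
  expect_equal(dd$z[1], -dswap$z[1])            # pair (col1, col2) both ways
})

test_that("Mantel r is a true matrix correlation with permutation significance", {
  withr::with_seed(507, x <- matrix(rnorm(30), 10))
  d1 <- as.matrix(dist(x)); dimnames(d1) <- list(paste0("p", 1:10), paste0("p", 1:10))
  self <- mantel_test(d1, d1, n_permutations = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_lte(self$p_value, 0.05)

  affine <- mantel_test(d1, 2.5 * d1, n_permutations = 99, seed = 1)
  expect_equal(affine$r, 1)

  # symmetric in arguments
  withr::with_seed(509, y <- matrix(rnorm(30), 10))
  d2 <- as.matrix(dist(y)); dimnames(d2) <- dimnames(d1)
  expect_equal(mantel_test(d1, d2, 99, 1)$r, mantel_test(d2, d1, 99, 1)$r)

  # reproducible given seed
  expect_identical(mantel_test(d1, d2, 199, 5), mantel_test(d1, d2, 199, 5))

  bad <- d2; rownames(bad)[1] <- "zz"
  expect_error(mantel_test(d1, bad, 9, 1), "label mismatch")
})

test_that("Mantel r agrees with the vegan reference and stays small under the null", {
  skip_if_not_installed("vegan")
  withr::with_seed(511, {
    d1 <- as.matrix(dist(matrix(rnorm(36), 12)))
    d2 <- as.matrix(dist(matrix(rnorm(36), 12)))
    dimnames(d1) <- dimnames(d2) <- list(paste0("p", 1:12), paste0("p", 1:12))
  })
  ours <- mantel_test(d1, d2, 99, 1)$r
  ref <- vegan::mantel(d1, d2, permutations = 19)$statistic
  expect_equal(ours, unname(ref))

  # independent random matrices: |r| rarely large
  withr::with_seed(513, {
    rs <- replicate(40, {
      a <- as.matrix(dist(matrix(rnorm(60), 20)))
      b <- as.matrix(dist(matrix(rnorm(60), 20)))
      dimnames(a) <- dimnames(b) <- list(paste0("p", 1:20), paste0("p", 1:20))
      mantel_test(a, b, n_permutations = 1, seed = 1)$r
    })
  })
  expect_gte(mean(abs(rs) < 0.3), 0.95)
})

test_that("Spearman rho and p match the reference implementation", {
  expect_equal(spearman_test(1:5, 1:5)$rho, 1)
  expect_equal(spearman_test(1:5, 5:1)$rho, -1)
  s <- spearman_test(1:4, c(2, 1, 4, 3))
  expect_equal(s$rho, 0.6)
  ref <- suppressWarnings(stats::cor.test(1:4, c(2, 1, 4, 3), method = "spearman"))
  expect_equal(s$p_value, ref$p.value)

  withr::with_seed(515, { x <- rnorm(20); y <- rnorm(20) })
  big <- spearman_test(x, y)
  expect_equal(big$rho, stats::cor(x, y, method = "spearman"))
  expect_equal(big$method, "normal approximation")
  expect_error(spearman_test(rep(1, 5), 1:5), "rho undefined")
})

test_that("results flatten into one tidy statistics table", {
  pc <- matrix(rep(1:3, each = 5), 5, 3)
  withr::with_seed(517, d1 <- as.matrix(dist(matrix(rnorm(15), 5))))
  dimnames(d1) <- list(paste0("p", 1:5), paste0("p", 1:5))
  tab <- statistics_table(friedman_test(pc), dunn_posthoc(pc),
                          mantel_test(d1, d1, 9, 1),
                          spearman_test(1:5, c(2, 1, 3, 5, 4)))
  expect_setequal(unique(tab$test), c("friedman", "dunn", "mantel", "spearman"))
  expect_equal(nrow(tab), 1 + 3 + 1 + 1)
})
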