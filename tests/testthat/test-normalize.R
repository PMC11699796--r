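test_that("median-of-ratios size factors match the hand-computed example", {
  s <- size_factors_median_ratios(toy_counts())
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("size factors are all one for identical columns and track column scaling", {
  set.seed(1)
  base <- matrix(rpois(60, 50) * 2L, 20, 3,   # even counts: scalable exactly
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  same <- base
  same[, 2] <- same[, 1]
  same[, 3] <- same[, 1]
  expect_equal(unname(size_factors_median_ratios(same)), rep(1, 3))

  # doubling one column doubles its factor and rescales the others by
  # 2^(-1/n) through the geometric means
  doubled <- same
  doubled[, 3] <- 2L * doubled[, 3]
  s <- size_factors_median_ratios(doubled)
  expect_equal(unname(s[1] / s[3]), 1 / 2 * 1, tolerance = 1e-10)
  expect_equal(unname(s[1]), 2^(-1 / 3), tolerance = 1e-10)
  expect_equal(unname(s[3]), 2 * 2^(-1 / 3), tolerance = 1e-10)

  # arbitrary column scaling is recovered up to one global constant
  scales <- c(0.5, 1, 2.5)
  scaled <- sweep(same, 2, scales, `*`)
  storage.mode(scaled) <- "integer"
  s2 <- size_factors_median_ratios(scaled)
  expect_equal(unname(s2 / s2[2]), scales / scales[2], tolerance = 1e-10)
})

test_that("size factors error when no gene is nonzero everywhere", {
  m <- matrix(c(0L, 5L, 7L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors_median_ratios(m), "library-size")
})

test_that("CPM and median-of-ratios log2 transforms follow their closed forms", {
  m <- matrix(c(1L, 999999L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  e <- normalize_counts(m, "cpm_log2")
  expect_equal(unname(e[, 1]), c(log2(2), log2(1e6)), tolerance = 1e-12)

  withzero <- matrix(c(0L, 0L, 5L, 7L), 2, 2, byrow = TRUE,
                     dimnames = list(c("z", "g"), c("s1", "s2")))
  expect_equal(unname(normalize_counts(withzero, "cpm_log2")["z", ]),
               c(0, 0))
  expect_equal(unname(normalize_counts(withzero, "mor_log2")["z", ]),
               c(0, 0))

  same <- matrix(rep(c(3L, 9L), 2), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(normalize_counts(same, "mor_log2")),
               matrix(log2(1 + c(3, 9)), 2, 2), ignore_attr = TRUE)

  zerolib <- matrix(c(0L, 0L, 1L, 2L), 2, 2,
                    dimnames = list(c("a", "b"), c("empty", "ok")))
  expect_error(normalize_counts(zerolib, "cpm_log2"), "empty")
})

test_that("PCA overview separates duplicated sample groups and matches the eigen oracle", {
  set.seed(7)
  profile_a <- rnorm(50, 5, 2)
  profile_b <- profile_a + c(rep(4, 10), rep(0, 40))
  expr <- cbind(a1 = profile_a, a2 = profile_a, b1 = profile_b,
                b2 = profile_b) + matrix(rnorm(200, 0, 1e-3), 50, 4)
  rownames(expr) <- paste0("g", 1:50)
  ov <- pca_overview(expr, 2)
  expect_gt(ov$explained_variance[1], 0.99)
  expect_gt(abs(mean(ov$scores[1:2, 1]) - mean(ov$scores[3:4, 1])), 1)

  # eigen-decomposition oracle on the small sample covariance matrix
  xc <- scale(t(expr), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)$values
  expect_equal(ov$explained_variance,
               (ev / sum(ev))[1:2], tolerance = 1e-8)

  # deterministic sign convention: repeated runs give identical scores
  expect_identical(ov$scores, pca_overview(expr, 2)$scores)
  expect_error(pca_overview(expr, 10), "exceeds")
})

test_that("orthogonal planted factors are recovered in variance order", {
  set.seed(8)
  n <- 12
  f1 <- rep(c(-1, 1), each = n / 2) * 3   # strong factor
  f2 <- rep(c(-1, 1), times = n / 2) * 1  # weak factor, orthogonal
  load1 <- rnorm(200); load2 <- rnorm(200)
  expr <- outer(load1, f1) + outer(load2, f2) +
    matrix(rnorm(200 * n, 0, 0.1), 200, n)
  dimnames(expr) <- list(paste0("g", 1:200), paste0("s", 1:n))
  ov <- pca_overview(expr, 2)
  expect_gt(abs(cor(ov$scores[, 1], f1)), 0.99)
  expect_gt(abs(cor(ov$scores[, 2], f2)), 0.99)
  expect_gt(ov$explained_variance[1], ov$explained_variance[2])
})

test_that("sample correlation matrix is symmetric with unit diagonal and handles rank reversal", {
  set.seed(9)
  a <- rnorm(30)
  expr <- cbind(s1 = a, s2 = a, s3 = -a + 100)
  rownames(expr) <- paste0("g", 1:30)
  r <- sample_correlation_matrix(expr, "spearman")
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r["s1", "s2"], 1)
  expect_equal(r["s1", "s3"], -1)

  # 3-sample toy against the direct formula
  expr2 <- cbind(s1 = c(1, 2, 4), s2 = c(2, 3, 9), s3 = c(5, 1, 2))
  rownames(expr2) <- paste0("g", 1:3)
  rp <- sample_correlation_matrix(expr2, "pearson")
  direct <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(rp["s1", "s2"], direct(expr2[, 1], expr2[, 2]),
               tolerance = 1e-12)
  expect_equal(rp["s2", "s3"], direct(expr2[, 2], expr2[, 3]),
               tolerance = 1e-12)

  # constant profile -> undefined off-diagonal, reported missing
  expr3 <- cbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3))
  rownames(expr3) <- paste0("g", 1:3)
  r3 <- sample_correlation_matrix(expr3, "pearson")
  expect_true(is.na(r3["s1", "s2"]))
})

test_that("size factors agree with the reference RNA-seq implementation", {
  suppressMessages(suppressWarnings(requireNamespace("DESeq2")))
  set.seed(10)
  m <- matrix(rnbinom(500 * 6, mu = 80, size = 10), 500, 6,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  m <- sweep(m, 2, c(1, 2, 1, 3, 1, 1), `*`)
  storage.mode(m) <- "integer"
  expect_equal(unname(size_factors_median_ratios(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})
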