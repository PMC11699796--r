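test_that("expression PCs recover a planted rank-one factor and are centered", {
  set.seed(30)
  n <- 23
  factor_scores <- rnorm(n)
  loadings <- rnorm(300)
  expr <- outer(loadings, factor_scores) +
    matrix(rnorm(300 * n, 0, 0.01), 300, n)
  dimnames(expr) <- list(paste0("g", 1:300), paste0("s", 1:n))
  pcs <- compute_pcs(expr, 2)
  expect_gt(abs(cor(pcs[, 1], factor_scores)), 0.999)
  expect_equal(unname(colMeans(pcs)), c(0, 0), tolerance = 1e-10)

  expect_equal(ncol(compute_pcs(expr, 0)), 0)
  expect_error(compute_pcs(expr, n), "exceeds")
})

test_that("metabolome PCs exclude the phenotype and require enough complete columns", {
  set.seed(31)
  sm <- data.frame(sample_id = paste0("s", 1:10),
                   lactic_acid_30h = rnorm(10, 4),
                   glycerol = rnorm(10, 6), ethanol = rnorm(10, 10),
                   pH = rnorm(10, 3.4), PAN = rnorm(10, 20))
  pcs <- metabolome_pcs(sm, K = 3)
  expect_equal(dim(pcs), c(10, 3))
  expect_error(metabolome_pcs(sm[, 1:3], K = 3), "fewer than K")
})

test_that("surrogate analysis recovers a planted orthogonal batch factor", {
  set.seed(32)
  n <- 20
  G <- 800
  la <- rnorm(n, 4, 2)
  batch <- rnorm(n)
  batch <- as.numeric(scale(qr.resid(qr(cbind(1, la)), batch)))
  affected <- sample(G, round(0.3 * G))
  expr <- matrix(rnorm(G * n, 0, 0.5), G, n)
  expr[affected, ] <- expr[affected, ] +
    outer(rnorm(length(affected), 0, 1.2), batch)
  dimnames(expr) <- list(paste0("g", 1:G), paste0("s", 1:n))
  hf <- estimate_hidden_factors(expr, cbind(1, la), B = 50, seed = 1)
  expect_gte(ncol(hf), 1)
  expect_gt(abs(cor(hf[, 1], batch)), 0.8)

  expect_error(estimate_hidden_factors(expr, cbind(1, la), B = 0),
               "positive number of permutations")
})

test_that("pure-noise expression yields no surrogate variables most of the time", {
  n0 <- 0
  runs <- 50
  for (s in seq_len(runs)) {
    set.seed(600 + s)
    expr <- matrix(rnorm(300 * 12), 300, 12,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:12)))
    hf <- estimate_hidden_factors(expr, cbind(1, rnorm(12)), B = 100,
                                  seed = 700 + s)
    n0 <- n0 + (ncol(hf) == 0)
  }
  expect_gte(n0 / runs, 0.9)
})

test_that("the per-gene model matches closed forms and the normal-equation oracle", {
  # noise-free gene: exact intercept and slope
  la <- c(1, 2, 3, 5, 7, 8)
  expr <- matrix(2 + 0.5 * la, 1, 6,
                 dimnames = list("gene", paste0("s", 1:6)))
  fit <- fit_qtt_model(expr, la)
  expect_equal(fit$table$alpha, 0.5, tolerance = 1e-12)
  expect_equal(fit$table$intercept, 2, tolerance = 1e-12)

  # random 6-sample fixtures against (X'X)^-1 X'y
  set.seed(33)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    la <- rnorm(n, 4, 2)
    pcs <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("PC1", "PC2")))
    expr <- matrix(rnorm(5 * n), 5, n,
                   dimnames = list(paste0("g", 1:5), paste0("s", 1:n)))
    fit <- fit_qtt_model(expr, la, pcs)
    X <- cbind(1, la, pcs)
    beta <- solve(t(X) %*% X, t(X) %*% t(expr))
    expect_equal(unname(fit$table$alpha), unname(beta[2, ]),
                 tolerance = 1e-8)
    res <- t(expr) - X %*% beta
    sigma2 <- colSums(res^2) / (n - 4)
    se <- sqrt(sigma2 * solve(t(X) %*% X)[2, 2])
    expect_equal(unname(fit$table$se), unname(se), tolerance = 1e-8)
  }

  # residuals sum to ~0 gene-wise (intercept included)
  expect_equal(max(abs(colSums(fit$residuals))), 0, tolerance = 1e-8)

  expect_error(fit_qtt_model(expr, rep(3, ncol(expr))), "collinear.*LA")
})

test_that("QTT classification is inclusive at the threshold and signed", {
  tab <- data.frame(gene_id = c("at", "above", "null"),
                    alpha = c(1.2, -0.8, 0.1), se = 1, stat = 1,
                    pvalue = c(0.001, 0.001 + 1e-6, 1))
  # single-gene BH leaves p unchanged; test each row alone
  at <- call_qtts(tab[1, ])
  expect_equal(at$qtt_class, "positive")
  above <- call_qtts(tab[2, ])
  expect_equal(above$qtt_class, "none")
  none <- call_qtts(tab[3, ])
  expect_equal(none$qtt_class, "none")

  allone <- call_qtts(data.frame(gene_id = paste0("g", 1:5), alpha = 1,
                                 se = 1, stat = 0, pvalue = rep(1, 5)))
  expect_true(all(allone$qtt_class == "none"))
})

test_that("planted coefficients are recovered and precision improves with sample size", {
  rmse_at <- function(n_rep, seed) {
    set.seed(seed)
    la <- rep(c(1, 3.5, 3.5, 3.5, 7.5, 7.5), c(3, 4, 4, 4, 4, 4) * n_rep) +
      rnorm(23 * n_rep, 0, 0.75)
    alpha <- c(rep(1, 20), rep(0, 80))
    expr <- outer(alpha, la) + matrix(rnorm(100 * 23 * n_rep, 0, 0.5),
                                      100, 23 * n_rep)
    dimnames(expr) <- list(paste0("g", 1:100),
                           paste0("s", seq_len(23 * n_rep)))
    fit <- fit_qtt_model(expr, la)
    sqrt(mean((fit$table$alpha - alpha)^2))
  }
  r23 <- mean(vapply(1:5, function(s) rmse_at(1, s), numeric(1)))
  r92 <- mean(vapply(1:5, function(s) rmse_at(4, 100 + s), numeric(1)))
  expect_lt(r92, r23)
  expect_lt(r23, 0.2)   # unbiased and reasonably tight already at n = 23
})
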