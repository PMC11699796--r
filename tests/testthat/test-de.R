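test_that("BH adjustment matches the textbook step-up on examples and keeps its guarantees", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.73), 0.73)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
  }

  # missing values are excluded from the number of tests
  p <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_oracle(c(0.01, 0.04)))
})

test_that("dispersion estimation recovers moment estimates with floor and trend", {
  # constant gene has zero variance -> floored
  m <- matrix(c(rep(5L, 10), rpois(10, 50)), 2, 10, byrow = TRUE,
              dimnames = list(c("const", "var"), paste0("s", 1:10)))
  set.seed(12)
  d <- estimate_dispersions(m, size_factors = rep(1, 10))
  expect_equal(d$phi_mom[1], 1e-8)

  # Poisson gene: variance ~ mean, phi near the floor
  set.seed(13)
  pois <- matrix(rpois(3 * 1000, lambda = c(50, 200, 1000)), 3, 1000,
                 dimnames = list(paste0("g", 1:3), paste0("s", 1:1000)))
  dp <- estimate_dispersions(pois, size_factors = rep(1, 1000))
  expect_true(all(dp$phi_mom < 0.01))

  # NB gene with true phi = 0.2 at n = 200: moment estimate in [0.1, 0.3]
  set.seed(14)
  nb <- matrix(rnbinom(200 * 20, mu = 300, size = 1 / 0.2), 20, 200,
               dimnames = list(paste0("g", 1:20), paste0("s", 1:200)))
  dn <- estimate_dispersions(nb, size_factors = rep(1, 200))
  expect_true(median(dn$phi_mom) > 0.1 && median(dn$phi_mom) < 0.3)

  expect_error(estimate_dispersions(m[, 1, drop = FALSE], 1), ">= 2 samples")

  # shrinkage pulls gene estimates toward the fitted trend in log space
  expect_true(all(
    pmin(dn$phi_mom, dn$phi_trend) - 1e-12 <= dn$phi_shrunk &
      dn$phi_shrunk <= pmax(dn$phi_mom, dn$phi_trend) + 1e-12))
})

test_that("noise-free proportional groups give the constructed log2 fold-change", {
  n <- 23
  samples <- two_group_samples()
  m <- matrix(0L, 2, n, dimnames = list(c("gA", "gB"), samples$sample_id))
  m[, 1:4] <- c(4000L, 2000L)    # focal counts exactly 2x the rest
  m[, 5:n] <- c(2000L, 1000L)
  de <- de_contrast(m, samples, "focal", dispersions = 1e-8,
                    size_factors = rep(1, n))
  expect_equal(de$log2FC, c(1, 1), tolerance = 1e-6)
  expect_true(all(de$padj < 0.05))
  # |log2FC| must strictly exceed 1, so the exact 2-fold boundary is "ns"
  expect_equal(de$direction, c("ns", "ns"))
})

test_that("the DEG rule is exactly padj < alpha and |log2FC| > threshold", {
  set.seed(15)
  counts <- nb_two_group_counts(400, spiked = 1:40, lfc = 3)
  counts <- drop_all_zero_genes(counts)
  de <- de_contrast(counts, two_group_samples(), "focal",
                    dispersions = 0.05, size_factors = rep(1, 23))
  expected <- ifelse(!is.na(de$padj) & de$padj < 0.05 & abs(de$log2FC) > 1,
                     ifelse(de$log2FC > 0, "up", "down"), "ns")
  expect_identical(de$direction, expected)
  # spiked genes overwhelmingly recovered as upregulated
  spiked_dir <- de$direction[match(sprintf("g%05d", 1:40), de$gene_id)]
  expect_gt(mean(spiked_dir == "up", na.rm = TRUE), 0.9)
})

test_that("contrast preconditions and degenerate genes are handled", {
  m <- toy_counts()
  samples <- data.frame(sample_id = c("s1", "s2"),
                        subpopulation = c("A", "B"))
  expect_error(de_contrast(m, samples, "A"), ">= 2 samples")

  # a gene entirely zero in one group is flagged, not silently estimated
  set.seed(16)
  counts <- nb_two_group_counts(50)
  counts[1, 1:4] <- 0L
  counts[1, 5:23] <- 50L
  de <- de_contrast(counts, two_group_samples(), "focal",
                    dispersions = 0.05, size_factors = rep(1, 23))
  expect_false(de$converged[1])
  expect_true(is.na(de$pvalue[1]))
})

test_that("DEG summaries reproduce per-group totals and rounded dataset means", {
  published <- data.frame(
    subpopulation = c("Asia", "Americas", "Canada_trees",
                      "Europe_Domestic_1", "Europe_Domestic_2", "Europe_Mix"),
    n_up = c(74, 67, 66, 105, 26, 45),
    n_down = c(314, 321, 165, 28, 53, 83))
  s <- summarize_degs(published)
  expect_equal(s$table$n_total, c(388, 388, 231, 133, 79, 128))
  expect_equal(s$mean_down, 161)
  expect_equal(s$mean_up, 64)

  empty <- structure(
    data.frame(gene_id = character(0), base_mean = numeric(0),
               log2FC = numeric(0), lfcSE = numeric(0), stat = numeric(0),
               pvalue = numeric(0), padj = numeric(0),
               direction = character(0), converged = logical(0)),
    class = c("de_table", "data.frame"))
  s0 <- summarize_degs(list(only = empty))
  expect_equal(s0$table$n_total, 0)

  set.seed(17)
  tabs <- list(a = random_de_table(30, paste0("g", 1:60)),
               b = random_de_table(40, paste0("g", 1:60)))
  st <- summarize_degs(tabs)
  expect_equal(st$table$n_total, st$table$n_up + st$table$n_down)
})
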