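test_that("group statistics match hand arithmetic and a brute-force oracle", {
  m <- matrix(c(4, 6, 1, 3), 1, 4,
              dimnames = list("g1", c("a1", "a2", "b1", "b2")))
  st <- group_stats(m, group_contrast("c", c("a1", "a2"), c("b1", "b2")))
  expect_equal(unname(st$logfc), 3)
  expect_equal(unname(st$s2), 2)
  expect_identical(st$df, 2L)

  mat <- rand_matrix(500L, 10L, seed = 60L)
  ct <- group_contrast("c", colnames(mat)[1:6], colnames(mat)[7:10])
  st <- group_stats(mat, ct)
  for (g in sample(rownames(mat), 25)) {
    xa <- mat[g, 1:6]; xb <- mat[g, 7:10]
    expect_equal(unname(st$logfc[g]), mean(xa) - mean(xb))
    expect_equal(unname(st$s2[g]),
                 (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / 8)
  }
  ident <- matrix(rep(c(1, 2), each = 2), 1, 4,
                  dimnames = list("g", c("a1", "a2", "b1", "b2")))
  st0 <- group_stats(ident, group_contrast("c", c("a1", "a2"),
                                           c("b1", "b2")))
  expect_equal(unname(st0$s2), 0)
  expect_error(group_contrast("c", "a1", c("b1", "b2")), ">= 2")
})

test_that("prior estimation hits the exact limits and small-input guards", {
  s2 <- rep(0.3, 50)
  pr <- estimate_prior(s2, 10)
  expect_identical(pr$d0, Inf)
  # bias-corrected geometric mean of a constant is the constant
  expect_equal(pr$s0_sq, 0.3 * exp(log(10 / 2) - digamma(10 / 2)),
               tolerance = 1e-12)
  expect_error(estimate_prior(rep(0.3, 9), 10), ">= 10")
  expect_error(estimate_prior(rep(0, 20), 10), "zero")
})

test_that("prior hyperparameters are recovered from simulated variances", {
  set.seed(61)
  d0 <- 4; s0 <- 0.05; dg <- 12
  errs <- t(sapply(1:20, function(i) {
    true_var <- s0 * d0 / rchisq(5000, d0)
    s2 <- true_var * rchisq(5000, dg) / dg
    pr <- estimate_prior(s2, dg)
    c(d0 = pr$d0 / d0 - 1, s0 = pr$s0_sq / s0 - 1)
  }))
  expect_lt(abs(median(errs[, "d0"])), 0.15)
  expect_lt(abs(median(errs[, "s0"])), 0.15)
})

test_that("prior estimation cross-checks against limma's moment fit", {
  skip_if_not_installed("limma")
  set.seed(62)
  s2 <- 0.05 * 4 / rchisq(2000, 4) * rchisq(2000, 12) / 12
  pr <- estimate_prior(s2, 12)
  lf <- limma::fitFDist(s2, df1 = 12)
  expect_equal(pr$d0, lf$df2, tolerance = 1e-6)
  expect_equal(pr$s0_sq, lf$scale, tolerance = 1e-6)
})

test_that("moderated t hits the no-shrinkage and full-shrinkage limits", {
  mat <- rand_matrix(50L, 8L, seed = 63L)
  ct <- group_contrast("c", colnames(mat)[1:4], colnames(mat)[5:8])
  st <- group_stats(mat, ct)
  ord <- moderated_test(st, list(d0 = 0, s0_sq = 1))
  t_classic <- st$logfc / sqrt(st$s2 * (1 / 4 + 1 / 4))
  expect_equal(ord$t, unname(t_classic), tolerance = 1e-12)
  full <- moderated_test(st, list(d0 = Inf, s0_sq = 0.25))
  expect_equal(full$t, unname(st$logfc / sqrt(0.25 * 0.5)),
               tolerance = 1e-12)
})

test_that("moderated pipeline matches an independent reimplementation", {
  mat <- rand_matrix(20L, 8L, seed = 64L)
  a <- colnames(mat)[1:4]; b <- colnames(mat)[5:8]
  de <- run_de(mat, group_contrast("c", a, b))
  oracle <- moderated_oracle(mat, a, b, de$d0, de$s0_sq)
  expect_equal(de$table$logfc, oracle$logfc, tolerance = 1e-10)
  expect_equal(de$table$t, oracle$t, tolerance = 1e-10)
  expect_equal(de$table$p, oracle$p, tolerance = 1e-10)
  expect_equal(de$table$fdr, bh_oracle(oracle$p), tolerance = 1e-10)
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(65)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p order
  }
})

test_that("DE calls use strict fdr < alpha with no fold-change filter", {
  mat <- rand_matrix(20L, 8L, seed = 66L)
  de <- run_de(mat, group_contrast("c", colnames(mat)[1:4],
                                   colnames(mat)[5:8]))
  de$table$fdr <- rep(1, 20)
  expect_identical(lengths(call_de(de)), c(up = 0L, down = 0L))
  de$table$fdr <- c(0.05, rep(1, 19))  # boundary: exactly alpha excluded
  expect_identical(lengths(call_de(de, 0.05)), c(up = 0L, down = 0L))
  de$table$fdr <- c(0.049, rep(1, 19))
  called <- call_de(de, 0.05)
  expect_identical(length(called$up) + length(called$down), 1L)
  expect_error(call_de(de, 1), "alpha")
})

test_that("planted contrasts are recovered with high recall", {
  cfg <- two_class_config(n_genes = 1000L, n_a = 15L, n_b = 15L,
                          n_up = 50L, n_down = 50L, effect = 1.5,
                          seed = 67L)
  sim <- simulate_dataset(cfg)
  ct <- contrast_from_annotation(sim$annotation, "A", "B")
  calls <- call_de(run_de(sim$matrix, ct))
  up <- planted_genes(sim$truth, "A_vs_B", "up")
  dn <- planted_genes(sim$truth, "A_vs_B", "down")
  recall <- (sum(up %in% calls$up) + sum(dn %in% calls$down)) / 100
  expect_gte(recall, 0.9)
})

test_that("the moderated test controls false calls under the global null", {
  set.seed(68)
  fracs <- replicate(50, {
    mat <- matrix(rnorm(500 * 12), 500, 12,
                  dimnames = list(sprintf("g%d", 1:500),
                                  sprintf("s%d", 1:12)))
    de <- run_de(mat, group_contrast("null", colnames(mat)[1:6],
                                     colnames(mat)[7:12]))
    calls <- call_de(de)
    (length(calls$up) + length(calls$down)) / 500
  })
  expect_lte(mean(fracs), 0.05)
})
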