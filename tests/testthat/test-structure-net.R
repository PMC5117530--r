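test_that("PCA variance fractions match the covariance eigendecomposition", {
  mat <- rand_matrix(10L, 6L, seed = 90L)
  pca <- pca_expression(mat, variables = "genes")  # samples = observations
  ev <- eigen(cov(t(mat)), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(pca$variance_fraction[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-9)
  expect_equal(sum(pca$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(pca$cumulative_variance) >= -1e-12))
})

test_that("rank-1 data loads everything on the first component", {
  u <- 1:8; v <- c(2, 5, 1, 3)
  mat <- outer(u, v)
  dimnames(mat) <- list(sprintf("g%d", 1:8), sprintf("s%d", 1:4))
  pca <- pca_expression(mat, variables = "samples")
  expect_equal(pca$variance_fraction[1], 1, tolerance = 1e-12)
})

test_that("PCA orientation and scaling guards work", {
  mat <- rand_matrix(10L, 6L, seed = 91L)
  mat[, "s001"] <- 5  # constant sample
  expect_error(pca_expression(mat, variables = "samples", scale = TRUE),
               "s001")
  perm <- sample(ncol(mat))
  p1 <- pca_expression(mat, variables = "genes")
  p2 <- pca_expression(mat[, perm], variables = "genes")
  expect_equal(p1$variance_fraction, p2$variance_fraction,
               tolerance = 1e-9)
})

test_that("correlation-derived distances match a double-loop oracle", {
  mat <- rand_matrix(30L, 8L, seed = 92L)
  D <- correlation_distance_matrix(mat)
  C <- cor(mat)
  for (i in 1:8) for (j in 1:8)
    expect_equal(D[i, j], sqrt(sum((C[i, ] - C[j, ])^2)),
                 tolerance = 1e-12)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 8))
  dup <- cbind(mat, dupe = mat[, 1])
  D2 <- correlation_distance_matrix(dup)
  expect_equal(D2["s001", "dupe"], 0, tolerance = 1e-12)
  bad <- mat; bad[, 2] <- 3
  expect_error(correlation_distance_matrix(bad), "s002")
})

test_that("UPGMA reproduces a hand-computed 4-point instance", {
  # d(A,B)=2, d(C,D)=4, d({A,B},{C,D}) = mean(6,10,6,10) = 8
  D <- matrix(c(0, 2, 6, 10,
                2, 0, 6, 10,
                6, 6, 0, 4,
                10, 10, 4, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  hc <- hcluster_samples(D)
  expect_equal(sort(hc$height), c(2, 4, 8))
  # permutation invariance up to relabeling
  perm <- c(3, 1, 4, 2)
  hc2 <- hcluster_samples(D[perm, perm])
  expect_equal(sort(hc2$height), c(2, 4, 8))
  cm1 <- as.matrix(cophenetic(hc)); cm1 <- cm1[LETTERS[1:4], LETTERS[1:4]]
  cm2 <- as.matrix(cophenetic(hc2)); cm2 <- cm2[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cm1, cm2)
  expect_error(hcluster_samples(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("well-separated duplicated groups merge within groups first", {
  set.seed(93)
  g1 <- rnorm(20); g2 <- rnorm(20) + 50
  mat <- cbind(a1 = g1, a2 = g1 + rnorm(20, 0, 0.01),
               b1 = g2, b2 = g2 + rnorm(20, 0, 0.01))
  rownames(mat) <- sprintf("g%d", 1:20)
  hc <- hcluster_samples(correlation_distance_matrix(mat))
  # first two merges join {a1,a2} and {b1,b2}
  first_two <- hc$merge[1:2, ]
  expect_true(all(first_two < 0))
  pairs <- lapply(1:2, function(i) sort(hc$labels[-first_two[i, ]]))
  expect_setequal(vapply(pairs, paste, "", collapse = "+"),
                  c("a1+a2", "b1+b2"))
})

test_that("duplicated genes give an r = 1 edge and thresholds are
           monotone", {
  mat <- rand_matrix(10L, 12L, seed = 94L)
  mat <- rbind(mat, twin = mat["g0001", ])
  net <- coexpression_network(mat, r_min = 0.999)
  expect_true(any(net$edges$gene_a == "g0001" &
                    net$edges$gene_b == "twin"))
  lo <- coexpression_network(mat, r_min = 0.5)
  hi <- coexpression_network(mat, r_min = 0.9)
  key <- function(n) paste(n$edges$gene_a, n$edges$gene_b)
  expect_true(all(key(hi) %in% key(lo)))  # lowering r_min only adds edges
  expect_true(all(hi$edges$r >= 0.9))
  expect_error(coexpression_network(mat, r_min = 0), "r_min")
  expect_error(coexpression_network(mat, r_min = 1.5), "r_min")
})

test_that("independent noise yields essentially no edges at r >= 0.95", {
  set.seed(95)
  fracs <- replicate(10, {
    mat <- matrix(rnorm(60 * 50), 60, 50,
                  dimnames = list(sprintf("g%02d", 1:60),
                                  sprintf("s%02d", 1:50)))
    net <- coexpression_network(mat, r_min = 0.95)
    nrow(net$edges) / choose(60, 2)
  })
  expect_lte(mean(fracs), 0.001)
})

test_that("a planted latent-factor module is fully connected with few
           cross edges", {
  set.seed(96)
  n_s <- 40L
  factor_ <- rnorm(n_s)
  module <- t(sapply(1:20, function(i) factor_ + rnorm(n_s, 0, 0.12)))
  noise <- matrix(rnorm(80 * n_s), 80, n_s)
  mat <- rbind(module, noise)
  dimnames(mat) <- list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:n_s))
  net <- coexpression_network(mat, r_min = 0.95)
  mod_genes <- sprintf("g%03d", 1:20)
  in_mod <- net$edges$gene_a %in% mod_genes & net$edges$gene_b %in% mod_genes
  expect_equal(sum(in_mod), choose(20L, 2L))  # fully connected
  cross <- sum(xor(net$edges$gene_a %in% mod_genes,
                   net$edges$gene_b %in% mod_genes))
  expect_lt(cross / (20 * 80), 0.01)
})

test_that("network edge sets are invariant to gene and sample order", {
  mat <- rand_matrix(30L, 20L, seed = 97L)
  net <- coexpression_network(mat, r_min = 0.3)
  net_p <- coexpression_network(mat[sample(30), sample(20)], r_min = 0.3)
  expect_equal(net$edges, net_p$edges, tolerance = 1e-12)
})

test_that("network export round-trips in both dialects", {
  mat <- rand_matrix(15L, 10L, seed = 98L)
  net <- coexpression_network(mat, r_min = 0.4,
                              node_labels = c(g0001 = "CD"))
  d <- withr::local_tempdir()
  el <- file.path(d, "net.tsv")
  export_network(net, el, "edgelist")
  back <- read_network(el, "edgelist")
  expect_equal(back$edges, net$edges, tolerance = 1e-12)
  expect_identical(back$nodes, net$nodes)
  sif <- file.path(d, "net.sif")
  export_network(net, sif, "sif")
  back_sif <- read_network(sif, "sif")
  expect_identical(back_sif$edges[, 1:2], net$edges[, 1:2])
  expect_true(file.exists(paste0(el, ".nodes.tsv")))
  # single-edge round-trip
  one <- net; one$edges <- net$edges[1, , drop = FALSE]
  f1 <- file.path(d, "one.sif")
  export_network(one, f1, "sif")
  expect_identical(nrow(read_network(f1, "sif")$edges), 1L)
})
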