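test_that("a dominant shifted gene is stable with median rank 1", {
  set.seed(70)
  mat <- matrix(rnorm(100 * 12, 7, 0.05), 100, 12,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("s%02d", 1:12)))
  mat["g001", 1:6] <- mat["g001", 1:6] + 10
  ct <- group_contrast("dom", colnames(mat)[1:6], colnames(mat)[7:12])
  res <- resample_contrast(mat, ct, resampling_config(
    k_per_group = 4L, max_iters = 30L, min_iters = 10L, patience = 5L,
    seed = 1L))
  expect_true("g001" %in% res$stable_up)
  freq <- res$call_frequency
  expect_equal(freq$up[freq$gene == "g001"], 1)
  expect_equal(unname(res$median_rank["g001"]), 1)
})

test_that("stable genes have call frequency 1 and cumulative sets shrink
           monotonically", {
  cfg <- two_class_config(n_genes = 300L, n_a = 8L, n_b = 8L,
                          n_up = 20L, n_down = 20L, effect = 1.2,
                          seed = 71L)
  sim <- simulate_dataset(cfg)
  ct <- contrast_from_annotation(sim$annotation, "A", "B")
  res <- resample_contrast(sim$matrix, ct, resampling_config(
    k_per_group = 5L, max_iters = 40L, min_iters = 15L, patience = 8L,
    seed = 2L))
  expect_true(all(diff(res$trace$n_stable_up) <= 0))
  expect_true(all(diff(res$trace$n_stable_down) <= 0))
  expect_length(intersect(res$stable_up, res$stable_down), 0L)
  freq <- res$call_frequency
  expect_true(all(freq$up[match(res$stable_up, freq$gene)] == 1))
  expect_true(all(freq$down[match(res$stable_down, freq$gene)] == 1))
})

test_that("resampling is deterministic end to end under a fixed seed", {
  cfg <- two_class_config(n_genes = 200L, seed = 72L)
  sim <- simulate_dataset(cfg)
  ct <- contrast_from_annotation(sim$annotation, "A", "B")
  rc <- resampling_config(k_per_group = 4L, max_iters = 20L,
                          min_iters = 10L, patience = 5L, seed = 9L)
  r1 <- resample_contrast(sim$matrix, ct, rc)
  r2 <- resample_contrast(sim$matrix, ct, rc)
  expect_identical(r1$stable_up, r2$stable_up)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$median_rank, r2$median_rank)
})

test_that("plateau detection agrees with a brute-force window check", {
  mk_trace <- function(up, dn) data.frame(
    iteration = seq_along(up), n_de_up = up, n_de_down = dn,
    n_stable_up = up, n_stable_down = dn)
  const <- mk_trace(rep(5L, 15), rep(3L, 15))
  expect_true(plateau_reached(const, patience = 5L, min_iters = 10L))
  decreasing <- mk_trace(20:6, 20:6)
  expect_false(plateau_reached(decreasing, patience = 5L, min_iters = 10L))
  short <- mk_trace(rep(5L, 8), rep(3L, 8))
  expect_false(plateau_reached(short, patience = 5L, min_iters = 10L))
  expect_error(plateau_reached(mk_trace(integer(), integer()), 2L, 1L),
               "empty")
  set.seed(73)
  for (i in 1:30) {
    n <- sample(5:25, 1)
    up <- cummin(sample(0:10, n, replace = TRUE))
    dn <- cummin(sample(0:10, n, replace = TRUE))
    tr <- mk_trace(up, dn)
    patience <- sample(2:6, 1); min_iters <- sample(3:15, 1)
    # oracle: explicit window constancy
    oracle <- n >= min_iters && n >= patience &&
      length(unique(up[(n - patience + 1):n])) == 1 &&
      length(unique(dn[(n - patience + 1):n])) == 1
    expect_identical(plateau_reached(tr, patience, min_iters), oracle)
  }
})

test_that("median-rank aggregation equals a brute-force per-gene median", {
  rt <- matrix(c(1, 1, 1, 1, 3, 2), 2, 3, byrow = TRUE,
               dimnames = list(c("gA", "gB"), NULL))
  agg <- aggregate_ranks(rt, c("gA", "gB"))
  expect_equal(unname(agg["gA"]), 1)
  expect_equal(unname(agg["gB"]), 2)  # true median of (1, 3, 2)
  expect_equal(unname(aggregate_ranks(
    matrix(c(1, 3), 1, 2, dimnames = list("g", NULL)), "g")), 2)
  set.seed(74)
  rt2 <- matrix(sample(1:50, 200, replace = TRUE), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  agg2 <- aggregate_ranks(rt2, rownames(rt2))
  for (g in rownames(rt2))
    expect_equal(unname(agg2[g]), median(rt2[g, ]))
  expect_error(aggregate_ranks(rt2, "missing_gene"), "absent")
})

test_that("null contrasts leave almost no stable genes", {
  set.seed(75)
  sizes <- replicate(3, {
    mat <- matrix(rnorm(1000 * 16), 1000, 16,
                  dimnames = list(sprintf("g%04d", 1:1000),
                                  sprintf("s%02d", 1:16)))
    ct <- group_contrast("null", colnames(mat)[1:8], colnames(mat)[9:16])
    res <- resample_contrast(mat, ct, resampling_config(
      k_per_group = 5L, max_iters = 30L, min_iters = 30L, patience = 30L,
      seed = 1L))
    length(res$stable_up) + length(res$stable_down)
  })
  expect_lte(median(sizes), 0.01 * 1000)
})

test_that("the DE-count matrix respects orientation symmetry", {
  cfg <- sim_config(
    n_genes = 300L,
    cell_classes = data.frame(
      name = c("A", "B"), lineage = c("mesenchymal", "hematopoietic"),
      n_samples = c(8L, 8L)),
    n_batches = 1L, batch_sd = 0,
    signature_plan = data.frame(contrast = "A_vs_B", n_up = 25L,
                                n_down = 15L, effect = 2),
    seed = 76L)
  sim <- simulate_dataset(cfg)
  rc <- resampling_config(k_per_group = 5L, max_iters = 20L,
                          min_iters = 10L, patience = 5L, seed = 4L)
  ab <- resample_contrast(
    sim$matrix, contrast_from_annotation(sim$annotation, "A", "B"), rc)
  ba <- resample_contrast(
    sim$matrix, contrast_from_annotation(sim$annotation, "B", "A"), rc)
  m <- de_count_matrix(list(A_vs_B = ab, B_vs_A = ba))
  expect_identical(dim(m), c(2L, 2L))
  expect_identical(m["A", "B"], length(ab$stable_up))
  expect_identical(m["B", "A"], length(ba$stable_up))
  # up in A-vs-B should essentially be down in B-vs-A (same seed stream,
  # so allow the sets rather than counts to witness the symmetry)
  expect_gt(length(intersect(ab$stable_up, ba$stable_down)) /
              max(1, length(ab$stable_up)), 0.8)
  expect_error(de_count_matrix(list(A_vs_B = ab)), "missing contrast")
})

test_that("stability results serialize to the TSV/YAML bundle", {
  cfg <- two_class_config(n_genes = 150L, seed = 77L)
  sim <- simulate_dataset(cfg)
  res <- resample_contrast(
    sim$matrix, contrast_from_annotation(sim$annotation, "A", "B"),
    resampling_config(k_per_group = 4L, max_iters = 15L, min_iters = 8L,
                      patience = 4L, seed = 5L))
  prefix <- file.path(withr::local_tempdir(), "run")
  write_stability_result(res, prefix)
  stable <- read.delim(paste0(prefix, "_stable.tsv"))
  expect_setequal(stable$gene[stable$direction == "up"], res$stable_up)
  man <- yaml::read_yaml(paste0(prefix, "_manifest.yaml"))
  expect_identical(man$iterations_run, res$iterations_run)
})
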