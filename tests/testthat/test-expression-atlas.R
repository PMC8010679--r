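toy_counts <- function(mat, samples, reps = 2) {
  colnames(mat) <- paste(rep(samples, each = reps), rep(seq_len(reps),
                                                        length(samples)),
                         sep = ".")
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  mat
}

test_that("median-of-ratios size factors: identical columns, doubled column, scaling", {
  m <- toy_counts(matrix(rep(c(10, 20, 40, 80), 4), ncol = 4), c("A", "B"))
  expect_equal(unname(size_factors(m)), rep(1, 4))

  m2 <- toy_counts(cbind(c(10, 20, 40), c(20, 40, 80)), "A")
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  # global rescaling cancels in the ratio to the geometric-mean reference:
  # factors are invariant and normalized values scale linearly
  set.seed(5)
  m3 <- toy_counts(matrix(rpois(120, 30), ncol = 4), c("A", "B"))
  expect_equal(size_factors(m3 * 7), size_factors(m3))
  expect_equal(normalize_counts(m3 * 7), 7 * normalize_counts(m3))

  m4 <- toy_counts(rbind(c(1, 0, 2, 1), c(0, 3, 1, 2)), c("A", "B"))
  expect_error(size_factors(m4), "positive counts in every column")
})

test_that("normalization divides by the per-column factor and preserves zeros", {
  set.seed(6)
  m <- toy_counts(matrix(rpois(80, 10), ncol = 4), c("A", "B"))
  m[3, ] <- 0
  expect_equal(normalize_counts(m, rep(1, 4)), m)
  f <- c(0.5, 1, 2, 4)
  norm <- normalize_counts(m, f)
  expect_equal(norm[1, ], m[1, ] / f)
  expect_true(all(norm[3, ] == 0))
})

test_that("expressed calls need the threshold in both replicates (inclusive)", {
  m <- toy_counts(rbind(c(5, 5, 0, 0),
                        c(5, 4.9, 10, 10),
                        c(0, 0, 0, 0),
                        c(9, 8, 7, 6)), c("A", "B"))
  res <- call_expressed(m, threshold = 5)
  expect_true(res$calls["g001", "A"])
  expect_false(res$calls["g002", "A"])    # 4.9 in one replicate
  expect_true(res$calls["g002", "B"])
  expect_identical(res$summary$expressed_none, 1L)
  expect_identical(res$summary$expressed_any, 3L)
  expect_identical(res$summary$expressed_all, 1L)
  # partition: none and any are disjoint and cover all genes
  expect_identical(res$summary$expressed_none + res$summary$expressed_any,
                   res$summary$n_genes)

  m3 <- m[, 1:3]
  expect_error(call_expressed(m3), "exactly 2 replicates")
})

test_that("entropy breadth is log2(S) for uniform genes and 0 for single-sample genes", {
  S <- 46
  m <- matrix(0, 3, 2 * S)
  m[1, ] <- 50                                  # uniform across all samples
  m[2, 1:2] <- c(100, 100)                      # single sample
  m <- toy_counts(m, sprintf("S%02d", 1:S))
  br <- expression_breadth(m)
  expect_equal(br$entropy_bits[1], log2(46), tolerance = 1e-12)
  expect_equal(br$entropy_bits[2], 0)
  expect_true(is.na(br$entropy_bits[3]))        # zero-total gene
  expect_true(all(br$entropy_bits <= log2(S) + 1e-9, na.rm = TRUE))
})

test_that("SD/mean stability uses the configured SD estimator", {
  m <- toy_counts(cbind(c(10, 7), c(10, 7), c(30, 7), c(30, 7)), c("A", "B"))
  pop <- stability_ranking(m, sd_type = "population")
  expect_equal(pop$scores$sd_over_mean[pop$scores$gene_id == "g001"], 0.5)
  expect_equal(pop$scores$sd_over_mean[pop$scores$gene_id == "g002"], 0)

  smp <- stability_ranking(m, sd_type = "sample")
  expect_equal(smp$scores$sd_over_mean[smp$scores$gene_id == "g001"],
               sqrt(2) * 10 / 20)

  expect_identical(unname(pop$threshold_counts["<0.2"]), 1L)

  m2 <- rbind(m, g003 = rep(0, 4))
  rownames(m2) <- c("g001", "g002", "g003")
  out <- stability_ranking(m2)
  expect_identical(out$excluded, "g003")
})

test_that("sample distance is 1 - r^2 on replicate-averaged profiles", {
  m <- toy_counts(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4),
                        c(3, 6, 9, 12), c(3, 6, 9, 12)), c("A", "B"))
  d <- sample_distance(m)
  expect_equal(unname(diag(d)), c(0, 0))
  expect_equal(d["A", "B"], 0)                  # perfectly correlated

  m2 <- toy_counts(cbind(c(1, 2, 1, 2), c(1, 2, 1, 2),
                         c(1, 1, 2, 2), c(1, 1, 2, 2)), c("A", "B"))
  expect_equal(sample_distance(m2)["A", "B"], 1) # r = 0

  m3 <- toy_counts(cbind(c(1, 1, 1, 1), c(1, 1, 1, 1),
                         c(1, 2, 3, 4), c(1, 2, 3, 4)), c("A", "B"))
  expect_error(sample_distance(m3), "zero-variance")
})

test_that("sample clustering joins closest samples first and handles duplicates", {
  d <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.8,
                0.8, 0.8, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- cluster_samples(d)
  expect_setequal(tree$tip.label, c("a", "b", "c"))
  coph <- ape::cophenetic.phylo(tree)
  expect_lt(coph["a", "b"], coph["a", "c"])
  expect_equal(coph["a", "c"], coph["b", "c"])  # ultrametric under UPGMA

  d2 <- matrix(c(0, 0, 0, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  d2[1, 2] <- d2[2, 1] <- 0
  tree2 <- cluster_samples(d2)
  expect_equal(ape::cophenetic.phylo(tree2)["x", "y"], 0)

  bad <- matrix(c(0, 0.2, 0.5, 0), 2, 2,
                dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(cluster_samples(bad), "symmetric")
})

test_that("size factors agree with the established median-ratio implementation", {
  set.seed(88)
  sim <- simulate_count_matrix(count_sim_spec(n_genes = 500,
                                              samples = sprintf("S%d", 1:6),
                                              seed = 3))
  f_pkg <- size_factors(sim$counts)
  f_ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts)
  expect_equal(unname(f_pkg), unname(f_ref), tolerance = 1e-8)
})

test_that("planted specific and stable genes separate in entropy and stability", {
  sim <- simulate_count_matrix(count_sim_spec(n_genes = 800,
                                              samples = sprintf("S%02d", 1:12),
                                              seed = 14))
  res <- atlas_stats(sim$counts)
  br <- merge(res$breadth, sim$truth, by = "gene_id")
  H_spec <- br$entropy_bits[br$class == "specific"]
  H_broad <- br$entropy_bits[br$class == "broad"]
  expect_gt(mean(outer(H_spec, H_broad, "<")), 0.99)

  st <- merge(res$stability$scores, sim$truth, by = "gene_id")
  cv_stable <- st$sd_over_mean[st$class == "stable"]
  cv_broad <- st$sd_over_mean[st$class == "broad"]
  expect_gt(mean(outer(cv_stable, cv_broad, "<")), 0.99)
})
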