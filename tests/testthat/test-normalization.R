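test_that("upper quartile uses linear interpolation between order statistics", {
  x <- tibble::tibble(gene_id = paste0("g", 1:4), s = c(10L, 20L, 30L, 40L))
  expect_equal(unname(upper_quartile_factors(x)), 32.5)

  # positive homogeneity: doubling a sample's counts doubles its UQ
  x2 <- tibble::tibble(gene_id = paste0("g", 1:4),
                       s1 = c(10L, 20L, 30L, 40L), s2 = c(20L, 40L, 60L, 80L))
  uq <- upper_quartile_factors(x2)
  expect_equal(unname(uq["s2"]), 2 * unname(uq["s1"]))

  # a sample whose counts are nearly all zero has UQ 0 -> error naming it
  sparse <- tibble::tibble(gene_id = paste0("g", 1:10),
                           good = rep(5L, 10),
                           bad = c(rep(0L, 9), 1L))
  expect_error(upper_quartile_factors(sparse), "bad")
})

test_that("UQ-pgQ2 reproduces the hand-computed 2x2 example exactly", {
  x <- tibble::tibble(gene_id = c("g1", "g2"), s1 = c(10L, 30L), s2 = c(40L, 40L))
  n <- uq_pgq2_normalize(x, scale_constant = 100)
  expect_equal(n$sample_factors$uq, c(25, 40))
  expect_equal(n$gene_factors$q2, c(0.7, 1.1))
  v <- as.matrix(n$values[, -1])
  expect_equal(unname(v),
               matrix(c(100 * 0.4 / 0.7, 100 * 1.2 / 1.1,
                        100 * 1.0 / 0.7, 100 * 1.0 / 1.1), 2, 2),
               tolerance = 1e-12)
})

test_that("UQ-pgQ2 is exactly invariant to per-sample rescaling and sets gene medians", {
  sim <- simulate_counts(n_genes = 400, n1 = 4, n2 = 4, seed = 3,
                         size_factors = rep(1, 8), skew_fraction = 0.02)
  x <- suppressMessages(filter_all_zero_genes(sim$counts))
  n <- uq_pgq2_normalize(x)

  # multiply one sample's raw counts by c > 0: identical normalized values
  x2 <- x
  x2[[3]] <- x2[[3]] * 7L
  n2 <- uq_pgq2_normalize(x2)
  expect_equal(n2$values, n$values)

  # genes with a positive stage-1 median have across-sample median equal to
  # the scale constant
  v <- as.matrix(n$values[, -1])
  med <- apply(v, 1, median)
  ok <- !n$gene_factors$fallback
  expect_true(any(ok))
  expect_equal(med[ok], rep(100, sum(ok)), tolerance = 1e-9)

  # recorded factors reproduce the stored values exactly
  m <- as.matrix(x[, -1])
  recon <- 100 * sweep(m, 2, n$sample_factors$uq, "/") / n$gene_factors$q2
  expect_equal(unname(v), unname(recon), tolerance = 1e-9)
})

test_that("pgQ2 gene scaling preserves between-group log fold changes", {
  sim <- simulate_counts(n_genes = 300, n1 = 5, n2 = 5, de_fraction = 0.1,
                         skew_fraction = 0, seed = 8)
  x <- suppressMessages(filter_all_zero_genes(sim$counts))
  uq <- upper_quartile_factors(x)
  m <- as.matrix(x[, -1])
  stage1 <- sweep(m, 2, uq, "/")
  stage2 <- as.matrix(uq_pgq2_normalize(x)$values[, -1])
  g2 <- sim$samples$group[match(colnames(m), sim$samples$sample_id)] == "g2"
  lfc1 <- log2(rowMeans(stage1[, g2]) / rowMeans(stage1[, !g2]))
  lfc2 <- log2(rowMeans(stage2[, g2]) / rowMeans(stage2[, !g2]))
  fin <- is.finite(lfc1)
  expect_true(mean(fin) > 0.9)
  expect_equal(lfc1[fin], lfc2[fin], tolerance = 1e-9)
})

test_that("zero stage-1 medians fall back to the smallest positive value, flagged", {
  # gene gZ is zero in 3 of 4 samples -> stage-1 median 0
  x <- tibble::tibble(gene_id = c("gZ", paste0("g", 1:5)),
                      s1 = c(0L, 10L, 20L, 30L, 40L, 50L),
                      s2 = c(0L, 12L, 22L, 28L, 44L, 52L),
                      s3 = c(0L, 9L, 18L, 33L, 41L, 49L),
                      s4 = c(8L, 11L, 21L, 31L, 39L, 51L))
  n <- uq_pgq2_normalize(x)
  expect_true(n$gene_factors$fallback[1])
  expect_false(any(n$gene_factors$fallback[-1]))
  v <- as.matrix(n$values[, -1])
  # zeros preserved, positive entry mapped to the scale constant
  expect_equal(unname(v[1, ]), c(0, 0, 0, 100))
})

test_that("median-of-ratios factors match hand examples and have geometric mean 1", {
  x <- tibble::tibble(gene_id = c("a", "b"),
                      s1 = c(2L, 3L), s2 = c(4L, 6L), s3 = c(8L, 12L))
  expect_equal(unname(median_of_ratios_factors(x)), c(0.5, 1, 2))

  # sample2 = 2 x sample1 exactly
  y <- tibble::tibble(gene_id = paste0("g", 1:5),
                      s1 = c(3L, 10L, 7L, 20L, 1L),
                      s2 = c(6L, 20L, 14L, 40L, 2L))
  expect_equal(unname(median_of_ratios_factors(y)), c(1 / sqrt(2), sqrt(2)))

  # identical samples: all factors 1
  z <- tibble::tibble(gene_id = paste0("g", 1:3),
                      s1 = c(4L, 9L, 2L), s2 = c(4L, 9L, 2L))
  expect_equal(unname(median_of_ratios_factors(z)), c(1, 1))

  sim <- simulate_counts(n_genes = 500, n1 = 4, n2 = 4, seed = 5)
  s <- median_of_ratios_factors(sim$counts)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-9)

  # no gene positive everywhere -> error
  bad <- tibble::tibble(gene_id = c("a", "b"), s1 = c(1L, 0L), s2 = c(0L, 1L))
  expect_error(median_of_ratios_factors(bad), "positive")
})

test_that("median-of-ratios agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  sim <- simulate_counts(n_genes = 2000, n1 = 5, n2 = 5, seed = 17,
                         skew_fraction = 0.02)
  x <- suppressMessages(filter_all_zero_genes(sim$counts))
  ours <- median_of_ratios_factors(x)
  m <- as.matrix(x[, -1])
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  theirs <- theirs / exp(mean(log(theirs)))   # same geometric-mean convention
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("median-of-ratios recovers planted library-size multipliers", {
  sf_true <- c(0.5, 0.8, 1, 1.25, 2, 1.5, 0.6, 1.1)
  sim <- simulate_counts(n_genes = 10000, n1 = 4, n2 = 4,
                         size_factors = sf_true, de_fraction = 0,
                         skew_fraction = 0, seed = 23)
  s <- median_of_ratios_factors(sim$counts)
  sf_scaled <- sf_true / exp(mean(log(sf_true)))
  expect_equal(unname(s), sf_scaled, tolerance = 0.05)
})
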