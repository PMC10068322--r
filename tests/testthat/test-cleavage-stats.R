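two_by_two_samples <- function(reps = 2L) {
  data.frame(sample_id = c(paste0("c", seq_len(reps)),
                           paste0("t", seq_len(reps))),
             condition = rep(c("control", "treated"), each = reps),
             replicate = rep(seq_len(reps), 2L))
}

test_that("size factors are 1 on identical libraries and scale-equivariant", {
  samples <- two_by_two_samples()
  up <- matrix(rep(c(50L, 200L, 10L, 400L), 4L), ncol = 4,
               dimnames = list(paste0("g", 1:4), samples$sample_id))
  x <- pas_counts(up, up, samples)
  expect_equal(unname(estimate_size_factors(x)), rep(1, 4))

  up2 <- up; up2[, 2] <- up2[, 2] * 2L
  x2 <- pas_counts(up2, up2, samples)
  sf <- estimate_size_factors(x2)
  expect_equal(unname(sf[2] / sf[1]), 2)
})

test_that("size factors recover known library scalars within 5%", {
  truth <- c(1.0, 1.5, 0.7, 2.0)
  sim <- simulate_count_matrix(sim_config(n_genes = 500,
                                          library_scalars = truth,
                                          seed = 51))
  sf <- estimate_size_factors(sim$counts)
  rel <- (sf / sf[1]) / (truth / truth[1])
  expect_true(all(abs(rel - 1) < 0.05))
})

test_that("size factors agree with the median-of-ratios reference implementation", {
  sim <- simulate_count_matrix(sim_config(n_genes = 400,
                                          library_scalars = c(1, 2, 0.5, 1.3),
                                          seed = 52))
  sf <- estimate_size_factors(sim$counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$up)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-10)
})

test_that("size factor estimation fails informatively without an all-positive gene", {
  samples <- two_by_two_samples()
  up <- matrix(c(0L, 5L, 0L, 7L, 3L, 0L, 2L, 0L), nrow = 2, byrow = TRUE,
               dimnames = list(c("g1", "g2"), samples$sample_id))
  x <- pas_counts(up, up, samples)
  expect_error(estimate_size_factors(x), "positive upstream")
})

test_that("dispersion estimates hit the floor for Poisson-like and constant genes", {
  sim <- simulate_count_matrix(sim_config(n_genes = 300, dispersion = 0,
                                          mean_log = log(500), seed = 53))
  sf <- estimate_size_factors(sim$counts)
  raw <- estimate_dispersion(sim$counts, sf, shrink_weight = 0)
  expect_lt(median(raw), 0.01)

  samples <- two_by_two_samples()
  const <- matrix(100L, 3, 4, dimnames = list(paste0("g", 1:3),
                                              samples$sample_id))
  xc <- pas_counts(const, const, samples)
  ac <- estimate_dispersion(xc, rep(1, 4), shrink_weight = 0)
  expect_true(all(ac <= 1e-8 + 1e-12))
})

test_that("dispersion is recovered within 25% from deep NB counts with many replicates", {
  sim <- simulate_count_matrix(sim_config(n_genes = 400, n_reps = 6,
                                          dispersion = 0.1,
                                          mean_log = log(2000),
                                          sd_log = 0.3, seed = 54))
  sf <- estimate_size_factors(sim$counts)
  raw <- estimate_dispersion(sim$counts, sf, shrink_weight = 0)
  expect_lt(abs(mean(raw) - 0.1) / 0.1, 0.25)
  fixed <- estimate_dispersion(sim$counts, sf, fixed = 0.07)
  expect_true(all(fixed == 0.07))
})

test_that("a symmetric null gene gives delta zero and p of one", {
  samples <- two_by_two_samples()
  m <- matrix(100L, 1, 4, dimnames = list("g1", samples$sample_id))
  x <- pas_counts(m, m, samples)
  res <- test_differential_cleavage(x, rep(1, 4), 0.05)
  expect_equal(res$delta_log2, 0, tolerance = 1e-8)
  expect_equal(res$p_value, 1, tolerance = 1e-6)
  expect_true(res$converged)
})

test_that("interaction effect is recovered at deep counts and equals the fold-change difference", {
  sim <- simulate_count_matrix(sim_config(n_genes = 150,
                                          mean_log = log(5000),
                                          sd_log = 0.25, readthrough = 0.2,
                                          dispersion = 0.05,
                                          frac_regulated = 1,
                                          effect_fold = 4, seed = 55))
  sf <- estimate_size_factors(sim$counts)
  res <- test_differential_cleavage(sim$counts, sf, 0.05)
  expect_true(all(res$converged))
  expect_lt(abs(mean(res$delta_log2) - 2), 0.15)
  expect_equal(res$delta_log2, res$log2fc_down - res$log2fc_up,
               tolerance = 1e-8)
})

test_that("the interaction fit matches DESeq2 on a per-gene region x condition design", {
  sim <- simulate_count_matrix(sim_config(n_genes = 15,
                                          mean_log = log(800),
                                          readthrough = 0.4,
                                          dispersion = 0.08,
                                          frac_regulated = 0.5,
                                          effect_fold = 2, seed = 56))
  x <- sim$counts
  sf <- estimate_size_factors(x)
  res <- test_differential_cleavage(x, sf, 0.08)

  mat <- cbind(x$up, x$down)
  colnames(mat) <- paste0(rep(c("up_", "down_"), each = 4),
                          colnames(x$up))
  coldata <- data.frame(
    condition = factor(rep(x$samples$condition, 2),
                       levels = c("control", "treated")),
    region = factor(rep(c("up", "down"), each = 4),
                    levels = c("up", "down")))
  dds <- DESeq2::DESeqDataSetFromMatrix(mat, coldata,
                                        ~ condition + region +
                                          condition:region)
  DESeq2::sizeFactors(dds) <- rep(sf, 2)
  DESeq2::dispersions(dds) <- rep(0.08, nrow(mat))
  dds <- DESeq2::nbinomWaldTest(dds, betaPrior = FALSE)
  ref <- DESeq2::results(dds, name = "conditiontreated.regiondown")
  expect_equal(res$delta_log2, ref$log2FoldChange, tolerance = 1e-4)
  expect_equal(res$se, ref$lfcSE, tolerance = 1e-3)
  expect_equal(res$p_value, ref$pvalue, tolerance = 1e-3)
})

test_that("swapping condition labels negates delta and preserves p-values", {
  sim <- simulate_count_matrix(sim_config(n_genes = 60, frac_regulated = 0.3,
                                          effect_fold = 3, seed = 57))
  x <- sim$counts
  sf <- estimate_size_factors(x)
  res <- test_differential_cleavage(x, sf, 0.05)
  swapped <- x
  swapped$samples$condition <- ifelse(x$samples$condition == "control",
                                      "treated", "control")
  res_swap <- test_differential_cleavage(swapped, sf, 0.05)
  ok <- res$converged & res_swap$converged
  expect_equal(res_swap$delta_log2[ok], -res$delta_log2[ok],
               tolerance = 1e-6)
  expect_equal(res_swap$p_value[ok], res$p_value[ok], tolerance = 1e-6)
})

test_that("rescaling a sample and its size factor leaves the estimates unchanged", {
  sim <- simulate_count_matrix(sim_config(n_genes = 50, frac_regulated = 0.2,
                                          effect_fold = 3, seed = 58))
  x <- sim$counts
  sf <- estimate_size_factors(x)
  # uniform depth rescaling with matched size factors: in the Poisson
  # limit the fitted cell means depend only on offset-normalized sums, so
  # every estimate is reproduced exactly
  k <- 3L
  scaled <- pas_counts(x$up * k, x$down * k, x$samples)
  res0 <- test_differential_cleavage(x, sf, 1e-8)
  res0k <- test_differential_cleavage(scaled, sf * k, 1e-8)
  ok0 <- res0$converged & res0k$converged
  expect_equal(res0k$delta_log2[ok0], res0$delta_log2[ok0],
               tolerance = 1e-6)
  expect_equal(res0k$log2fc_up[ok0], res0$log2fc_up[ok0],
               tolerance = 1e-6)
  expect_equal(res0k$log2fc_down[ok0], res0$log2fc_down[ok0],
               tolerance = 1e-6)
})

test_that("genes with an all-zero cell get missing p-values unless pseudo-counted", {
  samples <- two_by_two_samples()
  up <- matrix(c(100L, 110L, 90L, 95L), 1, dimnames = list("g1", samples$sample_id))
  down <- matrix(c(0L, 0L, 40L, 50L), 1, dimnames = list("g1", samples$sample_id))
  x <- pas_counts(up, down, samples)
  res <- test_differential_cleavage(x, rep(1, 4), 0.05)
  expect_false(res$converged)
  expect_true(is.na(res$p_value))
  res_pc <- test_differential_cleavage(x, rep(1, 4), 0.05, pseudo_count = 1)
  expect_true(res_pc$converged)
  expect_true(is.finite(res_pc$p_value))
  expect_gt(res_pc$delta_log2, 0)
})

test_that("regulation calls follow the sign of delta at the significance threshold", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    delta_log2 = c(1.2, -1.0, -0.8, 0.5),
                    p_value = c(0.01, 0.01, 0.2, NA))
  called <- classify_regulation(res, alpha = 0.05)
  expect_equal(as.character(called$label),
               c("repressed_cleavage", "increased_cleavage",
                 "unchanged", "unchanged"))
})

test_that("the plug-in uncleaved/total ratio matches its defining cases and the generative r", {
  samples <- two_by_two_samples()
  up <- matrix(c(100L, 120L, 80L, 90L), 1,
               dimnames = list("g1", samples$sample_id))
  x_eq <- pas_counts(up, up, samples)
  r_eq <- uncleaved_total_ratio_from_counts(x_eq, rep(1, 4))
  expect_equal(r_eq$ratio_control, 1)
  expect_equal(r_eq$ratio_treated, 1)
  zero <- up * 0L
  r_zero <- uncleaved_total_ratio_from_counts(
    pas_counts(up, zero, samples), rep(1, 4))
  expect_equal(r_zero$ratio_control, 0)

  sim <- simulate_count_matrix(sim_config(n_genes = 200, n_reps = 4,
                                          mean_log = log(3000),
                                          sd_log = 0.2, readthrough = 0.3,
                                          seed = 59))
  sf <- estimate_size_factors(sim$counts)
  est <- uncleaved_total_ratio_from_counts(sim$counts, sf)
  expect_lt(abs(mean(est$ratio_control) - 0.3), 0.05)
  expect_lt(abs(mean(est$ratio_treated) - 0.3), 0.05)
})
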