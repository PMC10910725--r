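test_that("CPM follows its defining formula", {
  m <- matrix(c(0, 50, 10, 0, 25, 100), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  cpm <- compute_cpm(m, lib_sizes = c(1e6, 1e6))
  expect_equal(cpm["g1", "s1"], 0)
  expect_equal(cpm["g2", "s1"], 50)
  # hand-computed with normalisation factors 2 and 0.5
  cpm2 <- compute_cpm(m, norm_factors = c(2, 0.5), lib_sizes = c(1e6, 1e6))
  expect_equal(unname(cpm2[, "s1"]), c(0, 25, 5))
  expect_equal(unname(cpm2[, "s2"]), c(0, 50, 200))
  # zero library size is an error naming the sample
  m0 <- cbind(a = c(1, 2), b = c(0, 0))
  expect_error(compute_cpm(m0), "b")
})

test_that("expression filter implements 'at least 1 CPM in at least half'", {
  # exactly 1 CPM in exactly half of an even number of samples -> retained
  cpm <- rbind(edge = c(1, 1, 0.5, 0.2),
               zero = c(0, 0, 0, 0),
               high = c(5, 5, 5, 5))
  keep <- filter_expressed(cpm)
  expect_true(keep["edge"])
  expect_false(keep["zero"])
  expect_true(keep["high"])
  # 10 samples: >= 1 CPM in 4 -> removed, in 5 -> retained
  cpm10 <- rbind(four = c(rep(2, 4), rep(0.1, 6)),
                 five = c(rep(2, 5), rep(0.1, 5)))
  expect_identical(unname(filter_expressed(cpm10)), c(FALSE, TRUE))
  expect_error(filter_expressed(matrix(nrow = 0, ncol = 0)), "empty")
})

test_that("raising the filter threshold never retains more genes", {
  set.seed(1)
  cpm <- matrix(rexp(400, 1 / 2), 40, 10)
  kept <- vapply(c(0.5, 1, 2, 4), function(th)
    sum(filter_expressed(cpm, threshold = th)), integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("TMM factors match the published definition", {
  # identical samples: all factors 1 by symmetry
  m <- cbind(a = 1:50, b = 1:50, c = 1:50)
  expect_equal(unname(tmm_factors(m)), rep(1, 3))
  # pure depth scaling is absorbed by the library size: factors stay 1
  set.seed(2)
  m2 <- matrix(rpois(200, 50), 100, 2)
  m2[, 2] <- m2[, 1] * 2
  expect_equal(unname(tmm_factors(m2)), c(1, 1), tolerance = 1e-10)
  # 4-sample matrix with a composition shift vs the naive oracle
  set.seed(42)
  m3 <- matrix(rnbinom(1600, mu = 100, size = 5), 400, 4)
  m3[1:40, 1] <- m3[1:40, 1] * 6
  expect_equal(unname(tmm_factors(m3)), naive_tmm(m3), tolerance = 1e-10)
  expect_equal(exp(mean(log(tmm_factors(m3)))), 1, tolerance = 1e-12)
  expect_error(tmm_factors(matrix(1:5)), "two samples")
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  # permutation invariance
  set.seed(3)
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # missing p-values are excluded from the number of tests
  expect_warning(q <- bh_adjust(c(0.01, NA, 0.02)), "missing")
  expect_equal(q, c(0.02, NA, 0.02))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("top-fraction selection sizes and orders correctly", {
  expect_equal(top_fraction_count(20), 1)
  expect_equal(top_fraction_count(100), 5)
  res <- structure(
    data.frame(gene = c("b", "a", "c", "d"),
               logFC = c(1, -3, 2, 0.5),
               p = c(0.001, 0.001, 0.01, 0.5),
               q = c(0.01, 0.01, 0.02, 0.5)),
    class = c("contrast_result", "data.frame"),
    n_tested = 4)
  # k = floor(0.05 * 4) = 0 -> warning and empty set
  expect_warning(sel0 <- select_top_fraction(res), "empty")
  expect_length(sel0, 0)
  # ties on q broken by p then |logFC| then gene ID
  expect_equal(select_top_fraction(res, 0.5), c("a", "b"))
  expect_equal(select_top_fraction(res, 0.8), c("a", "b", "c"))
})

test_that("differential expression recovers planted effects", {
  d <- sim_design(n_genes = 400, tissues = "liver", n_per_cell = 5, seed = 21)
  sim <- simulate_counts(d, sim_params(n_de = 25, de_lfc = 2, n_modules = 0,
                                       wired_coupling = 0, n_tf = 20,
                                       n_secretome = 10,
                                       tf_secretome_overlap = 0))
  ct <- contrast_spec("liver", "rfi", "High", "Low")
  res <- de_test(sim$counts, sim$samples, ct)
  expect_s3_class(res, "contrast_result")
  expect_equal(attr(res, "n_tested"), nrow(res))
  expect_true(all(res$q >= res$p))
  expect_true(all(res$q <= 1))
  truth <- sim$truth$de_genes$RL
  est <- res$logFC[match(truth$gene, res$gene)]
  # median estimated |log2FC| close to the planted magnitude of 2
  expect_gt(median(abs(est), na.rm = TRUE), 1.7)
  expect_lt(median(abs(est), na.rm = TRUE), 2.3)
  # and signs agree
  expect_gt(mean(sign(est) == sign(truth$lfc), na.rm = TRUE), 0.95)
})

test_that("two groups with identical counts give log2FC = 0", {
  m <- matrix(rep(c(5L, 40L, 100L, 7L, 60L, 33L), 8), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  samples <- data.frame(sample = paste0("s", 1:8), tissue = "liver",
                        breed = "B", rfi = rep(c("High", "Low"), each = 4),
                        diet = "ZG", timepoint = 1,
                        animal = paste0("a", 1:8))
  ct <- contrast_spec("liver", "rfi", "High", "Low")
  res <- de_test(m, samples, ct)
  expect_equal(res$logFC, rep(0, nrow(res)), tolerance = 1e-8)
})

test_that("diet contrast adjusts for time-point without losing the diet effect", {
  d <- sim_design(n_genes = 300, tissues = "liver", n_per_cell = 4, seed = 31)
  sim <- simulate_counts(d, sim_params(n_de = 20, de_lfc = 2, n_modules = 0,
                                       wired_coupling = 0, n_tf = 10,
                                       n_secretome = 10,
                                       tf_secretome_overlap = 0))
  ct <- contrast_spec("liver", "diet", "HC", "ZG")
  expect_true("timepoint" %in% ct$covariates)
  res <- de_test(sim$counts, sim$samples, ct)
  sel <- select_top_fraction(res, 0.05)
  truth <- sim$truth$de_genes$DL$gene
  expect_gt(length(intersect(sel, truth)) / length(sel), 0.8)
})

test_that("null data are calibrated: uniform p under the true model,
           nominal type-I error under the fitted model", {
  sim <- null_sim(seed = 11)
  counts <- sim$counts[filter_expressed(compute_cpm(sim$counts)), ]
  grp <- factor(sim$samples$rfi, levels = c("Low", "High"))
  dm <- stats::model.matrix(~grp)
  # oracle fit with the generator's true dispersions: p ~ Uniform(0, 1)
  fit <- edgeR::glmFit(counts, dm,
                       dispersion = sim$truth$dispersion[rownames(counts)],
                       lib.size = colSums(counts))
  p_true <- edgeR::glmLRT(fit, coef = 2)$table$PValue
  expect_gt(stats::ks.test(p_true, "punif")$p.value, 0.01)
  # the pipeline's estimator keeps the false-positive rate nominal
  ctr <- contrast_spec("liver", "rfi", "High", "Low")
  res <- de_test(sim$counts, sim$samples, ctr)
  expect_gt(mean(res$p < 0.05), 0.03)
  expect_lt(mean(res$p < 0.05), 0.07)
})
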