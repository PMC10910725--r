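# Independent oracles and small fixtures used across the suite.

# Brute-force PCIT: literal triple loop over trios, no vectorisation,
# coded independently of the package's compiled kernel.
brute_pcit <- function(R) {
  n <- nrow(R)
  keep <- matrix(TRUE, n, n)
  diag(keep) <- FALSE
  if (n < 3) return(keep)
  pc <- function(a, b, c) {
    den <- (1 - b^2) * (1 - c^2)
    if (den <= 0) return(0)
    (a - b * c) / sqrt(den)
  }
  for (x in 1:(n - 2)) for (y in (x + 1):(n - 1)) for (z in (y + 1):n) {
    rxy <- R[x, y]; rxz <- R[x, z]; ryz <- R[y, z]
    terms <- c()
    if (rxy != 0) terms <- c(terms, abs(pc(rxy, rxz, ryz) / rxy))
    if (rxz != 0) terms <- c(terms, abs(pc(rxz, rxy, ryz) / rxz))
    if (ryz != 0) terms <- c(terms, abs(pc(ryz, rxy, rxz) / ryz))
    if (length(terms) == 0) next
    eps <- mean(terms)
    if (abs(rxy) < eps * abs(rxz) && abs(rxy) < eps * abs(ryz)) {
      keep[x, y] <- keep[y, x] <- FALSE
    }
    if (abs(rxz) < eps * abs(rxy) && abs(rxz) < eps * abs(ryz)) {
      keep[x, z] <- keep[z, x] <- FALSE
    }
    if (abs(ryz) < eps * abs(rxy) && abs(ryz) < eps * abs(rxz)) {
      keep[y, z] <- keep[z, y] <- FALSE
    }
  }
  keep
}

# Random correlation matrix from a data matrix (guaranteed valid).
random_cor <- function(n, samples = n + 2, seed = 1) {
  set.seed(seed)
  cor(matrix(rnorm(n * samples), samples, n))
}

# Naive TMM from its published definition: doubly trimmed (30% of
# M-values, 5% of A-values from each tail), precision-weighted mean of
# library-size-normalised log-ratios against the reference sample whose
# upper-quartile relative expression is closest to the mean, rescaled to
# geometric mean one.
naive_tmm <- function(counts, logratio_trim = 0.3, sum_trim = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(k) {
    o <- counts[, ref]; x <- counts[, k]
    pos <- x > 0 & o > 0
    x <- x[pos]; o <- o[pos]
    M <- log2((x / lib[k]) / (o / lib[ref]))
    A <- (log2(x / lib[k]) + log2(o / lib[ref])) / 2
    w <- (lib[k] - x) / (lib[k] * x) + (lib[ref] - o) / (lib[ref] * o)
    n <- length(M)
    keep <- rank(M) >= floor(n * logratio_trim) + 1 &
      rank(M) <= n - floor(n * logratio_trim) &
      rank(A) >= floor(n * sum_trim) + 1 &
      rank(A) <= n - floor(n * sum_trim)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Small simulation presets ------------------------------------------------

# Single-tissue null data: no DE, no modules, no wiring.
null_sim <- function(seed, n_genes = 2000, n_per_cell = 10) {
  d <- sim_design(n_genes = n_genes, breeds = "B1", tissues = "liver",
                  diet_phases = "ZG", n_per_cell = n_per_cell, seed = seed)
  simulate_counts(d, sim_params(n_de = 0, de_lfc = 0, n_modules = 0,
                                wired_coupling = 0, n_tf = 10,
                                n_secretome = 10, tf_secretome_overlap = 0))
}

# Differential-wiring scenario: one flipped regulator, >= 50 decoy TFs,
# 20 targets, 20 samples per RFI condition.
wired_sim <- function(seed) {
  d <- sim_design(n_genes = 200, breeds = c("CH", "HF"), diet_phases = "ZG",
                  tissues = "liver", n_per_cell = 10, seed = seed)
  simulate_counts(d, sim_params(n_tf = 60, n_secretome = 30,
                                tf_secretome_overlap = 0, n_de = 0,
                                de_lfc = 0, n_modules = 1, module_size = 20,
                                wired_coupling = 0.8, wired_target_lfc = 1))
}

# Does the wired regulator rank first by |RIF1 z-score|?
wired_regulator_recovered <- function(sim) {
  tr <- sim$truth
  cts <- sim$counts
  keep <- filter_expressed(compute_cpm(cts))
  cts <- cts[keep, , drop = FALSE]
  lc <- compute_cpm(cts, tmm_factors(cts), log = TRUE)
  regs <- intersect(tr$tf_ids, rownames(lc))
  targets <- intersect(tr$wired_targets, rownames(lc))
  ct <- contrast_spec("liver", "rfi", "High", "Low")
  rt <- rif_for_contrast(lc, sim$samples, ct, regs, targets)
  rt$regulator[which.max(abs(rt$rif1_z))] == tr$wired_regulator
}

# log2(CPM + 1) on filtered genes, plus the truth, for network tests.
module_logcpm <- function(seed, n_genes = 600) {
  d <- sim_design(n_genes = n_genes, breeds = c("CH", "HF"),
                  diet_phases = "ZG", tissues = "liver", n_per_cell = 10,
                  seed = seed)
  sim <- simulate_counts(d, sim_params(n_tf = 60, n_secretome = 80,
                                       tf_secretome_overlap = 10,
                                       n_de = 40, de_lfc = 2, n_modules = 3,
                                       module_size = 20))
  cts <- sim$counts
  keep <- filter_expressed(compute_cpm(cts))
  cts <- cts[keep, , drop = FALSE]
  list(logcpm = compute_cpm(cts, tmm_factors(cts), log = TRUE),
       truth = sim$truth, samples = sim$samples)
}

# Write TF / secretome gene-list fixtures to a temp dir; returns paths.
tmp_lists <- function(tf, sec, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- c(tf = file.path(dir, "tf.txt"), sec = file.path(dir, "sec.txt"))
  writeLines(tf, paths["tf"])
  writeLines(sec, paths["sec"])
  paths
}
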