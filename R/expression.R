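#' Counts per million
#'
#' `cpm[g, s] = counts[g, s] / (lib_size[s] * norm_factor[s]) * 1e6`, with
#' library sizes taken as column sums unless supplied.
#'
#' @param counts integer gene-by-sample matrix.
#' @param norm_factors per-sample normalisation factors (e.g. from
#'   [tmm_factors()]); defaults to 1.
#' @param lib_sizes per-sample library sizes; defaults to `colSums(counts)`.
#' @param log if `TRUE`, return `log2(cpm + prior_count)`.
#' @param prior_count offset used on the log scale.
#' @return numeric matrix with the dimensions and dimnames of `counts`.
#' @export
compute_cpm <- function(counts, norm_factors = NULL, lib_sizes = NULL,
                        log = FALSE, prior_count = 1) {
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (any(lib_sizes == 0)) {
    bad <- colnames(counts)[lib_sizes == 0]
    if (is.null(bad)) bad <- which(lib_sizes == 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  cpm <- sweep(counts, 2, lib_sizes * norm_factors, "/") * 1e6
  if (log) log2(cpm + prior_count) else cpm
}

#' Expression filter: at least `threshold` CPM in at least a fraction of samples
#'
#' A gene is retained when the number of samples with
#' `CPM >= threshold` is at least `ceiling(min_fraction * n_samples)` — i.e.
#' at least 1 CPM in at least half of the samples at the defaults.
#'
#' @param cpm CPM matrix for exactly the samples entering the contrast.
#' @param threshold CPM threshold (default 1).
#' @param min_fraction minimum fraction of samples (default 0.5).
#' @return named logical vector over genes (`TRUE` = retained).
#' @export
filter_expressed <- function(cpm, threshold = 1, min_fraction = 0.5) {
  cpm <- as.matrix(cpm)
  if (nrow(cpm) == 0 || ncol(cpm) == 0) stop("empty CPM matrix")
  need <- ceiling(min_fraction * ncol(cpm))
  setNames(rowSums(cpm >= threshold) >= need, rownames(cpm))
}

#' TMM normalisation factors
#'
#' Trimmed mean of M-values: against a reference sample (the one whose
#' upper-quartile expression is closest to the mean upper quartile), the
#' per-sample factor is the doubly trimmed (30% of M-values, 5% of A-values)
#' precision-weighted mean of log ratios, and factors are rescaled so their
#' geometric mean is 1. Computed with [edgeR::calcNormFactors()]. A sample
#' for which no factor can be computed (no expressed genes shared with the
#' reference) gets factor 1 with a warning.
#'
#' @param counts integer gene-by-sample matrix with at least two samples.
#' @return numeric vector of normalisation factors, geometric mean 1.
#' @export
tmm_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  f <- edgeR::calcNormFactors(counts, method = "TMM")
  if (any(!is.finite(f))) {
    warning("normalisation factor undefined for ",
            sum(!is.finite(f)), " sample(s); set to 1")
    f[!is.finite(f)] <- 1
    f <- f / exp(mean(log(f)))
  }
  setNames(f, colnames(counts))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Wraps [stats::p.adjust()] with explicit handling of missing p-values:
#' `NA`/`NaN` entries are excluded from the number of tests and returned as
#' `NA`, with a warning.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return vector of BH-adjusted q-values, same length and names as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  if (!all(ok)) warning(sum(!ok), " missing p-value(s) excluded from the adjustment")
  q <- rep(NA_real_, length(p))
  q[ok] <- p.adjust(p[ok], method = "BH")
  names(q) <- names(p)
  q
}

#' Specify one differential-expression contrast
#'
#' @param tissue tissue whose samples enter the contrast.
#' @param factor one of `"rfi"`, `"breed"`, `"diet"`.
#' @param level_a,level_b the two levels compared (log2FC is A vs B). For
#'   the diet factor, levels are the derived classes `"HC"` (any phase other
#'   than `"ZG"`) and `"ZG"`.
#' @param covariates covariate column names; the diet contrast always
#'   carries the numeric `timepoint` covariate so the two high-concentrate
#'   phases are adjusted for when they were fed.
#' @param label short contrast label (e.g. `"RL"` for RFI in liver).
#' @return an object of class `contrast_spec`.
#' @export
contrast_spec <- function(tissue, factor = c("rfi", "breed", "diet"),
                          level_a, level_b, covariates = character(0),
                          label = NULL) {
  factor <- match.arg(factor)
  if (factor == "diet" && !"timepoint" %in% covariates) {
    covariates <- c(covariates, "timepoint")
  }
  if (is.null(label)) {
    label <- paste0(toupper(substr(factor, 1, 1)), toupper(substr(tissue, 1, 1)))
  }
  structure(list(tissue = tissue, factor = factor, level_a = level_a,
                 level_b = level_b, covariates = covariates, label = label),
            class = "contrast_spec")
}

# Map a sample table to the grouping variable of a contrast; diet phases
# other than "ZG" collapse to the high-concentrate class "HC".
contrast_group <- function(samples, contrast) {
  g <- switch(contrast$factor,
              rfi = samples$rfi,
              breed = samples$breed,
              diet = ifelse(samples$diet == "ZG", "ZG", "HC"))
  factor(g, levels = c(contrast$level_b, contrast$level_a))
}

#' Per-contrast negative-binomial differential expression
#'
#' Subsets the samples of the contrast's tissue, TMM-normalises, applies the
#' expression filter, fits a gene-wise NB log-linear model
#' (`~ group + covariates`) and tests the group coefficient by likelihood
#' ratio against chi-squared(1), via edgeR's GLM machinery
#' ([edgeR::glmFit()]/[edgeR::glmLRT()]) with dispersion estimated per gene
#' and shrunk toward the common value with `prior_df` prior degrees of
#' freedom. P-values are BH-adjusted with [bh_adjust()].
#'
#' @param counts full count matrix.
#' @param samples sample table (columns sample, tissue, breed, rfi, diet,
#'   timepoint).
#' @param contrast a [contrast_spec()].
#' @param cpm_threshold,min_fraction expression-filter settings.
#' @param prior_df prior degrees of freedom for dispersion shrinkage.
#' @return a data.frame (class `contrast_result`) with columns `gene`,
#'   `logFC` (A vs B), `p`, `q`, ordered by `q` then `p`; attributes
#'   `n_tested`, `label` and `contrast`.
#' @export
de_test <- function(counts, samples, contrast,
                    cpm_threshold = 1, min_fraction = 0.5, prior_df = 20) {
  stopifnot(inherits(contrast, "contrast_spec"))
  sel <- samples$tissue == contrast$tissue
  if (!any(sel)) stop("no samples for tissue ", contrast$tissue)
  samples <- samples[sel, , drop = FALSE]
  counts <- counts[, samples$sample, drop = FALSE]
  group <- contrast_group(samples, contrast)
  if (any(is.na(group))) stop("contrast levels not found in the design")
  if (any(table(group) < 3)) stop("need at least 3 samples per level")

  keep <- filter_expressed(compute_cpm(counts),
                           threshold = cpm_threshold,
                           min_fraction = min_fraction)
  counts <- counts[keep, , drop = FALSE]
  nf <- tmm_factors(counts)

  dge <- edgeR::DGEList(counts = counts, norm.factors = nf)
  mm_data <- data.frame(group = group)
  for (v in contrast$covariates) mm_data[[v]] <- samples[[v]]
  design <- stats::model.matrix(
    stats::reformulate(c("group", contrast$covariates)), data = mm_data)
  dge <- edgeR::estimateDisp(dge, design, prior.df = prior_df)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit, coef = 2)
  tab <- lrt$table
  res <- data.frame(gene = rownames(tab), logFC = tab$logFC,
                    p = tab$PValue, stringsAsFactors = FALSE)
  res$p[is.na(res$p)] <- 1
  res$q <- bh_adjust(res$p)
  res <- res[order(res$q, res$p, -abs(res$logFC), res$gene), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("contrast_result", "data.frame"),
            n_tested = nrow(res), label = contrast$label, contrast = contrast)
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("Contrast ", attr(x, "label"), ": ", attr(x, "n_tested"),
      " genes tested\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more genes)\n", sep = "")
  invisible(x)
}

#' Number of genes in the top fraction
#'
#' `floor(fraction * n_tested)` — the rule used to size the top-5% DEG set
#' of each contrast.
#'
#' @param n_tested number of genes tested in the contrast.
#' @param fraction selected fraction (default 0.05).
#' @return integer count.
#' @export
top_fraction_count <- function(n_tested, fraction = 0.05) {
  as.integer(floor(fraction * n_tested))
}

#' Select the top fraction of differentially expressed genes
#'
#' Takes the `floor(fraction * n_tested)` genes with the smallest adjusted
#' p-value; ties are broken by raw p-value, then by decreasing |log2FC|,
#' then by gene ID.
#'
#' @param result a [de_test()] result.
#' @param fraction selected fraction (default 0.05, the top 5%).
#' @return character vector of selected gene IDs.
#' @export
select_top_fraction <- function(result, fraction = 0.05) {
  if (nrow(result) == 0) stop("empty contrast result")
  k <- top_fraction_count(attr(result, "n_tested") %||% nrow(result), fraction)
  if (k == 0) {
    warning("top-fraction selection is empty (fraction too small)")
    return(character(0))
  }
  ord <- order(result$q, result$p, -abs(result$logFC), result$gene)
  result$gene[ord][seq_len(k)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
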