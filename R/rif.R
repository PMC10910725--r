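#' Annotate a gene universe with TF, secretome and DEG membership
#'
#' Matching is case-insensitive and exact; list entries absent from the
#' universe are reported with a message.
#'
#' @param genes character vector: the gene universe (network candidates).
#' @param tf_file path to a one-gene-per-line transcription-factor list.
#' @param secretome_file path to a one-gene-per-line secretome list.
#' @param deg_sets optional named list of per-contrast DEG character
#'   vectors; each adds a logical `deg_<label>` column.
#' @return data.frame (one row per gene) with columns `gene`, `is_tf`,
#'   `is_secretome` and one `deg_<label>` column per DEG set; attribute
#'   `provenance` records the list files.
#' @export
annotate_nodes <- function(genes, tf_file, secretome_file, deg_sets = NULL) {
  if (length(genes) == 0) stop("empty gene universe")
  tf <- read_gene_list(tf_file)
  sec <- read_gene_list(secretome_file)
  key <- toupper(genes)
  flag <- function(lst, what) {
    hit <- key %in% toupper(lst)
    missed <- setdiff(toupper(lst), key)
    if (length(missed) > 0) {
      message(length(missed), " ", what,
              " list entr(ies) not in the gene universe")
    }
    hit
  }
  out <- data.frame(gene = genes,
                    is_tf = flag(tf, "TF"),
                    is_secretome = flag(sec, "secretome"),
                    stringsAsFactors = FALSE)
  for (lab in names(deg_sets)) {
    out[[paste0("deg_", lab)]] <- key %in% toupper(deg_sets[[lab]])
  }
  attr(out, "provenance") <- c(tf = tf_file, secretome = secretome_file)
  out
}

#' Regulator-target correlations within each of two conditions
#'
#' Pearson correlations of regulator and target expression profiles,
#' computed separately inside each condition. Genes with zero variance in a
#' condition get correlation 0 there, with a warning.
#'
#' @param log_cpm expression matrix (genes x samples), typically
#'   `log2(CPM + 1)`.
#' @param condition vector over samples with exactly two levels; the first
#'   level (of the factor, or sort order) is condition 1.
#' @param regulators,targets gene IDs (rows of `log_cpm`).
#' @return list with `r1`, `r2` (regulator x target correlation matrices)
#'   and `levels` (the two condition labels).
#' @export
condition_correlations <- function(log_cpm, condition, regulators, targets) {
  if (length(condition) != ncol(log_cpm)) {
    stop("'condition' must have one entry per sample")
  }
  condition <- as.factor(condition)
  if (nlevels(condition) != 2) stop("exactly two conditions are required")
  if (any(table(condition) < 3)) stop("each condition needs at least 3 samples")
  missing <- setdiff(c(regulators, targets), rownames(log_cpm))
  if (length(missing) > 0) {
    stop("genes absent from the expression matrix: ",
         paste(head(missing, 5), collapse = ", "))
  }
  one <- function(cols) {
    X <- t(log_cpm[regulators, cols, drop = FALSE])
    Y <- t(log_cpm[targets, cols, drop = FALSE])
    flat_x <- apply(X, 2, sd) == 0
    flat_y <- apply(Y, 2, sd) == 0
    if (any(flat_x) || any(flat_y)) {
      warning("constant expression for ", sum(flat_x) + sum(flat_y),
              " gene(s) in one condition; correlations set to 0")
    }
    r <- suppressWarnings(cor(X, Y))
    r[flat_x, ] <- 0
    r[, flat_y] <- 0
    r[is.na(r)] <- 0
    r
  }
  lv <- levels(condition)
  list(r1 = one(which(condition == lv[1])),
       r2 = one(which(condition == lv[2])),
       levels = lv)
}

#' Regulatory impact factors (RIF1 and RIF2)
#'
#' For regulator *i* over *n* differentially expressed targets *j*, with
#' `e1`/`e2` the mean expression of each target in condition 1/2 and
#' `r1`/`r2` the within-condition regulator-target correlations:
#'
#' \deqn{RIF1_i = \frac{1}{n}\sum_j a_j d_j (r1_{ij} - r2_{ij})^2, \quad
#'       a_j = \frac{e1_j + e2_j}{2},\; d_j = e1_j - e2_j}
#' \deqn{RIF2_i = \frac{1}{n}\sum_j (e1_j r1_{ij})^2 - (e2_j r2_{ij})^2}
#'
#' RIF1 rewards consistent differential co-expression with abundant,
#' strongly differentially expressed targets (the weight `a_j d_j` is the
#' target's phenotype impact factor); RIF2 rewards change in the
#' regulator's ability to predict target abundance. Both metrics are
#' z-standardised across regulators; `|z| >= 1.96` is flagged significant.
#'
#' @param e1,e2 numeric vectors: mean expression (log2 CPM scale) of each
#'   target in condition 1 and 2.
#' @param r1,r2 regulator x target correlation matrices (see
#'   [condition_correlations()]).
#' @param condition_pair optional label for the condition pair.
#' @return data.frame (class `rif_table`) with columns `regulator`,
#'   `rif1_raw`, `rif2_raw`, `rif1_z`, `rif2_z`, `sig_rif1`, `sig_rif2`;
#'   attributes `n_targets` and `condition_pair`. With a single regulator
#'   the z-scores are `NA` (with a warning).
#' @export
rif_scores <- function(e1, e2, r1, r2, condition_pair = NULL) {
  r1 <- as.matrix(r1); r2 <- as.matrix(r2)
  n_de <- length(e1)
  if (n_de < 1) stop("at least one DE target is required")
  if (length(e2) != n_de || ncol(r1) != n_de || ncol(r2) != n_de ||
      nrow(r1) != nrow(r2)) {
    stop("inconsistent dimensions between expression and correlation inputs")
  }
  a <- (e1 + e2) / 2
  d <- e1 - e2
  pif <- a * d
  rif1 <- as.vector((r1 - r2)^2 %*% pif) / n_de
  rif2 <- rowMeans(sweep(r1, 2, e1, "*")^2 - sweep(r2, 2, e2, "*")^2)
  regs <- rownames(r1) %||% paste0("regulator", seq_len(nrow(r1)))
  zscore <- function(x) {
    if (length(x) < 2 || sd(x) == 0) rep(NA_real_, length(x))
    else (x - mean(x)) / sd(x)
  }
  if (nrow(r1) < 2) {
    warning("z-scores undefined for a single regulator; returning raw scores only")
  }
  z1 <- zscore(rif1); z2 <- zscore(rif2)
  structure(data.frame(regulator = regs,
                       rif1_raw = rif1, rif2_raw = rif2,
                       rif1_z = z1, rif2_z = z2,
                       sig_rif1 = !is.na(z1) & abs(z1) >= 1.96,
                       sig_rif2 = !is.na(z2) & abs(z2) >= 1.96,
                       stringsAsFactors = FALSE),
            class = c("rif_table", "data.frame"),
            n_targets = n_de, condition_pair = condition_pair)
}

#' Score all regulators for one contrast
#'
#' Convenience wrapper: splits the contrast's tissue samples into its two
#' levels, computes within-condition regulator-target correlations on
#' `log2(CPM + 1)`, takes per-condition mean target expression, and calls
#' [rif_scores()].
#'
#' @param log_cpm expression matrix over the tissue's samples.
#' @param samples matching sample table rows.
#' @param contrast a [contrast_spec()].
#' @param regulators,targets gene IDs present in `log_cpm`.
#' @return a `rif_table` (see [rif_scores()]).
#' @export
rif_for_contrast <- function(log_cpm, samples, contrast, regulators, targets) {
  group <- contrast_group(samples, contrast)
  cond <- factor(as.character(group),
                 levels = c(contrast$level_a, contrast$level_b))
  cc <- condition_correlations(log_cpm, cond, regulators, targets)
  e1 <- rowMeans(log_cpm[targets, cond == contrast$level_a, drop = FALSE])
  e2 <- rowMeans(log_cpm[targets, cond == contrast$level_b, drop = FALSE])
  rif_scores(e1, e2, cc$r1, cc$r2,
             condition_pair = paste(contrast$level_a, "vs", contrast$level_b,
                                    "in", contrast$tissue))
}
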