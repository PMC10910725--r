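#' Describe a factorial RNA-seq study design for simulation
#'
#' The default design emulates a two-breed, two-RFI-group (High/Low residual
#' feed intake), three-diet-phase (growing high-concentrate H1, zero-grazed
#' grass ZG, finishing high-concentrate H2) experiment sampled in liver and
#' skeletal muscle, with `n_per_cell` animals per breed-by-RFI cell. Animals
#' are re-used across diet phases and tissues (repeated measures), as in
#' multi-phase feed-efficiency trials.
#'
#' @param n_genes number of genes to simulate.
#' @param breeds character vector of breed labels.
#' @param rfi_groups exactly two phenotype-group labels; the first is the
#'   "High" (feed-inefficient) level of the RFI contrast.
#' @param diet_phases diet-phase labels in chronological order. Any phase not
#'   named `"ZG"` is treated as high-concentrate when forming the diet
#'   contrast.
#' @param tissues tissue labels (one or two).
#' @param n_per_cell animals per breed-by-RFI cell (at least 2).
#' @param seed integer seed; together with the parameters it fully determines
#'   the simulated output.
#' @return an object of class `sim_design`.
#' @seealso [simulate_counts()], [sim_params()]
#' @export
sim_design <- function(n_genes = 2000,
                       breeds = c("CH", "HF"),
                       rfi_groups = c("High", "Low"),
                       diet_phases = c("H1", "ZG", "H2"),
                       tissues = c("liver", "muscle"),
                       n_per_cell = 10,
                       seed = 1L) {
  if (length(rfi_groups) != 2L) {
    stop("'rfi_groups' must have exactly two labels")
  }
  if (n_per_cell < 2L) stop("'n_per_cell' must be at least 2")
  if (n_genes < 1L) stop("'n_genes' must be positive")
  if (length(breeds) < 1L || length(diet_phases) < 1L || length(tissues) < 1L) {
    stop("'breeds', 'diet_phases' and 'tissues' must each have at least one label")
  }
  structure(list(n_genes = as.integer(n_genes),
                 breeds = as.character(breeds),
                 rfi_groups = as.character(rfi_groups),
                 diet_phases = as.character(diet_phases),
                 tissues = as.character(tissues),
                 n_per_cell = as.integer(n_per_cell),
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Simulation parameters: effect sizes, dispersion and library-size model
#'
#' Counts are negative binomial with `Var = mu + phi * mu^2`. Baseline
#' relative abundances are log-normal; gene-wise dispersions `phi` are Gamma
#' with shape `dispersion_shape` and mean `dispersion_mean`; library sizes
#' are log-normal around a few million reads. Co-expression modules are
#' induced by latent standard-normal factors shared by module members on the
#' log2-mean scale (loading `module_loading`, idiosyncratic noise
#' `module_noise_sd`); one transcription factor (the "wired regulator")
#' couples to the first module's factor with coefficient `+wired_coupling`
#' in High-RFI samples and `-wired_coupling` (mode `"flip"`) or `0`
#' (mode `"on_off"`) in Low-RFI samples. Its targets additionally carry a
#' common RFI log2 fold-change of `wired_target_lfc` so they behave like
#' differentially expressed target genes.
#'
#' @param n_tf number of genes designated transcription factors.
#' @param n_secretome number of genes designated secretome (plasma-secreted).
#' @param tf_secretome_overlap how many genes belong to both lists.
#' @param n_de planted differentially expressed genes per contrast.
#' @param de_lfc magnitude of the planted log2 fold-change (sign random);
#'   `0` disables differential expression (truth sets come back empty).
#' @param n_modules,module_size number and size of latent co-expression
#'   modules (each module has at least 5 members).
#' @param module_loading,module_noise_sd factor loading and idiosyncratic
#'   noise SD on the log2-mean scale.
#' @param wired_coupling latent coupling magnitude of the wired regulator;
#'   `0` disables wiring.
#' @param wired_mode `"flip"` (coupling +c vs -c) or `"on_off"` (+c vs 0).
#' @param wired_target_lfc RFI log2 fold-change given to the wired
#'   regulator's targets (all with positive sign in High-RFI samples).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline expression.
#' @param dispersion_shape,dispersion_mean Gamma model for NB dispersion.
#' @param libsize_meanlog,libsize_sdlog log-normal library-size model.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(n_tf = 100, n_secretome = 80, tf_secretome_overlap = 10,
                       n_de = 60, de_lfc = 2,
                       n_modules = 3, module_size = 20,
                       module_loading = 1, module_noise_sd = 0.3,
                       wired_coupling = 0.8,
                       wired_mode = c("flip", "on_off"),
                       wired_target_lfc = 1,
                       baseline_meanlog = log(5), baseline_sdlog = 1.2,
                       dispersion_shape = 2, dispersion_mean = 0.1,
                       libsize_meanlog = log(3e6), libsize_sdlog = 0.25) {
  wired_mode <- match.arg(wired_mode)
  if (dispersion_shape <= 0 || dispersion_mean <= 0) {
    stop("dispersion parameters must be positive")
  }
  if (libsize_meanlog <= 0) stop("'libsize_meanlog' must be positive")
  if (module_noise_sd < 0) stop("'module_noise_sd' must be non-negative")
  if (n_modules > 0 && module_size < 5) {
    stop("'module_size' must be at least 5")
  }
  if (tf_secretome_overlap > min(n_tf, n_secretome)) {
    stop("'tf_secretome_overlap' cannot exceed either list size")
  }
  structure(list(n_tf = as.integer(n_tf),
                 n_secretome = as.integer(n_secretome),
                 tf_secretome_overlap = as.integer(tf_secretome_overlap),
                 n_de = as.integer(n_de), de_lfc = de_lfc,
                 n_modules = as.integer(n_modules),
                 module_size = as.integer(module_size),
                 module_loading = module_loading,
                 module_noise_sd = module_noise_sd,
                 wired_coupling = wired_coupling,
                 wired_mode = wired_mode,
                 wired_target_lfc = wired_target_lfc,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 dispersion_shape = dispersion_shape,
                 dispersion_mean = dispersion_mean,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog),
            class = "sim_params")
}

contrast_label <- function(factor_name, tissue, tissues) {
  code <- c(rfi = "R", diet = "D", breed = "B")[[factor_name]]
  tcode <- toupper(substr(tissue, 1, 1))
  if (length(unique(toupper(substr(tissues, 1, 1)))) != length(tissues)) {
    tcode <- paste0("T", match(tissue, tissues))
  }
  paste0(code, tcode)
}

# The six contrasts implied by a design (fewer if a factor has one level).
design_contrasts <- function(design) {
  out <- list()
  for (tissue in design$tissues) {
    out[[length(out) + 1L]] <- contrast_spec(
      tissue = tissue, factor = "rfi",
      level_a = design$rfi_groups[1], level_b = design$rfi_groups[2],
      label = contrast_label("rfi", tissue, design$tissues))
    if (any(design$diet_phases == "ZG") && any(design$diet_phases != "ZG")) {
      out[[length(out) + 1L]] <- contrast_spec(
        tissue = tissue, factor = "diet",
        level_a = "HC", level_b = "ZG", covariates = "timepoint",
        label = contrast_label("diet", tissue, design$tissues))
    }
    if (length(design$breeds) >= 2) {
      out[[length(out) + 1L]] <- contrast_spec(
        tissue = tissue, factor = "breed",
        level_a = design$breeds[1], level_b = design$breeds[2],
        label = contrast_label("breed", tissue, design$tissues))
    }
  }
  names(out) <- vapply(out, function(x) x$label, character(1))
  out
}

#' Simulate negative-binomial counts over the factorial design
#'
#' Generates a gene-by-sample integer count matrix, the matching sample
#' table, and a ground-truth record (planted DE genes per contrast, module
#' assignments, TF and secretome lists, and the wired regulator with its
#' targets). Planted log2 fold-changes are applied to the first level of
#' each contrast (High RFI, the first breed, the high-concentrate diet
#' class). Module co-expression and the regulator's condition-dependent
#' wiring act on the log2-mean scale, so downstream correlation-based
#' analyses see realistic, noisy signal rather than duplicated counts.
#'
#' @param design a [sim_design()].
#' @param params a [sim_params()].
#' @return a list with elements `counts` (integer matrix, genes x samples),
#'   `samples` (data.frame: sample, tissue, breed, rfi, diet, timepoint,
#'   animal) and `truth` (list: `de_genes` — per-contrast data.frames of
#'   gene and log2 fold-change; `modules` — named integer vector of module
#'   ids; `tf_ids`; `secretome_ids`; `wired_regulator`; `wired_targets`;
#'   `wired_coupling`; `dispersion`; `baseline`).
#' @export
simulate_counts <- function(design, params = sim_params()) {
  stopifnot(inherits(design, "sim_design"), inherits(params, "sim_params"))
  G <- design$n_genes
  if (params$n_tf + params$n_secretome - params$tf_secretome_overlap +
      params$n_modules * params$module_size > G) {
    stop("'n_genes' too small for the requested TF/secretome/module layout")
  }
  set.seed(design$seed)

  genes <- sprintf("G%05d", seq_len(G))

  ## gene annotation blocks: TFs first, then secretome (the last
  ## 'tf_secretome_overlap' TFs are also secretome), modules planted among
  ## the non-TF secretome genes (spilling into background genes if needed)
  tf_idx <- seq_len(params$n_tf)
  ov <- params$tf_secretome_overlap
  sec_idx <- c(if (ov > 0) (params$n_tf - ov + 1L):params$n_tf,
               params$n_tf + seq_len(params$n_secretome - ov))
  n_mod_genes <- params$n_modules * params$module_size
  mod_pool <- setdiff(seq_len(G), tf_idx)
  mod_pool <- c(intersect(sec_idx, mod_pool), setdiff(mod_pool, sec_idx))
  mod_idx <- mod_pool[seq_len(n_mod_genes)]
  modules <- setNames(rep(NA_integer_, G), genes)
  if (n_mod_genes > 0) {
    modules[mod_idx] <- rep(seq_len(params$n_modules),
                            each = params$module_size)
  }

  baseline <- rlnorm(G, params$baseline_meanlog, params$baseline_sdlog)
  rel_ab <- baseline / sum(baseline)
  phi <- rgamma(G, shape = params$dispersion_shape,
                rate = params$dispersion_shape / params$dispersion_mean)
  names(baseline) <- names(phi) <- genes

  ## sample table: animals shared across diet phases and tissues
  cells <- expand.grid(rep = seq_len(design$n_per_cell),
                       rfi = design$rfi_groups, breed = design$breeds,
                       stringsAsFactors = FALSE)
  samples <- do.call(rbind, lapply(design$tissues, function(tissue) {
    do.call(rbind, lapply(seq_along(design$diet_phases), function(ti) {
      data.frame(tissue = tissue, breed = cells$breed, rfi = cells$rfi,
                 diet = design$diet_phases[ti], timepoint = ti,
                 animal = paste0(cells$breed, "_", cells$rfi, "_",
                                 sprintf("%02d", cells$rep)),
                 stringsAsFactors = FALSE)
    }))
  }))
  samples$sample <- sprintf("S%03d_%s", seq_len(nrow(samples)),
                            samples$tissue)
  samples <- samples[, c("sample", "tissue", "breed", "rfi", "diet",
                         "timepoint", "animal")]
  n_s <- nrow(samples)

  wired_reg <- if (params$wired_coupling != 0 && params$n_modules > 0) {
    genes[tf_idx[1]]
  } else NA_character_
  wired_targets <- if (!is.na(wired_reg)) {
    genes[mod_idx[seq_len(params$module_size)]]
  } else character(0)

  ## planted DE truth, one draw per contrast (overlap across contrasts
  ## allowed); the wired regulator is kept out of the DE pool so its RIF
  ## signal is purely differential wiring
  contrasts <- design_contrasts(design)
  de_pool <- setdiff(seq_len(G), match(wired_reg, genes))
  de_genes <- lapply(contrasts, function(ct) {
    df <- data.frame(gene = character(0), lfc = numeric(0),
                     stringsAsFactors = FALSE)
    if (params$n_de > 0 && params$de_lfc != 0) {
      idx <- sample(de_pool, min(params$n_de, length(de_pool)))
      df <- data.frame(gene = genes[idx],
                       lfc = params$de_lfc *
                         sample(c(-1, 1), length(idx), replace = TRUE),
                       stringsAsFactors = FALSE)
    }
    ## the wired regulator's targets behave as DE genes of the RFI contrast
    if (ct$factor == "rfi" && length(wired_targets) > 0 &&
        params$wired_target_lfc != 0) {
      df <- rbind(df[!df$gene %in% wired_targets, , drop = FALSE],
                  data.frame(gene = wired_targets,
                             lfc = params$wired_target_lfc))
    }
    df[order(df$gene), , drop = FALSE]
  })

  ## log2-mean offsets: planted fold-changes on the contrast's first level
  delta <- matrix(0, G, n_s, dimnames = list(genes, samples$sample))
  level_a_samples <- function(ct) {
    in_tissue <- samples$tissue == ct$tissue
    if (ct$factor == "rfi") in_tissue & samples$rfi == ct$level_a
    else if (ct$factor == "breed") in_tissue & samples$breed == ct$level_a
    else in_tissue & samples$diet != "ZG"
  }
  for (lab in names(contrasts)) {
    df <- de_genes[[lab]]
    if (nrow(df) == 0) next
    cols <- which(level_a_samples(contrasts[[lab]]))
    delta[df$gene, cols] <- delta[df$gene, cols] + df$lfc
  }

  ## latent module factors + idiosyncratic noise
  if (params$n_modules > 0) {
    fac <- matrix(rnorm(params$n_modules * n_s), params$n_modules, n_s)
    for (m in seq_len(params$n_modules)) {
      members <- which(modules == m)
      delta[members, ] <- delta[members, ] +
        params$module_loading * matrix(fac[m, ], length(members), n_s,
                                       byrow = TRUE) +
        matrix(rnorm(length(members) * n_s, 0, params$module_noise_sd),
               length(members), n_s)
    }
    if (!is.na(wired_reg)) {
      w <- ifelse(samples$rfi == design$rfi_groups[1], 1,
                  if (params$wired_mode == "flip") -1 else 0)
      delta[wired_reg, ] <- delta[wired_reg, ] +
        params$wired_coupling * w * fac[1, ] +
        rnorm(n_s, 0, params$module_noise_sd)
    }
  }

  lib <- rlnorm(n_s, params$libsize_meanlog, params$libsize_sdlog)
  mu <- sweep(rel_ab * 2^delta, 2, lib, "*")
  counts <- matrix(rnbinom(G * n_s, mu = mu,
                           size = rep(1 / phi, n_s)),
                   G, n_s, dimnames = list(genes, samples$sample))

  truth <- list(de_genes = de_genes, modules = modules,
                tf_ids = genes[tf_idx], secretome_ids = genes[sec_idx],
                wired_regulator = wired_reg, wired_targets = wired_targets,
                wired_coupling = params$wired_coupling,
                wired_mode = params$wired_mode,
                dispersion = phi, baseline = baseline)
  list(counts = counts, samples = samples, truth = truth)
}

#' Write transcription-factor and secretome fixture lists
#'
#' One gene per line, newline-terminated, no duplicates — the plain-text
#' format expected by [annotate_nodes()].
#'
#' @param truth the `truth` element of a [simulate_counts()] result (or any
#'   list with `tf_ids` and `secretome_ids`).
#' @param tf_path,secretome_path output file paths (must differ).
#' @return invisibly, a named character vector of the two paths.
#' @export
write_fixture_lists <- function(truth, tf_path, secretome_path) {
  if (normalizePath(tf_path, mustWork = FALSE) ==
      normalizePath(secretome_path, mustWork = FALSE)) {
    stop("TF and secretome output paths collide")
  }
  writeLines(unique(truth$tf_ids), tf_path)
  writeLines(unique(truth$secretome_ids), secretome_path)
  invisible(c(tf = tf_path, secretome = secretome_path))
}

#' Read a one-gene-per-line list file
#' @param path file path.
#' @return character vector of unique, non-empty gene IDs.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x)])
}
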