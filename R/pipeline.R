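#' Read / write the pipeline's tabular interchange formats
#'
#' Counts are TSV with gene IDs in the first column and sample IDs in the
#' header; the design is TSV with columns sample, tissue, breed, rfi, diet,
#' timepoint, animal.
#'
#' @param counts gene-by-sample matrix.
#' @param path file path.
#' @return `read_counts` returns an integer matrix; `read_design` a
#'   data.frame; the writers return `path` invisibly.
#' @name coexnet-io
NULL

#' @rdname coexnet-io
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coexnet-io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname coexnet-io
#' @param design sample design data.frame.
#' @export
write_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname coexnet-io
#' @export
read_design <- function(path) {
  need <- c("sample", "tissue", "breed", "rfi", "diet", "timepoint", "animal")
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0) {
    stop("design file lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

default_thresholds <- function() {
  list(cpm_threshold = 1, min_fraction = 0.5, top_fraction = 0.05,
       abs_r = 0.8, sd_mult = 2, vwp = 0.2, degree_cutoff = 2,
       prior_df = 20)
}

#' Validate a pipeline configuration
#'
#' A configuration is a plain list with either a `simulate` block
#' (arguments for [sim_design()] plus an optional `params` list for
#' [sim_params()]) or input paths (`counts_file`, `design_file`, `tf_file`,
#' `secretome_file`); optional `gmt_file`; an output directory `outdir`; an
#' integer `seed`; optional threshold overrides (`cpm_threshold`,
#' `min_fraction`, `top_fraction`, `abs_r`, `sd_mult`, `vwp`,
#' `degree_cutoff`, `prior_df`) and `stages` (`"all"` or `"simulate"`).
#' Unknown keys are rejected and all problems are reported together.
#'
#' @param raw named list.
#' @return validated config (class `coex_config`) with defaults filled in.
#' @export
validate_config <- function(raw) {
  if (!is.list(raw)) stop("configuration must be a list")
  known <- c("simulate", "counts_file", "design_file", "tf_file",
             "secretome_file", "gmt_file", "outdir", "seed", "stages",
             names(default_thresholds()))
  errs <- character(0)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(c(default_thresholds(),
                      list(seed = 1L, stages = "all", outdir = NULL)),
                    raw[intersect(names(raw), known)])
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$top_fraction) && cfg$top_fraction > 0 &&
        cfg$top_fraction <= 0.5, "'top_fraction' must lie in (0, 0.5]")
  chk(is.numeric(cfg$abs_r) && cfg$abs_r >= 0 && cfg$abs_r <= 1,
      "'abs_r' must lie in [0, 1]")
  chk(is.numeric(cfg$vwp) && cfg$vwp >= 0 && cfg$vwp < 1,
      "'vwp' must lie in [0, 1)")
  chk(is.numeric(cfg$min_fraction) && cfg$min_fraction > 0 &&
        cfg$min_fraction <= 1, "'min_fraction' must lie in (0, 1]")
  chk(is.numeric(cfg$cpm_threshold) && cfg$cpm_threshold >= 0,
      "'cpm_threshold' must be non-negative")
  chk(is.numeric(cfg$sd_mult) && cfg$sd_mult >= 0,
      "'sd_mult' must be non-negative")
  chk(cfg$stages %in% c("all", "simulate"),
      "'stages' must be \"all\" or \"simulate\"")
  has_sim <- !is.null(cfg$simulate)
  has_files <- !is.null(cfg$counts_file) && !is.null(cfg$design_file)
  if (!has_sim && !has_files) {
    errs <- c(errs,
              "either a 'simulate' block or 'counts_file' + 'design_file' is required")
  }
  if (!has_sim && cfg$stages == "all" &&
      (is.null(cfg$tf_file) || is.null(cfg$secretome_file))) {
    errs <- c(errs, "'tf_file' and 'secretome_file' are required with file input")
  }
  if (length(errs) > 0) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = "coex_config")
}

stage_seed <- function(seed, offset) (as.integer(seed) + 1009L * offset) %% 2147483647L

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full co-expression analysis pipeline
#'
#' Orchestrates simulate (or load) -> per-contrast differential expression
#' and top-fraction selection -> node annotation and RIF regulator scoring
#' -> per-contrast PCIT network inference -> labelled-network merge ->
#' MCODE-style clustering -> hub / first-neighbour / overlap summaries.
#' All stage outputs are written under `config$outdir` together with a
#' manifest of file checksums; a rerun with the same configuration and seed
#' reproduces the manifest bit for bit.
#'
#' @param config a list accepted by [validate_config()].
#' @return an object of class `coex_run`: list with `config`, `manifest`,
#'   `de` (per-contrast results), `deg_sets`, `rif`, `network`, `clusters`,
#'   `hubs`, `overlap_deg`, `overlap_network`, `truth` (if simulated) and
#'   `enrichment` (if a GMT file is given).
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  outdir <- cfg$outdir
  if (is.null(outdir)) stop("'outdir' is required to run the pipeline")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(file, stage) {
    manifest[[length(manifest) + 1L]] <<-
      data.frame(file = basename(file), stage = stage,
                 md5 = unname(tools::md5sum(file)),
                 stringsAsFactors = FALSE)
  }

  ## ---- stage: inputs (simulate or load) ----
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    par_args <- sim_args$params
    sim_args$params <- NULL
    if (is.null(sim_args$seed)) sim_args$seed <- stage_seed(cfg$seed, 1L)
    design <- do.call(sim_design, sim_args)
    params <- do.call(sim_params, par_args %||% list())
    sim <- simulate_counts(design, params)
    counts <- sim$counts; samples <- sim$samples; truth <- sim$truth
    sim_design_obj <- design
    note(write_counts(counts, file.path(outdir, "counts.tsv")), "simulate")
    note(write_design(samples, file.path(outdir, "design.tsv")), "simulate")
    tr <- truth
    tr$de_genes <- lapply(tr$de_genes, function(df) as.list(df))
    tr$modules <- as.list(tr$modules[!is.na(tr$modules)])
    tr$dispersion <- NULL; tr$baseline <- NULL
    jsonlite::write_json(tr, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    note(file.path(outdir, "truth.json"), "simulate")
    fx <- write_fixture_lists(truth,
                              file.path(outdir, "tf_list.txt"),
                              file.path(outdir, "secretome_list.txt"))
    note(fx["tf"], "simulate"); note(fx["secretome"], "simulate")
    tf_ids <- truth$tf_ids; sec_ids <- truth$secretome_ids
    tf_file <- fx[["tf"]]; sec_file <- fx[["secretome"]]
  } else {
    counts <- read_counts(cfg$counts_file)
    samples <- read_design(cfg$design_file)
    tf_file <- cfg$tf_file; sec_file <- cfg$secretome_file
    tissues <- unique(samples$tissue)
    sim_design_obj <- NULL
  }
  if (cfg$stages == "simulate") {
    manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
    write_tsv(manifest, file.path(outdir, "manifest.tsv"))
    return(structure(list(config = cfg, manifest = manifest, truth = truth),
                     class = "coex_run"))
  }

  ## ---- stage: contrasts ----
  contrasts <- if (!is.null(sim_design_obj)) {
    design_contrasts(sim_design_obj)
  } else {
    dsg <- sim_design(n_genes = nrow(counts),
                      breeds = unique(samples$breed),
                      rfi_groups = unique(samples$rfi),
                      diet_phases = unique(samples$diet),
                      tissues = unique(samples$tissue),
                      n_per_cell = max(2L, as.integer(
                        nrow(samples) / max(1, length(unique(samples$tissue))) /
                          max(1, length(unique(samples$diet))) / 4L)),
                      seed = cfg$seed)
    design_contrasts(dsg)
  }

  ## ---- stage: differential expression ----
  de <- list(); deg_sets <- list()
  for (lab in names(contrasts)) {
    res <- de_test(counts, samples, contrasts[[lab]],
                   cpm_threshold = cfg$cpm_threshold,
                   min_fraction = cfg$min_fraction,
                   prior_df = cfg$prior_df)
    de[[lab]] <- res
    deg_sets[[lab]] <- select_top_fraction(res, cfg$top_fraction)
    out <- as.data.frame(res)
    out$selected <- out$gene %in% deg_sets[[lab]]
    note(write_tsv(out, file.path(outdir, paste0("de_", lab, ".tsv"))), "de")
    message(sprintf("[de] %s: %d genes tested, %d selected",
                    lab, attr(res, "n_tested"), length(deg_sets[[lab]])))
  }

  ## ---- per-tissue expression for correlation-based stages ----
  tissues <- unique(samples$tissue)
  logcpm <- list(); expressed <- list()
  for (tis in tissues) {
    sel <- samples$tissue == tis
    cts <- counts[, samples$sample[sel], drop = FALSE]
    keep <- filter_expressed(compute_cpm(cts),
                             threshold = cfg$cpm_threshold,
                             min_fraction = cfg$min_fraction)
    cts <- cts[keep, , drop = FALSE]
    nf <- tmm_factors(cts)
    logcpm[[tis]] <- compute_cpm(cts, nf, log = TRUE)
    expressed[[tis]] <- rownames(cts)
  }

  ## ---- stage: node annotation + RIF ----
  universe <- rownames(counts)
  nodes <- annotate_nodes(universe, tf_file, sec_file, deg_sets = deg_sets)
  rif <- list()
  for (lab in names(contrasts)) {
    ct <- contrasts[[lab]]
    tis <- ct$tissue
    regs <- intersect(nodes$gene[nodes$is_tf], expressed[[tis]])
    targets <- intersect(deg_sets[[lab]], expressed[[tis]])
    if (length(regs) >= 2 && length(targets) >= 1) {
      rt <- rif_for_contrast(logcpm[[tis]], samples[samples$tissue == tis, ],
                             ct, regs, targets)
      rt$contrast <- lab
      rif[[lab]] <- rt
      note(write_tsv(as.data.frame(rt),
                     file.path(outdir, paste0("rif_", lab, ".tsv"))), "rif")
    }
  }

  ## ---- stage: PCIT per contrast ----
  edge_lists <- list()
  for (lab in names(contrasts)) {
    ct <- contrasts[[lab]]
    tis <- ct$tissue
    node_set <- intersect(
      unique(c(deg_sets[[lab]],
               nodes$gene[nodes$is_tf | nodes$is_secretome])),
      expressed[[tis]])
    if (length(node_set) < 2) next
    R <- cor(t(logcpm[[tis]][node_set, , drop = FALSE]))
    R[is.na(R)] <- 0; diag(R) <- 1
    el <- significant_edges(R, abs_threshold = cfg$abs_r,
                            sd_mult = cfg$sd_mult, label = lab)
    edge_lists[[lab]] <- el
    note(write_tsv(el, file.path(outdir, paste0("edges_", lab, ".tsv"))),
         "network")
    message(sprintf("[pcit] %s: %d nodes in run, %d significant edges",
                    lab, length(node_set), nrow(el)))
  }
  network <- build_network(edge_lists, nodes, labels = names(contrasts))
  note(write_network(network, file.path(outdir, "network.graphml"),
                     "graphml"), "network")

  ## ---- stage: clustering ----
  clusters <- mcode_clusters(network, vwp = cfg$vwp,
                             degree_cutoff = cfg$degree_cutoff)
  if (length(clusters) > 0) {
    cl_df <- do.call(rbind, lapply(seq_along(clusters), function(i) {
      cl <- clusters[[i]]
      data.frame(cluster = i, score = cl$score, size = length(cl$members),
                 density = cl$density, seed = cl$seed,
                 members = paste(cl$members, collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  } else {
    cl_df <- data.frame(cluster = integer(0), score = numeric(0),
                        size = integer(0), density = numeric(0),
                        seed = character(0), members = character(0))
  }
  note(write_tsv(cl_df, file.path(outdir, "clusters.tsv")), "cluster")
  message(sprintf("[mcode] %d cluster(s) found", length(clusters)))

  ## ---- stage: summaries ----
  hubs <- hub_per_contrast(network)
  note(write_tsv(hubs$table, file.path(outdir, "hubs.tsv")), "summary")
  tfnet <- tf_first_neighbors(network, hubs$table$hub)
  note(write_network(tfnet, file.path(outdir, "tf_neighbors.graphml"),
                     "graphml"), "summary")
  per_label_nodes <- lapply(names(contrasts), function(lab) {
    el <- network$edges[network$edges$label == lab, , drop = FALSE]
    unique(c(el$gene_a, el$gene_b))
  })
  names(per_label_nodes) <- names(contrasts)
  overlap_deg <- list(); overlap_net <- list()
  for (tis in tissues) {
    labs <- names(contrasts)[vapply(contrasts, function(ct)
      ct$tissue == tis, logical(1))]
    if (length(labs) >= 2) {
      overlap_deg[[tis]] <- contrast_overlap(deg_sets[labs])
      overlap_net[[tis]] <- contrast_overlap(per_label_nodes[labs])
    }
  }
  ov_json <- list(deg = lapply(overlap_deg, function(o)
                    as.list(setNames(o$regions$count, rownames(o$regions)))),
                  network = lapply(overlap_net, function(o)
                    as.list(setNames(o$regions$count, rownames(o$regions)))))
  jsonlite::write_json(ov_json, file.path(outdir, "overlaps.json"),
                       auto_unbox = TRUE, digits = NA)
  note(file.path(outdir, "overlaps.json"), "summary")

  enrichment <- NULL
  if (!is.null(cfg$gmt_file) && length(clusters) > 0) {
    sets <- read_gmt(cfg$gmt_file)
    enrichment <- lapply(seq_along(clusters), function(i) {
      enrichment_hypergeom(clusters[[i]]$members, sets, universe)
    })
    enr_df <- do.call(rbind, lapply(seq_along(enrichment), function(i)
      cbind(cluster = i, enrichment[[i]])))
    note(write_tsv(enr_df, file.path(outdir, "enrichment.tsv")), "summary")
  }

  manifest <- do.call(rbind, c(manifest, make.row.names = FALSE))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))

  structure(list(config = cfg, manifest = manifest, de = de,
                 deg_sets = deg_sets, rif = rif, network = network,
                 clusters = clusters, hubs = hubs,
                 overlap_deg = overlap_deg, overlap_network = overlap_net,
                 enrichment = enrichment, truth = truth),
            class = "coex_run")
}

#' @export
print.coex_run <- function(x, ...) {
  cat("coexnet pipeline run\n")
  cat("  artifacts:", nrow(x$manifest), "files in",
      x$config$outdir %||% "<no outdir>", "\n")
  if (!is.null(x$de)) {
    cat("  contrasts:", paste(names(x$de), collapse = ", "), "\n")
    cat("  network:", nrow(x$network$nodes), "nodes /",
        nrow(x$network$edges), "labelled edges\n")
    cat("  clusters:", length(x$clusters), "\n")
  }
  invisible(x)
}

#' @export
summary.coex_run <- function(object, ...) {
  x <- object
  if (is.null(x$de)) {
    cat("simulate-only run;", nrow(x$manifest), "artifacts\n")
    return(invisible(x))
  }
  de_tab <- data.frame(
    label = names(x$de),
    n_tested = vapply(x$de, attr, integer(1), "n_tested"),
    n_selected = vapply(x$deg_sets, length, integer(1)),
    row.names = NULL)
  cat("Differential expression:\n"); print(de_tab)
  cat("\nNetwork edges per contrast:\n"); print(x$network$label_counts)
  cat("\nHubs:\n"); print(x$hubs$table)
  cat("\nClusters:", length(x$clusters), "\n")
  invisible(de_tab)
}
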