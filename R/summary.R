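#' Most interconnected gene (hub) per contrast
#'
#' Degree counts only edges of the given label, so a pair significant in
#' two contrasts contributes once to each. Ties are broken by gene ID. The
#' degree share is the hub's degree divided by that label's edge count.
#'
#' @param network a `labeled_network`.
#' @return list with `table` (data.frame: label, hub, degree, share,
#'   n_edges) and `tf_neighbors` (named list of the hub's transcription-
#'   factor first neighbours per label). Labels with no edges are omitted
#'   with a warning.
#' @export
hub_per_contrast <- function(network) {
  e <- network$edges
  labs <- names(network$label_counts)
  present <- labs[network$label_counts > 0]
  absent <- labs[network$label_counts == 0]
  if (length(absent) > 0) {
    warning("no edges for contrast(s): ", paste(absent, collapse = ", "))
  }
  if (length(present) == 0) stop("network has no edges")
  is_tf <- setNames(network$nodes$is_tf, network$nodes$gene)
  rows <- list(); tf_nb <- list()
  for (lab in present) {
    el <- e[e$label == lab, , drop = FALSE]
    deg <- table(c(el$gene_a, el$gene_b))
    top <- max(deg)
    hub <- sort(names(deg)[deg == top])[1]
    nbs <- sort(unique(c(el$gene_b[el$gene_a == hub],
                         el$gene_a[el$gene_b == hub])))
    rows[[lab]] <- data.frame(label = lab, hub = hub,
                              degree = as.integer(top),
                              share = as.integer(top) / nrow(el),
                              n_edges = nrow(el),
                              stringsAsFactors = FALSE)
    tf_nb[[lab]] <- nbs[is_tf[nbs] %in% TRUE]
  }
  tab <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(table = tab, tf_neighbors = tf_nb)
}

#' First-neighbour transcription-factor subnetwork of the hubs
#'
#' Restricts the network to edges joining a hub to a transcription-factor
#' neighbour (labels preserved). Hubs with no TF neighbour remain as
#' isolated nodes of the subnetwork.
#'
#' @param network a `labeled_network`.
#' @param hubs character vector of hub gene IDs (must be network nodes).
#' @param node_flags node annotation table; defaults to `network$nodes`.
#' @return a `labeled_network` over the hubs and their TF neighbours.
#' @export
tf_first_neighbors <- function(network, hubs, node_flags = network$nodes) {
  missing <- setdiff(hubs, network$nodes$gene)
  if (length(missing) > 0) {
    stop("hub(s) absent from the network: ", paste(missing, collapse = ", "))
  }
  is_tf <- setNames(node_flags$is_tf, node_flags$gene)
  e <- network$edges
  tf_of <- function(g) is_tf[g] %in% TRUE
  keep <- (e$gene_a %in% hubs & tf_of(e$gene_b)) |
          (e$gene_b %in% hubs & tf_of(e$gene_a))
  sub_edges <- e[keep, , drop = FALSE]
  sub_nodes_ids <- sort(unique(c(hubs, sub_edges$gene_a, sub_edges$gene_b)))
  nodes <- node_flags[node_flags$gene %in% sub_nodes_ids, , drop = FALSE]
  rownames(sub_edges) <- rownames(nodes) <- NULL
  cnt <- table(factor(sub_edges$label, levels = names(network$label_counts)))
  structure(list(edges = sub_edges, nodes = nodes,
                 label_counts = setNames(as.integer(cnt), names(cnt))),
            class = "labeled_network")
}

#' Exclusive Venn regions of named gene sets
#'
#' For k sets, all `2^k - 1` exclusive membership regions with their counts
#' and gene identities.
#'
#' @param sets named list (length >= 2) of character vectors.
#' @return list with `regions` (data.frame: one indicator column per set,
#'   `count`) and `genes` (list of gene vectors, named by region, e.g.
#'   `"A&B"`).
#' @export
contrast_overlap <- function(sets) {
  if (length(sets) < 2) stop("at least two sets are required")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("'sets' must be named")
  }
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) universe %in% s,
                 logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  region_name <- apply(combos, 1, function(z)
    paste(names(sets)[as.logical(z)], collapse = "&"))
  genes <- lapply(seq_len(nrow(combos)), function(i) {
    z <- as.logical(combos[i, ])
    sel <- apply(memb, 1, function(row) all(row == z))
    universe[sel]
  })
  names(genes) <- region_name
  regions <- cbind(combos,
                   count = vapply(genes, length, integer(1)))
  rownames(regions) <- region_name
  list(regions = regions, genes = genes)
}

#' Hypergeometric over-representation of a gene cluster
#'
#' Upper-tail hypergeometric test of the overlap between the cluster and
#' each gene set, with sets first intersected with the universe and
#' p-values BH-adjusted across sets. A generic stand-in for pathway
#' enrichment of network clusters.
#'
#' @param cluster_genes character vector, a subset of `universe`.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of candidate genes.
#' @return data.frame with columns `set`, `set_size`, `overlap`, `p`, `q`,
#'   ordered by `p`.
#' @export
enrichment_hypergeom <- function(cluster_genes, gene_sets, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  if (!all(cluster_genes %in% universe)) {
    stop("cluster genes must be contained in the universe")
  }
  cluster_genes <- unique(cluster_genes)
  n_u <- length(universe); n_c <- length(cluster_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(s, cluster_genes))
    p <- phyper(k - 1, length(s), n_u - length(s), n_c, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$set), , drop = FALSE]
}

#' Read a GMT gene-set file
#' @param path GMT file path.
#' @return named list of gene-ID character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Precision of network edges with respect to planted modules
#'
#' Of the distinct edges touching at least one module-assigned gene, the
#' fraction joining two genes of the same module. Used to benchmark PCIT
#' output against the simulator's ground truth.
#'
#' @param network a `labeled_network`.
#' @param modules named integer vector of module assignments (NA = none),
#'   as in the `truth$modules` element of [simulate_counts()].
#' @return precision in `[0, 1]`, or `NA` if no edge touches a module gene.
#' @export
module_edge_precision <- function(network, modules) {
  e <- unique(network$edges[, c("gene_a", "gene_b")])
  ma <- modules[e$gene_a]
  mb <- modules[e$gene_b]
  touch <- !is.na(ma) | !is.na(mb)
  if (!any(touch)) return(NA_real_)
  tp <- sum(touch & !is.na(ma) & !is.na(mb) & ma == mb)
  tp / sum(touch)
}
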