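#' First-order partial correlation
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))` —
#' the correlation of x and y after removing the linear effect of z.
#' Vectorised over its arguments. When `|r_xz| = 1` or `|r_yz| = 1` the
#' partial correlation is undefined; 0 is returned with a warning.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations, each in `[-1, 1]`.
#' @return numeric vector of partial correlations.
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xy, r_xz, r_yz)) > 1 + 1e-12)) {
    stop("correlations must lie in [-1, 1]")
  }
  den <- (1 - r_xz^2) * (1 - r_yz^2)
  bad <- den <= 0
  if (any(bad)) {
    warning("partial correlation undefined for ", sum(bad),
            " trio(s) with a unit conditioning correlation; returning 0")
  }
  out <- rep(0, length(den))
  out[!bad] <- (r_xy - r_xz * r_yz)[!bad] / sqrt(den[!bad])
  out
}

#' PCIT trio-elimination filter
#'
#' For every trio of nodes (x, y, z) the three first-order partial
#' correlations are computed and the information-theoretic tolerance
#' `eps = mean(|partial / direct|)` is taken over the trio's edges with
#' non-zero direct correlation. The edge (x, y) is eliminated if some third
#' node z satisfies both `|r_xy| < eps * |r_xz|` and
#' `|r_xy| < eps * |r_yz|`; edges never dominated this way are retained.
#' With fewer than three nodes every edge is retained.
#'
#' @param R symmetric correlation matrix (diagonal 1).
#' @return symmetric logical matrix of retained edges (diagonal `FALSE`).
#' @export
pcit_filter <- function(R) {
  R <- as.matrix(R)
  n <- nrow(R)
  if (n != ncol(R)) stop("'R' must be square")
  if (max(abs(R - t(R))) > 1e-12) stop("'R' must be symmetric")
  if (any(abs(R) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  keep <- if (n < 3) {
    k <- matrix(TRUE, n, n); diag(k) <- FALSE; k
  } else {
    pcit_keep_cpp(R)
  }
  dimnames(keep) <- dimnames(R)
  keep
}

#' Significant co-expression edges for one contrast run
#'
#' An edge is reported when it (i) survives PCIT trio elimination, (ii) has
#' `|r| >= abs_threshold` (0.80 by default) and (iii) has `|r|` at least
#' `sd_mult` standard deviations above the mean of `|r|` over all
#' off-diagonal pairs of the run's matrix. When the off-diagonal `|r|`
#' values are all identical the SD rule is degenerate and only the absolute
#' threshold (plus PCIT retention) applies, with a warning.
#'
#' @param R symmetric correlation matrix with gene IDs as dimnames.
#' @param retained logical retained-edge matrix; computed with
#'   [pcit_filter()] if missing.
#' @param abs_threshold absolute-correlation threshold.
#' @param sd_mult multiplier for the mean + k*SD rule.
#' @param label optional contrast label attached to every edge.
#' @return data.frame with columns `gene_a`, `gene_b` (lexically ordered
#'   within each row), `r` and `label`.
#' @export
significant_edges <- function(R, retained = NULL, abs_threshold = 0.8,
                              sd_mult = 2, label = NA_character_) {
  R <- as.matrix(R)
  if (is.null(rownames(R))) {
    rownames(R) <- colnames(R) <- paste0("n", seq_len(nrow(R)))
  }
  if (is.null(retained)) retained <- pcit_filter(R)
  ut <- upper.tri(R)
  absr <- abs(R[ut])
  s <- sd(absr)
  cut_sd <- if (is.na(s) || s == 0) {
    warning("degenerate |r| spread; applying the absolute threshold only")
    -Inf
  } else {
    mean(absr) + sd_mult * s
  }
  pass <- ut & retained & abs(R) >= abs_threshold & abs(R) >= cut_sd
  idx <- which(pass, arr.ind = TRUE)
  a <- rownames(R)[idx[, 1]]
  b <- colnames(R)[idx[, 2]]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(gene_a = a, gene_b = b, r = R[idx],
                    label = rep(label, length(a)),
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Merge per-contrast edge lists into one labelled network
#'
#' The network is a union multigraph keyed by (gene pair, contrast label):
#' the same pair may carry one edge per contrast in which it is
#' significant. Nodes are kept only if they have at least one significant
#' edge.
#'
#' @param edge_lists named list of [significant_edges()] data.frames; names
#'   are used as labels when an edge list lacks them.
#' @param nodes node annotation data.frame from [annotate_nodes()].
#' @param labels the set of admissible contrast labels.
#' @return an object of class `labeled_network`: list with `edges`
#'   (gene_a, gene_b, r, label), `nodes` (annotation of connected nodes)
#'   and `label_counts`.
#' @export
build_network <- function(edge_lists, nodes,
                          labels = c("RL", "RM", "DL", "DM", "BL", "BM")) {
  if (length(edge_lists) == 0) stop("no edge lists supplied")
  for (i in seq_along(edge_lists)) {
    el <- edge_lists[[i]]
    if (!"label" %in% names(el) || all(is.na(el$label))) {
      el$label <- rep(names(edge_lists)[i], nrow(el))
      edge_lists[[i]] <- el
    }
  }
  edges <- do.call(rbind, c(edge_lists, make.row.names = FALSE))
  if (is.null(edges)) edges <- data.frame(gene_a = character(0),
                                          gene_b = character(0),
                                          r = numeric(0),
                                          label = character(0))
  bad <- setdiff(unique(edges$label), labels)
  if (length(bad) > 0) {
    stop("unknown contrast label(s): ", paste(bad, collapse = ", "))
  }
  if (any(edges$gene_a == edges$gene_b)) stop("self-loops are not allowed")
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b", "label")]), ,
                 drop = FALSE]
  edges <- edges[order(edges$label, edges$gene_a, edges$gene_b), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  connected <- unique(c(edges$gene_a, edges$gene_b))
  node_tab <- nodes[nodes$gene %in% connected, , drop = FALSE]
  extra <- setdiff(connected, node_tab$gene)
  if (length(extra) > 0) {
    add <- data.frame(gene = extra, is_tf = FALSE, is_secretome = FALSE,
                      stringsAsFactors = FALSE)
    for (cl in setdiff(names(node_tab), names(add))) add[[cl]] <- FALSE
    node_tab <- rbind(node_tab, add[, names(node_tab), drop = FALSE])
  }
  node_tab <- node_tab[order(node_tab$gene), , drop = FALSE]
  rownames(node_tab) <- NULL
  counts <- table(factor(edges$label, levels = labels))
  structure(list(edges = edges, nodes = node_tab,
                 label_counts = setNames(as.integer(counts), names(counts))),
            class = "labeled_network")
}

#' @export
print.labeled_network <- function(x, ...) {
  pairs <- unique(x$edges[, c("gene_a", "gene_b")])
  cat("Labelled co-expression network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "labelled edges,", nrow(pairs), "distinct pairs\n")
  cat("Edges per contrast:\n")
  print(x$label_counts)
  invisible(x)
}

#' Convert a labelled network to an igraph graph
#'
#' @param network a `labeled_network`.
#' @param collapse if `TRUE`, parallel labelled edges between the same pair
#'   are merged into one simple edge (labels joined with `;`); otherwise a
#'   multigraph with an edge per label is returned.
#' @return an [igraph::graph] with node attributes `is_tf`/`is_secretome`
#'   and edge attributes `r` and `label`.
#' @export
as_igraph <- function(network, collapse = FALSE) {
  stopifnot(inherits(network, "labeled_network"))
  e <- network$edges
  if (collapse && nrow(e) > 0) {
    key <- paste(e$gene_a, e$gene_b, sep = "\r")
    lab <- tapply(e$label, key, function(l) paste(sort(l), collapse = ";"))
    rr <- tapply(e$r, key, function(v) v[which.max(abs(v))])
    parts <- do.call(rbind, strsplit(names(lab), "\r", fixed = TRUE))
    e <- data.frame(gene_a = parts[, 1], gene_b = parts[, 2],
                    r = as.numeric(rr), label = as.character(lab),
                    stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = network$nodes[, c("gene", setdiff(names(network$nodes), "gene")),
                             drop = FALSE])
  g
}

#' Export a labelled network to GraphML or GML
#'
#' @param network a `labeled_network`.
#' @param path output file path.
#' @param format `"graphml"` or `"gml"`.
#' @return invisibly, `path`.
#' @export
write_network <- function(network, path, format = c("graphml", "gml")) {
  format <- match.arg(format)
  g <- as_igraph(network, collapse = FALSE)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
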