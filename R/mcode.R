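#' MCODE-style vertex weights
#'
#' The weight of a vertex v is `k * density(H)` where H is the highest
#' k-core of the closed neighbourhood `N[v]` (v plus its neighbours), k is
#' that core's level, and density is `2E / (V (V - 1))`. Isolated vertices
#' weigh 0.
#'
#' @param graph an undirected [igraph::graph] (parallel edges and loops are
#'   collapsed first).
#' @return named numeric vector of weights over vertices.
#' @export
vertex_weights <- function(graph) {
  graph <- igraph::simplify(igraph::as_undirected(graph))
  vs <- igraph::V(graph)
  w <- numeric(length(vs))
  names(w) <- vs$name %||% as.character(seq_along(vs))
  deg <- igraph::degree(graph)
  for (i in seq_along(vs)) {
    if (deg[i] == 0) next
    nb <- c(i, as.integer(igraph::neighbors(graph, i)))
    sub <- igraph::induced_subgraph(graph, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    hs <- igraph::induced_subgraph(sub, which(core == kmax))
    nv <- igraph::vcount(hs)
    dens <- if (nv < 2) 0 else
      2 * igraph::ecount(hs) / (nv * (nv - 1))
    w[i] <- kmax * dens
  }
  w
}

#' MCODE-style seeded complex detection
#'
#' Vertices with degree below `degree_cutoff` are ignored (weight treated
#' as 0). Remaining vertices seed clusters in decreasing weight order (ties
#' broken by vertex name); from each unvisited seed a breadth-first
#' expansion adds unvisited neighbours whose weight exceeds
#' `(1 - vwp) * seed_weight`. Members join at most one cluster. With
#' `haircut`, singly connected members are peeled off (the cluster is
#' reduced to the 2-core of its induced subgraph); with `fluff`, unclustered
#' neighbours whose closed-neighbourhood density exceeds `fluff_density`
#' are appended (they may then appear in several clusters). Clusters of
#' fewer than two vertices are dropped; the rest are scored
#' `density * size` and returned in decreasing score order.
#'
#' @param graph an undirected [igraph::graph].
#' @param weights optional precomputed [vertex_weights()].
#' @param vwp vertex weight percentage (node-score cutoff) in `[0, 1)`.
#' @param degree_cutoff minimum degree for a vertex to be scored/seeded.
#' @param haircut remove singly connected cluster members.
#' @param fluff append dense unclustered neighbours.
#' @param fluff_density closed-neighbourhood density threshold for fluff.
#' @return object of class `cluster_set`: list of clusters, each with
#'   `members`, `seed`, `density`, `score`.
#' @export
find_complexes <- function(graph, weights = NULL, vwp = 0.2,
                           degree_cutoff = 2, haircut = TRUE, fluff = FALSE,
                           fluff_density = 0.2) {
  if (vwp < 0 || vwp >= 1) stop("'vwp' must lie in [0, 1)")
  graph <- igraph::simplify(igraph::as_undirected(graph))
  if (igraph::vcount(graph) == 0) {
    return(structure(list(), class = "cluster_set"))
  }
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  if (is.null(weights)) weights <- vertex_weights(graph)
  nm <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  w <- ifelse(deg < degree_cutoff, 0, weights[nm])
  names(w) <- nm

  order_idx <- order(-w, nm)
  visited <- setNames(rep(FALSE, length(nm)), nm)
  clusters <- list()
  for (i in order_idx) {
    seed <- nm[i]
    if (visited[seed] || w[seed] <= 0) next
    thr <- (1 - vwp) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    queue <- seed
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (u in igraph::neighbors(graph, v)$name) {
        if (!visited[u] && w[u] > thr) {
          visited[u] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    sub <- igraph::induced_subgraph(graph, members)
    if (haircut && igraph::vcount(sub) > 2) {
      core <- igraph::coreness(sub)
      sub <- igraph::induced_subgraph(sub, which(core >= 2))
    }
    members <- sort(igraph::V(sub)$name)
    if (fluff) {
      cand <- setdiff(unique(unlist(lapply(members, function(v)
        igraph::neighbors(graph, v)$name))), c(members, nm[visited]))
      for (u in cand) {
        nbu <- c(u, igraph::neighbors(graph, u)$name)
        subu <- igraph::induced_subgraph(graph, nbu)
        nv <- igraph::vcount(subu)
        densu <- if (nv < 2) 0 else
          2 * igraph::ecount(subu) / (nv * (nv - 1))
        if (densu > fluff_density) members <- c(members, u)
      }
      members <- sort(unique(members))
      sub <- igraph::induced_subgraph(graph, members)
    }
    nv <- igraph::vcount(sub)
    if (nv < 2) next
    dens <- 2 * igraph::ecount(sub) / (nv * (nv - 1))
    clusters[[length(clusters) + 1L]] <-
      list(members = sort(igraph::V(sub)$name), seed = seed,
           density = dens, score = dens * nv)
  }
  if (length(clusters) > 0) {
    ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
                 vapply(clusters, `[[`, character(1), "seed"))
    clusters <- clusters[ord]
  }
  structure(clusters, class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(length(x), "cluster(s)\n")
  for (i in seq_along(x)) {
    cl <- x[[i]]
    cat(sprintf("  %d: size %d, density %.3f, score %.3f, seed %s\n",
                i, length(cl$members), cl$density, cl$score, cl$seed))
  }
  invisible(x)
}

#' Cluster a labelled network with MCODE-style detection
#'
#' The labelled multigraph is collapsed to a simple graph for clustering;
#' each cluster is annotated with the contrast composition of its internal
#' labelled edges.
#'
#' @param network a `labeled_network` (see [build_network()]).
#' @inheritParams find_complexes
#' @return a `cluster_set`; each cluster additionally carries
#'   `label_composition`, a table of internal edge counts per contrast.
#' @export
mcode_clusters <- function(network, vwp = 0.2, degree_cutoff = 2,
                           haircut = TRUE, fluff = FALSE) {
  g <- as_igraph(network, collapse = TRUE)
  cs <- find_complexes(g, vwp = vwp, degree_cutoff = degree_cutoff,
                       haircut = haircut, fluff = fluff)
  e <- network$edges
  for (i in seq_along(cs)) {
    m <- cs[[i]]$members
    inside <- e$gene_a %in% m & e$gene_b %in% m
    cs[[i]]$label_composition <- table(e$label[inside])
  }
  cs
}
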