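toy_network <- function() {
  nodes <- data.frame(gene = c("hub", "t1", "t2", "t3", "x1", "x2", "y"),
                      is_tf = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
                      is_secretome = FALSE)
  rl <- data.frame(gene_a = "hub",
                   gene_b = c("t1", "t2", "t3", "x1", "x2"),
                   r = 0.9, label = "RL")
  dl <- data.frame(gene_a = c("t1", "x1"), gene_b = c("y", "y"),
                   r = 0.85, label = "DL")
  build_network(list(RL = rl, DL = dl), nodes)
}

test_that("hub detection counts labelled degree with ID tie-breaks", {
  net <- toy_network()
  hubs <- suppressWarnings(hub_per_contrast(net))
  rl <- hubs$table[hubs$table$label == "RL", ]
  expect_equal(rl$hub, "hub")
  expect_equal(rl$degree, 5L)
  expect_equal(rl$share, 1)
  # DL: y has degree 2 over 2 edges -> share 1
  dl <- hubs$table[hubs$table$label == "DL", ]
  expect_equal(dl$hub, "y")
  expect_equal(dl$degree, 2L)
  # TF first neighbours of the RL hub
  expect_setequal(hubs$tf_neighbors$RL, c("t1", "t2", "t3"))
  # single labelled edge: tie broken by gene ID, share 1
  nodes <- data.frame(gene = c("b", "a"), is_tf = FALSE, is_secretome = FALSE)
  single <- build_network(
    list(RL = data.frame(gene_a = "a", gene_b = "b", r = 0.9, label = "RL")),
    nodes, labels = "RL")
  h1 <- hub_per_contrast(single)
  expect_equal(h1$table$hub, "a")
  expect_equal(h1$table$share, 1)
})

test_that("hub degrees are recomputable from the exported edge list", {
  net <- toy_network()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(path, stringsAsFactors = FALSE)
  hubs <- suppressWarnings(hub_per_contrast(net))
  for (lab in hubs$table$label) {
    el <- back[back$label == lab, ]
    deg <- table(c(el$gene_a, el$gene_b))
    expect_equal(unname(max(deg)),
                 hubs$table$degree[hubs$table$label == lab])
  }
})

test_that("the TF first-neighbour subnetwork keeps only hub-TF edges", {
  net <- toy_network()
  sub <- tf_first_neighbors(net, "hub")
  # 3 TF neighbours of 5 -> 3 edges
  expect_equal(nrow(sub$edges), 3)
  expect_setequal(unique(c(sub$edges$gene_a, sub$edges$gene_b)),
                  c("hub", "t1", "t2", "t3"))
  # a hub with no TF neighbour stays as an isolated node
  sub2 <- tf_first_neighbors(net, "x2")
  expect_equal(nrow(sub2$edges), 0)
  expect_true("x2" %in% sub2$nodes$gene)
  # two hubs sharing a TF neighbour: the TF appears once, with 2 edges
  sub3 <- tf_first_neighbors(net, c("t1", "x1"))
  expect_equal(sum(sub3$nodes$gene == "y"), 1)
  expect_equal(sum(sub3$edges$gene_a == "y" | sub3$edges$gene_b == "y"), 2)
  expect_error(tf_first_neighbors(net, "absent"), "absent")
})

test_that("Venn regions partition the union of the sets", {
  # disjoint sets
  ov <- contrast_overlap(list(A = c("a1", "a2"), B = c("b1")))
  expect_equal(ov$regions["A", "count"], 2)
  expect_equal(ov$regions["B", "count"], 1)
  expect_equal(ov$regions["A&B", "count"], 0)
  # identical sets concentrate in the triple region
  s <- paste0("g", 1:5)
  ov3 <- contrast_overlap(list(A = s, B = s, C = s))
  expect_equal(ov3$regions["A&B&C", "count"], 5)
  expect_equal(sum(ov3$regions$count), 5)
  # planted overlap fixture vs direct enumeration
  A <- paste0("g", 1:10); B <- paste0("g", 6:13); C <- paste0("g", c(9, 10, 14:17))
  ovf <- contrast_overlap(list(A = A, B = B, C = C))
  expect_equal(ovf$regions["A&B&C", "count"], 2)   # g9, g10
  expect_setequal(ovf$genes[["A&B&C"]], c("g9", "g10"))
  expect_equal(sum(ovf$regions$count), length(union(union(A, B), C)))
  # per-set totals: regions containing a set sum to its cardinality
  for (nm in c("A", "B", "C")) {
    expect_equal(sum(ovf$regions$count[ovf$regions[[nm]]]),
                 length(get(nm)))
  }
  expect_error(contrast_overlap(list(A = A)), "at least two")
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  # universe 20, set 5, cluster 5, full overlap: p = 1 / choose(20, 5)
  uni <- paste0("g", 1:20)
  p <- enrichment_hypergeom(uni[1:5], list(S = uni[1:5]), uni)
  expect_equal(p$p, 1 / choose(20, 5))
  # cluster = set = universe -> p = 1
  p1 <- enrichment_hypergeom(uni, list(S = uni), uni)
  expect_equal(p1$p, 1)
  # zero overlap with a small set: p approaches 1 (exact tail sum)
  p0 <- enrichment_hypergeom(uni[1:5], list(S = uni[16:18]), uni)
  exact <- sum(vapply(0:3, function(k)
    choose(3, k) * choose(17, 5 - k) / choose(20, 5), numeric(1)))
  expect_equal(p0$p, 1)          # P(X >= 0) = 1
  expect_equal(exact, 1, tolerance = 1e-12)
  expect_error(enrichment_hypergeom(uni[1:2], list(S = uni), character(0)),
               "empty")
  expect_error(enrichment_hypergeom(c("zz"), list(S = uni), uni),
               "contained")
})

test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  # enumerate all size-4 clusters of a 10-gene universe and compare the
  # upper-tail probability of the observed overlap
  uni <- paste0("g", 1:10)
  set <- uni[1:4]
  draws <- combn(10, 4)
  for (obs in 0:4) {
    p_enum <- mean(apply(draws, 2, function(ix)
      length(intersect(uni[ix], set))) >= obs)
    p_pkg <- stats::phyper(obs - 1, 4, 6, 4, lower.tail = FALSE)
    expect_equal(p_pkg, p_enum, tolerance = 1e-12)
  }
  cl <- uni[c(1, 2, 5, 6)]
  res <- enrichment_hypergeom(cl, list(S = set), uni)
  expect_equal(res$overlap, 2)
  expect_equal(res$p, mean(apply(draws, 2, function(ix)
    length(intersect(uni[ix], set))) >= 2), tolerance = 1e-12)
})

test_that("GMT files are parsed into named gene sets", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("setA", "setB"))
  expect_setequal(sets$setA, c("g1", "g2", "g3"))
})

test_that("module edge precision counts same-module pairs among module edges", {
  nodes <- data.frame(gene = c("m1", "m2", "m3", "n1", "n2"),
                      is_tf = FALSE, is_secretome = FALSE)
  mods <- c(m1 = 1L, m2 = 1L, m3 = 2L, n1 = NA_integer_, n2 = NA_integer_)
  el <- data.frame(gene_a = c("m1", "m1", "m1", "n1"),
                   gene_b = c("m2", "m3", "n1", "n2"),
                   r = 0.9, label = "RL")
  net <- build_network(list(RL = el), nodes)
  # edges touching a module gene: (m1,m2) TP, (m1,m3) cross-module FP,
  # (m1,n1) mixed FP; (n1,n2) not counted
  expect_equal(module_edge_precision(net, mods), 1 / 3)
})
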