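# Network construction semantics and topology metrics against hand-computed
# values on canonical graphs.

test_that("edges require strict |r| > r_min AND p < alpha", {
  taxa <- c("a", "b", "c", "d")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.65      # exactly at threshold: no edge
  r[1, 3] <- r[3, 1] <- 0.9       # strong but not significant
  r[2, 4] <- r[4, 2] <- -0.7      # strong and significant
  p <- matrix(0.01, 4, 4)
  p[1, 3] <- p[3, 1] <- 0.2
  g <- build_network(list(r_matrix = r, taxa = taxa), p)
  edges <- igraph::as_data_frame(g)
  expect_equal(nrow(edges), 1)
  expect_setequal(c(edges$from, edges$to), c("b", "d"))
  expect_equal(edges$r, -0.7)
  # p exactly at alpha excluded too
  p[2, 4] <- p[4, 2] <- 0.05
  expect_equal(igraph::ecount(build_network(list(r_matrix = r, taxa = taxa), p)), 0)
  # isolated nodes are dropped
  expect_equal(igraph::vcount(g), 2)
})

test_that("an all-null estimate yields an empty network with a valid summary", {
  g <- build_network(list(r_matrix = diag(5), taxa = letters[1:5]))
  expect_equal(igraph::vcount(g), 0)
  ts <- topology(g)
  expect_equal(ts$n_nodes, 0)
  expect_equal(ts$n_links, 0)
  expect_true(is.na(ts$density))
})

test_that("topology metrics match hand computations on canonical graphs", {
  gs <- canonical_graphs()
  tri <- topology(gs$triangle)
  expect_equal(tri[, c("density", "avgK", "clustering_coefficient",
                       "centralization_degree", "diameter")],
               data.frame(density = 1, avgK = 2, clustering_coefficient = 1,
                          centralization_degree = 0, diameter = 1))
  star <- topology(gs$star4)     # hub of degree 3, three leaves
  expect_equal(star$avgK, 1.5)
  expect_equal(star$density, 0.5)
  expect_equal(star$centralization_degree, 1)   # Freeman maximum
  expect_equal(star$clustering_coefficient, 0)
  path <- topology(gs$path4)     # degrees 1,2,2,1
  expect_equal(path$avgK, 1.5)
  expect_equal(path$centralization_degree, (1 + 0 + 0 + 1) / (3 * 2))
  expect_equal(path$diameter, 3)
  expect_equal(path$avg_path_length, (3 * 1 + 2 * 2 + 1 * 3) / 6)
  cyc <- topology(gs$cycle5)
  expect_equal(cyc$centralization_degree, 0)
  expect_equal(cyc$density, 0.5)
  expect_equal(cyc$diameter, 2)
  expect_equal(cyc$avg_path_length, 1.5)
  two <- topology(gs$two_triangles)
  # Newman Q with communities = the two components: 2 * (1/2 - 1/4)
  expect_equal(two$modularity, 0.5)
  expect_equal(two$n_communities, 2)
  expect_equal(two$diameter, 1)      # largest component is a triangle
  expect_equal(two$avg_path_length, 1)
  # CD undefined below 3 nodes
  expect_true(is.na(topology(igraph::make_full_graph(2))$centralization_degree))
})

test_that("module composition ranks by size and recovers planted blocks", {
  gs <- canonical_graphs()
  mc <- module_composition(gs$two_triangles)
  expect_equal(nrow(mc), 2)
  expect_equal(mc$n_nodes, c(3, 3))
  expect_equal(mc$module_rank, 1:2)
  expect_equal(nrow(module_composition(build_network(
    list(r_matrix = diag(3), taxa = c("a", "b", "c"))))), 0)

  # planted 2-block structure comes back as the top modules
  cm <- block_correlation_matrix(14, list(1:5, 6:10), 0.9)
  tb <- simulate_otu_table(
    basis_correlation_spec(n_taxa = 14, correlation_matrix = cm,
                           sequencing_depth = 5000), 100, seed = 61)
  est <- sparcc(tb, n_iter = 10, seed = 62)
  g <- build_network(est, r_min = 0.5,
                     domains = setNames(rep("bacteria", 14), est$taxa))
  mc2 <- module_composition(g, top_k = 2)
  got <- lapply(strsplit(mc2$taxa, ","), sort)
  expect_true(all(sort(rownames(tb)[1:5]) %in% unlist(got)))
  expect_true(all(sort(rownames(tb)[6:10]) %in% unlist(got)))
})

test_that("degree-distribution KS statistic matches ECDF arithmetic", {
  gs <- canonical_graphs()
  self <- degree_distribution_ks(gs$cycle5, gs$cycle5)
  expect_equal(self$statistic, 0)
  # star10: one node of degree 9, nine of degree 1; complete10: all degree 9.
  # Max ECDF gap is 9/10 on [1, 9).
  d <- degree_distribution_ks(igraph::make_star(10, mode = "undirected"),
                              igraph::make_full_graph(10))
  expect_equal(d$statistic, 0.9)
  # bounds
  set.seed(63)
  for (i in 1:10) {
    a <- igraph::sample_gnp(15, 0.3); b <- igraph::sample_gnp(15, 0.6)
    if (igraph::vcount(a) == 0 || igraph::vcount(b) == 0) next
    s <- degree_distribution_ks(a, b)$statistic
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_error(degree_distribution_ks(igraph::make_empty_graph(0, directed = FALSE),
                                      gs$cycle5), "non-empty")
})

test_that("network export writes GraphML and a signed edge list", {
  r <- diag(3); r[1, 2] <- r[2, 1] <- 0.8
  g <- build_network(list(r_matrix = r, taxa = c("a", "b", "c")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  el <- export_network(g, gml, csv)
  expect_true(file.exists(gml))
  got <- read.csv(csv)
  expect_equal(got$r, 0.8)
  expect_setequal(c(got$source, got$target), c("a", "b"))
})
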