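# Co-occurrence network construction and topology summaries.
#
# Networks are igraph objects: nodes are OTUs retained after thresholding
# (isolated taxa are dropped — node counts conventionally mean connected
# OTUs), edges carry the signed SparCC correlation as `r` and |r| as
# `weight`.

#' Build a filtered co-occurrence network
#'
#' Keeps an edge between two taxa only when the correlation is both robust
#' (`|r| > r_min`, strictly) and significant (`p < alpha`, strictly).
#'
#' @param estimate a `sparcc_estimate` from [sparcc()], or a list with
#'   `r_matrix` and `taxa`.
#' @param p_matrix pseudo p-value matrix from [bootstrap_pseudo_p()]; if
#'   `NULL` every p is treated as 0 (threshold on |r| alone).
#' @param r_min correlation magnitude threshold (default 0.65).
#' @param alpha significance threshold (default 0.05).
#' @param domains optional named character vector mapping taxon id to
#'   `"bacteria"`/`"fungi"`; stored as a vertex attribute.
#' @return An igraph graph with edge attributes `r` and `weight` (= |r|) and
#'   graph attributes `r_min`, `alpha`.
#' @examples
#' r <- diag(3); r[1, 2] <- r[2, 1] <- 0.9
#' g <- build_network(list(r_matrix = r, taxa = c("a", "b", "c")))
#' igraph::ecount(g)
#' @export
build_network <- function(estimate, p_matrix = NULL, r_min = 0.65,
                          alpha = 0.05, domains = NULL) {
  r <- estimate$r_matrix
  taxa <- estimate$taxa %||% rownames(r) %||% as.character(seq_len(nrow(r)))
  d <- nrow(r)
  if (is.null(p_matrix)) p_matrix <- matrix(0, d, d)
  keep <- abs(r) > r_min & p_matrix < alpha
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = taxa[idx[, 1]], to = taxa[idx[, 2]],
                      r = r[idx], stringsAsFactors = FALSE)
  used <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = used, stringsAsFactors = FALSE))
  igraph::E(g)$weight <- abs(igraph::E(g)$r)
  if (!is.null(domains))
    igraph::V(g)$domain <- unname(domains[igraph::V(g)$name])
  g <- igraph::set_graph_attr(g, "r_min", r_min)
  igraph::set_graph_attr(g, "alpha", alpha)
}

# Community detection used throughout: greedy modularity maximisation,
# weighted by |r| when present. Deterministic, but seeded for uniformity with
# the rest of the pipeline.
detect_communities <- function(network, seed = 1L) {
  w <- igraph::E(network)$weight
  with_seed(seed, igraph::cluster_fast_greedy(network, weights = w))
}

#' Topology summary of a co-occurrence network
#'
#' All metrics conventionally reported for microbial co-occurrence networks:
#' node and link counts, average connectivity `avgK = 2L/n`, average weighted
#' degree, diameter and average path length (computed unweighted on the
#' largest connected component), density `2L/(n(n-1))`, modularity and number
#' of communities from greedy modularity maximisation, mean local clustering
#' coefficient (0 for nodes of degree < 2), mean eigenvector centrality, and
#' Freeman degree centralization `CD = sum(kmax - k_i) / ((n-1)(n-2))`.
#'
#' @param network an igraph graph (possibly disconnected; possibly empty).
#' @param seed seed for community detection.
#' @return One-row data.frame with columns `n_nodes`, `n_links`, `avgK`,
#'   `avg_weighted_degree`, `diameter`, `avg_path_length`, `density`,
#'   `modularity`, `n_communities`, `clustering_coefficient`,
#'   `eigenvector_centrality`, `centralization_degree`.
#' @examples
#' topology(igraph::make_full_graph(3))
#' @export
topology <- function(network, seed = 1L) {
  n <- igraph::vcount(network)
  L <- igraph::ecount(network)
  if (n == 0) {
    return(data.frame(n_nodes = 0L, n_links = 0L, avgK = NA_real_,
                      avg_weighted_degree = NA_real_, diameter = NA_real_,
                      avg_path_length = NA_real_, density = NA_real_,
                      modularity = NA_real_, n_communities = 0L,
                      clustering_coefficient = NA_real_,
                      eigenvector_centrality = NA_real_,
                      centralization_degree = NA_real_))
  }
  k <- igraph::degree(network)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, L)
  strength <- igraph::strength(network, weights = w)

  comps <- igraph::components(network)
  giant <- igraph::induced_subgraph(
    network, which(comps$membership == which.max(comps$csize)))
  diam <- if (igraph::vcount(giant) > 1)
    igraph::diameter(giant, weights = NA) else 0
  apl <- if (igraph::vcount(giant) > 1)
    igraph::mean_distance(giant, weights = NA) else 0

  comm <- detect_communities(network, seed)
  cc_local <- igraph::transitivity(network, type = "local", isolates = "zero")
  eig <- igraph::eigen_centrality(network, weights = w)$vector
  cd <- if (n >= 3) sum(max(k) - k) / ((n - 1) * (n - 2)) else NA_real_

  data.frame(
    n_nodes = n, n_links = L,
    avgK = 2 * L / n,
    avg_weighted_degree = mean(strength),
    diameter = diam, avg_path_length = apl,
    density = if (n > 1) 2 * L / (n * (n - 1)) else NA_real_,
    modularity = igraph::modularity(comm),
    n_communities = length(comm),
    clustering_coefficient = mean(cc_local),
    eigenvector_centrality = mean(eig),
    centralization_degree = cd)
}

#' Composition of the largest network modules
#'
#' Modules (communities) ranked by node count — ties broken by module id —
#' with the taxa they contain and the bacterial/fungal share of each, for the
#' top `top_k` modules.
#'
#' @param network an igraph graph with optional vertex attribute `domain`.
#' @param top_k how many modules to report (default 3; all if fewer exist).
#' @param seed seed for community detection.
#' @return data.frame with one row per reported module: `module_rank`,
#'   `module_id`, `n_nodes`, `prop_bacteria`, `prop_fungi`, `taxa`
#'   (comma-separated ids). Zero rows for an empty network.
#' @export
module_composition <- function(network, top_k = 3, seed = 1L) {
  empty <- data.frame(module_rank = integer(0), module_id = integer(0),
                      n_nodes = integer(0), prop_bacteria = numeric(0),
                      prop_fungi = numeric(0), taxa = character(0),
                      stringsAsFactors = FALSE)
  if (igraph::vcount(network) == 0) return(empty)
  comm <- detect_communities(network, seed)
  mem <- igraph::membership(comm)
  vn <- igraph::vertex_attr(network, "name") %||%
    as.character(seq_len(igraph::vcount(network)))
  sizes <- table(mem)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  ids <- as.integer(names(sizes))[ord]
  ids <- ids[seq_len(min(top_k, length(ids)))]
  dom <- igraph::vertex_attr(network, "domain")
  rows <- lapply(seq_along(ids), function(rk) {
    members <- vn[mem == ids[rk]]
    dsub <- if (is.null(dom)) character(0) else dom[match(members, vn)]
    data.frame(module_rank = rk, module_id = ids[rk],
               n_nodes = length(members),
               prop_bacteria = if (length(dsub)) mean(dsub == "bacteria")
                               else NA_real_,
               prop_fungi = if (length(dsub)) mean(dsub == "fungi")
                            else NA_real_,
               taxa = paste(sort(members), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kolmogorov–Smirnov comparison of two degree distributions
#'
#' Two-sample KS test on the node-degree distributions of two networks, used
#' to ask whether two co-occurrence networks differ in connectivity structure.
#'
#' @param network_a,network_b non-empty igraph graphs.
#' @return List with `statistic` (D in \[0, 1\]) and `p_value`.
#' @examples
#' g <- igraph::make_full_graph(5)
#' degree_distribution_ks(g, g)$statistic  # 0
#' @export
degree_distribution_ks <- function(network_a, network_b) {
  if (igraph::vcount(network_a) == 0 || igraph::vcount(network_b) == 0)
    stop("both networks must be non-empty")
  da <- igraph::degree(network_a)
  db <- igraph::degree(network_b)
  # degrees are discrete so ties are expected; the asymptotic statistic is
  # still the max ECDF gap, which is what we report
  kt <- suppressWarnings(stats::ks.test(da, db))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Export a network as GraphML and edge-list CSV
#'
#' @param network an igraph graph.
#' @param graphml_path,edges_path output file paths (either may be `NULL`).
#' @param p_matrix optional pseudo p-value matrix for the edge list.
#' @return Invisibly, the edge-list data.frame.
#' @export
export_network <- function(network, graphml_path = NULL, edges_path = NULL,
                           p_matrix = NULL) {
  el <- igraph::as_data_frame(network, what = "edges")
  names(el)[1:2] <- c("source", "target")
  if (!is.null(p_matrix))
    el$p <- p_matrix[cbind(el$source, el$target)]
  if (!is.null(graphml_path))
    igraph::write_graph(network, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    utils::write.csv(el, edges_path, row.names = FALSE, quote = FALSE)
  invisible(el)
}
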