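# Shared fixtures: canonical graphs with hand-computed topology, and a
# compact synthetic study for pipeline tests.

canonical_graphs <- function() {
  list(
    triangle = igraph::make_full_graph(3),
    star4 = igraph::make_star(4, mode = "undirected"),
    path4 = igraph::make_ring(4, circular = FALSE),
    cycle5 = igraph::make_ring(5),
    two_triangles = igraph::disjoint_union(igraph::make_full_graph(3),
                                           igraph::make_full_graph(3)))
}

# 4 species x 2 positions x 3 replicates = 24 samples; small OTU tables
small_design <- function(noise_cv = 0.1) {
  study_design(
    species = data.frame(species = c("AM_a", "AM_b", "ECM_a", "ECM_b"),
                         mycorrhizal_type = c("AM", "AM", "ECM", "ECM"),
                         stringsAsFactors = FALSE),
    replicates_per_cell = 3, noise_cv = noise_cv)
}

small_study <- function(seed = 1, noise_cv = 0.1, include_otus = TRUE) {
  simulate_study(
    small_design(noise_cv),
    bacterial_spec = basis_correlation_spec(
      n_taxa = 12,
      correlation_matrix = block_correlation_matrix(12, list(1:4), 0.85),
      sequencing_depth = 1500),
    fungal_spec = basis_correlation_spec(n_taxa = 8, sequencing_depth = 800),
    seed = seed, include_otus = include_otus)
}
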