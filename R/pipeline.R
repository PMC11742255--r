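# Orchestration: from raw input tables to rates, chemistry, diversity, four
# group-level co-occurrence networks (AM/ECM x rhizosphere/non-rhizosphere),
# topology comparison and group statistics. Every stage draws its own seed
# from the master seed, and no sample is ever dropped silently: each
# per-sample output row either carries results or a flag.

#' Pipeline run configuration
#'
#' @param input_dir directory with `metadata.tsv`, `incubation.tsv`,
#'   `fumigation.tsv`, `otu_bacteria.tsv`, `otu_fungi.tsv` (the layout
#'   written by [write_study()]).
#' @param out_dir output directory; `NULL` keeps results in memory only.
#' @param seed master seed.
#' @param rarefy_depth_bacteria,rarefy_depth_fungi rarefaction depths;
#'   `NULL` uses each table's minimum column sum.
#' @param prevalence_bacteria,prevalence_fungi prevalence-filter fractions
#'   (defaults 0.8 and 0.5).
#' @param r_min,alpha network edge thresholds (defaults 0.65 and 0.05).
#' @param n_iter,n_bootstrap SparCC iterations and pseudo-p bootstrap count
#'   (defaults 20 and 100).
#' @param incubation an [incubation_config()].
#' @return List of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, out_dir = NULL, seed = 1L,
                       rarefy_depth_bacteria = NULL,
                       rarefy_depth_fungi = NULL,
                       prevalence_bacteria = 0.8, prevalence_fungi = 0.5,
                       r_min = 0.65, alpha = 0.05,
                       n_iter = 20, n_bootstrap = 100,
                       incubation = incubation_config()) {
  stopifnot(r_min > 0, r_min < 1, alpha > 0, alpha < 1,
            n_iter >= 1, n_bootstrap >= 1,
            prevalence_bacteria > 0, prevalence_bacteria <= 1,
            prevalence_fungi > 0, prevalence_fungi <= 1)
  structure(list(input_dir = input_dir, out_dir = out_dir, seed = seed,
                 rarefy_depth_bacteria = rarefy_depth_bacteria,
                 rarefy_depth_fungi = rarefy_depth_fungi,
                 prevalence_bacteria = prevalence_bacteria,
                 prevalence_fungi = prevalence_fungi,
                 r_min = r_min, alpha = alpha, n_iter = n_iter,
                 n_bootstrap = n_bootstrap, incubation = incubation),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; `incubation` may
#' be a mapping with [incubation_config()] fields.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  inc <- do.call(incubation_config, y$incubation %||% list())
  y$incubation <- NULL
  do.call(run_config, c(y, list(incubation = inc)))
}

#' Validate pipeline inputs
#'
#' Structural checks only — never mutates anything: id cross-references
#' between tables and metadata, duplicate ids, factor levels, count
#' integrality and sign.
#'
#' @param inputs list with `metadata`, `incubation`, `fumigation` data.frames
#'   and optional `otu_bacteria`, `otu_fungi` [otu_table()]s.
#' @return data.frame report with columns `check`, `location`, `message`;
#'   zero rows when everything is consistent.
#' @export
validate_inputs <- function(inputs) {
  rep_rows <- list()
  note <- function(check, location, message)
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      check = check, location = location, message = message,
      stringsAsFactors = FALSE)
  md <- inputs$metadata
  ids <- md$sample_id
  if (anyDuplicated(ids))
    note("duplicate_id", "metadata",
         paste("duplicated:", paste(unique(ids[duplicated(ids)]), collapse = ",")))
  bad_m <- setdiff(unique(md$mycorrhizal_type), c("AM", "ECM"))
  if (length(bad_m))
    note("factor_levels", "metadata$mycorrhizal_type",
         paste("unknown levels:", paste(bad_m, collapse = ",")))
  bad_p <- setdiff(unique(md$position), c("rhizosphere", "non_rhizosphere"))
  if (length(bad_p))
    note("factor_levels", "metadata$position",
         paste("unknown levels:", paste(bad_p, collapse = ",")))
  for (tbl in c("incubation", "fumigation")) {
    if (is.null(inputs[[tbl]])) next
    extra <- setdiff(inputs[[tbl]]$sample_id, ids)
    if (length(extra))
      note("id_crossref", tbl,
           paste("samples absent from metadata:", paste(extra, collapse = ",")))
  }
  for (tbl in c("otu_bacteria", "otu_fungi")) {
    ot <- inputs[[tbl]]
    if (is.null(ot)) next
    m <- unclass(ot)
    if (any(m < 0)) {
      idx <- which(m < 0, arr.ind = TRUE)[1, ]
      note("negative_count", tbl,
           sprintf("taxon %s, sample %s", rownames(m)[idx[1]],
                   colnames(m)[idx[2]]))
    }
    if (any(m != round(m))) {
      idx <- which(m != round(m), arr.ind = TRUE)[1, ]
      note("non_integer_count", tbl,
           sprintf("taxon %s, sample %s", rownames(m)[idx[1]],
                   colnames(m)[idx[2]]))
    }
    extra <- setdiff(colnames(m), ids)
    if (length(extra))
      note("id_crossref", tbl,
           paste("samples absent from metadata:", paste(extra, collapse = ",")))
  }
  if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(check = character(0), location = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

# Build one group network (prevalence filter per domain, joint SparCC,
# bootstrap pseudo-p, threshold) and summarise it.
group_network <- function(bact, fung, config, seed) {
  fb <- suppressWarnings(prevalence_filter(bact, config$prevalence_bacteria))
  ff <- suppressWarnings(prevalence_filter(fung, config$prevalence_fungi))
  counts <- rbind(unclass(fb), unclass(ff))
  domains <- stats::setNames(rep(c("bacteria", "fungi"),
                                 c(nrow(fb), nrow(ff))), rownames(counts))
  if (nrow(counts) < 3)
    return(list(network = igraph::make_empty_graph(0, directed = FALSE),
                topology = topology(igraph::make_empty_graph(0, directed = FALSE)),
                estimate = NULL, p_matrix = NULL, modules = NULL))
  est <- sparcc(counts, n_iter = config$n_iter, seed = stage_seed(seed, "sparcc"))
  p <- bootstrap_pseudo_p(counts, est$r_matrix, B = config$n_bootstrap,
                          n_iter = config$n_iter,
                          seed = stage_seed(seed, "bootstrap"))
  g <- build_network(est, p, r_min = config$r_min, alpha = config$alpha,
                     domains = domains)
  list(network = g, topology = topology(g, seed = stage_seed(seed, "topology")),
       estimate = est, p_matrix = p,
       modules = module_composition(g, seed = stage_seed(seed, "topology")))
}

#' Run the full analysis on in-memory study tables
#'
#' @param study list with `metadata`, `incubation`, `fumigation` and optional
#'   `otu_bacteria`, `otu_fungi` (e.g. a [simulate_study()] result or tables
#'   read from disk).
#' @param config a [run_config()].
#' @return List of class `result_bundle`: `rates`, `chemistry`, `diversity`,
#'   `networks` (per-group list with `network`, `topology`, `modules`),
#'   `topology` (combined table), `stats`, `position_tests`, `screen`,
#'   `validation`, `manifest`.
#' @export
run_study <- function(study, config = run_config()) {
  md <- study$metadata
  seed <- config$seed
  validation <- validate_inputs(study)
  if (nrow(validation))
    warning("input validation reported ", nrow(validation), " issue(s)")

  rates <- process_incubation_table(study$incubation, config$incubation)
  chemistry <- process_chemistry_table(study$fumigation)

  diversity <- NULL
  networks <- NULL
  topo <- NULL
  if (!is.null(study$otu_bacteria) && !is.null(study$otu_fungi)) {
    rb_depth <- config$rarefy_depth_bacteria %||% min(colSums(study$otu_bacteria))
    rf_depth <- config$rarefy_depth_fungi %||% min(colSums(study$otu_fungi))
    rare_b <- rarefy(study$otu_bacteria, rb_depth,
                     seed = stage_seed(seed, "rarefy_bacteria"))
    rare_f <- rarefy(study$otu_fungi, rf_depth,
                     seed = stage_seed(seed, "rarefy_fungi"))
    diversity <- rbind(alpha_diversity(rare_b), alpha_diversity(rare_f))

    groups <- unique(md[, c("mycorrhizal_type", "position")])
    groups <- groups[order(groups$mycorrhizal_type, groups$position), ]
    networks <- list()
    topo_rows <- list()
    for (k in seq_len(nrow(groups))) {
      gm <- groups$mycorrhizal_type[k]; gp <- groups$position[k]
      gname <- paste(gm, gp, sep = ".")
      samp <- md$sample_id[md$mycorrhizal_type == gm & md$position == gp]
      nb <- group_network(
        as_otu(unclass(study$otu_bacteria)[, samp, drop = FALSE],
               study$otu_bacteria),
        as_otu(unclass(study$otu_fungi)[, samp, drop = FALSE],
               study$otu_fungi),
        config, seed = stage_seed(seed, paste0("network_", gname)))
      networks[[gname]] <- nb
      topo_rows[[gname]] <- data.frame(group = gname,
                                       mycorrhizal_type = gm, position = gp,
                                       nb$topology, stringsAsFactors = FALSE)
      message(sprintf("[cuenet] network %-20s samples=%d nodes=%d links=%d",
                      gname, length(samp), nb$topology$n_nodes,
                      nb$topology$n_links))
    }
    topo <- do.call(rbind, c(topo_rows, list(make.row.names = FALSE)))
  }

  # factorial statistics on every per-sample response
  key <- match(rates$sample_id, md$sample_id)
  fm <- md$mycorrhizal_type[key]; fp <- md$position[key]
  responses <- c("growth", "respiration", "uptake", "cue", "q_growth",
                 "q_co2", "q_uptake", "turnover")
  stats_rows <- lapply(responses, function(rr)
    factorial_compare(rates[[rr]], fm, fp, response_name = rr))
  ckey <- match(chemistry$sample_id, md$sample_id)
  cfm <- md$mycorrhizal_type[ckey]; cfp <- md$position[ckey]
  for (rr in c("MBC", "MBN", "r_cn", "b_cn", "imbalance"))
    stats_rows[[length(stats_rows) + 1L]] <-
      factorial_compare(chemistry[[rr]], cfm, cfp, response_name = rr)
  stats_tbl <- do.call(rbind, stats_rows)

  # position contrasts (rhizosphere vs non-rhizosphere) within each type
  pos_rows <- list()
  for (gm in unique(fm)) for (rr in responses) {
    a <- rates[[rr]][fm == gm & fp == "non_rhizosphere"]
    b <- rates[[rr]][fm == gm & fp == "rhizosphere"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3) next
    wt <- wilcoxon_pair(a, b)
    pos_rows[[paste(gm, rr)]] <- data.frame(
      mycorrhizal_type = gm, response = rr, statistic = wt$statistic,
      p_value = wt$p_value, method = wt$method, stringsAsFactors = FALSE)
  }
  position_tests <- do.call(rbind, c(pos_rows, list(make.row.names = FALSE)))

  # Spearman screen of CUE predictors: per-sample soil/diversity predictors
  # plus each sample's group-level network topology
  screen <- NULL
  if (!is.null(diversity) && !is.null(topo)) {
    ss <- rates$sample_id
    div_b <- diversity[diversity$domain == "bacteria", ]
    div_f <- diversity[diversity$domain == "fungi", ]
    gkey <- paste(fm, fp, sep = ".")
    tkey <- match(gkey, topo$group)
    predictors <- data.frame(
      richness_bacteria = div_b$richness[match(ss, div_b$sample_id)],
      shannon_bacteria = div_b$shannon[match(ss, div_b$sample_id)],
      richness_fungi = div_f$richness[match(ss, div_f$sample_id)],
      shannon_fungi = div_f$shannon[match(ss, div_f$sample_id)],
      avgK = topo$avgK[tkey], density = topo$density[tkey],
      clustering_coefficient = topo$clustering_coefficient[tkey],
      centralization_degree = topo$centralization_degree[tkey],
      pH = chemistry$pH[match(ss, chemistry$sample_id)],
      b_cn = chemistry$b_cn[match(ss, chemistry$sample_id)],
      r_cn = chemistry$r_cn[match(ss, chemistry$sample_id)],
      imbalance = chemistry$imbalance[match(ss, chemistry$sample_id)])
    screen <- spearman_screen(predictors, rates[responses])
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cuenet")),
    seed = seed, r_min = config$r_min, alpha = config$alpha,
    n_iter = config$n_iter, n_bootstrap = config$n_bootstrap,
    prevalence = c(bacteria = config$prevalence_bacteria,
                   fungi = config$prevalence_fungi),
    n_samples = nrow(md), n_rate_rows = nrow(rates),
    n_chemistry_rows = nrow(chemistry),
    path_metrics_scope = "largest_connected_component",
    turnover_definition = "growth_per_unit_MBC")

  structure(list(rates = rates, chemistry = chemistry, diversity = diversity,
                 networks = networks, topology = topo, stats = stats_tbl,
                 position_tests = position_tests, screen = screen,
                 validation = validation, manifest = manifest),
            class = "result_bundle")
}

#' Run the pipeline from files on disk
#'
#' Reads the input tables named in the configuration, validates them, runs
#' [run_study()] and (when `out_dir` is set) writes every result table, the
#' per-group networks (GraphML + edge-list CSV) and a YAML manifest.
#'
#' @param config a [run_config()] with `input_dir` set.
#' @return The `result_bundle`, invisibly when writing to disk.
#' @export
run_all <- function(config) {
  if (is.null(config$input_dir)) stop("config$input_dir is required")
  path <- function(f) file.path(config$input_dir, f)
  for (f in c("metadata.tsv", "incubation.tsv", "fumigation.tsv"))
    if (!file.exists(path(f))) stop("missing input file: ", path(f))
  study <- list(metadata = read_tsv(path("metadata.tsv")),
                incubation = read_tsv(path("incubation.tsv")),
                fumigation = read_tsv(path("fumigation.tsv")))
  if (file.exists(path("otu_bacteria.tsv")))
    study$otu_bacteria <- read_otu_tsv(path("otu_bacteria.tsv"), "bacteria")
  if (file.exists(path("otu_fungi.tsv")))
    study$otu_fungi <- read_otu_tsv(path("otu_fungi.tsv"), "fungi")
  bundle <- run_study(study, config)
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a result bundle to disk
#'
#' @param bundle a `result_bundle` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(bundle$rates, file.path(out_dir, "rates.tsv"))
  write_tsv(bundle$chemistry, file.path(out_dir, "chemistry.tsv"))
  if (!is.null(bundle$diversity))
    write_tsv(bundle$diversity, file.path(out_dir, "diversity.tsv"))
  if (!is.null(bundle$topology))
    write_tsv(bundle$topology, file.path(out_dir, "topology.tsv"))
  write_tsv(bundle$stats, file.path(out_dir, "stats.tsv"))
  if (!is.null(bundle$position_tests))
    write_tsv(bundle$position_tests, file.path(out_dir, "position_tests.tsv"))
  if (!is.null(bundle$screen)) {
    utils::write.csv(bundle$screen$rho, file.path(out_dir, "screen_rho.csv"))
    utils::write.csv(bundle$screen$p, file.path(out_dir, "screen_p.csv"))
  }
  if (nrow(bundle$validation))
    write_tsv(bundle$validation, file.path(out_dir, "validation.tsv"))
  for (gname in names(bundle$networks)) {
    nb <- bundle$networks[[gname]]
    if (igraph::vcount(nb$network) == 0) next
    export_network(nb$network,
                   graphml_path = file.path(out_dir, paste0(gname, ".graphml")),
                   edges_path = file.path(out_dir, paste0(gname, "_edges.csv")),
                   p_matrix = nb$p_matrix)
    if (!is.null(nb$modules) && nrow(nb$modules))
      write_tsv(nb$modules, file.path(out_dir, paste0(gname, "_modules.tsv")))
  }
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
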