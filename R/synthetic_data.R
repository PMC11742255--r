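# Synthetic-study generator. Emulates the field design — 8 arbuscular
# mycorrhizal (AM) and 7 ectomycorrhizal (ECM) tree species, rhizosphere and
# non-rhizosphere soil, 5 replicate trees per species — with known
# group-level truths, so every downstream stage has a recovery test. The
# generators invert the measurement equations: at zero noise the emitted
# instrument readings reproduce the true rates exactly.

#' Study design for the synthetic generator
#'
#' @param species data.frame with columns `species` and `mycorrhizal_type`
#'   (`"AM"`/`"ECM"`); defaults to 8 AM + 7 ECM species.
#' @param replicates_per_cell replicate trees per species x position
#'   (default 5).
#' @param group_effects data.frame keyed by `mycorrhizal_type` and `position`
#'   with true means `growth`, `respiration` (ng C g^-1 h^-1), `MBC`, `MBN`,
#'   `DOC`, `TDN` (ug g^-1). The defaults encode the qualitative pattern of
#'   interest: equal growth but higher rhizosphere respiration under ECM, so
#'   ECM non-rhizosphere CUE (0.5) exceeds both ECM rhizosphere and AM
#'   (0.3) by 0.2.
#' @param noise_cv coefficient of variation of the multiplicative log-normal
#'   measurement noise (default 0.15; 0 = noise-free).
#' @param DW,t,dna_content,atpct_final,atpct_control,blank_ppm_mean incubation
#'   constants: dry weight (g), time (h), extractable DNA (ug g^-1), soil
#'   water labeling (at% 18O), natural-abundance control DNA reading
#'   (at% 18O) and mean empty-vial CO2 (ppm).
#' @return A list of class `study_design`.
#' @examples
#' d <- study_design()
#' nrow(d$species) * 2 * d$replicates_per_cell  # 150 samples
#' @export
study_design <- function(species = NULL, replicates_per_cell = 5,
                         group_effects = NULL, noise_cv = 0.15,
                         DW = 1, t = 24, dna_content = 10,
                         atpct_final = 20, atpct_control = 0.2,
                         blank_ppm_mean = 20) {
  if (is.null(species))
    species <- data.frame(
      species = c(sprintf("AM_sp%02d", 1:8), sprintf("ECM_sp%02d", 1:7)),
      mycorrhizal_type = rep(c("AM", "ECM"), c(8, 7)),
      stringsAsFactors = FALSE)
  if (is.null(group_effects))
    group_effects <- data.frame(
      mycorrhizal_type = c("AM", "AM", "ECM", "ECM"),
      position = rep(c("rhizosphere", "non_rhizosphere"), 2),
      growth      = c(90, 90, 150, 150),
      respiration = c(210, 210, 350, 150),
      MBC = c(300, 300, 400, 400),
      MBN = c(30, 30, 40, 40),
      DOC = c(100, 100, 150, 150),
      TDN = c(12, 12, 15, 15),
      stringsAsFactors = FALSE)
  stopifnot(replicates_per_cell >= 1, noise_cv >= 0,
            all(species$mycorrhizal_type %in% c("AM", "ECM")),
            !anyDuplicated(species$species))
  need <- c("growth", "respiration", "MBC", "MBN", "DOC", "TDN")
  if (!all(need %in% names(group_effects)) ||
      any(as.matrix(group_effects[need]) <= 0))
    stop("group_effects must provide positive means for ",
         paste(need, collapse = ", "))
  cells <- unique(species$mycorrhizal_type)
  for (m in cells) for (p in c("rhizosphere", "non_rhizosphere"))
    if (!any(group_effects$mycorrhizal_type == m & group_effects$position == p))
      stop("group_effects lacks cell ", m, " / ", p)
  structure(list(species = species,
                 positions = c("rhizosphere", "non_rhizosphere"),
                 replicates_per_cell = replicates_per_cell,
                 group_effects = group_effects, noise_cv = noise_cv,
                 DW = DW, t = t, dna_content = dna_content,
                 atpct_final = atpct_final, atpct_control = atpct_control,
                 blank_ppm_mean = blank_ppm_mean),
            class = "study_design")
}

#' Simulate 18O incubation records from true rates
#'
#' Inverts the qSIP measurement chain: true growth fixes the DNA production
#' and hence the 18O atom-percent of the labeled DNA; true respiration fixes
#' the blank-corrected headspace CO2 through the ideal gas law. At
#' `noise_cv = 0` feeding the records to [process_incubation_table()] returns
#' the truths exactly; at `noise_cv > 0` multiplicative log-normal noise is
#' applied to the O content, both at% readings and the CO2 reading.
#'
#' @param truth data.frame with columns `sample_id`, `growth`, `respiration`
#'   (ng C g^-1 h^-1) and `MBC` (ug g^-1).
#' @param design a [study_design()] supplying the incubation constants.
#' @param config an [incubation_config()].
#' @param noise_cv overrides `design$noise_cv` when not `NULL`.
#' @param seed integer seed.
#' @return data.frame of incubation records (one labeled/control vial pair
#'   per sample) accepted by [process_incubation_table()].
#' @export
simulate_incubation <- function(truth, design = study_design(),
                                config = incubation_config(),
                                noise_cv = NULL, seed = 1L) {
  cv <- noise_cv %||% design$noise_cv
  if (any(truth$growth <= 0) || any(truth$respiration <= 0))
    stop("true growth and respiration must be positive")
  n <- nrow(truth)
  DW <- design$DW; t <- design$t
  dna_content <- design$dna_content
  o_pct <- config$o_pct_in_dna
  f_dna <- truth$MBC / dna_content
  O_total <- dna_content * DW * o_pct / 100

  dna_prod <- truth$growth * DW * t / (1000 * f_dna)
  excess <- dna_prod * design$atpct_final * o_pct / (100 * O_total)
  atpct_labeled <- design$atpct_control + excess
  if (any(atpct_labeled >= 100) || any(atpct_labeled >= design$atpct_final))
    stop("implied labeled at% outside (natural abundance, at%_final): ",
         "truth growth too large for the configured label")

  k_gas <- config$pressure_kPa * config$molar_mass_C /
    (config$gas_constant * config$temperature_K)
  rs_ppm <- truth$respiration * DW * t /
    (k_gas * config$headspace_volume_L * 1000)

  with_seed(seed, {
    data.frame(
      sample_id = truth$sample_id,
      O_total = ln_noise(rep(O_total, n), cv),
      atpct_labeled = ln_noise(atpct_labeled, cv),
      atpct_control = ln_noise(rep(design$atpct_control, n), cv),
      atpct_final = design$atpct_final,
      co2_ppm = ln_noise(rs_ppm, cv) + design$blank_ppm_mean,
      blank_ppm_mean = design$blank_ppm_mean,
      DW = DW, t = t, dna_content = dna_content, MBC = truth$MBC,
      stringsAsFactors = FALSE)
  })
}

#' Simulate fumigation-extraction pairs from true biomass and extract pools
#'
#' Inverts the fumigation conversion: the fumigated extract carries the
#' unfumigated pool plus the biomass flush (`0.45 * MBC` for C,
#' `0.54 * MBN` for N). Exact round trip at zero noise.
#'
#' @param truth data.frame with columns `sample_id`, `MBC`, `MBN`, `DOC`,
#'   `TDN` (ug g^-1), optionally `pH`.
#' @param noise_cv coefficient of variation of the measurement noise.
#' @param seed integer seed.
#' @param k_c,k_n extraction efficiencies.
#' @return data.frame accepted by [process_chemistry_table()].
#' @examples
#' tr <- data.frame(sample_id = "s1", MBC = 200, MBN = 50, DOC = 60, TDN = 10)
#' simulate_fumigation(tr, noise_cv = 0)  # fumigated DOC 150, TDN 37
#' @export
simulate_fumigation <- function(truth, noise_cv = 0.15, seed = 1L,
                                k_c = 0.45, k_n = 0.54) {
  need <- c("MBC", "MBN", "DOC", "TDN")
  if (any(as.matrix(truth[need]) <= 0))
    stop("true MBC, MBN, DOC, TDN must be positive")
  n <- nrow(truth)
  with_seed(seed, {
    data.frame(
      sample_id = truth$sample_id,
      doc_fumigated = ln_noise(truth$DOC + k_c * truth$MBC, noise_cv),
      doc_unfumigated = ln_noise(truth$DOC, noise_cv),
      tdn_fumigated = ln_noise(truth$TDN + k_n * truth$MBN, noise_cv),
      tdn_unfumigated = ln_noise(truth$TDN, noise_cv),
      pH = if ("pH" %in% names(truth)) truth$pH else 6.0,
      stringsAsFactors = FALSE)
  })
}

#' Specification of a basis correlation structure for OTU simulation
#'
#' @param n_taxa number of taxa (>= 3).
#' @param correlation_matrix symmetric positive-semidefinite matrix with unit
#'   diagonal (default identity).
#' @param log_mean_abundances,log_sd mean and sd of log basis abundances
#'   (defaults: a linear ramp over ~4 natural-log units, sd 1 — a realistic
#'   spread of dominant to rare taxa).
#' @param sequencing_depth reads per sample.
#' @return List of class `basis_spec`.
#' @export
basis_correlation_spec <- function(n_taxa = 50, correlation_matrix = NULL,
                                   log_mean_abundances = NULL, log_sd = 1,
                                   sequencing_depth = 50000) {
  if (n_taxa < 3) stop("n_taxa must be at least 3")
  if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
  if (is.null(correlation_matrix)) correlation_matrix <- diag(n_taxa)
  if (is.null(log_mean_abundances))
    log_mean_abundances <- seq(4, 0, length.out = n_taxa)
  log_sd <- rep_len(log_sd, n_taxa)
  cm <- correlation_matrix
  if (nrow(cm) != n_taxa || ncol(cm) != n_taxa)
    stop("correlation_matrix dimension mismatch")
  if (max(abs(cm - t(cm))) > 1e-10 || max(abs(diag(cm) - 1)) > 1e-10)
    stop("correlation_matrix must be symmetric with unit diagonal")
  if (min(eigen(cm, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("correlation_matrix is not positive semi-definite")
  structure(list(n_taxa = n_taxa, correlation_matrix = cm,
                 log_mean_abundances = log_mean_abundances, log_sd = log_sd,
                 sequencing_depth = sequencing_depth),
            class = "basis_spec")
}

#' Correlation matrix with planted pairwise correlations
#'
#' Identity matrix with specified off-diagonal entries — block-diagonal in
#' 2x2 blocks when the planted pairs are disjoint, hence always positive
#' semi-definite for |rho| <= 1.
#'
#' @param n_taxa matrix dimension.
#' @param pairs data.frame with columns `i`, `j`, `rho`.
#' @return n_taxa x n_taxa correlation matrix.
#' @examples
#' planted_correlation_matrix(5, data.frame(i = 1, j = 2, rho = 0.9))
#' @export
planted_correlation_matrix <- function(n_taxa, pairs) {
  cm <- diag(n_taxa)
  for (k in seq_len(nrow(pairs)))
    cm[pairs$i[k], pairs$j[k]] <- cm[pairs$j[k], pairs$i[k]] <- pairs$rho[k]
  cm
}

#' Correlation matrix with correlated taxon blocks
#'
#' Identity matrix with constant positive correlation `rho` inside each
#' listed block — the co-occurring guilds that give a synthetic community a
#' non-trivial network and module structure. Equicorrelated blocks are
#' positive definite for any `rho` in (0, 1).
#'
#' @param n_taxa matrix dimension.
#' @param blocks list of integer index vectors (disjoint).
#' @param rho within-block correlation (recycled over blocks).
#' @return n_taxa x n_taxa correlation matrix.
#' @examples
#' block_correlation_matrix(6, list(1:3), 0.8)
#' @export
block_correlation_matrix <- function(n_taxa, blocks, rho = 0.85) {
  if (anyDuplicated(unlist(blocks))) stop("blocks must be disjoint")
  rho <- rep_len(rho, length(blocks))
  cm <- diag(n_taxa)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    cm[b, b] <- rho[k]
    cm[cbind(b, b)] <- 1
  }
  cm
}

#' Simulate an OTU count table from a known basis correlation structure
#'
#' Basis abundances are multivariate log-normal with the specified
#' correlation; reads are multinomial draws at the sequencing depth from the
#' closed (per-sample normalised) basis — the generative model under which
#' log-ratio correlation inference is consistent.
#'
#' @param spec a [basis_correlation_spec()].
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed.
#' @param domain passed to [otu_table()].
#' @param taxon_prefix,sample_ids naming of rows/columns.
#' @return An [otu_table()]; every column sums to `spec$sequencing_depth`.
#' @export
simulate_otu_table <- function(spec, n_samples, seed = 1L,
                               domain = "bacteria",
                               taxon_prefix = "OTU", sample_ids = NULL) {
  if (n_samples < 2) stop("n_samples must be at least 2")
  d <- spec$n_taxa
  sigma <- diag(spec$log_sd) %*% spec$correlation_matrix %*% diag(spec$log_sd)
  counts <- with_seed(seed, {
    z <- MASS::mvrnorm(n_samples, mu = spec$log_mean_abundances, Sigma = sigma)
    basis <- exp(z)                       # n_samples x d
    fr <- basis / rowSums(basis)
    vapply(seq_len(n_samples),
           function(i) stats::rmultinom(1, spec$sequencing_depth, fr[i, ])[, 1],
           integer(d))
  })
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(n_samples))
  otu_table(counts, domain = domain,
            taxon_ids = sprintf("%s_%03d", taxon_prefix, seq_len(d)),
            sample_ids = sample_ids)
}

#' Simulate a complete synthetic study
#'
#' Expands the design into a per-sample metadata table, derives each sample's
#' true rates and pools from its design cell, and generates all measurement
#' tables plus a ground-truth sidecar for recovery tests. Per-stage seeds are
#' derived from `seed` so the components are independently reproducible.
#'
#' @param design a [study_design()].
#' @param bacterial_spec,fungal_spec [basis_correlation_spec()]s for the two
#'   OTU tables; compact defaults are used when `NULL`.
#' @param seed master integer seed.
#' @param include_otus set `FALSE` to skip OTU simulation (e.g. for
#'   rate-only power studies).
#' @param config an [incubation_config()].
#' @return List of class `synthetic_study`: `metadata`, `incubation`,
#'   `fumigation`, `truth`, `otu_bacteria`, `otu_fungi`, `design`.
#' @examples
#' st <- simulate_study(study_design(noise_cv = 0), seed = 1,
#'                      include_otus = FALSE)
#' nrow(st$metadata)  # 150
#' @export
simulate_study <- function(design = study_design(), bacterial_spec = NULL,
                           fungal_spec = NULL, seed = 1L,
                           include_otus = TRUE,
                           config = incubation_config()) {
  sp <- design$species
  grid <- expand.grid(replicate = seq_len(design$replicates_per_cell),
                      position = design$positions,
                      species = sp$species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$mycorrhizal_type <-
    sp$mycorrhizal_type[match(grid$species, sp$species)]
  metadata <- data.frame(
    sample_id = sprintf("%s_%s_r%d", grid$species,
                        ifelse(grid$position == "rhizosphere", "R", "N"),
                        grid$replicate),
    species = grid$species, mycorrhizal_type = grid$mycorrhizal_type,
    position = grid$position, replicate = grid$replicate,
    stringsAsFactors = FALSE)
  metadata <- metadata[order(metadata$sample_id), ]
  rownames(metadata) <- NULL

  ge <- design$group_effects
  key <- match(paste(metadata$mycorrhizal_type, metadata$position),
               paste(ge$mycorrhizal_type, ge$position))
  truth <- data.frame(
    sample_id = metadata$sample_id,
    growth = ge$growth[key], respiration = ge$respiration[key],
    MBC = ge$MBC[key], MBN = ge$MBN[key],
    DOC = ge$DOC[key], TDN = ge$TDN[key],
    stringsAsFactors = FALSE)
  truth$uptake <- truth$growth + truth$respiration
  truth$cue <- truth$growth / truth$uptake
  truth$imbalance <- (truth$DOC / truth$TDN) / (truth$MBC / truth$MBN)

  incubation <- simulate_incubation(truth, design, config,
                                    seed = stage_seed(seed, "incubation"))
  fumigation <- simulate_fumigation(truth, noise_cv = design$noise_cv,
                                    seed = stage_seed(seed, "fumigation"))
  out <- list(metadata = metadata, incubation = incubation,
              fumigation = fumigation, truth = truth, design = design)
  if (include_otus) {
    # defaults carry two bacterial guilds and one fungal guild of strongly
    # co-occurring taxa, so group networks and modules are non-trivial
    if (is.null(bacterial_spec))
      bacterial_spec <- basis_correlation_spec(
        n_taxa = 40,
        correlation_matrix = block_correlation_matrix(40, list(1:6, 7:12), 0.85),
        sequencing_depth = 5000)
    if (is.null(fungal_spec))
      fungal_spec <- basis_correlation_spec(
        n_taxa = 20,
        correlation_matrix = block_correlation_matrix(20, list(1:4), 0.85),
        sequencing_depth = 2000)
    out$otu_bacteria <- simulate_otu_table(
      bacterial_spec, nrow(metadata), seed = stage_seed(seed, "otu_bacteria"),
      domain = "bacteria", taxon_prefix = "bOTU",
      sample_ids = metadata$sample_id)
    out$otu_fungi <- simulate_otu_table(
      fungal_spec, nrow(metadata), seed = stage_seed(seed, "otu_fungi"),
      domain = "fungi", taxon_prefix = "fOTU",
      sample_ids = metadata$sample_id)
  }
  structure(out, class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Emits every file the pipeline consumes: metadata, incubation and
#' fumigation TSVs, OTU tables as TSV (and BIOM when the biomformat package
#' is available), and the ground-truth sidecar.
#'
#' @param study a [simulate_study()] result.
#' @param out_dir output directory (created if needed).
#' @param biom also write BIOM copies of the OTU tables (default TRUE when
#'   biomformat is installed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, out_dir,
                        biom = requireNamespace("biomformat", quietly = TRUE)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metadata = file.path(out_dir, "metadata.tsv"),
             incubation = file.path(out_dir, "incubation.tsv"),
             fumigation = file.path(out_dir, "fumigation.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_tsv(study$metadata, paths["metadata"])
  write_tsv(study$incubation, paths["incubation"])
  write_tsv(study$fumigation, paths["fumigation"])
  write_tsv(study$truth, paths["truth"])
  for (dom in c("otu_bacteria", "otu_fungi")) {
    if (is.null(study[[dom]])) next
    p <- file.path(out_dir, paste0(dom, ".tsv"))
    write_otu_tsv(study[[dom]], p)
    paths[dom] <- p
    if (biom) {
      pb <- file.path(out_dir, paste0(dom, ".biom"))
      write_otu_biom(study[[dom]], pb)
      paths[paste0(dom, "_biom")] <- pb
    }
  }
  invisible(paths)
}
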