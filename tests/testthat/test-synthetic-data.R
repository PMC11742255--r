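# Generator contracts: measurement inversion, noise propagation,
# compositional closure and determinism.

test_that("noise-free incubation records round-trip the true rates", {
  truth <- data.frame(sample_id = sprintf("s%02d", 1:10),
                      growth = seq(20, 380, length.out = 10),
                      respiration = seq(350, 50, length.out = 10),
                      MBC = rep(c(300, 400), 5))
  rec <- simulate_incubation(truth, study_design(noise_cv = 0), seed = 1)
  rates <- process_incubation_table(rec)
  key <- match(rates$sample_id, truth$sample_id)
  expect_equal(rates$growth, truth$growth[key], tolerance = 1e-12)
  expect_equal(rates$respiration, truth$respiration[key], tolerance = 1e-12)
  expect_equal(rates$cue,
               truth$growth[key] / (truth$growth + truth$respiration)[key],
               tolerance = 1e-12)
})

test_that("implied blank-corrected CO2 matches the dimensional inversion", {
  # respiration of ~381 ng C/g/h in 18 ml at 101.325 kPa / 288.15 K over
  # 24 h corresponds to ~1000 ppm of accumulated CO2
  truth <- data.frame(sample_id = "s1", growth = 100, respiration = 380.9713,
                      MBC = 300)
  d <- study_design(noise_cv = 0)
  rec <- simulate_incubation(truth, d, seed = 1)
  expect_equal(rec$co2_ppm - rec$blank_ppm_mean, 1000, tolerance = 1e-3)
})

test_that("generator rejects unphysical truths", {
  bad <- data.frame(sample_id = "s1", growth = -5, respiration = 100, MBC = 300)
  expect_error(simulate_incubation(bad, study_design()), "positive")
  # growth so large the labeled DNA would exceed the water enrichment
  huge <- data.frame(sample_id = "s1", growth = 3e5, respiration = 100,
                     MBC = 300)
  expect_error(simulate_incubation(huge, study_design()), "at%")
})

test_that("multiplicative noise propagates to recomputed growth as predicted", {
  # strong labeling regime: per-reading cv of 0.1 propagates through the
  # product/difference chain to a growth cv near 0.10-0.15
  truth <- data.frame(sample_id = sprintf("s%04d", 1:1000), growth = 1800,
                      respiration = 300, MBC = 300)
  rec <- simulate_incubation(truth, study_design(noise_cv = 0), noise_cv = 0.1,
                             seed = 99)
  rates <- process_incubation_table(rec)
  cv_obs <- sd(rates$growth) / mean(rates$growth)
  # error-propagation oracle: var from O_total plus the two at% readings
  d <- study_design()
  exc <- 1800 * d$DW * d$t / (1000 * (300 / d$dna_content)) *
    d$atpct_final / (d$dna_content * d$DW)
  lab <- d$atpct_control + exc
  cv_pred <- sqrt(0.1^2 + (0.1 * lab / exc)^2 + (0.1 * d$atpct_control / exc)^2)
  expect_lt(abs(cv_obs - cv_pred) / cv_pred, 0.2)
  expect_gt(cv_obs, 0.08); expect_lt(cv_obs, 0.18)
})

test_that("fumigation pairs embed the biomass flush and recover it", {
  tr <- data.frame(sample_id = "s1", MBC = 200, MBN = 50, DOC = 60, TDN = 10)
  pair <- simulate_fumigation(tr, noise_cv = 0)
  expect_equal(pair$doc_fumigated, 60 + 0.45 * 200)   # 150
  expect_equal(pair$tdn_fumigated, 10 + 0.54 * 50)    # 37
  expect_error(simulate_fumigation(transform(tr, MBN = -1)), "positive")
  # noisy Monte Carlo: recovered MBC unbiased to ~2%
  trn <- data.frame(sample_id = sprintf("s%04d", 1:1000), MBC = 200, MBN = 50,
                    DOC = 60, TDN = 10)
  noisy <- simulate_fumigation(trn, noise_cv = 0.05, seed = 17)
  chem <- process_chemistry_table(noisy)
  expect_lt(abs(mean(chem$MBC) - 200) / 200, 0.02)
})

test_that("OTU simulation closes to depth and honours the basis structure", {
  spec <- basis_correlation_spec(n_taxa = 10, sequencing_depth = 2000)
  tb <- simulate_otu_table(spec, 30, seed = 5)
  expect_true(all(colSums(tb) == 2000))
  expect_identical(dim(unclass(tb)), c(10L, 30L))
  # determinism
  expect_identical(unclass(simulate_otu_table(spec, 30, seed = 5)),
                   unclass(tb))
  # a planted strong pair dominates the SparCC estimate
  cm <- planted_correlation_matrix(10, data.frame(i = 1, j = 2, rho = 0.9))
  tb2 <- simulate_otu_table(
    basis_correlation_spec(n_taxa = 10, correlation_matrix = cm,
                           sequencing_depth = 5000), 150, seed = 6)
  r <- sparcc(tb2, n_iter = 10, seed = 7)$r_matrix
  ut <- upper.tri(r)
  expect_equal(unname(which(abs(r * ut) == max(abs(r * ut)), arr.ind = TRUE)[1, ]),
               c(1, 2))
  expect_error(basis_correlation_spec(n_taxa = 5, sequencing_depth = 0),
               "depth")
  notpsd <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(basis_correlation_spec(n_taxa = 3, correlation_matrix = notpsd),
               "semi-definite")
})

test_that("full study has the design arithmetic and deterministic output", {
  st <- simulate_study(study_design(noise_cv = 0), seed = 2,
                       include_otus = FALSE)
  expect_equal(nrow(st$metadata), 15 * 2 * 5)
  expect_equal(nrow(st$incubation), 150)
  expect_equal(nrow(st$fumigation), 150)
  expect_equal(nrow(st$truth), 150)
  expect_equal(sort(unique(st$metadata$mycorrhizal_type)), c("AM", "ECM"))

  st_small_a <- small_study(seed = 11)
  st_small_b <- small_study(seed = 11)
  dir_a <- withr::local_tempdir(); dir_b <- withr::local_tempdir()
  write_study(st_small_a, dir_a, biom = FALSE)
  write_study(st_small_b, dir_b, biom = FALSE)
  for (f in list.files(dir_a))
    expect_identical(readLines(file.path(dir_a, f)),
                     readLines(file.path(dir_b, f)), label = f)
})
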