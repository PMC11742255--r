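# qSIP rate computations: hand-arithmetic oracles, dimensional analysis,
# limiting cases and the per-table contract.

test_that("DNA production matches hand arithmetic and limiting cases", {
  # O_total * (excess/100) * (100/at%final) * (100/31.21)
  expect_equal(dna_produced(10, 5.2, 0.2, 20)$dna_produced,
               10 * 0.05 * 5 * (100 / 31.21), tolerance = 1e-12)
  # zero excess -> zero new DNA
  expect_equal(dna_produced(10, 0.2, 0.2, 20)$dna_produced, 0)
  # identity limit: pure-O "DNA" fully labeled at the water enrichment
  expect_equal(dna_produced(7, 20.2, 0.2, 20, o_pct_in_dna = 100)$dna_produced,
               7, tolerance = 1e-12)
  # negative excess is clipped and flagged, not propagated
  res <- dna_produced(10, 0.1, 0.2, 20)
  expect_equal(res$dna_produced, 0)
  expect_true(res$clipped)
  expect_error(dna_produced(10, 5, 0.2, 0), "positive")
  expect_error(dna_produced(10, 5, 0.3, 0.2), "labeling impossible")
})

test_that("growth rate follows the f_DNA scaling with linear symmetries", {
  expect_equal(growth_rate(0.1, f_dna = 40, DW = 1, t = 24),
               40 * 0.1 * 1000 / 24, tolerance = 1e-12)
  expect_equal(growth_rate(0, 40, 1, 24), 0)
  g1 <- growth_rate(0.2, 30, 1, 24)
  expect_equal(growth_rate(0.2, 30, 2, 24), g1 / 2)   # doubling DW halves
  expect_equal(growth_rate(0.4, 30, 1, 24), g1 * 2)   # linear in DNA
  expect_error(growth_rate(0.1, 40, 0, 24), "positive")
})

test_that("respiration rate agrees with an independent mol-count oracle", {
  # worked value: 1000 ppm over 24 h in 18 ml at 101.325 kPa, 288.15 K
  expect_equal(respiration_rate(1000, 1, 24), 380.97, tolerance = 1e-4)
  # independent route: ppm -> mol gas (pV/RT) -> mol CO2 -> ng C
  mol_oracle <- function(rs, DW, t, p, T, V) {
    mol_gas <- (p * 1000) * (V * 1e-3) / (8.314 * T)
    rs * 1e-6 * mol_gas * 12.01 * 1e9 / (DW * t)
  }
  set.seed(101)
  for (i in 1:100) {
    rs <- runif(1, 0, 5000); DW <- runif(1, 0.5, 5); t <- runif(1, 1, 72)
    p <- runif(1, 80, 110); T <- runif(1, 270, 310); V <- runif(1, 0.005, 0.1)
    cfg <- incubation_config(pressure_kPa = p, temperature_K = T,
                             headspace_volume_L = V)
    expect_equal(respiration_rate(rs, DW, t, cfg), mol_oracle(rs, DW, t, p, T, V),
                 tolerance = 1e-9)
  }
  expect_equal(respiration_rate(0, 1, 24), 0)
  # linear in headspace volume
  cfg2 <- incubation_config(headspace_volume_L = 0.036)
  expect_equal(respiration_rate(1000, 1, 24, cfg2),
               2 * respiration_rate(1000, 1, 24), tolerance = 1e-12)
})

test_that("blank correction subtracts and clips", {
  expect_equal(blank_correct(1050, 50), 1000)
  expect_warning(res <- blank_correct(30, 50), "clipping")
  expect_equal(res, 0)
  expect_equal(blank_correct(77, 0), 77)
})

test_that("CUE is bounded, with both-zero undefined", {
  expect_equal(cue(100, 300), 0.25)
  expect_equal(cue(0, 5), 0)
  expect_equal(cue(5, 0), 1)
  expect_true(is.na(cue(0, 0)))
  set.seed(7)
  for (i in 1:50) {
    v <- cue(runif(1, 0, 500), runif(1, 0, 500))
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("mass-specific rates divide by MBC and add up", {
  q <- mass_specific_rates(200, 100, MBC = 100)
  expect_equal(q$q_growth, 2)
  expect_equal(q$q_co2, 1)
  expect_equal(q$q_uptake, q$q_growth + q$q_co2)
  expect_equal(q$turnover, q$q_growth)
  expect_equal(mass_specific_rates(50, 0, 10)$q_co2, 0)
  expect_error(mass_specific_rates(1, 1, 0), "positive")
})

test_that("incubation table processing flags bad rows and is order-invariant", {
  st <- simulate_study(small_design(noise_cv = 0), seed = 3,
                       include_otus = FALSE)
  rates <- process_incubation_table(st$incubation)
  expect_equal(nrow(rates), nrow(st$incubation))
  expect_true(all(rates$flag == ""))
  expect_equal(rates$uptake, rates$growth + rates$respiration)

  # a row violating at%_final > at%_control is flagged, not dropped
  bad <- st$incubation
  bad$atpct_final[1] <- bad$atpct_control[1] / 2
  rates_bad <- process_incubation_table(bad)
  expect_equal(nrow(rates_bad), nrow(bad))
  flagged <- rates_bad[rates_bad$sample_id == bad$sample_id[1], ]
  expect_true(is.na(flagged$growth))
  expect_match(flagged$flag, "error:")

  # permuting input order changes nothing (output keyed by sample_id)
  perm <- st$incubation[rev(seq_len(nrow(st$incubation))), ]
  expect_identical(process_incubation_table(perm), rates)

  expect_error(process_incubation_table(st$incubation[0, ]), "empty")
  expect_error(process_incubation_table(rbind(st$incubation, st$incubation[1, ])),
               "duplicate")
})
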