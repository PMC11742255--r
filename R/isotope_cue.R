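# Microbial growth, respiration and carbon use efficiency from 18O-H2O
# quantitative stable isotope probing (qSIP) incubations.
#
# The chain of quantities is:
#   DNA produced (ug)  <- total O in the DNA extract and the 18O atom-percent
#                         excess of labeled over control DNA
#   growth (ng C/g/h)  <- DNA produced scaled by f_DNA = MBC / DNA content
#   respiration        <- blank-corrected headspace CO2 via the ideal gas law
#   CUE                <- growth / (growth + respiration)

#' Incubation physical configuration
#'
#' Physical constants and vial geometry entering the respiration and DNA
#' production calculations. Defaults describe a 24 h incubation at 15 degC in a
#' 20 ml headspace vial containing a 2 ml sample bottle (headspace 0.018 L)
#' at standard atmospheric pressure.
#'
#' @param pressure_kPa atmospheric pressure in kPa.
#' @param temperature_K incubation temperature in kelvin.
#' @param headspace_volume_L vial headspace volume in litres.
#' @param molar_mass_C molar mass of carbon, g mol^-1.
#' @param gas_constant ideal gas constant, J mol^-1 K^-1.
#' @param o_pct_in_dna average mass percentage of oxygen in DNA (31.21 for
#'   the canonical DNA monomer composition C39H44O24N15P4).
#' @return A list of class `incubation_config`.
#' @examples
#' incubation_config()
#' incubation_config(temperature_K = 298.15)
#' @export
incubation_config <- function(pressure_kPa = 101.325,
                              temperature_K = 288.15,
                              headspace_volume_L = 0.018,
                              molar_mass_C = 12.01,
                              gas_constant = 8.314,
                              o_pct_in_dna = 31.21) {
  cfg <- list(pressure_kPa = pressure_kPa,
              temperature_K = temperature_K,
              headspace_volume_L = headspace_volume_L,
              molar_mass_C = molar_mass_C,
              gas_constant = gas_constant,
              o_pct_in_dna = o_pct_in_dna)
  if (any(vapply(cfg, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1))))
    stop("all incubation_config values must be single positive numbers")
  structure(cfg, class = "incubation_config")
}

#' DNA produced during an 18O-H2O incubation
#'
#' Converts the oxygen pool of the extracted DNA and its 18O enrichment into
#' micrograms of newly synthesised DNA, assuming all oxygen in new DNA derives
#' from soil water at `atpct_final` atom percent 18O.
#'
#' @param O_total total O content of the dried DNA extract (ug).
#' @param atpct_labeled at% 18O of the labeled-sample DNA.
#' @param atpct_control at% 18O of the non-labeled control DNA.
#' @param atpct_final at% 18O of soil water at the start of incubation
#'   (20 in the standard labeling protocol).
#' @param o_pct_in_dna mass percentage of O in DNA (default 31.21).
#' @return Named list with `dna_produced` (ug) and logical `clipped`, TRUE
#'   when a negative atom-percent excess (measurement noise) was clipped to 0.
#' @examples
#' dna_produced(10, 5.2, 0.2, 20)$dna_produced  # 8.0103 ug
#' @export
dna_produced <- function(O_total, atpct_labeled, atpct_control,
                         atpct_final = 20, o_pct_in_dna = 31.21) {
  stopifnot(O_total >= 0, atpct_labeled >= 0, atpct_labeled <= 100,
            atpct_control >= 0, atpct_control <= 100)
  if (atpct_final <= 0)
    stop("atpct_final must be positive")
  if (atpct_final <= atpct_control)
    stop("atpct_final must exceed atpct_control: labeling impossible")
  excess <- atpct_labeled - atpct_control
  clipped <- excess < 0
  excess <- max(excess, 0)
  dna <- O_total * (excess / 100) * (100 / atpct_final) * (100 / o_pct_in_dna)
  list(dna_produced = dna, clipped = clipped)
}

#' Microbial growth rate from DNA production
#'
#' Scales DNA production to carbon growth using `f_dna`, the ratio of
#' microbial biomass carbon to extractable soil DNA content, both per gram of
#' dry soil.
#'
#' @param dna_produced_ug newly produced DNA (ug).
#' @param f_dna conversion factor MBC / DNA content (dimensionless, both in
#'   ug g^-1 soil).
#' @param DW dry weight of incubated soil (g).
#' @param t incubation time (h).
#' @return Growth rate in ng C g^-1 h^-1.
#' @examples
#' growth_rate(0.1, f_dna = 40, DW = 1, t = 24)  # 166.67
#' @export
growth_rate <- function(dna_produced_ug, f_dna, DW, t) {
  if (DW <= 0 || t <= 0) stop("DW and t must be positive")
  if (f_dna <= 0) stop("f_dna must be positive")
  f_dna * dna_produced_ug * 1000 / (DW * t)
}

#' Blank-correct a headspace CO2 reading
#'
#' Subtracts the mean CO2 of empty negative-control vials; negative results
#' (blank above sample, from instrument noise) are clipped to zero with a
#' warning.
#'
#' @param co2_ppm headspace CO2 of the sample vial (ppm).
#' @param blank_ppm_mean mean CO2 of the empty control vials (ppm).
#' @return Blank-corrected CO2 (ppm), never negative.
#' @examples
#' blank_correct(1050, 50)  # 1000
#' @export
blank_correct <- function(co2_ppm, blank_ppm_mean) {
  stopifnot(co2_ppm >= 0, blank_ppm_mean >= 0)
  rs <- co2_ppm - blank_ppm_mean
  if (rs < 0) {
    warning("blank CO2 exceeds sample CO2; clipping to 0")
    rs <- 0
  }
  rs
}

#' Microbial respiration rate from headspace CO2
#'
#' Converts a blank-corrected CO2 mixing ratio to a mass rate of carbon via
#' the ideal gas law: the headspace holds pV/RT moles of gas, of which
#' `Rs_ppm` parts per million are respired CO2.
#'
#' @param Rs_ppm blank-corrected CO2 accumulated over the incubation (ppm).
#' @param DW dry soil weight (g).
#' @param t incubation time (h).
#' @param config an [incubation_config()].
#' @return Respiration rate in ng C g^-1 h^-1.
#' @examples
#' respiration_rate(1000, DW = 1, t = 24)  # 380.97
#' @export
respiration_rate <- function(Rs_ppm, DW, t, config = incubation_config()) {
  if (Rs_ppm < 0) stop("Rs_ppm must be non-negative (blank-correct first)")
  if (DW <= 0 || t <= 0) stop("DW and t must be positive")
  (Rs_ppm / (DW * t)) *
    (config$pressure_kPa * config$molar_mass_C /
       (config$gas_constant * config$temperature_K)) *
    config$headspace_volume_L * 1000
}

#' Carbon use efficiency
#'
#' The fraction of total carbon uptake allocated to growth:
#' `growth / (growth + respiration)`, bounded in \[0, 1\].
#'
#' @param growth growth rate (ng C g^-1 h^-1).
#' @param respiration respiration rate (ng C g^-1 h^-1).
#' @return CUE in \[0, 1\], or `NA` when both rates are zero (undefined).
#' @examples
#' cue(100, 300)  # 0.25
#' @export
cue <- function(growth, respiration) {
  stopifnot(growth >= 0, respiration >= 0)
  if (growth + respiration == 0) return(NA_real_)
  growth / (growth + respiration)
}

#' Mass-specific rates and turnover
#'
#' Rates per unit microbial biomass carbon: qGrowth, qCO2 and qUptake are the
#' growth, respiration and uptake rates divided by MBC; turnover is defined
#' here as growth / MBC (the inverse of the mean residence time of biomass C
#' under steady growth — surfaced in output metadata since the field uses the
#' term loosely).
#'
#' @param growth,respiration growth and respiration rates (ng C g^-1 h^-1).
#' @param MBC microbial biomass carbon (ug C g^-1 soil).
#' @return Named list: `q_growth`, `q_co2`, `q_uptake` (ng C ug^-1 MBC h^-1)
#'   and `turnover` (h^-1 equivalent).
#' @examples
#' mass_specific_rates(200, 100, MBC = 100)
#' @export
mass_specific_rates <- function(growth, respiration, MBC) {
  if (MBC <= 0) stop("MBC must be positive")
  q_growth <- growth / MBC
  q_co2 <- respiration / MBC
  list(q_growth = q_growth, q_co2 = q_co2,
       q_uptake = q_growth + q_co2, turnover = q_growth)
}

#' Process a table of incubation records into microbial rates
#'
#' Applies the full qSIP chain to each row. Rows violating a precondition
#' (e.g. soil-water 18O not above the control DNA reading) are carried through
#' with missing rates and a reason code rather than dropped, so the output
#' always has one row per input sample.
#'
#' @param records data.frame with columns `sample_id`, `O_total`,
#'   `atpct_labeled`, `atpct_control`, `atpct_final`, `co2_ppm`,
#'   `blank_ppm_mean`, `DW`, `t`, `dna_content`, `MBC`.
#' @param config an [incubation_config()].
#' @return data.frame keyed by `sample_id` (sorted) with columns `growth`,
#'   `respiration`, `uptake`, `cue`, `q_growth`, `q_co2`, `q_uptake`,
#'   `turnover`, `f_dna` and a `flag` column ("" when clean).
#' @examples
#' rec <- data.frame(sample_id = "s1", O_total = 3.121, atpct_labeled = 0.344,
#'                   atpct_control = 0.2, atpct_final = 20, co2_ppm = 1050,
#'                   blank_ppm_mean = 50, DW = 1, t = 24, dna_content = 10,
#'                   MBC = 300)
#' process_incubation_table(rec)
#' @export
process_incubation_table <- function(records, config = incubation_config()) {
  required <- c("sample_id", "O_total", "atpct_labeled", "atpct_control",
                "atpct_final", "co2_ppm", "blank_ppm_mean", "DW", "t",
                "dna_content", "MBC")
  if (nrow(records) == 0) stop("empty incubation table")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("incubation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in incubation table")

  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    row <- data.frame(sample_id = r$sample_id, growth = NA_real_,
                      respiration = NA_real_, uptake = NA_real_,
                      cue = NA_real_, q_growth = NA_real_, q_co2 = NA_real_,
                      q_uptake = NA_real_, turnover = NA_real_,
                      f_dna = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    flags <- character(0)
    res <- tryCatch({
      dp <- dna_produced(r$O_total, r$atpct_labeled, r$atpct_control,
                         r$atpct_final, config$o_pct_in_dna)
      if (dp$clipped) flags <- c(flags, "negative_excess_clipped")
      f_dna <- r$MBC / r$dna_content
      g <- growth_rate(dp$dna_produced, f_dna, r$DW, r$t)
      rs <- withCallingHandlers(
        blank_correct(r$co2_ppm, r$blank_ppm_mean),
        warning = function(w) {
          flags <<- c(flags, "blank_exceeds_co2")
          invokeRestart("muffleWarning")
        })
      resp <- respiration_rate(rs, r$DW, r$t, config)
      q <- mass_specific_rates(g, resp, r$MBC)
      list(growth = g, respiration = resp, f_dna = f_dna, q = q)
    }, error = function(e) {
      flags <<- c(flags, paste0("error:", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      row$growth <- res$growth
      row$respiration <- res$respiration
      row$uptake <- res$growth + res$respiration
      row$cue <- cue(res$growth, res$respiration)
      row$q_growth <- res$q$q_growth
      row$q_co2 <- res$q$q_co2
      row$q_uptake <- res$q$q_uptake
      row$turnover <- res$q$turnover
      row$f_dna <- res$f_dna
    }
    row$flag <- paste(flags, collapse = ";")
    row
  })
  out <- do.call(rbind, out)
  out <- out[order(out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
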