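#' Reference equilibrium binding parameters for Sir3 constructs
#'
#' Apparent dissociation constants and Hill coefficients describing binding
#' of full-length Sir3 and its truncations (Sir3-delta-wH, Sir3BAH, with or
#' without the Sir4 coiled-coil) to mono- and di-nucleosome templates,
#' unmodified or carrying anti-silencing marks. BLI-derived values include
#' Hill coefficients; EMSA rows report apparent K_D only, since Hill
#' coefficients from EMSA are considered unreliable (gel artifacts,
#' non-specific DNA binding). Uncertainties are +/- 1 SD. These values
#' parameterize the default occupancy report and the synthetic-data
#' generators, so parameter-recovery tests double as regression checks
#' against the reference estimates.
#'
#' @return Data frame with columns `protein`, `template`, `modifications`,
#'   `assay`, `K_D_uM`, `sd_K_D`, `hill_n`, `sd_n`.
#' @export
sir3_equilibrium_params <- function() {
  df <- rbind(
    data.frame(protein = c("Sir3", "Sir3dwH", "Sir3BAH"),
               template = "MonoN", modifications = "",
               assay = "BLI_normalized_signal",
               K_D_uM = c(1.4, 1.2, 1.4), sd_K_D = c(0.06, 0.10, 0.10),
               hill_n = c(1.3, 0.93, 1.5), sd_n = c(0.1, 0.07, 0.2)),
    data.frame(protein = c("Sir3", "Sir3dwH", "Sir3BAH"),
               template = "DiN", modifications = "",
               assay = "BLI_normalized_signal",
               K_D_uM = c(0.12, 1.1, 1.6), sd_K_D = c(0.01, 0.05, 0.10),
               hill_n = c(1.9, 1.2, 1.4), sd_n = c(0.2, 0.1, 0.1)),
    data.frame(protein = c("Sir3", "Sir3+Sir4CC", "Sir3dwH",
                           "Sir3dwH+Sir4CC", "Sir3BAH"),
               template = "MonoN", modifications = "",
               assay = "EMSA_fraction_unbound",
               K_D_uM = c(1.7, 1.4, 1.0, 0.9, 2.1),
               sd_K_D = c(0.20, 0.10, 0.10, 0.05, 0.20),
               hill_n = NA_real_, sd_n = NA_real_),
    data.frame(protein = c("Sir3", "Sir3+Sir4CC", "Sir3dwH",
                           "Sir3dwH+Sir4CC", "Sir3BAH"),
               template = "DiN", modifications = "",
               assay = "EMSA_fraction_unbound",
               K_D_uM = c(0.17, 0.08, 0.62, 0.12, 1.40),
               sd_K_D = c(0.10, 0.01, 0.10, 0.01, 0.20),
               hill_n = NA_real_, sd_n = NA_real_),
    data.frame(protein = "Sir3",
               template = c("MonoN", "MonoN", "DiN", "DiN"),
               modifications = c("H4K16ac", "H3KC79me3",
                                 "H4K16ac", "H3KC79me3"),
               assay = "EMSA_fraction_unbound",
               K_D_uM = c(4.0, 5.2, 0.7, 0.8),
               sd_K_D = c(0.20, 0.20, 0.05, 0.05),
               hill_n = NA_real_, sd_n = NA_real_)
  )
  rownames(df) <- NULL
  df
}

#' Reference kinetic parameters for Sir3-nucleosome binding
#'
#' Amplitude fractions and rates of the exponential phases describing Sir3
#' association with and dissociation from mono- and di-nucleosome
#' templates at low protein concentration (< 0.3 uM), where binding is
#' specific and diffusion-limited. Mono-nucleosome binding of full-length
#' Sir3 is biphasic; di-nucleosome binding is mono-phasic. Association
#' rows carry observed saturation rates `k1_s`/`k2_s` (1/s); dissociation
#' rows carry time constants `tau1_s`/`tau2_s` (s). `A1_pct`/`A2_pct` are
#' percent of summed amplitude; `i` is the presumed number of binding
#' sites used when deriving `k_on`; `sd_*` columns are the reported +/- 1
#' SD over replicate measurements (`NA` where the underlying fit could not
#' determine the value, e.g. the minor fast association phase of
#' Sir3-delta-wH on DiN). Rows with a single phase have `NA` second-phase
#' entries. These rows parameterize [simulate_sensogram()] scenarios, so
#' kinetic recovery tests double as regression checks.
#'
#' @return Data frame with columns `protein`, `template`, `phase`,
#'   `A1_pct`, `k1_s`, `sd_k1`, `tau1_s`, `sd_tau1`, `A2_pct`, `k2_s`,
#'   `sd_k2`, `tau2_s`, `sd_tau2`, `i`.
#' @export
sir3_kinetic_params <- function() {
  df <- rbind(
    data.frame(protein = c("Sir3", "Sir3dwH", "Sir3BAH"),
               template = "MonoN", phase = "association",
               A1_pct = c(51, 73, 100),
               k1_s = c(0.25, 0.14, 0.65), sd_k1 = c(0.07, 0.06, 0.34),
               tau1_s = NA_real_, sd_tau1 = NA_real_,
               A2_pct = c(49, 27, 0),
               k2_s = c(0.04, 0.03, NA), sd_k2 = c(0.01, 0.01, NA),
               tau2_s = NA_real_, sd_tau2 = NA_real_, i = 2L),
    data.frame(protein = c("Sir3", "Sir3dwH", "Sir3BAH"),
               template = "DiN", phase = "association",
               A1_pct = c(100, 11, 100),
               k1_s = c(0.06, 0.16, 0.40), sd_k1 = c(0.01, NA, 0.18),
               tau1_s = NA_real_, sd_tau1 = NA_real_,
               A2_pct = c(0, 89, 0),
               k2_s = c(NA, 0.08, NA), sd_k2 = c(NA, 0.01, NA),
               tau2_s = NA_real_, sd_tau2 = NA_real_,
               i = c(1L, 4L, 4L)),
    data.frame(protein = c("Sir3", "Sir3dwH", "Sir3BAH"),
               template = "MonoN", phase = "dissociation",
               A1_pct = c(38, 56, 100),
               k1_s = NA_real_, sd_k1 = NA_real_,
               tau1_s = c(7.4, 8.4, 5.6), sd_tau1 = c(3.5, 0.9, 1.9),
               A2_pct = c(62, 44, 0),
               k2_s = NA_real_, sd_k2 = NA_real_,
               tau2_s = c(78.5, 75.3, NA), sd_tau2 = c(23.7, 3.6, NA),
               i = 2L),
    data.frame(protein = c("Sir3", "Sir3dwH", "Sir3BAH"),
               template = "DiN", phase = "dissociation",
               A1_pct = c(92, 52, 100),
               k1_s = NA_real_, sd_k1 = NA_real_,
               tau1_s = c(51.6, 10.8, 5.0), sd_tau1 = c(3.8, 1.2, 1.4),
               A2_pct = c(8, 48, 0),
               k2_s = NA_real_, sd_k2 = NA_real_,
               tau2_s = c(NA, 83.8, NA), sd_tau2 = c(NA, 6.5, NA),
               i = c(1L, 4L, 4L))
  )
  rownames(df) <- NULL
  df
}

#' Expand a kinetic parameter row into a generator scenario
#'
#' Turns one row of [sir3_kinetic_params()] into the amplitude/rate vectors
#' a sensogram generator or fit needs: phases with a finite rate (directly
#' or via `tau`) and positive amplitude are kept, amplitude fractions are
#' renormalized, and a logical `determined` marks rates the reference table
#' reports with an uncertainty.
#'
#' @param row single-row data frame from [sir3_kinetic_params()].
#' @return List with `amplitudes` (fractions summing to 1), `rates` (1/s,
#'   fast first), `order`, `phase`, `determined`.
#' @export
kinetic_scenario <- function(row) {
  stopifnot(nrow(row) == 1)
  if (row$phase == "association") {
    rates <- c(row$k1_s, row$k2_s); sds <- c(row$sd_k1, row$sd_k2)
  } else {
    rates <- 1 / c(row$tau1_s, row$tau2_s)
    sds <- c(row$sd_tau1, row$sd_tau2)
  }
  fr <- c(row$A1_pct, row$A2_pct)
  keep <- is.finite(rates) & fr > 0
  rates <- rates[keep]; fr <- fr[keep]; sds <- sds[keep]
  ord <- order(rates, decreasing = TRUE)
  list(amplitudes = fr[ord] / sum(fr[ord]), rates = rates[ord],
       order = length(rates), phase = row$phase,
       determined = is.finite(sds[ord]))
}
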