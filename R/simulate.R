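#' Simulation configuration
#'
#' Single configuration object for every synthetic-data generator in the
#' package. All randomness flows from `seed`; each generated object draws
#' from a substream at `seed + stream` so that individual objects are
#' reproducible in isolation. Identical configurations produce identical
#' output.
#'
#' Defaults emulate the assay conditions of the binding study: titrations
#' on a 12-point logarithmic concentration grid (0.01-10 uM) with 3 pooled
#' replicates and additive Gaussian noise of SD 0.03 response units;
#' sensograms sampled at 2 Hz with noise at 1% of total amplitude and a
#' linearly rising nonspecific drift; a toy genome of 16 chromosomes (32
#' subtelomeres) with ChIP signal decaying exponentially from the
#' chromosome end over a Poisson background.
#'
#' @param seed integer RNG seed.
#' @param noise_sd titration noise SD, response units.
#' @param conc_grid titration concentration grid, micromolar.
#' @param replicates number of replicate titrations pooled per curve.
#' @param sensogram_noise_frac sensogram noise SD as a fraction of total
#'   amplitude.
#' @param drift_slope nonspecific baseline drift, nm/s.
#' @param sampling_hz sensogram sampling rate, Hz.
#' @param n_chrom,chrom_length toy genome shape (chromosomes, bp each).
#' @param anchor_offset C-ACS anchor distance from each chromosome end, bp.
#' @param coverage_amplitude,coverage_decay subtelomeric ChIP domain peak
#'   amplitude (reads) and exponential decay length (bp).
#' @param coverage_background Poisson background mean (reads per base).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       noise_sd = 0.03,
                       conc_grid = 10^seq(log10(0.01), log10(10),
                                          length.out = 12),
                       replicates = 3L,
                       sensogram_noise_frac = 0.01,
                       drift_slope = 0.001,
                       sampling_hz = 2,
                       n_chrom = 16L,
                       chrom_length = 60000L,
                       anchor_offset = 1500L,
                       coverage_amplitude = 50,
                       coverage_decay = 3000,
                       coverage_background = 1) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            noise_sd >= 0, all(conc_grid >= 0), replicates >= 1,
            sensogram_noise_frac >= 0, sampling_hz > 0,
            n_chrom >= 1, chrom_length > 4 * anchor_offset,
            coverage_amplitude >= 0, coverage_decay > 0,
            coverage_background >= 0)
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 conc_grid = sort(conc_grid), replicates = as.integer(replicates),
                 sensogram_noise_frac = sensogram_noise_frac,
                 drift_slope = drift_slope, sampling_hz = sampling_hz,
                 n_chrom = as.integer(n_chrom),
                 chrom_length = as.integer(chrom_length),
                 anchor_offset = as.integer(anchor_offset),
                 coverage_amplitude = coverage_amplitude,
                 coverage_decay = coverage_decay,
                 coverage_background = coverage_background),
            class = "sim_config")
}

## seed the substream for one generated object
.sim_seed <- function(config, stream) {
  set.seed((config$seed + as.integer(stream)) %% .Machine$integer.max)
}

#' Simulate a noisy titration curve
#'
#' Generates responses from the Hill equation (or the two-independent-sites
#' model) on the configured concentration grid, adds Gaussian noise
#' truncated to `[0, 1]`, and pools the configured number of replicates
#' into one [titration_curve()]. With `noise_sd = 0` the responses lie
#' exactly on the generating model, enabling end-to-end identity tests.
#'
#' @param config a [sim_config()].
#' @param K_D generating dissociation constant, micromolar.
#' @param n generating Hill coefficient (ignored for `model = "two_site"`).
#' @param model generating model: `"hill"` or `"two_site"`.
#' @param assay readout convention, as in [titration_curve()].
#' @param stream RNG substream index (default 0).
#' @param ... metadata passed to [titration_curve()].
#' @return A [titration_curve()] with `replicates * length(conc_grid)`
#'   points.
#' @export
simulate_titration <- function(config, K_D, n = 1,
                               model = c("hill", "two_site"),
                               assay = c("BLI_normalized_signal",
                                         "EMSA_fraction_unbound"),
                               stream = 0L, ...) {
  stopifnot(inherits(config, "sim_config"))
  model <- match.arg(model)
  assay <- match.arg(assay)
  .sim_seed(config, stream)
  S <- rep(config$conc_grid, times = config$replicates)
  rid <- rep(seq_len(config$replicates), each = length(config$conc_grid))
  mu <- if (model == "hill") {
    kind <- if (assay == "EMSA_fraction_unbound") "fraction_unbound"
            else "normalized_signal"
    hill_response(S, K_D, n, kind = kind)
  } else {
    .assay_response(two_site_saturation(S, K_D), assay)
  }
  resp <- pmin(pmax(mu + rnorm(length(mu), 0, config$noise_sd), 0), 1)
  titration_curve(S, resp, assay = assay, replicate_id = rid, ...)
}

#' Simulate a BLI sensogram
#'
#' Generates a time course from a 1- or 2-phase exponential model
#' (association: saturating; dissociation: decaying onto baseline `B`),
#' optionally adds the configured linearly rising nonspecific drift and
#' Gaussian noise at `sensogram_noise_frac` of total amplitude. The trace
#' duration defaults to five time constants of the slowest phase, so every
#' phase is observed to near-completion.
#'
#' @param config a [sim_config()].
#' @param amplitudes phase amplitudes, nm (length 1 or 2).
#' @param rates phase rates, 1/s (same length as `amplitudes`).
#' @param phase `"association"` or `"dissociation"`.
#' @param B dissociation baseline, nm.
#' @param conc_uM protein concentration metadata, micromolar.
#' @param duration trace length, s (default `5 / min(rates)`).
#' @param drift if `TRUE`, add `config$drift_slope * t`.
#' @param noise if `FALSE`, suppress noise regardless of config.
#' @param stream RNG substream index (default 0).
#' @param template_label template metadata.
#' @return A [sensogram_trace()].
#' @export
simulate_sensogram <- function(config, amplitudes, rates,
                               phase = c("association", "dissociation"),
                               B = 0, conc_uM = NA_real_, duration = NULL,
                               drift = FALSE, noise = TRUE, stream = 0L,
                               template_label = "DiN") {
  stopifnot(inherits(config, "sim_config"),
            length(amplitudes) == length(rates),
            length(rates) %in% c(1, 2), all(rates > 0),
            all(amplitudes >= 0))
  phase <- match.arg(phase)
  .sim_seed(config, stream)
  if (is.null(duration)) duration <- 5 / min(rates)
  ## short traces (fast phases) are sampled finer so every trace carries at
  ## least 100 points, as an instrument acquiring short steps would
  dt <- min(1 / config$sampling_hz, duration / 100)
  time <- seq(0, duration, by = dt)
  p <- list(A1 = amplitudes[1], k1 = rates[1],
            A2 = if (length(rates) == 2) amplitudes[2] else 0,
            k2 = if (length(rates) == 2) rates[2] else 1, B = B)
  mu <- .exp_model(time, phase, length(rates), p)
  if (drift) mu <- mu + config$drift_slope * time
  if (noise && config$sensogram_noise_frac > 0)
    mu <- mu + rnorm(length(mu), 0,
                     config$sensogram_noise_frac * sum(amplitudes))
  sensogram_trace(time, mu, phase = phase, protein_conc_uM = conc_uM,
                  template_label = template_label)
}

#' Simulate subtelomeric coverage tracks and anchors
#'
#' Builds a toy genome of `n_chrom` chromosomes (32 subtelomeres for the
#' default 16) in which the ChIP sample carries an exponentially decaying
#' signal domain at every chromosome end,
#' `amplitude * exp(-d / decay)` with `d` the distance from the end, over
#' a Poisson background; the control sample (emulating a sir3 deletion) is
#' background only. C-ACS anchors are placed `anchor_offset` bp from each
#' end, oriented toward the centromere; the anchor set carries the two
#' conventional exclusions (TEL01R, TEL13R), leaving 30 subtelomeres.
#'
#' @param config a [sim_config()].
#' @param stream RNG substream index (default 0).
#' @return List with `signal` and `control` [coverage_track()]s and
#'   `anchors` (an [anchor_set()] of kind `C_ACS`).
#' @export
simulate_coverage <- function(config, stream = 0L) {
  stopifnot(inherits(config, "sim_config"))
  .sim_seed(config, stream)
  chroms <- sprintf("chr%02d", seq_len(config$n_chrom))
  L <- config$chrom_length
  pos <- seq_len(L)
  d_end <- pmin(pos - 1L, L - pos)  # distance to nearest chromosome end
  dom <- config$coverage_amplitude * exp(-d_end / config$coverage_decay)
  signal <- control <- vector("list", length(chroms))
  names(signal) <- names(control) <- chroms
  for (ch in chroms) {
    bg1 <- rpois(L, config$coverage_background)
    bg2 <- rpois(L, config$coverage_background)
    signal[[ch]] <- dom + bg1
    control[[ch]] <- as.numeric(bg2)
  }
  entries <- do.call(rbind, lapply(seq_along(chroms), function(i) {
    data.frame(
      name = sprintf("TEL%02d%s", i, c("L", "R")),
      chrom = chroms[i],
      pos = c(config$anchor_offset + 1L, L - config$anchor_offset),
      orientation = c("+", "-")
    )
  }))
  list(signal = coverage_track(signal, genome = "toy"),
       control = coverage_track(control, genome = "toy"),
       anchors = anchor_set(entries, kind = "C_ACS"))
}

#' Simulate a ChIP-qPCR CT table
#'
#' Generates threshold-cycle values for a set of samples and loci with
#' known fold enrichments over a control sample: each true template amount
#' halves CT by one cycle per two-fold enrichment, and replicate CTs get
#' Gaussian jitter. The reference gene is enriched in no sample.
#'
#' @param config a [sim_config()]; `noise_sd` is reused as the CT jitter
#'   SD (cycles) scaled by `ct_jitter`.
#' @param fold matrix or data frame of true fold enrichments (samples in
#'   rows, loci in columns) relative to the control sample.
#' @param control_sample control sample name, appended with fold 1 at
#'   every locus.
#' @param reference_gene reference locus name.
#' @param base_ct CT of an unenriched locus.
#' @param replicates biological replicates per sample.
#' @param ct_jitter replicate CT SD in cycles.
#' @param stream RNG substream index (default 0).
#' @return Data frame with columns `sample`, `locus`, `replicate`, `ct`
#'   suitable for [qpcr_fold_enrichment()].
#' @export
simulate_qpcr <- function(config, fold, control_sample = "sir3d",
                          reference_gene = "cup1", base_ct = 25,
                          replicates = 3L, ct_jitter = 0.05, stream = 0L) {
  stopifnot(inherits(config, "sim_config"))
  fold <- as.matrix(fold)
  .sim_seed(config, stream)
  samples <- c(rownames(fold), control_sample)
  loci <- c(colnames(fold), reference_gene)
  rows <- list()
  for (s in samples) {
    for (l in loci) {
      f <- if (s == control_sample || l == reference_gene) 1
           else fold[s, l]
      ct0 <- base_ct - log2(f)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, locus = l, replicate = seq_len(replicates),
        ct = ct0 + rnorm(replicates, 0, ct_jitter))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
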