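#' Construct a BLI sensogram trace
#'
#' One biolayer-interferometry time course (wavelength shift in nm versus
#' time in seconds) for a single sensor, phase and protein concentration.
#' Time is re-zeroed to the first sample: association and dissociation
#' phases are each aligned at time zero, and absolute signal offsets carry
#' no meaning (dissociation traces may start from an arbitrary value).
#'
#' @param time numeric, seconds, monotone increasing; at least 20 samples.
#' @param signal numeric, nm wavelength shift, same length as `time`.
#' @param phase `"association"` or `"dissociation"`.
#' @param protein_conc_uM protein concentration in micromolar (metadata;
#'   used by [derive_kon()]).
#' @param template_label template metadata, e.g. `"MonoN"`, `"DiN"`.
#' @return An object of class `sensogram_trace`.
#' @export
sensogram_trace <- function(time, signal,
                            phase = c("association", "dissociation"),
                            protein_conc_uM = NA_real_,
                            template_label = "DiN") {
  phase <- match.arg(phase)
  stopifnot(length(time) == length(signal))
  if (length(time) < 20) stop("need at least 20 samples per trace")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  structure(
    list(time = time - time[1], signal = signal, phase = phase,
         protein_conc_uM = protein_conc_uM, template_label = template_label),
    class = "sensogram_trace"
  )
}

#' @export
print.sensogram_trace <- function(x, ...) {
  cat(sprintf("Sensogram: %s phase, %s, [S] = %.3g uM\n", x$phase,
              x$template_label, x$protein_conc_uM))
  cat(sprintf("  %d samples over %.1f s, signal range %.3g-%.3g nm\n",
              length(x$time), max(x$time), min(x$signal), max(x$signal)))
  invisible(x)
}

#' Subtract a linearly rising nonspecific baseline
#'
#' Nonspecific protein-sensor interactions produce a linearly rising
#' baseline on top of the exponential binding signal; this removes
#' `slope * t + intercept` from the trace (non-destructively). The slope is
#' normally estimated from an empty-sensor control at the same protein
#' concentration via [estimate_drift()].
#'
#' @param trace a [sensogram_trace()].
#' @param control_slope baseline slope in nm/s.
#' @param intercept baseline intercept in nm (default 0).
#' @return A corrected `sensogram_trace`.
#' @export
correct_baseline <- function(trace, control_slope, intercept = 0) {
  stopifnot(inherits(trace, "sensogram_trace"), is.finite(control_slope))
  out <- trace
  out$signal <- trace$signal - control_slope * trace$time - intercept
  out
}

#' Estimate linear drift from an empty-sensor control trace
#'
#' Ordinary least-squares slope and intercept of signal versus time on a
#' control trace containing only nonspecific drift (plus noise).
#'
#' @param trace a [sensogram_trace()] from an empty sensor.
#' @return Named numeric vector `c(slope, intercept)` (nm/s, nm).
#' @export
estimate_drift <- function(trace) {
  stopifnot(inherits(trace, "sensogram_trace"))
  cf <- coef(lm(trace$signal ~ trace$time))
  c(slope = unname(cf[2]), intercept = unname(cf[1]))
}

## model evaluation for a given phase/order
.exp_model <- function(time, phase, order, p) {
  if (phase == "association") {
    if (order == 1) p$A1 * (1 - exp(-p$k1 * time))
    else p$A1 * (1 - exp(-p$k1 * time)) + p$A2 * (1 - exp(-p$k2 * time))
  } else {
    if (order == 1) p$A1 * exp(-p$k1 * time) + p$B
    else p$A1 * exp(-p$k1 * time) + p$A2 * exp(-p$k2 * time) + p$B
  }
}

## crude rate guess: time to half range
.rate_guess <- function(time, signal, phase) {
  rng <- range(signal)
  if (phase == "association") {
    i <- which(signal - rng[1] >= 0.5 * diff(rng))[1]
  } else {
    i <- which(rng[2] - signal >= 0.5 * diff(rng))[1]
  }
  th <- time[max(i, 2)]
  if (!is.finite(th) || th <= 0) th <- max(time) / 4
  log(2) / th
}

#' Fit a mono- or bi-exponential model to a sensogram phase
#'
#' Least-squares fit of the phase-appropriate rate equation to a
#' baseline-corrected trace. Association:
#' `A1 (1 - exp(-k1 t)) [+ A2 (1 - exp(-k2 t))]` (no constant term);
#' dissociation: `A1 exp(-k1 t) [+ A2 exp(-k2 t)] + B`, with the baseline
#' `B` free. For `order = 2` the phases are reported fast-to-slow
#' (`k1 > k2`) and amplitude fractions as percent of summed amplitude.
#' Rates within 5% of each other are flagged as collapsed
#' (`collapsed = TRUE`): such a fit is effectively first order and model
#' selection falls back to order 1.
#'
#' Initialization: the overall rate from the time to half signal range
#' (fast/slow starts bracket it for order 2), amplitudes from the signal
#' range.
#'
#' @param trace a baseline-corrected [sensogram_trace()].
#' @param order 1 or 2 exponential phases.
#' @return An object of class `exp_fit`: amplitudes `A` (nm), rates `k`
#'   (1/s), `tau` (s, `1/k`), `amplitude_fractions` (percent),
#'   dissociation baseline `B`, `residuals`, `rss`, `phase`, `order`.
#' @export
fit_exponential <- function(trace, order = 1) {
  stopifnot(inherits(trace, "sensogram_trace"), order %in% c(1, 2))
  time <- trace$time; signal <- trace$signal
  phase <- trace$phase
  rng <- diff(range(signal))
  if (rng <= 0) stop("flat trace cannot be fit")
  k0 <- .rate_guess(time, signal, phase)
  lo_k <- 1e-6; hi_k <- 1e3
  rf <- function(p) signal - .exp_model(time, phase, order, as.list(p))
  start <- if (phase == "association" && order == 1) {
    c(A1 = max(signal), k1 = k0)
  } else if (phase == "association" && order == 2) {
    c(A1 = max(signal) / 2, k1 = 4 * k0, A2 = max(signal) / 2, k2 = k0 / 4)
  } else if (phase == "dissociation" && order == 1) {
    c(A1 = rng, k1 = k0, B = min(signal))
  } else {
    c(A1 = rng / 2, k1 = 4 * k0, A2 = rng / 2, k2 = k0 / 4, B = min(signal))
  }
  bound <- function(v) {
    lo <- c(A1 = 0, k1 = lo_k, A2 = 0, k2 = lo_k, B = -Inf)
    hi <- c(A1 = Inf, k1 = hi_k, A2 = Inf, k2 = hi_k, B = Inf)
    if (v == "lo") lo[names(start)] else hi[names(start)]
  }
  fit <- tryCatch(
    .lm_fit(rf, start = start, lower = bound("lo"), upper = bound("hi")),
    error = function(e) stop("exponential fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  if (order == 2) {
    ## the bi-exponential model nests the mono-exponential one: also start
    ## from the order-1 optimum (second phase at zero amplitude) so the
    ## order-2 rss can never exceed the order-1 rss
    f1 <- fit_exponential(trace, order = 1)
    nested <- c(A1 = f1$A[1], k1 = f1$k[1], A2 = 0,
                k2 = max(f1$k[1] / 10, lo_k))
    if (phase == "dissociation") nested <- c(nested, B = f1$B)
    fit_n <- tryCatch(
      .lm_fit(rf, start = nested[names(start)], lower = bound("lo"),
              upper = bound("hi")),
      error = function(e) NULL)
    if (!is.null(fit_n) && fit_n$rss < fit$rss) fit <- fit_n
  }
  cf <- as.list(fit$par)
  B <- if (phase == "dissociation") cf$B else 0
  if (order == 1) {
    A <- cf$A1; k <- cf$k1
  } else {
    A <- c(cf$A1, cf$A2); k <- c(cf$k1, cf$k2)
    ord <- order(k, decreasing = TRUE)  # fast phase first
    A <- A[ord]; k <- k[ord]
  }
  collapsed <- order == 2 &&
    (abs(k[1] - k[2]) / max(k) < 0.05 || min(A) / sum(A) < 1e-3)
  structure(
    list(order = order, phase = phase, A = A, k = k, tau = 1 / k, B = B,
         amplitude_fractions = 100 * A / sum(A),
         residuals = fit$residuals, rss = fit$rss,
         collapsed = collapsed, n_par = length(start),
         n_obs = length(time), trace = trace, fit = fit),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("%s fit, order %d%s:\n", x$phase, x$order,
              if (isTRUE(x$collapsed)) " (rates collapsed: effective order 1)"
              else ""))
  for (i in seq_along(x$k))
    cat(sprintf("  phase %d: %.0f%% amplitude, k = %.4g /s (tau = %.3g s)\n",
                i, x$amplitude_fractions[i], x$k[i], x$tau[i]))
  if (x$phase == "dissociation")
    cat(sprintf("  baseline B = %.3g nm\n", x$B))
  cat(sprintf("  rss = %.4g nm^2 on %d points\n", x$rss, x$n_obs))
  invisible(x)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' Tests whether the sign sequence of fit residuals is random. Systematic
#' (periodic) sign changes around a mis-specified model produce too few
#' runs; the normal approximation to the run-count distribution gives a
#' two-sided p-value. Zero residuals are dropped.
#'
#' @param residuals numeric residual series (time-ordered).
#' @return List with `n_runs`, `expected_runs`, `z`, `p_value`.
#' @export
runs_test <- function(residuals) {
  s <- sign(residuals)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(n_runs = 1, expected_runs = 1, z = 0, p_value = 1))
  r <- 1 + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (r - mu) / sqrt(v)
  list(n_runs = r, expected_runs = mu, z = z,
       p_value = 2 * pnorm(-abs(z)))
}

#' Choose between mono- and bi-exponential fits
#'
#' Order 2 is accepted only when both diagnostics agree that the
#' mono-exponential model is inadequate: an extra-sum-of-squares F-test
#' shows a substantial rss decrease (p < `alpha_f`) AND the order-1
#' residual sign sequence is non-random by a runs test (p < `alpha_runs`).
#' A bi-exponential fit whose rates collapsed is never selected.
#'
#' @param fit1,fit2 order-1 and order-2 [fit_exponential()] results on the
#'   same trace.
#' @param alpha_f F-test significance level (default 0.01).
#' @param alpha_runs runs-test significance level (default 0.05).
#' @return List of class `model_selection`: `chosen_order`, `f_test_p`,
#'   `runs_test_p`, `rss_ratio`.
#' @export
select_model_order <- function(fit1, fit2, alpha_f = 0.01,
                               alpha_runs = 0.05) {
  stopifnot(inherits(fit1, "exp_fit"), inherits(fit2, "exp_fit"),
            fit1$order == 1, fit2$order == 2,
            fit1$n_obs == fit2$n_obs)
  n <- fit1$n_obs
  df1 <- fit2$n_par - fit1$n_par
  df2 <- n - fit2$n_par
  f <- ((fit1$rss - fit2$rss) / df1) / (fit2$rss / df2)
  f_p <- if (is.finite(f) && f > 0) pf(f, df1, df2, lower.tail = FALSE) else 1
  runs_p <- runs_test(fit1$residuals)$p_value
  chosen <- if (!isTRUE(fit2$collapsed) && f_p < alpha_f &&
                runs_p < alpha_runs) 2L else 1L
  structure(list(chosen_order = chosen, f_test_p = f_p,
                 runs_test_p = runs_p,
                 rss_ratio = fit1$rss / fit2$rss),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf(
    "Model selection: order %d (F-test p = %.3g, runs-test p = %.3g, rss ratio = %.3g)\n",
    x$chosen_order, x$f_test_p, x$runs_test_p, x$rss_ratio))
  invisible(x)
}

#' Derive the association rate constant
#'
#' `k_on = (k_obs - k_off) / (i * S)`, where `i` is the presumed number of
#' binding sites on the template and `S` the protein concentration.
#' Concentration is supplied in micromolar; `k_on` is returned in 1/M/s.
#' Rates from bi-exponential fits are paired by phase: `(k_obs,1, k_off,1)`
#' and `(k_obs,2, k_off,2)`. When `k_obs < k_off` the result is negative
#' and flagged with a warning rather than clamped.
#'
#' @param k_obs observed saturation rate(s), 1/s.
#' @param k_off dissociation rate(s), 1/s, paired with `k_obs`.
#' @param i presumed number of binding sites (positive integer).
#' @param S_uM protein concentration, micromolar (`> 0`).
#' @return List of class `rate_constants`: `k_on` (1/M/s), inputs, and
#'   `flagged` for negative results.
#' @export
derive_kon <- function(k_obs, k_off, i = 1L, S_uM) {
  stopifnot(length(k_obs) == length(k_off))
  if (!is.finite(S_uM) || S_uM <= 0) stop("S_uM must be positive")
  if (i < 1 || i != round(i)) stop("i must be a positive integer")
  k_on <- (k_obs - k_off) / (i * S_uM * 1e-6)
  flagged <- k_on < 0
  if (any(flagged))
    warning("k_obs < k_off: negative k_on reported (flagged, not clamped)")
  structure(list(k_on = k_on, i = as.integer(i), k_obs = k_obs,
                 k_off = k_off, S_uM = S_uM, flagged = flagged),
            class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  for (j in seq_along(x$k_on))
    cat(sprintf("k_on,%d = %.3g /M/s (k_obs = %.3g, k_off = %.3g, i = %d, [S] = %.3g uM)%s\n",
                j, x$k_on[j], x$k_obs[j], x$k_off[j], x$i, x$S_uM,
                if (x$flagged[j]) " [flagged: k_obs < k_off]" else ""))
  invisible(x)
}

#' Amplitude-weighted mean residence time
#'
#' Summary residence time of a dissociation fit:
#' `sum(fraction_i * tau_i)` over the exponential phases, with fractions
#' taken from the fitted amplitudes.
#'
#' @param fit a dissociation [fit_exponential()] result, or a list with
#'   `amplitude_fractions` (percent) and `tau` (s).
#' @return Residence time in seconds.
#' @export
residence_summary <- function(fit) {
  if (inherits(fit, "exp_fit") && fit$phase != "dissociation")
    stop("residence time is defined for dissociation fits")
  sum(fit$amplitude_fractions / 100 * fit$tau)
}
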