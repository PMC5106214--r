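#' Construct a titration curve
#'
#' Container for one equilibrium titration: protein concentration versus
#' binding response, read out either as the EMSA fraction of free (unshifted)
#' nucleosomes or as the min-max normalized BLI equilibrium signal. Points
#' from replicate titrations are pooled in a single curve (a `replicate_id`
#' column keeps their provenance); pooling, rather than per-concentration
#' averaging, is the fitting convention used throughout.
#'
#' @param concentration_uM numeric, protein concentrations in micromolar.
#'   Non-negative; a zero point is allowed.
#' @param response numeric, dimensionless response in `[0, 1]`.
#' @param assay `"EMSA_fraction_unbound"` or `"BLI_normalized_signal"`.
#' @param protein_label,template_label curve metadata. `template_label` is
#'   conventionally one of `"MonoN"`, `"DiN"`, `"TriN"`, `"TetraN"`.
#' @param modifications character vector of histone marks carried by the
#'   template, subset of `c("H4K16ac", "H3KC79me3")`.
#' @param replicate_id optional replicate labels, recycled to length.
#'
#' @return An object of class `titration_curve`: a list with `points`
#'   (a data frame sorted by concentration), `assay`, and metadata fields.
#' @export
titration_curve <- function(concentration_uM, response,
                            assay = c("EMSA_fraction_unbound",
                                      "BLI_normalized_signal"),
                            protein_label = "Sir3",
                            template_label = "DiN",
                            modifications = character(),
                            replicate_id = 1L) {
  assay <- match.arg(assay)
  stopifnot(length(concentration_uM) == length(response))
  if (any(concentration_uM < 0)) stop("negative concentrations not allowed")
  if (any(!is.finite(response))) stop("non-finite responses")
  if (any(response < -0.05 | response > 1.05))
    stop("responses must lie in [0, 1] (small numeric overshoot tolerated)")
  bad <- setdiff(modifications, c("H4K16ac", "H3KC79me3"))
  if (length(bad)) stop("unknown modifications: ", paste(bad, collapse = ", "))
  pts <- data.frame(
    concentration_uM = concentration_uM,
    response = pmin(pmax(response, 0), 1),
    replicate_id = rep_len(replicate_id, length(response))
  )
  pts <- pts[order(pts$concentration_uM), , drop = FALSE]
  rownames(pts) <- NULL
  structure(
    list(points = pts, assay = assay, protein_label = protein_label,
         template_label = template_label,
         modifications = sort(unique(modifications))),
    class = "titration_curve"
  )
}

#' @export
print.titration_curve <- function(x, ...) {
  mods <- if (length(x$modifications))
    paste(x$modifications, collapse = "+") else "unmodified"
  cat(sprintf("Titration: %s on %s (%s), %s\n", x$protein_label,
              x$template_label, mods, x$assay))
  cat(sprintf("  %d points, [S] %.3g-%.3g uM, %d replicate(s)\n",
              nrow(x$points), min(x$points$concentration_uM),
              max(x$points$concentration_uM),
              length(unique(x$points$replicate_id))))
  invisible(x)
}

#' Hill binding isotherm
#'
#' Phenomenological cooperative binding transition. With `x = (S/K_D)^n`,
#' the fraction of free nucleosomes (EMSA readout) is `1/(1 + x)` and the
#' normalized bound signal (BLI readout) is `x/(1 + x)`; the two always sum
#' to one. `K_D` is the protein concentration at the transition midpoint and
#' `n` is the Hill coefficient, a steepness descriptor: values near 1 mean
#' non-cooperative binding, values above 1 positive cooperativity. Free
#' protein is approximated by total protein concentration.
#'
#' @param S protein concentration, micromolar (vectorized, `>= 0`).
#' @param K_D apparent dissociation constant, micromolar (`> 0`).
#' @param n Hill coefficient (`> 0`).
#' @param kind `"fraction_unbound"` or `"normalized_signal"`.
#' @return Dimensionless response in `[0, 1]`.
#' @examples
#' hill_response(0.12, K_D = 0.12, n = 1.9, kind = "normalized_signal") # 0.5
#' @export
hill_response <- function(S, K_D, n,
                          kind = c("fraction_unbound", "normalized_signal")) {
  kind <- match.arg(kind)
  if (!is.finite(K_D) || K_D <= 0) stop("K_D must be positive")
  if (!is.finite(n) || n <= 0) stop("Hill coefficient n must be positive")
  if (any(S < 0)) stop("concentrations must be non-negative")
  x <- (S / K_D)^n
  if (kind == "fraction_unbound") 1 / (1 + x) else x / (1 + x)
}

#' Two identical independent sites saturation
#'
#' Fractional saturation of two identical, non-interacting binding sites
#' (the two faces of a nucleosome core particle). The binding polynomial
#' of two independent sites with per-site macroscopic dissociation
#' constant `K_D_macro` is `(1 + x)^2` with `x = S/K_D_macro`, giving
#' fractional saturation
#' `Theta = (x + x^2) / (1 + 2x + x^2) = x / (1 + x)`:
#' `Theta(0) = 0`, `Theta(K_D_macro) = 1/2`, `Theta -> 1` at saturation.
#' Because the sites are independent, the isotherm is exactly
#' non-cooperative: a Hill fit to data following this model returns
#' `n = 1`, which is how absence of cooperativity is recognized
#' operationally.
#'
#' @param S protein concentration, micromolar (vectorized, `>= 0`).
#' @param K_D_macro macroscopic dissociation constant, micromolar (`> 0`).
#' @return Fractional saturation in `[0, 1)`.
#' @export
two_site_saturation <- function(S, K_D_macro) {
  if (!is.finite(K_D_macro) || K_D_macro <= 0)
    stop("K_D_macro must be positive")
  if (any(S < 0)) stop("concentrations must be non-negative")
  x <- S / K_D_macro
  (x + x^2) / (1 + 2 * x + x^2)
}

## response in the assay's own convention (EMSA reads disappearance of the
## free band, BLI reads appearance of bound signal)
.assay_response <- function(theta_bound, assay) {
  if (assay == "EMSA_fraction_unbound") 1 - theta_bound else theta_bound
}

## Levenberg-Marquardt least squares over a residual function, with
## parameter standard errors from the Jacobian-based covariance at the
## optimum. nls.lm tolerates rank-deficient Jacobians (damping), which
## matters when an overparameterized model meets degenerate data; in that
## case the covariance is singular and the SEs are reported as NA.
.lm_fit <- function(resid_fn, start, lower, upper) {
  out <- minpack.lm::nls.lm(
    par = start, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15))
  if (out$info == 0 || out$info == 9)
    stop("nonlinear least squares did not converge (info ", out$info, ")")
  se <- tryCatch(
    summary(out)$coefficients[, "Std. Error"],
    error = function(e) setNames(rep(NA_real_, length(start)), names(start)))
  names(se) <- names(start)
  list(par = out$par, se = se, residuals = as.numeric(out$fvec),
       rss = out$deviance)
}

#' Fit the Hill equation to a titration curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) over `(K_D, n)`, with the
#' model form chosen by the curve's assay: fraction-unbound for EMSA,
#' normalized signal for BLI. Starting values are `K_D` at the concentration
#' nearest half-response and `n = 1`; parameters are bounded to
#' `K_D <= 100` uM and `n <= 6`. Uncertainties are +/- 1 SD from the
#' Jacobian-based covariance at the optimum (68% confidence), the
#' convention used for the reported thermodynamic parameter tables.
#'
#' Hill coefficients fitted to EMSA curves are tagged low-confidence
#' (`n_confidence = "low"`): non-specific binding to DNA and other gel
#' artifacts distort the EMSA transition shape, so only BLI-derived `n` is
#' treated as a reliable cooperativity estimate.
#'
#' @param curve a [titration_curve()] with at least 5 points spanning the
#'   transition.
#' @return An object of class `hill_fit`: list with `K_D`, `n`, `sd_K_D`,
#'   `sd_n`, `rss`, `n_confidence`, `curve` metadata and the `nls` fit.
#' @seealso [fit_two_site()] for the one-parameter non-cooperative model.
#' @export
fit_hill <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  pts <- curve$points
  if (nrow(pts) < 5) stop("need at least 5 titration points")
  if (diff(range(pts$response)) < 0.05)
    stop("degenerate (flat) titration: response range < 0.05; cannot fit")
  kind <- if (curve$assay == "EMSA_fraction_unbound")
    "fraction_unbound" else "normalized_signal"
  ## start K_D at concentration nearest half response
  pos <- pts$concentration_uM > 0
  half <- which.min(abs(pts$response[pos] - 0.5))
  K0 <- pts$concentration_uM[pos][half]
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(pts$concentration_uM[pos])
  rf <- function(p) pts$response -
    hill_response(pts$concentration_uM, p[["K_D"]], p[["n"]], kind = kind)
  fit <- tryCatch(
    .lm_fit(rf, start = c(K_D = K0, n = 1),
            lower = c(K_D = 1e-6, n = 1e-3), upper = c(K_D = 100, n = 6)),
    error = function(e) stop("Hill fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  structure(
    list(K_D = unname(fit$par[["K_D"]]), n = unname(fit$par[["n"]]),
         sd_K_D = unname(fit$se[["K_D"]]), sd_n = unname(fit$se[["n"]]),
         rss = fit$rss,
         n_confidence = if (kind == "fraction_unbound") "low" else "high",
         assay = curve$assay, protein_label = curve$protein_label,
         template_label = curve$template_label,
         modifications = curve$modifications, fit = fit),
    class = c("hill_fit", "binding_fit")
  )
}

#' Fit the two-identical-independent-sites model
#'
#' One-parameter nonlinear least-squares fit of [two_site_saturation()] to a
#' titration curve (EMSA curves are fit as `1 - Theta`). Same optimizer,
#' starting-value and uncertainty conventions as [fit_hill()].
#'
#' @inheritParams fit_hill
#' @return An object of class `two_site_fit`: list with `K_D_macro`,
#'   `sd_K_D_macro`, `rss`, metadata and the `nls` fit.
#' @export
fit_two_site <- function(curve) {
  stopifnot(inherits(curve, "titration_curve"))
  pts <- curve$points
  if (nrow(pts) < 5) stop("need at least 5 titration points")
  if (diff(range(pts$response)) < 0.05)
    stop("degenerate (flat) titration: response range < 0.05; cannot fit")
  assay <- curve$assay
  pos <- pts$concentration_uM > 0
  half <- which.min(abs(pts$response[pos] - 0.5))
  K0 <- pts$concentration_uM[pos][half]
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(pts$concentration_uM[pos])
  rf <- function(p) pts$response -
    .assay_response(two_site_saturation(pts$concentration_uM,
                                        p[["K_D_macro"]]), assay)
  fit <- tryCatch(
    .lm_fit(rf, start = c(K_D_macro = K0),
            lower = c(K_D_macro = 1e-6), upper = c(K_D_macro = 100)),
    error = function(e) stop("two-site fit failed to converge: ",
                             conditionMessage(e), call. = FALSE)
  )
  structure(
    list(K_D_macro = unname(fit$par[["K_D_macro"]]),
         sd_K_D_macro = unname(fit$se[["K_D_macro"]]),
         rss = fit$rss,
         assay = curve$assay, protein_label = curve$protein_label,
         template_label = curve$template_label,
         modifications = curve$modifications, fit = fit),
    class = c("two_site_fit", "binding_fit")
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: %s / %s (%s)\n", x$protein_label, x$template_label,
              x$assay))
  cat(sprintf("  K_D = %.3g +/- %.2g uM; n = %.3g +/- %.2g%s; rss = %.3g\n",
              x$K_D, x$sd_K_D, x$n, x$sd_n,
              if (x$n_confidence == "low") " (low confidence)" else "",
              x$rss))
  invisible(x)
}

#' @export
print.two_site_fit <- function(x, ...) {
  cat(sprintf("Two-site fit: %s / %s (%s)\n", x$protein_label,
              x$template_label, x$assay))
  cat(sprintf("  K_D(macro) = %.3g +/- %.2g uM; rss = %.3g\n",
              x$K_D_macro, x$sd_K_D_macro, x$rss))
  invisible(x)
}

#' Min-max normalize a raw binding signal
#'
#' Affine map of a raw titration signal to `[0, 1]` (minimum to 0, maximum
#' to 1), the normalization applied to BLI equilibrium amplitudes before
#' Hill fitting. Order-preserving; idempotent on already-normalized data.
#'
#' @param concentration_uM protein concentrations, micromolar.
#' @param signal raw signal values; at least two distinct values.
#' @param ... metadata passed to [titration_curve()] (assay defaults to
#'   `"BLI_normalized_signal"`).
#' @return A [titration_curve()] with normalized responses.
#' @export
normalize_minmax <- function(concentration_uM, signal, ...) {
  if (length(signal) < 2) stop("need at least 2 signal values")
  rng <- range(signal)
  if (diff(rng) == 0) stop("constant signal cannot be min-max normalized")
  resp <- (signal - rng[1]) / diff(rng)
  args <- list(...)
  if (is.null(args$assay)) args$assay <- "BLI_normalized_signal"
  do.call(titration_curve,
          c(list(concentration_uM = concentration_uM, response = resp), args))
}

#' Affinity fold change between two fits
#'
#' Ratio of apparent dissociation constants `K_D(a) / K_D(b)`; values above
#' 1 mean `b` binds more tightly. Accepts `hill_fit`, `two_site_fit`, or
#' bare numeric `K_D` values.
#'
#' @param fit_a,fit_b binding fits or positive numbers (micromolar).
#' @return Dimensionless fold change.
#' @export
fold_change <- function(fit_a, fit_b) {
  kd <- function(f) {
    if (inherits(f, "hill_fit")) f$K_D
    else if (inherits(f, "two_site_fit")) f$K_D_macro
    else if (is.numeric(f) && length(f) == 1) f
    else stop("expected a binding fit or a single K_D value")
  }
  a <- kd(fit_a); b <- kd(fit_b)
  if (a <= 0 || b <= 0) stop("K_D values must be positive")
  a / b
}
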