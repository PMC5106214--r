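#' Define a nucleosome binding state
#'
#' One state of the multi-state Sir3-chromatin system, parameterized by the
#' apparent dissociation constant and Hill coefficient measured for that
#' template (e.g. unmodified di-nucleosome unit, isolated unmodified
#' mono-nucleosome, acetylated nucleosome).
#'
#' @param label state name.
#' @param K_D apparent dissociation constant, micromolar (`> 0`).
#' @param n Hill coefficient (`> 0`); use `n = 1` for a non-cooperative
#'   counterfactual.
#' @return An object of class `binding_state`.
#' @export
binding_state <- function(label, K_D, n = 1) {
  if (!is.finite(K_D) || K_D <= 0) stop("K_D must be positive")
  if (!is.finite(n) || n <= 0) stop("n must be positive")
  structure(list(label = label, K_D = K_D, n = n), class = "binding_state")
}

#' @export
print.binding_state <- function(x, ...) {
  cat(sprintf("State %s: K_D = %.3g uM, n = %.3g\n", x$label, x$K_D, x$n))
  invisible(x)
}

#' Free energy of a bound state in RT units
#'
#' Gibbs free energy of the Sir3-bound state relative to the unbound
#' reference, `dG/RT = -n * log(S / K_D)`: negative (favourable) when the
#' protein concentration exceeds the apparent `K_D`, scaled by the Hill
#' coefficient. Carrying energies in RT units makes temperature and the
#' gas/Boltzmann-constant distinction drop out of all occupancy ratios.
#'
#' @param S protein concentration, micromolar (`> 0`).
#' @param state a [binding_state()].
#' @return Dimensionless `dG/RT`.
#' @export
state_free_energy <- function(S, state) {
  stopifnot(inherits(state, "binding_state"))
  if (any(!is.finite(S) | S <= 0)) stop("S must be positive")
  -state$n * log(S / state$K_D)
}

#' Boltzmann occupancy probabilities across binding states
#'
#' Probability of finding the bound protein in each state at protein
#' concentration `S`: `p_i = exp(-dG_i/RT) / sum_j exp(-dG_j/RT)`, with the
#' free energies from [state_free_energy()] and log-sum-exp stabilization.
#' The unbound reference state cancels from every ratio and is not included
#' in the partition sum.
#'
#' @param states list of [binding_state()] objects (at least one).
#' @param S protein concentration, micromolar (`> 0`).
#' @return An object of class `occupancy_result`: `S`, named
#'   `probabilities` (summing to 1), and named `dG_over_RT`.
#' @export
occupancy_probabilities <- function(states, S) {
  if (inherits(states, "binding_state")) states <- list(states)
  if (length(states) == 0) stop("need at least one binding state")
  stopifnot(all(vapply(states, inherits, logical(1), "binding_state")))
  labels <- vapply(states, `[[`, character(1), "label")
  dG <- vapply(states, function(st) state_free_energy(S, st), numeric(1))
  logw <- -dG
  m <- max(logw)
  w <- exp(logw - m)
  p <- w / sum(w)
  structure(
    list(S = S, probabilities = setNames(p, labels),
         dG_over_RT = setNames(dG, labels)),
    class = "occupancy_result"
  )
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("Boltzmann occupancy at [S] = %.3g uM:\n", x$S))
  for (l in names(x$probabilities))
    cat(sprintf("  %-12s p = %.4g   dG/RT = %+.3f\n", l,
                x$probabilities[l], x$dG_over_RT[l]))
  invisible(x)
}

#' Selectivity ratio between two binding states
#'
#' Boltzmann-factor ratio `p_a / p_b = exp(-(dG_a - dG_b)/RT) =
#' (S/K_D,a)^n_a / (S/K_D,b)^n_b`. Independent of any other states in the
#' system. When `n_a > n_b` the ratio grows with concentration -- the
#' signature of cooperativity-driven selectivity; with `n_a = n_b` it is
#' concentration-independent.
#'
#' @param a,b [binding_state()] objects.
#' @param S protein concentration, micromolar (`> 0`).
#' @return Dimensionless fold preference for `a` over `b`.
#' @export
selectivity_ratio <- function(a, b, S) {
  exp(-(state_free_energy(S, a) - state_free_energy(S, b)))
}

#' Selectivity over a concentration range
#'
#' [selectivity_ratio()] evaluated at both endpoints of a concentration
#' interval (e.g. the estimated 0.4-0.8 uM intranuclear Sir3 range).
#'
#' @param a,b [binding_state()] objects.
#' @param S_low,S_high interval endpoints, micromolar, `0 < S_low < S_high`.
#' @return Named numeric vector `c(low, high)`.
#' @export
selectivity_range <- function(a, b, S_low, S_high) {
  if (!(S_low > 0 && S_high > S_low))
    stop("need 0 < S_low < S_high")
  c(low = selectivity_ratio(a, b, S_low),
    high = selectivity_ratio(a, b, S_high))
}

#' Default binding-state set for the occupancy report
#'
#' The three-state system used for the packaged selectivity calculation:
#' unmodified di-nucleosome and isolated mono-nucleosome states carry the
#' BLI-derived Hill parameters (K_D 0.12 uM / n 1.9 and 1.4 uM / 1.3), and
#' the H4K16-acetylated mono-nucleosome state the EMSA K_D of 4.0 uM with
#' n = 1 assumed (EMSA Hill coefficients are not considered reliable).
#' See [sir3_equilibrium_params()] for the full published parameter table.
#'
#' @return Named list of [binding_state()] objects.
#' @export
default_binding_states <- function() {
  list(
    DiN = binding_state("DiN", K_D = 0.12, n = 1.9),
    MonoN = binding_state("MonoN", K_D = 1.4, n = 1.3),
    acMonoN = binding_state("acMonoN", K_D = 4.0, n = 1)
  )
}
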