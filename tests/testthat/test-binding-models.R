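test_that("Hill isotherm forms are complementary and hit the midpoint", {
  # midpoint and limits, for a grid of parameter sets
  for (K_D in c(0.05, 0.12, 1.4, 10)) {
    for (n in c(0.5, 1, 1.9, 3)) {
      expect_equal(hill_response(K_D, K_D, n, "fraction_unbound"), 0.5)
      expect_equal(hill_response(K_D, K_D, n, "normalized_signal"), 0.5)
      expect_equal(hill_response(0, K_D, n, "fraction_unbound"), 1)
      expect_equal(hill_response(0, K_D, n, "normalized_signal"), 0)
      S <- 10^seq(-3, 2, length.out = 41)
      fu <- hill_response(S, K_D, n, "fraction_unbound")
      ns <- hill_response(S, K_D, n, "normalized_signal")
      expect_equal(fu + ns, rep(1, length(S)))
      expect_true(all(diff(ns) > 0))  # strictly monotone
    }
  }
  # frozen high-precision evaluation at the DiN BLI parameters
  expect_equal(hill_response(0.4, 0.12, 1.9, "normalized_signal"),
               0.907840533251, tolerance = 1e-10)
  expect_error(hill_response(1, K_D = 0, n = 1), "K_D")
  expect_error(hill_response(1, K_D = 1, n = -1), "n must be")
  expect_error(hill_response(-1, K_D = 1, n = 1), "non-negative")
})

test_that("two-site saturation is a non-cooperative isotherm", {
  expect_equal(two_site_saturation(1.3, 1.3), 0.5)
  expect_equal(two_site_saturation(0, 1.3), 0)
  expect_equal(two_site_saturation(1.3e6, 1.3), 1, tolerance = 1e-5)
  # half the macroscopic constant
  expect_equal(two_site_saturation(0.5, 1), 1 / 3)
  S <- 10^seq(-3, 2, length.out = 41)
  expect_true(all(diff(two_site_saturation(S, 1.3)) > 0))
  expect_error(two_site_saturation(1, -2), "positive")
})

test_that("noiseless Hill data is recovered to machine-level accuracy", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  for (p in list(c(0.05, 0.5), c(0.12, 1.9), c(1.4, 1.3), c(10, 3))) {
    cv <- simulate_titration(cfg, K_D = p[1], n = p[2])
    f <- fit_hill(cv)
    expect_lt(abs(f$K_D - p[1]) / p[1], 1e-6)
    expect_lt(abs(f$n - p[2]) / p[2], 1e-6)
    expect_lt(f$rss, 1e-12)
  }
  # EMSA readout: same recovery through the fraction-unbound form,
  # but the Hill coefficient is tagged low-confidence
  cv <- simulate_titration(cfg, K_D = 1.7, n = 1.2,
                           assay = "EMSA_fraction_unbound")
  f <- fit_hill(cv)
  expect_lt(abs(f$K_D - 1.7) / 1.7, 1e-6)
  expect_identical(f$n_confidence, "low")
})

test_that("noisy Hill data is recovered without bias (MonoN BLI scenario)", {
  kd <- n <- numeric(30)
  for (s in seq_len(30)) {
    f <- fit_hill(simulate_titration(sim_config(seed = s), K_D = 1.4, n = 1.3))
    kd[s] <- f$K_D; n[s] <- f$n
  }
  # medians within 3 reported SD of the generating values
  expect_lt(abs(median(kd) - 1.4), 3 * 0.06)
  expect_lt(abs(median(n) - 1.3), 3 * 0.1)
  # fitted uncertainties are positive for noisy fits
  expect_true(all(vapply(1:3, function(s)
    fit_hill(simulate_titration(sim_config(seed = s),
                                K_D = 1.4, n = 1.3))$sd_K_D > 0,
    logical(1))))
})

test_that("Hill fit to two-site data reports no cooperativity", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  f <- fit_hill(simulate_titration(cfg, K_D = 1.3, model = "two_site"))
  expect_gt(f$n, 0.9)
  expect_lt(f$n, 1.1)
  expect_lt(abs(f$K_D - 1.3) / 1.3, 0.1)
})

test_that("two-site fit recovers its own model and loses to Hill on cooperative data", {
  cfg <- sim_config(seed = 1, noise_sd = 0)
  ft <- fit_two_site(simulate_titration(cfg, K_D = 1.3, model = "two_site"))
  expect_lt(abs(ft$K_D_macro - 1.3) / 1.3, 1e-6)
  # non-cooperative Hill data is one-site-equivalent: recovered within 10%
  ft2 <- fit_two_site(simulate_titration(cfg, K_D = 1.3, n = 1))
  expect_lt(abs(ft2$K_D_macro - 1.3) / 1.3, 0.1)
  # cooperative (n = 1.9) data: the Hill model must fit strictly better
  cv <- simulate_titration(cfg, K_D = 0.12, n = 1.9)
  expect_gt(fit_two_site(cv)$rss, fit_hill(cv)$rss)
})

test_that("degenerate titrations are rejected with diagnostics", {
  flat <- titration_curve(c(0.01, 0.1, 0.5, 1, 5), rep(0.5, 5))
  expect_error(fit_hill(flat), "flat")
  expect_error(fit_two_site(flat), "flat")
  short <- titration_curve(c(0.1, 1, 10), c(0.1, 0.5, 0.9))
  expect_error(fit_hill(short), "at least 5")
  expect_error(titration_curve(c(-1, 1), c(0, 1)), "negative")
  expect_error(titration_curve(c(1, 2), c(0.2, 3)), "0, 1")
})

test_that("min-max normalization maps the signal range onto [0, 1]", {
  cv <- normalize_minmax(c(0.1, 1, 10), c(2, 6, 10))
  expect_equal(cv$points$response, c(0, 0.5, 1))
  # idempotence
  cv2 <- normalize_minmax(cv$points$concentration_uM, cv$points$response)
  expect_equal(cv2$points$response, cv$points$response)
  # arbitrary input: endpoints exact, order preserved
  set.seed(42)
  sig <- cumsum(runif(8))
  cv3 <- normalize_minmax(seq_len(8), sig)
  expect_equal(min(cv3$points$response), 0)
  expect_equal(max(cv3$points$response), 1)
  expect_true(all(diff(cv3$points$response) > 0))
  expect_error(normalize_minmax(1:3, rep(2, 3)), "constant")
})

test_that("fold changes reproduce the printed affinity ratios", {
  expect_equal(fold_change(1.7, 0.17), 10)
  expect_equal(fold_change(0.17, 0.08), 2.125)
  expect_equal(fold_change(1.4, 1.4), 1)
  # works on fit objects too
  cfg <- sim_config(seed = 3, noise_sd = 0)
  fa <- fit_hill(simulate_titration(cfg, K_D = 1.4, n = 1.3))
  fb <- fit_hill(simulate_titration(cfg, K_D = 0.12, n = 1.9))
  expect_equal(fold_change(fa, fb), 1.4 / 0.12, tolerance = 1e-6)
  expect_error(fold_change(-1, 2), "positive")
})
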