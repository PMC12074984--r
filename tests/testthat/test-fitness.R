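test_that("log-VAF density matches its closed form and limits", {
  # low-VAF plateau: rho -> theta
  expect_equal(log_vaf_density(-25, theta = 3.2, phi = 1e-4), 3.2,
               tolerance = 1e-6)
  # essential singularity at VAF 0.5: rho -> 0
  expect_lt(log_vaf_density(log(0.5) - 1e-6, 1, 1e-4), 1e-300)
  expect_error(log_vaf_density(log(0.5), 1, 1e-4), "domain|below")
  # frozen values from an independent high-precision evaluation
  # (mpmath, 30 significant digits) at theta = 1, phi = 1e-4
  oracle <- c(`-9` = 0.291080369647, `-8` = 0.0348672479985,
              `-7` = 0.00010797021169, `-6` = 1.52559974538e-11,
              `-5` = 2.20614904964e-30)
  got <- log_vaf_density(-9:-5, 1, 1e-4)
  expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
})

test_that("phi follows the fitness/age arithmetic", {
  expect_equal(phi_from_params(0, 2, 16500), 2 / 33000, tolerance = 1e-12)
  # continuity at s -> 0
  expect_lt(abs(phi_from_params(1e-8, 2, 16500) / (2 / 33000) - 1), 1e-7)
  # linear in t at s = 0; increasing in s and t
  expect_equal(phi_from_params(0, 4, 16500),
               2 * phi_from_params(0, 2, 16500), tolerance = 1e-9)
  expect_gt(phi_from_params(1, 2, 16500), phi_from_params(0.5, 2, 16500))
  expect_gt(phi_from_params(1, 3, 16500), phi_from_params(1, 2, 16500))
})

test_that("neutral fit recovers N*tau and mu at realistic scale", {
  # truths at the scale of the murine stem cell pool
  N_tau <- 16500; t_age <- 2
  mu <- 300 / N_tau  # aggregate panel rate scaled for ~1e3 variants
  errs_nt <- errs_mu <- numeric(0)
  for (seed in 1:8) {
    sp <- simulate_duplex_vafs(N_tau, mu, 0, age_t = t_age, seed = seed)
    fit <- fit_neutral(sp)
    errs_nt <- c(errs_nt, fit$N_tau / N_tau)
    errs_mu <- c(errs_mu, fit$mu / mu)
  }
  expect_lt(abs(stats::median(errs_nt) - 1), 0.25)
  expect_lt(abs(stats::median(errs_mu) - 1), 0.25)
})

test_that("doubling the cohort age doubles the fitted phi", {
  ratios <- vapply(21:24, function(seed) {
    sp2 <- simulate_duplex_vafs(16500, 500 / 16500, 0, age_t = 2,
                                seed = seed)
    sp4 <- simulate_duplex_vafs(16500, 500 / 16500, 0, age_t = 4,
                                seed = seed + 50)
    fit_neutral(sp4)$phi / fit_neutral(sp2)$phi
  }, numeric(1))
  expect_lt(abs(stats::median(ratios) - 2) / 2, 0.25)
})

test_that("duplicating every variant doubles theta and keeps phi", {
  sp <- simulate_duplex_vafs(16500, 300 / 16500, 0, age_t = 2, seed = 3)
  fit1 <- fit_neutral(sp)
  sp2 <- rbind(sp, sp)
  attr(sp2, "age_t") <- 2; attr(sp2, "vaf_floor") <- 5e-5
  class(sp2) <- class(sp)
  fit2 <- fit_neutral(sp2)
  expect_equal(fit2$phi, fit1$phi, tolerance = 0.15)
  expect_equal(fit2$theta / fit1$theta, 2, tolerance = 0.15)
})

test_that("neutral fit is self-consistent on its own predictions", {
  sp <- simulate_duplex_vafs(16500, 300 / 16500, 0, age_t = 2, seed = 5)
  fit <- fit_neutral(sp)
  # regenerate a spectrum by inverse-CDF sampling from the fitted density
  # (large n), refit: parameters must come back
  set.seed(6)
  l_grid <- seq(log(5e-5), log(0.5) - 1e-9, length.out = 4000)
  dens <- log_vaf_density(l_grid, fit$theta, fit$phi)
  cdf <- cumsum(dens); n_exp <- 5000
  l_new <- suppressWarnings(stats::approx(cdf / max(cdf), l_grid,
                                          xout = stats::runif(n_exp)))$y
  sp2 <- vaf_spectrum(exp(l_new), rep("synonymous", n_exp), age_t = 2)
  fit2 <- fit_neutral(sp2)
  expect_equal(fit2$phi, fit$phi, tolerance = 0.2)
  expect_error(fit_neutral(vaf_spectrum(c(1e-4, 2e-4),
                                        c("synonymous", "synonymous"),
                                        age_t = 2)), "neutral variants")
})

test_that("non-synonymous rate scales with neutral-range counts", {
  N_tau <- 16500; t_age <- 2
  mu_s <- 1500 / N_tau
  # construct non-synonymous sets with exactly twice the neutral-range
  # density by doubling the synonymous variants; the rate ratio estimate
  # carries the (theta, phi) fit noise, so check the median across seeds
  ratios <- vapply(7:11, function(seed) {
    sp_s <- simulate_duplex_vafs(N_tau, mu_s, 0, age_t = t_age, seed = seed)
    ns <- rbind(sp_s, sp_s)
    ns$class <- "non-synonymous"
    sp <- rbind(sp_s, ns)
    attr(sp, "age_t") <- t_age; attr(sp, "vaf_floor") <- 5e-5
    class(sp) <- class(sp_s)
    fit <- fit_neutral(sp)
    fit_nonsynonymous(sp, fit)$mu_ns / fit$mu
  }, numeric(1))
  expect_equal(stats::median(ratios), 2, tolerance = 0.15)
  sp_s <- simulate_duplex_vafs(N_tau, mu_s, 0, age_t = t_age, seed = 7)
  fit <- fit_neutral(sp_s)
  expect_error(fit_nonsynonymous(sp_s, fit), "non-synonymous")
})

test_that("DFE quadrature matches a Monte-Carlo mixture", {
  set.seed(8)
  d <- 2; beta <- 3; s_max <- 4
  t_age <- 2; N_tau <- 16500
  gq <- clonaldyn:::.gauss_legendre(64, 0, s_max)
  w <- exp(-(gq$nodes / d)^beta) * gq$weights
  w <- w / sum(w)
  l <- c(-9, -8, -7, -6.5)
  quad <- vapply(l, function(li)
    sum(w * vapply(gq$nodes, function(s)
      log_vaf_density(li, 1, phi_from_params(s, t_age, N_tau)),
      numeric(1))), numeric(1))
  s_mc <- clonaldyn:::.rdfe(2e5, d, beta, s_max)
  mc <- vapply(l, function(li)
    mean(log_vaf_density(li, 1, phi_from_params(s_mc, t_age, N_tau))),
    numeric(1))
  expect_equal(quad, mc, tolerance = 0.01)
})

test_that("DFE fit recovers scale and non-neutral fraction", {
  N_tau <- 16500; t_age <- 2
  mu_s <- 500 / N_tau
  d_hat <- f_hat <- numeric(0)
  for (seed in 1:6) {
    sp <- simulate_duplex_vafs(N_tau, mu_neutral = 0.88 * 2 * mu_s,
                               mu_selected = 0.12 * 2 * mu_s,
                               dfe_scale = 2, age_t = t_age, seed = seed)
    sp$class <- "non-synonymous"
    syn <- simulate_duplex_vafs(N_tau, mu_s, 0, age_t = t_age,
                                seed = seed + 100)
    sp2 <- rbind(syn, sp)
    attr(sp2, "age_t") <- t_age; attr(sp2, "vaf_floor") <- 5e-5
    class(sp2) <- class(syn)
    nf <- fit_neutral(sp2)
    dfe <- fit_dfe(sp2, nf)
    d_hat <- c(d_hat, dfe$d); f_hat <- c(f_hat, dfe$f)
  }
  expect_gte(stats::median(d_hat), 1.5)
  expect_lte(stats::median(d_hat), 2.7)
  # order of magnitude on the non-neutral fraction (truth 0.12)
  expect_gte(stats::median(f_hat), 0.04)
  expect_lte(stats::median(f_hat), 0.36)
})

test_that("a neutral-looking spectrum drives the fraction to zero", {
  sp <- simulate_duplex_vafs(16500, 400 / 16500, 0, age_t = 2, seed = 11)
  ns <- sp; ns$class <- "non-synonymous"
  sp2 <- rbind(sp, ns)
  attr(sp2, "age_t") <- 2; attr(sp2, "vaf_floor") <- 5e-5
  class(sp2) <- class(sp)
  nf <- fit_neutral(sp2)
  dfe <- fit_dfe(sp2, nf)
  expect_lt(dfe$f * dfe$strong_fraction, 0.05)
  expect_lte(dfe$f_ci[1], 0.05)
})

test_that("fitness conversions follow the compounding arithmetic", {
  # 200%/yr at a 6.4-week division interval: about 15% per division
  s_div <- annual_to_per_division(2, 6.4)
  expect_equal(s_div, 3^(6.4 / 52.18) - 1, tolerance = 1e-12)
  expect_equal(round(s_div, 2), 0.14)
  expect_equal(annual_to_per_division(0, 6.4), 0)
  # round trip
  expect_equal(per_division_to_annual(s_div, 6.4), 2, tolerance = 1e-12)
  # drift threshold at the posterior medians
  s_star <- drift_threshold(72414, 52.18 / 6.4)
  expect_equal(s_star, (52.18 / 6.4) / 72414, tolerance = 1e-12)
  expect_lt(abs(s_star - 1.1e-4) / 1.1e-4, 0.05)
  expect_equal(establishment_time(0.5), 2)
  expect_gt(drift_threshold(1e4, 8), drift_threshold(1e5, 8))
  # per-bp rates
  expect_equal(per_bp_rate(45.3), 45.3 / 5.46e9)
  expect_equal(round(per_bp_rate(45.3) * 1e9, 1), 8.3)
  expect_equal(per_bp_rate(0), 0)
  expect_equal(per_bp_rate(45.3) * 5.46e9, 45.3)
  r <- scale_panel_rate(5.2e-4 / 52.18)
  expect_equal(attr(r, "annual_genome_burden"),
               as.numeric(r) * 5.46e9)
})

test_that("Doane's rule tracks sample size and skewness", {
  set.seed(13)
  x <- stats::rnorm(200)
  k <- doane_bins(x)
  expect_gte(k, 8); expect_lte(k, 12)
  expect_gt(doane_bins(stats::rexp(200)^2), k - 2)
  expect_equal(doane_bins(c(1, 2)), 2)
})
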