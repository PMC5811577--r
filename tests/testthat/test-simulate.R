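small_cfg <- function(...) {
  sim_config(n_sites = 60,
             cohorts = data.frame(age_months = 9, n_biological = 8), ...)
}

test_that("simulation is byte-identical under the same seed", {
  s1 <- simulate_experiment(small_cfg(seed = 81))
  s2 <- simulate_experiment(small_cfg(seed = 81))
  expect_identical(s1$bs$M, s2$bs$M)
  expect_identical(s1$oxbs$U, s2$oxbs$U)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_experiment(small_cfg(seed = 82))
  expect_false(identical(s1$bs$M, s3$bs$M))
})

test_that("realized amplitudes match the configured distribution", {
  cfg <- sim_config(n_sites = 8000, frac_oscillating = 1, hmc_fraction = 0,
                    cohorts = data.frame(age_months = 9, n_biological = 4),
                    frac_aging = 0, seed = 83)
  sim <- simulate_experiment(cfg)
  amps <- sim$truth$amplitude[sim$truth$is_oscillating]
  # oracle: closed-form moments of the truncated normal the generator draws
  mu <- 0.045; s <- 0.022
  al <- (0.005 - mu) / s; be <- (0.17 - mu) / s
  z <- pnorm(be) - pnorm(al)
  m_trunc <- mu + s * (dnorm(al) - dnorm(be)) / z
  v_trunc <- s^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / z -
                      ((dnorm(al) - dnorm(be)) / z)^2)
  expect_equal(mean(amps), m_trunc, tolerance = 0.01)
  expect_equal(sd(amps), sqrt(v_trunc), tolerance = 0.03)
  expect_true(all(amps <= 2 * pmin(sim$truth$baseline,
                                   1 - sim$truth$baseline)))
})

test_that("technical-replicate variance follows binomial sampling", {
  for (depth in c(200, 1800, 20000)) {
    cfg <- sim_config(n_sites = 600, mean_depth = depth,
                      cohorts = data.frame(age_months = 9, n_biological = 2),
                      n_replicates = 30, frac_oscillating = 0,
                      sigma_biological = 0, frac_aging = 0,
                      baseline_shape1 = 30, baseline_shape2 = 30,
                      seed = 84 + depth)
    sim <- simulate_experiment(cfg)
    b <- compute_beta(sim$bs)
    one_bio <- b$samples$biological_id == b$samples$biological_id[1]
    v_obs <- apply(b$beta[, one_bio], 1, var)
    mu <- rowMeans(b$beta[, one_bio])
    expect_equal(mean(v_obs), mean(mu * (1 - mu) / depth), tolerance = 0.15)
  }
})

test_that("near-infinite depth recovers planted oscillations precisely", {
  cfg <- sim_config(n_sites = 40, mean_depth = 1e6, frac_oscillating = 1,
                    amplitude_mean = 0.2, amplitude_sd = 1e-9,
                    amplitude_min = 0.19, amplitude_max = 0.21,
                    sigma_biological = 0, frac_aging = 0, hmc_fraction = 0,
                    cohorts = data.frame(age_months = 9, n_biological = 30),
                    seed = 85)
  sim <- simulate_experiment(cfg)
  cl <- collapse_replicates(compute_beta(sim$bs))
  fits <- harmonic_fit_matrix(cl$beta, cl$samples$zt)
  tr <- sim$truth
  expect_lt(median(abs(fits$amplitude - tr$amplitude)), 0.005)
  expect_lt(median(circ_err(fits$acrophase, tr$acrophase)), 0.2)
})

test_that("a null simulation calibrates EVC and oscillation rates to alpha", {
  cfg <- sim_config(n_sites = 2500, frac_oscillating = 0,
                    sigma_biological = 0, frac_aging = 0, hmc_fraction = 0,
                    cohorts = data.frame(age_months = 9, n_biological = 10),
                    seed = 86)
  sim <- simulate_experiment(cfg)
  beta <- compute_beta(sim$bs)
  evc_rate <- mean(detect_evc(beta)$is_evc)
  ci <- qbinom(c(0.005, 0.995), 2500, 0.05) / 2500
  expect_gte(evc_rate, ci[1] - 0.005); expect_lte(evc_rate, ci[2] + 0.005)
  cl <- collapse_replicates(beta)
  osc_rate <- mean(harmonic_fit_matrix(cl$beta, cl$samples$zt)$p < 0.05)
  expect_gte(osc_rate, ci[1] - 0.005); expect_lte(osc_rate, ci[2] + 0.005)
})

test_that("antiphase partners are exactly 12 h apart in truth", {
  cfg <- small_cfg(frac_oscillating = 1, hmc_fraction = 1, seed = 87)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth[sim$truth$is_hmc_partner, ]
  expect_gt(nrow(tr), 0)
  expect_true(all(abs(minor_arc(tr$mc_acrophase, tr$hmc_acrophase) - 12)
                  < 1e-9))
})

test_that("acrophase-aging coupling drives slope signs as configured", {
  cfg <- sim_config(n_sites = 4000, frac_oscillating = 1, frac_aging = 1,
                    acrophase_aging_coupling = 1, hmc_fraction = 0,
                    cohorts = data.frame(age_months = c(9, 15, 25),
                                         n_biological = c(2, 2, 2)),
                    seed = 88)
  tr <- simulate_experiment(cfg)$truth
  sleep <- tr$acrophase_class == "sleep"
  expect_true(all(tr$slope[sleep] > 0))
  expect_true(all(tr$slope[!sleep] < 0))
})

test_that("expression truth wires the mRNA acrophase to nadir minus lag", {
  cfg <- small_cfg(frac_oscillating = 1, acrophase_site_jitter = 0,
                   mrna_lag_hours = 4, seed = 89)
  sim <- simulate_experiment(cfg)
  ex <- simulate_expression(sim)
  tg <- ex$truth_genes[ex$truth_genes$is_circadian, ]
  nadir <- (tg$mod_acrophase + 12) %% 24
  expect_true(all(circ_err(tg$mrna_acrophase, (nadir - 4) %% 24) < 1e-9))
  # circadian genes carry a detectable rhythm; flat genes do not
  fits <- harmonic_fit_matrix(ex$expr, ex$zt)
  circ <- ex$truth_genes$is_circadian
  if (any(circ)) expect_true(all(fits$p[circ] < 0.01))
})

test_that("metadata stores collection hour and wrapped ZT separately", {
  sim <- simulate_experiment(small_cfg(seed = 90))
  s <- sim$bs$samples
  expect_true(all(s$zt == s$collection_hour %% 24))
  expect_true(any(s$collection_hour >= 24))
  expect_true(all(s$zt >= 0 & s$zt < 24))
  # both assays share biological samples and metadata
  expect_identical(sim$bs$samples$biological_id, sim$oxbs$samples$biological_id)
})
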