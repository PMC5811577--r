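fisher_enum_p <- function(a, b, c, d) {
  # independent oracle: enumerate the hypergeometric distribution of the
  # top-left cell given fixed margins, two-sided by summing tables no more
  # probable than the observed
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("balanced tables give OR 1 and p 1; known table gives OR 16", {
  u <- paste0("x", 1:40)
  r <- fisher_association(u[1:20], u[c(1:10, 21:30)], u)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  r2 <- association_from_counts(20, 5, 5, 20)
  expect_equal(r2$odds_ratio, 16)
  expect_equal(r2$p, fisher_enum_p(20, 5, 5, 20), tolerance = 1e-10)
  expect_false(r2$corrected)
})

test_that("Fisher p matches hypergeometric enumeration across random tables", {
  set.seed(71)
  for (i in 1:50) {
    cells <- as.vector(rmultinom(1, sample(8:40, 1), runif(4, 0.05, 1)))
    r <- association_from_counts(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$p, fisher_enum_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("degenerate margins are flagged and zero cells corrected", {
  u <- paste0("x", 1:30)
  r <- fisher_association(u, u[1:10], u)  # set_a is the whole universe
  expect_true(r$degenerate)
  expect_true(is.na(r$odds_ratio))
  r2 <- association_from_counts(10, 0, 3, 9)
  expect_true(r2$corrected)
  expect_equal(r2$odds_ratio, Inf)
  expect_true(is.finite(r2$ci_low) && is.finite(r2$ci_high))
  expect_error(fisher_association("a", "a", character(0)), "empty universe")
  expect_error(fisher_association("zz", "a", letters), "subsets")
})

test_that("amplitude correlates perfectly with a proportional aging effect", {
  osc <- data.frame(series_id = paste0("s", 1:10),
                    amplitude = seq(0.01, 0.1, by = 0.01))
  aging <- data.frame(site_id = paste0("s", 1:10),
                      b1 = seq(0.001, 0.01, by = 0.001))
  res <- amplitude_magnitude_correlation(osc, aging)
  expect_equal(res$r, 1, tolerance = 1e-10)
  expect_equal(res$r2, 1, tolerance = 1e-10)
  expect_error(amplitude_magnitude_correlation(osc[1:2, ], aging), "fewer")
})

test_that("generator amplitude-aging coupling is recovered from truth", {
  cfg <- sim_config(n_sites = 2000, frac_oscillating = 0.5, frac_aging = 1,
                    amplitude_aging_corr = 0.6, seed = 72)
  sim <- simulate_experiment(cfg)
  tr <- sim$truth[sim$truth$is_oscillating & sim$truth$is_aging, ]
  res <- amplitude_magnitude_correlation(
    data.frame(series_id = tr$site_id, amplitude = tr$amplitude),
    data.frame(site_id = tr$site_id, b1 = tr$slope))
  expect_gt(res$n, 500)
  expect_equal(res$r, 0.6, tolerance = 0.1)
})

test_that("acrophase-direction asymmetry reflects planted coupling", {
  # perfect coupling: all sleep sites gain, all wake sites lose
  osc <- data.frame(series_id = paste0("s", 1:40), p = 0.01,
                    acrophase = rep(c(6, 18), 20))
  aging <- data.frame(site_id = paste0("s", 1:40), is_age_modc = TRUE,
                      direction = factor(rep(c("gain", "loss"), 20),
                                         levels = c("gain", "loss")))
  r <- acrophase_direction_asymmetry(osc, aging)
  expect_equal(unname(r$counts), c(20, 0, 0, 20))
  expect_equal(r$odds_ratio, Inf)
  expect_true(r$corrected)
  expect_lt(r$p, 1e-8)
  # no coupling: OR near 1 on average
  set.seed(73)
  ors <- replicate(20, {
    osc2 <- data.frame(series_id = paste0("s", 1:200), p = 0.01,
                       acrophase = runif(200, 0, 24))
    aging2 <- data.frame(site_id = paste0("s", 1:200), is_age_modc = TRUE,
                         direction = factor(sample(c("gain", "loss"), 200,
                                                   TRUE),
                                            levels = c("gain", "loss")))
    log(acrophase_direction_asymmetry(osc2, aging2)$odds_ratio)
  })
  expect_lt(abs(mean(ors)), 0.25)
})

test_that("Venn-region binomial enrichment flags only the planted region", {
  set.seed(74)
  u <- paste0("s", 1:3000)
  aging <- data.frame(site_id = u,
                      is_age_modc = runif(3000) < 0.08)
  # 9mo-only region heavily enriched for age-modCs
  age_ids <- aging$site_id[aging$is_age_modc]
  only9 <- c(sample(age_ids, 60), sample(setdiff(u, age_ids), 140))
  shared <- sample(setdiff(u, only9), 400)
  sets <- list(mo9 = c(only9, shared), mo15 = shared, mo25 = shared)
  res <- venn_binomial_enrichment(sets, aging)
  row9 <- res[res$region == "mo9", ]
  expect_lt(row9$p, 0.05)
  expect_gt(row9$proportion, row9$expected_prop)
  expect_equal(res$expected_prop[1], mean(aging$is_age_modc))
  # a region matching the expected proportion is not significant
  row_shared <- res[res$region == "mo9&mo15&mo25", ]
  expect_gt(row_shared$p, 0.05)
})

test_that("binomial region p equals the exact two-sided tail for zero hits", {
  aging <- data.frame(site_id = paste0("s", 1:1000),
                      is_age_modc = rep(c(TRUE, FALSE), c(80, 920)))
  sets <- list(a = paste0("s", 101:200),  # 100 sites, none age-modC
               b = paste0("s", 300:310), c = paste0("s", 400:410))
  res <- venn_binomial_enrichment(sets, aging)
  row_a <- res[res$region == "a", ]
  expect_equal(row_a$k, 0)
  # oracle: exact binomial two-sided p via minimum-likelihood enumeration
  probs <- dbinom(0:100, 100, 0.08)
  p_exact <- sum(probs[probs <= probs[1] * (1 + 1e-7)])
  expect_equal(row_a$p, p_exact, tolerance = 1e-10)
})

test_that("weighted Pearson reduces to plain Pearson with equal weights", {
  set.seed(75)
  x <- rnorm(20); y <- x + rnorm(20)
  r_eq <- weighted_pearson(x, y, rep(2, 20))
  ct <- cor.test(x, y)
  expect_equal(r_eq$r, unname(ct$estimate), tolerance = 1e-12)
  # hand-computed 3-point case with weights 1,2,3
  x3 <- c(1, 2, 4); y3 <- c(2, 1, 5); w3 <- c(1, 2, 3)
  xm <- sum(w3 * x3) / 6; ym <- sum(w3 * y3) / 6
  r_manual <- sum(w3 * (x3 - xm) * (y3 - ym)) /
    sqrt(sum(w3 * (x3 - xm)^2) * sum(w3 * (y3 - ym)^2))
  expect_equal(weighted_pearson(x3, y3, w3)$r, r_manual, tolerance = 1e-12)
  expect_error(weighted_pearson(x3, y3, c(0, 0, 0)), "zero total weight")
  expect_error(weighted_pearson(x3, y3, c(1, 0, 0)), "at least 3")
  expect_error(weighted_pearson(c(1, 1, 1), y3, w3), "variance")
})

test_that("subsampling is deterministic, order-preserving, and uniform", {
  samples <- make_samples(n_bio = 8, n_rep = 1)
  b <- make_beta(matrix(runif(5 * 8), 5), samples)
  expect_identical(subsample_match(b, 8)$samples$sample_id,
                   samples$sample_id)
  s1 <- subsample_match(b, 4, seed = 1)
  s2 <- subsample_match(b, 4, seed = 1)
  expect_identical(s1$samples$sample_id, s2$samples$sample_id)
  expect_identical(order(match(s1$samples$sample_id, samples$sample_id)),
                   1:4)
  expect_error(subsample_match(b, 0), "positive")
  expect_error(subsample_match(b, 9), "exceeds")
  # uniform coverage over repeated draws
  set.seed(76)
  counts <- table(unlist(replicate(2000, {
    sub <- subsample_match(b, 3)
    sub$samples$sample_id
  }, simplify = FALSE)))
  gof <- chisq.test(as.vector(counts))
  expect_gt(gof$p.value, 0.001)
})
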