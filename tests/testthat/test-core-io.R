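test_that("count round-trip through TSV preserves every value", {
  samples <- make_samples(n_bio = 2, n_rep = 1)
  sites <- make_sites(3)
  set.seed(1)
  M <- matrix(rpois(6, 100), 3)
  U <- matrix(rpois(6, 100), 3)
  cm <- make_counts(M, U, samples, sites)
  d <- withr::local_tempdir()
  paths <- file.path(d, c("counts.tsv", "meta.tsv", "sites.bed"))
  write_counts(cm, paths[1], paths[2], paths[3])
  back <- read_counts(paths[1], paths[2], paths[3])
  expect_identical(back$M, cm$M)
  expect_identical(back$U, cm$U)
  expect_equal(back$samples$zt, cm$samples$zt)
  expect_equal(back$sites$pos, cm$sites$pos)
})

test_that("malformed counts are rejected, not silently dropped", {
  samples <- make_samples(n_bio = 2, n_rep = 1)
  sites <- make_sites(2)
  d <- withr::local_tempdir()
  meta <- file.path(d, "meta.tsv"); bed <- file.path(d, "sites.bed")
  write.table(samples, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sites_bed(sites, bed)
  writef <- function(lines) {
    f <- file.path(d, "c.tsv"); writeLines(lines, f); f
  }
  hdr <- "site_id\tsample_id\tM\tU"
  expect_error(read_counts(writef(c(hdr, "s0001\tb01_BS_1\t-1\t5")), meta, bed),
               "negative")
  expect_error(read_counts(writef(c(hdr, "s0001\tb01_BS_1\t2\t5",
                                    "s0001\tb01_BS_1\t3\t5")), meta, bed),
               "duplicate")
  expect_error(read_counts(writef(c(hdr, "s0001\tghost\t2\t5")), meta, bed),
               "unknown sample")
  expect_error(read_counts(writef(c(hdr, "nope\tb01_BS_1\t2\t5")), meta, bed),
               "unknown site")
})

test_that("beta values follow M/(M+U) with a division guard", {
  samples <- make_samples(n_bio = 3, n_rep = 1)
  cm <- make_counts(M = matrix(c(30, 0, 0), 1), U = matrix(c(70, 50, 0), 1),
                    samples)
  b <- compute_beta(cm)
  expect_equal(unname(b$beta[1, ]), c(0.3, 0, NA))
  expect_equal(b$modality, "modC")
  ox <- make_counts(matrix(5, 1, 3), matrix(5, 1, 3),
                    make_samples(n_bio = 3, n_rep = 1, assay = "oxBS"))
  expect_equal(compute_beta(ox)$modality, "mC")
})

test_that("coverage filter is boundary-inclusive, exact, and monotone", {
  samples <- make_samples(n_bio = 3, n_rep = 1)
  M <- rbind(c(15, 15, 14), c(15, 15, 15), c(40, 40, 40))
  U <- rbind(c(15, 15, 15), c(15, 15, 15), c(0, 0, 0))
  cm <- make_counts(M, U, samples)
  f30 <- filter_min_coverage(cm, 30)
  expect_identical(rownames(f30$M), c("s0002", "s0003"))
  expect_identical(attr(f30, "drop_log")$site_id, "s0001")
  expect_equal(attr(f30, "drop_log")$min_coverage, 29)
  # idempotent and monotone in min_cov
  expect_identical(rownames(filter_min_coverage(f30, 30)$M), rownames(f30$M))
  for (mc in c(1, 30, 31, 41)) {
    kept <- rownames(filter_min_coverage(cm, mc)$M)
    kept_hi <- rownames(filter_min_coverage(cm, mc + 5)$M)
    expect_true(all(kept_hi %in% kept))
  }
})

test_that("planted low-coverage sites are exactly the ones dropped", {
  cfg <- sim_config(n_sites = 80, cohorts = data.frame(age_months = 9,
                                                       n_biological = 6),
                    frac_low_coverage = 0.25, seed = 3)
  sim <- simulate_experiment(cfg)
  filt <- filter_min_coverage(sim$bs, 30)
  expect_setequal(attr(filt, "drop_log")$site_id,
                  sim$truth$site_id[sim$truth$low_coverage])
})

test_that("outlier samples are flagged by mean inter-sample correlation", {
  set.seed(42)
  n_samp <- 30
  samples <- make_samples(n_bio = n_samp, n_rep = 1)
  base <- runif(200, 0.2, 0.8)
  Y <- sapply(seq_len(n_samp),
              function(i) pmin(pmax(base + rnorm(200, 0, 0.01), 0), 1))
  b <- make_beta(Y, samples)
  expect_length(remove_outlier_samples(b)$removed, 0)
  Y2 <- Y; Y2[, n_samp] <- 1 - Y[, n_samp]   # anti-correlated sample
  out <- remove_outlier_samples(make_beta(Y2, samples))
  expect_identical(out$removed, samples$sample_id[n_samp])
  expect_equal(ncol(out$beta$beta), n_samp - 1)
  # degenerate threshold removes nothing
  expect_length(remove_outlier_samples(make_beta(Y2, samples), Inf)$removed, 0)
  expect_error(remove_outlier_samples(subset_mod(b, samples = 1:2)),
               "at least 3")
})

test_that("replicate collapse takes medians and ignores missing values", {
  samples <- make_samples(n_bio = 1, n_rep = 3)
  b <- make_beta(rbind(c(0.2, 0.3, 0.4), c(0.1, NA, 0.5), c(NA, NA, NA)),
                 samples)
  cl <- collapse_replicates(b)
  expect_equal(unname(cl$beta[, 1]), c(0.3, 0.3, NA))
  expect_equal(cl$samples$n_replicates, 3)
  # even count -> midpoint
  s2 <- make_samples(n_bio = 1, n_rep = 2)
  b2 <- make_beta(matrix(c(0.2, 0.8), 1), s2)
  expect_equal(unname(collapse_replicates(b2)$beta[1, 1]), 0.5)
})

test_that("replicate collapse commutes with row/column permutation", {
  set.seed(7)
  samples <- make_samples(n_bio = 4, n_rep = 3)
  b <- make_beta(matrix(runif(10 * 12), 10), samples)
  cl <- collapse_replicates(b)
  perm_r <- sample(10); perm_c <- sample(12)
  bp <- mod_beta(b$beta[perm_r, perm_c], b$sites[perm_r, ],
                 b$samples[perm_c, ], "modC")
  clp <- collapse_replicates(bp)
  expect_equal(clp$beta[rownames(cl$beta), colnames(cl$beta)], cl$beta)
})

test_that("hmC subtraction preserves sign and demands alignment", {
  s_bs <- make_samples(n_bio = 3, n_rep = 1)
  s_ox <- make_samples(n_bio = 3, n_rep = 1, assay = "oxBS")
  bs <- collapse_replicates(make_beta(matrix(c(0.8, 0.5, 0.2), 1,
                                             dimnames = NULL), s_bs))
  ox <- collapse_replicates(make_beta(matrix(c(0.3, 0.5, 0.3), 1), s_ox))
  h <- estimate_hmc(bs, ox)
  expect_equal(unname(h$beta[1, ]), c(0.5, 0, -0.1))
  expect_equal(h$modality, "hmC")
  expect_equal(h$value_range, c(-1, 1))
  expect_equal(unname(estimate_hmc(bs, ox, clamp = TRUE)$beta[1, ]),
               c(0.5, 0, 0))
  ox_bad <- collapse_replicates(make_beta(matrix(0.3, 1, 3),
                                          s_ox, make_sites(1, prefix = "z")))
  expect_error(estimate_hmc(bs, ox_bad), "misaligned on sites")
})
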