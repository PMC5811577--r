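# Small in-code fixtures shared across test files.

make_samples <- function(n_bio = 4, n_rep = 3, zt = NULL, age = 9,
                         assay = "BS", tissue = "t") {
  if (is.null(zt)) zt <- seq(0, length.out = n_bio, by = 3) %% 24
  bio <- sprintf("b%02d", seq_len(n_bio))
  data.frame(
    sample_id = paste(rep(bio, each = n_rep), assay,
                      rep(seq_len(n_rep), n_bio), sep = "_"),
    biological_id = rep(bio, each = n_rep),
    replicate_index = rep(seq_len(n_rep), n_bio),
    tissue = tissue,
    age_months = age,
    zt = rep(zt, each = n_rep),
    assay = assay)
}

make_sites <- function(n, prefix = "s", chrom = "chr7", spacing = 1000L) {
  data.frame(site_id = sprintf("%s%04d", prefix, seq_len(n)),
             chrom = chrom, pos = seq_len(n) * spacing, strand = "+")
}

make_beta <- function(values, samples, sites = NULL, modality = "modC") {
  values <- as.matrix(values)
  if (is.null(sites)) sites <- make_sites(nrow(values))
  rownames(values) <- sites$site_id
  colnames(values) <- samples$sample_id
  mod_beta(values, sites, samples, modality)
}

make_counts <- function(M, U, samples, sites = NULL) {
  if (is.null(sites)) sites <- make_sites(nrow(as.matrix(M)))
  mod_counts(M, U, sites, samples)
}

# independent brute-force mean harmonic R^2 via lm(), for permutation oracles
lm_mean_r2 <- function(Y, zt) {
  mean(apply(Y, 1, function(y) {
    summary(lm(y ~ sin(2 * pi * zt / 24) + cos(2 * pi * zt / 24)))$r.squared
  }))
}

# recursive permutation enumerator independent of the package's
perm_enum <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perm_enum(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

circ_err <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}
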