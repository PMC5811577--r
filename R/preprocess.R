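#' Compute beta-values (modification densities) from read counts
#'
#' beta = M / (M + U) per cell. Cells with zero coverage are marked missing.
#' The modality tag is `mC` when every sample is an oxBS library (which reads
#' only true 5-methylcytosine) and `modC` otherwise.
#'
#' @param counts a [mod_counts()] object.
#' @return A [mod_beta()] object.
#' @export
compute_beta <- function(counts) {
  cov <- counts$M + counts$U
  beta <- counts$M / cov
  beta[cov == 0] <- NA_real_
  modality <- if (all(counts$samples$assay == "oxBS")) "mC" else "modC"
  mod_beta(beta, counts$sites, counts$samples, modality)
}

#' Filter sites by minimum per-sample coverage
#'
#' Retains exactly the sites whose coverage (M + U) is at least `min_cov` in
#' every sample. The default of 30 reads reflects common practice for
#' targeted bisulfite data, where beta-values below that depth are too noisy
#' for per-site inference.
#'
#' @param counts a [mod_counts()] object.
#' @param min_cov minimum read coverage required in each sample (default 30).
#' @return The filtered [mod_counts()] object, with a `drop_log` attribute: a
#'   data.frame of dropped site_ids and their minimum observed coverage.
#' @export
filter_min_coverage <- function(counts, min_cov = 30) {
  stopifnot(min_cov >= 1)
  cov <- counts$M + counts$U
  min_per_site <- apply(cov, 1, min)
  keep <- min_per_site >= min_cov
  out <- subset_mod(counts, sites = keep)
  attr(out, "drop_log") <- data.frame(
    site_id = rownames(counts$M)[!keep],
    min_coverage = min_per_site[!keep], row.names = NULL)
  out
}

#' Remove outlier samples by average inter-sample correlation
#'
#' Computes all pairwise Pearson correlations between samples (on sites
#' non-missing in both members of a pair), averages them per sample, and
#' excludes in a single pass the samples whose average correlation falls more
#' than `sd_threshold` standard deviations below the mean of the per-sample
#' averages.
#'
#' @param beta a [mod_beta()] object with at least 3 samples.
#' @param sd_threshold number of SDs below the mean that defines an outlier
#'   (default 3).
#' @return A list with elements `beta` (filtered object), `removed`
#'   (character vector of removed sample_ids) and `stats` (per-sample mean
#'   correlation, with zero-variance samples flagged).
#' @export
remove_outlier_samples <- function(beta, sd_threshold = 3) {
  n <- ncol(beta$beta)
  if (n < 3) stop("outlier removal requires at least 3 samples")
  cors <- suppressWarnings(
    stats::cor(beta$beta, use = "pairwise.complete.obs", method = "pearson"))
  diag(cors) <- NA
  mean_cor <- rowMeans(cors, na.rm = TRUE)
  zero_var <- apply(beta$beta, 2, function(x) stats::sd(x, na.rm = TRUE)) == 0
  mean_cor[zero_var | is.nan(mean_cor)] <- NA
  mu <- mean(mean_cor, na.rm = TRUE)
  sdv <- stats::sd(mean_cor, na.rm = TRUE)
  cut <- mu - sd_threshold * sdv
  removed <- colnames(beta$beta)[!is.na(mean_cor) & mean_cor < cut]
  stats_df <- data.frame(sample_id = colnames(beta$beta),
                         mean_correlation = unname(mean_cor),
                         zero_variance = unname(zero_var),
                         removed = colnames(beta$beta) %in% removed,
                         row.names = NULL)
  out <- if (length(removed))
    subset_mod(beta, samples = setdiff(colnames(beta$beta), removed))
  else beta
  list(beta = out, removed = removed, stats = stats_df)
}

#' Collapse technical replicates to one value per biological sample
#'
#' Each biological sample's technical replicates are summarized by their
#' median (even counts use the midpoint; missing values are ignored), giving
#' a single robust data point per biological sample. The collapsed object has
#' one column per `biological_id`; the merged metadata keeps the shared
#' fields and records the replicate count.
#'
#' @param beta a [mod_beta()] object holding a single assay.
#' @return A collapsed [mod_beta()] object.
#' @export
collapse_replicates <- function(beta) {
  samp <- beta$samples
  if (length(unique(samp$assay)) > 1)
    stop("collapse_replicates expects a single assay; split BS and oxBS first")
  bio_ids <- unique(samp$biological_id)
  out <- matrix(NA_real_, nrow(beta$beta), length(bio_ids),
                dimnames = list(rownames(beta$beta), bio_ids))
  n_rep <- integer(length(bio_ids))
  meta_rows <- vector("list", length(bio_ids))
  for (j in seq_along(bio_ids)) {
    cols <- which(samp$biological_id == bio_ids[j])
    block <- beta$beta[, cols, drop = FALSE]
    out[, j] <- apply(block, 1, stats::median, na.rm = TRUE)
    n_rep[j] <- length(cols)
    m <- samp[cols[1], , drop = FALSE]
    m$sample_id <- bio_ids[j]
    m$replicate_index <- 1L
    meta_rows[[j]] <- m
  }
  out[is.nan(out)] <- NA_real_
  meta <- do.call(rbind, meta_rows)
  meta$n_replicates <- n_rep
  rownames(meta) <- NULL
  res <- mod_beta(out, beta$sites, meta, beta$modality)
  res$collapsed <- TRUE
  res
}

#' Estimate 5-hydroxymethylcytosine by oxBS subtraction
#'
#' hmC = beta_BS - beta_oxBS per cell. The bisulfite assay reads total
#' modification (mC + hmC) while oxidative bisulfite reads only mC, so the
#' difference estimates hmC. Negative values are retained by default: the
#' subtraction estimator is unbiased and clamping would bias low-hmC sites
#' upward.
#'
#' @param bs collapsed [mod_beta()] from the bisulfite assay (modality modC).
#' @param oxbs collapsed [mod_beta()] from the oxBS assay (modality mC),
#'   aligned with `bs` on sites and biological samples.
#' @param clamp if `TRUE`, negative estimates are clamped to 0.
#' @return A [mod_beta()] object with modality `hmC` (value range `[-1, 1]`).
#' @export
estimate_hmc <- function(bs, oxbs, clamp = FALSE) {
  if (!identical(rownames(bs$beta), rownames(oxbs$beta))) {
    bad <- union(setdiff(rownames(bs$beta), rownames(oxbs$beta)),
                 setdiff(rownames(oxbs$beta), rownames(bs$beta)))
    stop("BS and oxBS matrices are misaligned on sites: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else
           if (!length(bad)) " (same sites, different order)")
  }
  if (!identical(bs$samples$biological_id, oxbs$samples$biological_id)) {
    bad <- union(setdiff(bs$samples$biological_id, oxbs$samples$biological_id),
                 setdiff(oxbs$samples$biological_id, bs$samples$biological_id))
    stop("BS and oxBS matrices are misaligned on biological samples: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else
           if (!length(bad)) " (same samples, different order)")
  }
  hmc <- bs$beta - oxbs$beta
  if (clamp) hmc <- pmax(hmc, 0)
  meta <- bs$samples
  meta$assay <- "BS"  # derived modality; metadata keys stay unique
  mod_beta(hmc, bs$sites, meta, "hmC")
}
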