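#' PCA-based oscillation screen
#'
#' Quantifies how much of the modification variance is explained by
#' oscillating structure. Sites are mean-centered, the site x sample matrix
#' is decomposed by SVD, and the sample scores of the leading components are
#' each fit with the harmonic regression against ZT. A component with a
#' significant harmonic fit concentrates oscillating variance.
#'
#' @param beta collapsed [mod_beta()] object (or matrix with `zt` supplied);
#'   rows with missing cells are dropped with a message.
#' @param zt sampling times in hours (defaults to `beta$samples$zt`).
#' @param n_components number of leading components to inspect (default 4;
#'   capped at the matrix rank with a warning).
#' @param period oscillation period in hours.
#' @return list with `components` (data.frame: component, variance_fraction,
#'   harmonic fit columns), `scores` (samples x components matrix of
#'   `d_k v_k`), and `svd` (the decomposition of the centered matrix).
#' @export
pca_oscillation <- function(beta, zt = NULL, n_components = 4, period = 24) {
  Y <- if (inherits(beta, "mod_beta")) beta$beta else as.matrix(beta)
  if (is.null(zt)) {
    if (!inherits(beta, "mod_beta")) stop("zt required for a plain matrix")
    zt <- beta$samples$zt
  }
  if (ncol(Y) < 4) stop("PCA oscillation screen requires >= 4 samples")
  complete <- !apply(is.na(Y), 1, any)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " series with missing cells")
    Y <- Y[complete, , drop = FALSE]
  }
  Xc <- Y - rowMeans(Y)
  sv <- svd(Xc)
  maxk <- sum(sv$d > sv$d[1] * 1e-12)
  if (n_components > maxk) {
    warning("n_components capped at matrix rank (", maxk, ")")
    n_components <- maxk
  }
  varfrac <- sv$d^2 / sum(sv$d^2)
  scores <- sweep(sv$v[, seq_len(n_components), drop = FALSE], 2,
                  sv$d[seq_len(n_components)], `*`)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- colnames(Y)
  fits <- harmonic_fit_matrix(t(scores), zt, period)
  fits$series_id <- NULL
  comp <- cbind(data.frame(component = seq_len(n_components),
                           variance_fraction = varfrac[seq_len(n_components)]),
                fits)
  list(components = comp, scores = scores, svd = sv)
}

#' Chromosome bin profiles of mean modification density
#'
#' Summarizes EVC modification along a chromosome: sites are grouped into
#' fixed-width genomic bins, the per-bin mean density is computed for every
#' sample, and each bin's profile is min-max normalized to `[0, 1]` across
#' samples so that synchronized oscillation shows as banding against ZT.
#' Bins without sites are reported missing; bins with a constant profile
#' (zero range) map to 0.5. The chromosome-wide per-sample mean and its
#' harmonic fit are returned as well.
#'
#' @param beta collapsed [mod_beta()] object.
#' @param bin_size bin width in bp (default 1 Mb).
#' @param period oscillation period for the chromosome-wide fit.
#' @return list with `bins` (data.frame: bin_id, chrom, bin_index, n_sites),
#'   `normalized` (bins x samples matrix in `[0,1]`), `raw_means` (bins x
#'   samples), `chrom_means` (data.frame: chrom, sample_id, zt, mean) and
#'   `chrom_fits` (harmonic fit per chromosome).
#' @export
bin_profile <- function(beta, bin_size = 1e6, period = 24) {
  sites <- beta$sites
  bin_index <- floor(sites$pos / bin_size)
  bin_id <- paste0(sites$chrom, ":", bin_index)
  ubin <- unique(bin_id[order(sites$chrom, bin_index)])
  nb <- length(ubin)
  raw <- matrix(NA_real_, nb, ncol(beta$beta),
                dimnames = list(ubin, colnames(beta$beta)))
  n_sites <- integer(nb)
  for (i in seq_len(nb)) {
    rows <- which(bin_id == ubin[i])
    n_sites[i] <- length(rows)
    raw[i, ] <- colMeans(beta$beta[rows, , drop = FALSE], na.rm = TRUE)
  }
  raw[is.nan(raw)] <- NA_real_
  rng_lo <- suppressWarnings(apply(raw, 1, min, na.rm = TRUE))
  rng_hi <- suppressWarnings(apply(raw, 1, max, na.rm = TRUE))
  span <- rng_hi - rng_lo
  ok_span <- is.finite(span)
  norm <- (raw - ifelse(ok_span, rng_lo, NA)) /
    ifelse(ok_span & span > 0, span, 1)
  norm[ok_span & span <= 0, ] <- 0.5
  norm[is.na(raw)] <- NA_real_
  bins <- data.frame(bin_id = ubin,
                     chrom = sub(":[^:]*$", "", ubin),
                     bin_index = as.integer(sub("^.*:", "", ubin)),
                     n_sites = n_sites, row.names = NULL)
  chrom_means <- do.call(rbind, lapply(unique(sites$chrom), function(ch) {
    m <- colMeans(beta$beta[sites$chrom == ch, , drop = FALSE], na.rm = TRUE)
    data.frame(chrom = ch, sample_id = colnames(beta$beta),
               zt = beta$samples$zt, mean = unname(m), row.names = NULL)
  }))
  chrom_fits <- do.call(rbind, lapply(unique(sites$chrom), function(ch) {
    cm <- chrom_means[chrom_means$chrom == ch, ]
    fit <- tryCatch(fit_harmonic(cm$mean, cm$zt, period),
                    error = function(e) NULL)
    if (is.null(fit)) NULL else cbind(data.frame(chrom = ch), fit)
  }))
  list(bins = bins, normalized = norm, raw_means = raw,
       chrom_means = chrom_means, chrom_fits = chrom_fits)
}
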