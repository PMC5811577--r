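#' Minor-arc difference between two clock times
#'
#' Shortest distance between two times on the 24 h circle:
#' `min(|a - b|, 24 - |a - b|)`, in hours, always in `[0, 12]`.
#'
#' @param a,b numeric vectors of clock times in `[0, 24)` hours (recycled).
#' @return numeric vector of minor-arc differences.
#' @export
minor_arc <- function(a, b) {
  if (any(a < 0 | a >= 24, na.rm = TRUE) || any(b < 0 | b >= 24, na.rm = TRUE))
    stop("clock times must lie in [0, 24)")
  d <- abs(a - b)
  pmin(d, 24 - d)
}

#' Permutation test of the median acrophase difference between paired sets
#'
#' The observed statistic is the median minor-arc difference over pairs
#' (e.g., the same cytosine's acrophase in two tissues, or its mC and hmC
#' acrophases). The null is built by shuffling the pairing of the b-side
#' acrophases relative to the a-side and recomputing the median. With
#' `alternative = "greater"` the p-value is the fraction of permutations
#' whose median strictly exceeds the observed (evidence for antiphase,
#' observed near 12 h); `"less"` counts those strictly below (evidence for
#' phase agreement, observed near 0 h).
#'
#' @param acrophase_a,acrophase_b paired acrophases in `[0, 24)` hours.
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed.
#' @param alternative `"greater"` or `"less"`.
#' @param exhaustive enumerate all pairings (up to 8 pairs) for an exact
#'   p-value.
#' @return A `perm_summary` object.
#' @export
median_acrophase_diff_test <- function(acrophase_a, acrophase_b,
                                       n_perm = 10000, seed = NULL,
                                       alternative = c("greater", "less"),
                                       exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  ok <- !is.na(acrophase_a) & !is.na(acrophase_b)
  a <- acrophase_a[ok]; b <- acrophase_b[ok]
  if (length(a) < 2) stop("need at least 2 complete pairs")
  observed <- stats::median(minor_arc(a, b))
  tol <- 1e-12  # ties at machine precision are not beyond the observed
  beyond <- if (alternative == "greater") function(s) s > observed + tol
            else function(s) s < observed - tol
  stat <- function(idx) stats::median(minor_arc(a, b[idx]))
  if (exhaustive) {
    if (length(a) > 8) stop("exhaustive enumeration limited to 8 pairs")
    perms <- all_permutations(length(a))
    stats_v <- apply(perms, 1, stat)
    return(new_perm_summary(observed, nrow(perms), sum(beyond(stats_v)),
                            exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n_exceed <- 0L
  for (i in seq_len(n_perm))
    if (beyond(stat(sample.int(length(b))))) n_exceed <- n_exceed + 1L
  new_perm_summary(observed, n_perm, n_exceed)
}

#' Map sites to genes by interval overlap
#'
#' A site maps to every gene whose interval contains its position; sites in
#' overlapping genes contribute to each.
#'
#' @param sites site table (`site_id`, `chrom`, `pos`).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open, BED-style).
#' @return data.frame with columns `site_id`, `gene_id`.
#' @export
map_sites_to_genes <- function(sites, genes) {
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L, genes$end))
  ov <- GenomicRanges::findOverlaps(sgr, ggr)
  data.frame(site_id = sites$site_id[S4Vectors::queryHits(ov)],
             gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
             row.names = NULL)
}

#' Cross-correlation scan of mRNA phase shifts against gene-body modification
#'
#' For each gene, the mean modification density of its (EVC) sites is the
#' per-sample profile `x_i`. The gene's mRNA time course is summarized by its
#' harmonic model; the model is evaluated at the modification sampling times
#' shifted backward by `p` hours (`ZT - p`, i.e., the mRNA curve moved `p`
#' hours later) for every integer shift `p` in 0..23, and Pearson-correlated
#' with `x_i`. The scan statistic `r_p` is the mean correlation over genes.
#'
#' Because the evaluated mRNA curve is a pure sinusoid about its mesor, the
#' scan is exactly antisymmetric under a half-period shift:
#' `r_(p+12) = -r_p`. A transcript whose peak precedes the modification nadir
#' by `k` hours therefore produces the strongest *anti*-correlation at shift
#' `k` (the shifted mRNA peak aligns with the nadir) and the strongest
#' positive correlation at `k + 12`; `lag_estimate` reports the former.
#'
#' The permutation null re-draws, jointly per permutation, (i) a shuffle of
#' the ZT labels of the modification samples and (ii) a shuffle of the
#' gene-to-modification-profile pairing; per-shift p-values are the fraction
#' of permutations with mean correlation strictly greater than observed,
#' Bonferroni-corrected by the 24 shifts.
#'
#' @param expr numeric matrix genes x timepoints of expression values (or a
#'   data.frame with a `gene_id` column and one column per timepoint).
#' @param expr_zt expression sampling times in hours, one per column.
#' @param beta collapsed [mod_beta()] of EVC sites.
#' @param gene_map data.frame (`site_id`, `gene_id`) pairing modification
#'   sites to genes, e.g. from [map_sites_to_genes()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param period oscillation period in hours.
#' @return list with `scan` (data.frame: shift, r, p_perm, p_bonf),
#'   `lag_estimate` (shift of strongest anticorrelation),
#'   `peak_shift` (shift of strongest positive correlation), `n_genes`,
#'   `n_dropped` (genes excluded for non-finite fits or zero-variance
#'   profiles) and `gene_fits`.
#' @export
phase_shift_scan <- function(expr, expr_zt, beta, gene_map, n_perm = 10000,
                             seed = NULL, period = 24) {
  if (is.data.frame(expr)) {
    stopifnot("gene_id" %in% names(expr))
    ids <- expr$gene_id
    expr <- as.matrix(expr[, setdiff(names(expr), "gene_id")])
    rownames(expr) <- ids
  }
  stopifnot(length(expr_zt) == ncol(expr))
  zt <- beta$samples$zt
  n <- length(zt)
  shifts <- 0:23

  gene_fits <- harmonic_fit_matrix(expr, expr_zt, period)
  genes <- intersect(rownames(expr), unique(gene_map$gene_id))
  x_list <- lapply(genes, function(g) {
    sid <- gene_map$site_id[gene_map$gene_id == g]
    rows <- intersect(sid, rownames(beta$beta))
    if (!length(rows)) return(NULL)
    colMeans(beta$beta[rows, , drop = FALSE], na.rm = TRUE)
  })
  names(x_list) <- genes
  ## a flat mRNA model has no phase: its correlation with x is undefined
  fit_ok <- gene_fits$series_id[is.finite(gene_fits$b1) &
                                is.finite(gene_fits$b2) &
                                gene_fits$amplitude > 0]
  usable <- vapply(genes, function(g) {
    x <- x_list[[g]]
    !is.null(x) && !anyNA(x) && stats::sd(x) > 0 && g %in% fit_ok
  }, logical(1))
  n_dropped <- sum(!usable)
  genes <- genes[usable]
  G <- length(genes)
  if (G < 1) stop("no usable genes for the phase-shift scan")

  ## standardized modification profiles (rows) and, per shift, standardized
  ## mRNA-model evaluations: r = sum of products / (n - 1)
  X <- t(vapply(genes, function(g) std_vec(x_list[[g]]), numeric(n)))
  fi <- match(genes, gene_fits$series_id)
  Zp <- lapply(shifts, function(p) {
    w <- 2 * pi * (zt - p) / period
    Yg <- outer(gene_fits$b1[fi], sin(w)) + outer(gene_fits$b2[fi], cos(w))
    t(apply(Yg, 1, std_vec))
  })
  r_for <- function(Xm) {
    vapply(Zp, function(Z) mean(rowSums(Xm * Z)) / (n - 1), numeric(1))
  }
  r_obs <- r_for(X)

  if (!is.null(seed)) set.seed(seed)
  exceed <- integer(24)
  for (b in seq_len(n_perm)) {
    Xp <- X[sample.int(G), sample.int(n), drop = FALSE]
    exceed <- exceed + (r_for(Xp) > r_obs)
  }
  p_perm <- exceed / n_perm
  scan <- data.frame(shift = shifts, r = r_obs, p_perm = p_perm,
                     p_bonf = pmin(1, 24 * p_perm))
  list(scan = scan,
       lag_estimate = shifts[which.min(r_obs)],
       peak_shift = shifts[which.max(r_obs)],
       n_genes = G, n_dropped = n_dropped, gene_fits = gene_fits)
}

std_vec <- function(x) {
  xc <- x - mean(x)
  s <- sqrt(sum(xc^2) / (length(x) - 1))
  if (s == 0) return(xc)
  xc / s
}
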