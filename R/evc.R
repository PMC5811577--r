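#' Detect epigenetically variable cytosines (EVCs)
#'
#' Per site, a one-way fixed-effects ANOVA with biological sample as the
#' grouping factor and technical replicates as within-group observations.
#' Sites whose between-biological-sample variance exceeds technical-replicate
#' variance (F-test p < alpha) are flagged as EVCs. Intended to be run on one
#' tissue x age group at a time, on pre-collapse data with replicates.
#'
#' Missing cells are ignored; biological samples with fewer than 2 non-missing
#' replicates at a site are excluded from that site's test. Sites with fewer
#' than 2 usable groups or no within-group degrees of freedom get `NA`
#' statistics. Two degenerate cases are flagged: zero within-group variance
#' with differing group means (`p = 0`, flag "degenerate") and all values
#' identical (`p = 1`, flag "constant").
#'
#' @param beta a [mod_beta()] object with technical replicates (pre-collapse).
#' @param alpha significance threshold for EVC status (default 0.05).
#' @return data.frame with columns `site_id`, `f_stat`, `p`, `is_evc`,
#'   `n_groups`, `n_obs`, `flag`.
#' @export
detect_evc <- function(beta, alpha = 0.05) {
  Y <- beta$beta
  g <- as.character(beta$samples$biological_id)
  groups <- unique(g)
  if (length(groups) < 2)
    stop("EVC detection requires at least 2 biological samples")
  ns <- nrow(Y)
  W <- !is.na(Y)
  Y0 <- Y
  Y0[!W] <- 0

  k <- length(groups)
  nj <- sj <- qj <- matrix(0, ns, k)
  for (j in seq_len(k)) {
    cols <- which(g == groups[j])
    nj[, j] <- rowSums(W[, cols, drop = FALSE])
    sj[, j] <- rowSums(Y0[, cols, drop = FALSE])
    qj[, j] <- rowSums(Y0[, cols, drop = FALSE]^2)
  }
  use <- nj >= 2  # groups contributing a complete replicate set
  nj_u <- nj * use
  sj_u <- sj * use
  qj_u <- qj * use
  N <- rowSums(nj_u)
  k_eff <- rowSums(use)
  grand <- sj_u_sum <- rowSums(sj_u)
  grand <- ifelse(N > 0, grand / N, NA_real_)
  mj <- ifelse(nj_u > 0, sj_u / nj_u, 0)
  ssb <- rowSums(nj_u * (mj - ifelse(is.na(grand), 0, grand))^2 * use)
  ssw <- rowSums((qj_u - nj_u * mj^2) * use)
  ssw <- pmax(ssw, 0)  # guard tiny negative round-off

  df1 <- k_eff - 1
  df2 <- N - k_eff
  testable <- k_eff >= 2 & df2 >= 1
  scale_tol <- pmax(ssb + ssw, .Machine$double.eps)
  msb <- ssb / df1
  msw <- ssw / df2
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  flag <- rep("", ns)

  const <- testable & (ssb + ssw) <= 1e-18
  degen <- testable & !const & (ssw / scale_tol) <= 1e-12 & ssb > 0
  f[const] <- 0; p[const] <- 1; flag[const] <- "constant"
  f[degen] <- Inf; p[degen] <- 0; flag[degen] <- "degenerate"
  f[!testable] <- NA_real_; p[!testable] <- NA_real_
  flag[!testable] <- "untestable"

  data.frame(site_id = rownames(Y), f_stat = unname(f), p = unname(p),
             is_evc = !is.na(p) & p < alpha,
             n_groups = unname(k_eff), n_obs = unname(N),
             flag = flag, row.names = NULL)
}

#' Union of EVC calls for hmC analyses
#'
#' hmC estimates are analysed on sites that are epigenetically variable in
#' either the total-modification (modC, BS assay) or the true-methylation
#' (mC, oxBS assay) data from the same tissue x age group.
#'
#' @param evc_modC,evc_mC EVC result data.frames from [detect_evc()].
#' @return Character vector of site_ids variable in either modality.
#' @export
evc_union_for_hmc <- function(evc_modC, evc_mC) {
  union(evc_modC$site_id[evc_modC$is_evc], evc_mC$site_id[evc_mC$is_evc])
}
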