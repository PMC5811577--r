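## Circadian-aging association battery.

#' Two-by-two association from cell counts
#'
#' Two-sided Fisher exact p, sample odds ratio `(a*d)/(b*c)` and Woolf logit
#' 95% CI, with a 0.5 continuity correction applied to every cell only when
#' some cell is zero. The table rows are the first classification
#' (`a`,`b` vs `c`,`d`), columns the second.
#'
#' @param a,b,c,d nonnegative integer cell counts.
#' @return An `osc_assoc` object.
#' @export
association_from_counts <- function(a, b, c, d) {
  tab <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  corrected <- any(tab == 0)
  tc <- if (corrected) tab + 0.5 else tab
  or_sample <- if (b * c > 0) (a * d) / (b * c)
               else if (a * d > 0) Inf else NA_real_
  log_or <- log((tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1]))
  se <- sqrt(sum(1 / tc))
  structure(list(counts = c(a = a, b = b, c = c, d = d),
                 odds_ratio = if (degenerate) NA_real_ else or_sample,
                 ci_low = if (degenerate) NA_real_ else exp(log_or - 1.96 * se),
                 ci_high = if (degenerate) NA_real_ else exp(log_or + 1.96 * se),
                 p = p, corrected = corrected, degenerate = degenerate),
            class = "osc_assoc")
}

#' @export
print.osc_assoc <- function(x, ...) {
  cat("2x2 association: OR = ", format(x$odds_ratio, digits = 3),
      " (95% CI ", format(x$ci_low, digits = 3), "-",
      format(x$ci_high, digits = 3), "), Fisher p = ",
      format(x$p, digits = 3), "\n", sep = "")
  if (x$corrected) cat("  (0.5 added to each cell for OR/CI: zero cell)\n")
  if (x$degenerate) cat("  (degenerate margin: OR undefined)\n")
  invisible(x)
}

#' Fisher exact association between two site sets
#'
#' Builds the 2x2 contingency table of membership in `set_a` vs `set_b` over
#' a common universe (e.g., osc-modCs vs age-modCs over all EVCs) and tests
#' it with a two-sided Fisher exact test. The odds ratio is the sample OR
#' with a Woolf logit 95% CI.
#'
#' @param set_a,set_b character vectors of site_ids, subsets of `universe`.
#' @param universe character vector of all eligible site_ids.
#' @return An `osc_assoc` object: counts, odds_ratio, ci_low/ci_high, p,
#'   correction and degeneracy flags.
#' @export
fisher_association <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe)))
    stop("set_a and set_b must be subsets of the universe")
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  association_from_counts(sum(in_a & in_b), sum(in_a & !in_b),
                          sum(!in_a & in_b), sum(!in_a & !in_b))
}

#' Correlation between oscillation amplitude and aging-effect magnitude
#'
#' Tests whether sites with larger circadian amplitudes also show larger
#' epigenetic aging effects. The aging magnitude is `|slope| * age_span`, the
#' modelled total modification change over the study's age range.
#'
#' @param osc_fits harmonic fit data.frame (`series_id`, `amplitude`).
#' @param aging_fits aging fit data.frame (`site_id`, `b1`).
#' @param age_span months spanned by the design (default `25 - 9 = 16`).
#' @return list with `r`, `p`, `r2`, `n`.
#' @export
amplitude_magnitude_correlation <- function(osc_fits, aging_fits,
                                            age_span = 16) {
  m <- merge(data.frame(site_id = osc_fits$series_id,
                        amplitude = osc_fits$amplitude),
             aging_fits[, c("site_id", "b1")], by = "site_id")
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("fewer than 3 sites shared between the two fits")
  ct <- stats::cor.test(m$amplitude, abs(m$b1) * age_span)
  list(r = unname(ct$estimate), p = ct$p.value,
       r2 = unname(ct$estimate)^2, n = nrow(m))
}

#' Asymmetry between acrophase class and aging direction
#'
#' Among sites that both oscillate and change with age, cross-tabulates the
#' acrophase class (sleep ZT0-12 vs wake ZT12-24) against the aging direction
#' (gain vs loss of modification) and tests the association. A large odds
#' ratio reflects the sleep-gain / wake-loss coupling.
#'
#' @param osc_fits harmonic fits (`series_id`, `p`, `acrophase`).
#' @param aging_fits aging fits (`site_id`, `is_age_modc`, `direction`).
#' @param alpha oscillation significance threshold (default 0.05).
#' @return An `osc_assoc` object for the table
#'   `[sleep&gain, sleep&loss; wake&gain, wake&loss]`.
#' @export
acrophase_direction_asymmetry <- function(osc_fits, aging_fits, alpha = 0.05) {
  osc <- osc_fits[!is.na(osc_fits$p) & osc_fits$p < alpha &
                  !is.na(osc_fits$acrophase), ]
  aging <- aging_fits[aging_fits$is_age_modc, ]
  m <- merge(data.frame(site_id = osc$series_id,
                        class = classify_acrophase(osc$acrophase)),
             aging[, c("site_id", "direction")], by = "site_id")
  if (!nrow(m)) stop("no sites are both oscillating and age-correlated")
  association_from_counts(sum(m$class == "sleep" & m$direction == "gain"),
                          sum(m$class == "sleep" & m$direction == "loss"),
                          sum(m$class == "wake" & m$direction == "gain"),
                          sum(m$class == "wake" & m$direction == "loss"))
}

#' Binomial enrichment of age-modCs across Venn regions of oscillation calls
#'
#' Partitions oscillating sites into the 7 regions of the Venn diagram of the
#' per-age-group oscillation calls (e.g., 9-, 15-, 25-month) and tests, per
#' region, whether its age-modC proportion deviates from the expected
#' proportion -- the age-modC fraction among all sites of the universe -- with
#' a two-sided exact binomial test.
#'
#' @param osc_sets named list of 3 character vectors of oscillating site_ids
#'   (one per age group).
#' @param aging_fits aging fit data.frame (`site_id`, `is_age_modc`).
#' @param universe site universe for the expected proportion (default: all
#'   sites in `aging_fits`).
#' @return data.frame with one row per non-empty region: `region`, `k`
#'   (age-modC count), `n` (region size), `proportion`, `expected_prop`,
#'   `p`, `ci_low`, `ci_high` (Clopper-Pearson 95%).
#' @export
venn_binomial_enrichment <- function(osc_sets, aging_fits,
                                     universe = aging_fits$site_id) {
  stopifnot(length(osc_sets) == 3)
  if (is.null(names(osc_sets))) names(osc_sets) <- paste0("set", 1:3)
  age_ids <- aging_fits$site_id[aging_fits$is_age_modc]
  expected <- mean(universe %in% age_ids)
  nm <- names(osc_sets)
  ids <- unique(unlist(osc_sets))
  if (!length(ids)) stop("all oscillation sets are empty")
  member <- matrix(vapply(osc_sets, function(s) ids %in% s,
                          logical(length(ids))),
                   nrow = length(ids), dimnames = list(NULL, nm))
  regions <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  out <- lapply(sort(unique(regions)), function(reg) {
    rid <- ids[regions == reg]
    k <- sum(rid %in% age_ids)
    n <- length(rid)
    bt <- stats::binom.test(k, n, p = expected, alternative = "two.sided")
    data.frame(region = reg, k = k, n = n, proportion = k / n,
               expected_prop = expected, p = bt$p.value,
               ci_low = bt$conf.int[1], ci_high = bt$conf.int[2])
  })
  res <- do.call(rbind, out)
  all_regions <- apply(expand.grid(rep(list(c(FALSE, TRUE)), 3))[-1, ], 1,
                       function(row) paste(nm[unlist(row)], collapse = "&"))
  attr(res, "empty_regions") <- setdiff(all_regions, res$region)
  res
}

#' Weighted Pearson correlation
#'
#' Pearson correlation with per-observation weights (e.g., genes weighted by
#' their number of cytosines): weighted means, variances and covariance give
#' `r_w`; the p-value uses a t approximation whose effective sample size is
#' Kish's `(sum w)^2 / sum(w^2)`.
#'
#' @param x,y numeric vectors.
#' @param w nonnegative weights.
#' @return list with `r`, `p`, `n_eff`.
#' @export
weighted_pearson <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  if (any(w < 0)) stop("weights must be nonnegative")
  ok <- stats::complete.cases(x, y, w) & w > 0
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (sum(w) == 0) stop("zero total weight")
  if (length(x) < 3) stop("need at least 3 observations with positive weight")
  xm <- sum(w * x) / sum(w)
  ym <- sum(w * y) / sum(w)
  vxx <- sum(w * (x - xm)^2)
  vyy <- sum(w * (y - ym)^2)
  if (vxx == 0 || vyy == 0)
    stop("weighted variance is zero; correlation undefined")
  r <- sum(w * (x - xm) * (y - ym)) / sqrt(vxx * vyy)
  n_eff <- sum(w)^2 / sum(w^2)
  df <- n_eff - 2
  if (df <= 0) stop("effective sample size too small for a p-value")
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
       n_eff = n_eff)
}

#' Subsample biological samples for cohort-size sensitivity checks
#'
#' Draws a uniform random subsample of biological samples without
#' replacement (column order preserved), e.g., to re-run an analysis with
#' cohort sizes matched across age groups.
#'
#' @param beta a [mod_beta()] object.
#' @param target_n number of samples to keep.
#' @param seed RNG seed (deterministic subsample under a fixed seed).
#' @return A [mod_beta()] with `target_n` columns.
#' @export
subsample_match <- function(beta, target_n, seed = NULL) {
  n <- ncol(beta$beta)
  if (target_n <= 0) stop("target_n must be positive")
  if (target_n > n) stop("target_n exceeds available samples")
  if (target_n == n) return(beta)
  if (!is.null(seed)) set.seed(seed)
  keep <- sort(sample.int(n, target_n))
  subset_mod(beta, samples = keep)
}
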