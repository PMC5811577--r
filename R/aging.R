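#' Per-site linear regression of modification density on age
#'
#' Fits `beta = b0 + b1 * age` per site by OLS across all biological samples
#' of the age cohorts, and compares it to the intercept-only model with an
#' F-test (df 1, n - 2). P-values are Bonferroni-corrected over the tested
#' sites (which should be the EVCs shared by all age groups); sites with a
#' corrected p below `alpha` are age-correlated cytosines (age-modCs), with
#' the slope sign giving the direction of change (gain or loss of
#' modification with age).
#'
#' @param beta collapsed [mod_beta()] spanning the age cohorts (ages taken
#'   from `beta$samples$age_months` unless `ages` is given).
#' @param ages age in months per sample column.
#' @param alpha Bonferroni-corrected significance threshold (default 0.05).
#' @return data.frame with `site_id`, `b0`, `b1` (beta units per month),
#'   `f_stat`, `p`, `p_bonf`, `is_age_modc`, `direction` (factor gain/loss).
#' @export
fit_aging <- function(beta, ages = NULL, alpha = 0.05) {
  Y <- if (inherits(beta, "mod_beta")) beta$beta else as.matrix(beta)
  if (is.null(ages)) {
    if (!inherits(beta, "mod_beta")) stop("ages required for a plain matrix")
    ages <- beta$samples$age_months
  }
  stopifnot(length(ages) == ncol(Y))
  if (length(unique(ages)) < 2) stop("aging fit requires >= 2 distinct ages")
  if (length(unique(ages)) < 3)
    warning("fewer than 3 distinct ages: linearity cannot be assessed")
  X <- cbind(1, age = ages)
  ns <- nrow(Y)
  out <- data.frame(site_id = rownames(Y) %||% as.character(seq_len(ns)),
                    b0 = NA_real_, b1 = NA_real_, f_stat = NA_real_,
                    p = NA_real_, row.names = NULL)
  complete <- !apply(is.na(Y), 1, any)
  fill <- function(Yb, Xb, rows) {
    n <- ncol(Yb)
    B <- qr.coef(qr(Xb), t(Yb))
    rss <- colSums((t(Yb) - Xb %*% B)^2)
    sst <- rowSums((Yb - rowMeans(Yb))^2)
    flat <- sst <= .Machine$double.eps * pmax(1, rowSums(Yb^2))
    r2 <- ifelse(flat, 0, pmin(pmax(1 - rss / sst, 0), 1))
    f <- r2 / ((1 - r2) / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
    p[flat] <- 1; f[flat] <- 0
    out$b0[rows] <<- B[1, ]; out$b1[rows] <<- B[2, ]
    out$f_stat[rows] <<- f; out$p[rows] <<- p
  }
  if (any(complete)) fill(Y[complete, , drop = FALSE], X, which(complete))
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) >= 3 && length(unique(ages[ok])) >= 2)
      fill(Y[i, ok, drop = FALSE], X[ok, , drop = FALSE], i)
  }
  n_tested <- sum(!is.na(out$p))
  out$p_bonf <- pmin(1, out$p * n_tested)
  out$is_age_modc <- !is.na(out$p_bonf) & out$p_bonf < alpha
  out$direction <- factor(ifelse(out$b1 >= 0, "gain", "loss"),
                          levels = c("gain", "loss"))
  out
}
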