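## Fixed-period harmonic (cosinor) regression.
##
## y = b0 + b1 sin(2 pi ZT / T) + b2 cos(2 pi ZT / T) + e,  T = 24 h default.
## Significance is the F-test of the sine+cosine terms against the
## intercept-only model; amplitude is peak-to-trough, A = 2 sqrt(b1^2+b2^2);
## acrophase (ZT of peak) is phi = (12/pi) atan2(b1, b2) mod 24 (for general
## period T, (T/2pi) atan2(b1, b2) mod T).

harmonic_design <- function(zt, period) {
  w <- 2 * pi * zt / period
  cbind(intercept = 1, s = sin(w), c = cos(w))
}

#' Fit a fixed-period harmonic regression to one series
#'
#' @param y numeric response (e.g., modification density), one value per
#'   observation.
#' @param zt observation times in hours (Zeitgeber time or absolute hours;
#'   only the phase modulo `period` matters).
#' @param period oscillation period in hours (default 24).
#' @return One-row data.frame with `b0`, `b1`, `b2`, `period`, `r2`,
#'   `f_stat`, `p`, `amplitude` (peak-to-trough, same units as `y`),
#'   `acrophase` (hours in `[0, period)`, `NA` when the fit is flat) and `n`.
#' @export
fit_harmonic <- function(y, zt, period = 24) {
  stopifnot(length(y) == length(zt), period > 0)
  ok <- !is.na(y) & !is.na(zt)
  y <- y[ok]; zt <- zt[ok]
  if (length(y) < 4) stop("harmonic fit requires >= 4 observations")
  if (length(unique(zt %% period)) < 4)
    stop("harmonic fit requires >= 4 distinct times (mod period)")
  fit <- harmonic_fit_matrix(matrix(y, nrow = 1), zt, period)
  fit$series_id <- NULL
  fit
}

#' Fit harmonic regressions to every row of a matrix
#'
#' Vectorized over sites: one QR decomposition of the shared design is reused
#' for all complete rows; rows with missing cells are fit individually on
#' their complete cases (and get `NA` if fewer than 4 distinct times remain).
#'
#' @param Y numeric matrix, series x observations (sites x samples).
#' @param zt observation times in hours, one per column.
#' @param period oscillation period in hours (default 24).
#' @return data.frame with one row per series: `series_id`, `b0`, `b1`,
#'   `b2`, `period`, `r2`, `f_stat`, `p`, `amplitude`, `acrophase`, `n`.
#' @export
harmonic_fit_matrix <- function(Y, zt, period = 24) {
  stopifnot(is.matrix(Y), length(zt) == ncol(Y), period > 0)
  if (length(unique(zt %% period)) < 4)
    stop("harmonic fit requires >= 4 distinct times (mod period)")
  X <- harmonic_design(zt, period)
  if (qr(X)$rank < 3) stop("rank-deficient harmonic design")
  ns <- nrow(Y)
  out <- data.frame(series_id = rownames(Y) %||% as.character(seq_len(ns)),
                    b0 = NA_real_, b1 = NA_real_, b2 = NA_real_,
                    period = period, r2 = NA_real_, f_stat = NA_real_,
                    p = NA_real_, amplitude = NA_real_, acrophase = NA_real_,
                    n = NA_integer_, row.names = NULL)
  complete <- !apply(is.na(Y), 1, any)
  if (any(complete)) {
    res <- harmonic_core(Y[complete, , drop = FALSE], X, period)
    out[complete, names(res)] <- res
  }
  for (i in which(!complete)) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) >= 4 && length(unique(zt[ok] %% period)) >= 4) {
      res <- harmonic_core(Y[i, ok, drop = FALSE],
                           harmonic_design(zt[ok], period), period)
      out[i, names(res)] <- res
    }
  }
  out
}

## Closed-form OLS on a shared full-rank design (QR-based, stable for
## near-collinear time grids). Y rows are series.
harmonic_core <- function(Y, X, period = 24) {
  n <- ncol(Y)
  qx <- qr(X)
  B <- qr.coef(qx, t(Y))            # 3 x nseries
  fitted <- X %*% B
  resid <- t(Y) - fitted
  rss <- colSums(resid^2)
  ym <- rowMeans(Y)
  sst <- rowSums((Y - ym)^2)
  flat <- sst <= .Machine$double.eps * pmax(1, rowSums(Y^2))
  r2 <- ifelse(flat, 0, pmin(pmax(1 - rss / sst, 0), 1))
  df2 <- n - 3
  f <- (r2 / 2) / ((1 - r2) / df2)
  p <- stats::pf(f, 2, df2, lower.tail = FALSE)
  p[flat] <- 1
  f[flat] <- 0
  b1 <- B[2, ]; b2 <- B[3, ]
  b1[flat] <- 0; b2[flat] <- 0
  amp <- 2 * sqrt(b1^2 + b2^2)
  acro <- acrophase_from_coef(b1, b2, period)
  acro[amp == 0] <- NA_real_
  data.frame(b0 = unname(B[1, ]), b1 = unname(b1), b2 = unname(b2),
             r2 = unname(r2), f_stat = unname(f), p = unname(p),
             amplitude = unname(amp), acrophase = unname(acro),
             n = n, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

acrophase_from_coef <- function(b1, b2, period = 24) {
  ((period / (2 * pi)) * atan2(b1, b2)) %% period
}

#' Call oscillating sites from harmonic fits
#'
#' @param fits data.frame from [harmonic_fit_matrix()] (run on EVCs).
#' @param alpha significance threshold (default 0.05).
#' @return list with `osc_ids` (series ids with `p < alpha`), `fraction`
#'   (of testable series) and `n_tested`.
#' @export
call_osc <- function(fits, alpha = 0.05) {
  tested <- !is.na(fits$p)
  osc <- tested & fits$p < alpha
  list(osc_ids = fits$series_id[osc],
       fraction = if (any(tested)) sum(osc) / sum(tested) else NA_real_,
       n_tested = sum(tested))
}

#' Classify acrophases as sleep or wake
#'
#' In a 12:12 light-dark design with nocturnal animals, ZT0-12 (lights on) is
#' the sleep phase and ZT12-24 (lights off) the wake phase. The intervals are
#' half-open (`[0,12)` sleep, `[12,24)` wake) so ZT12 is counted once, as
#' wake.
#'
#' @param acrophase numeric vector of acrophases in `[0, 24)` hours (`NA`
#'   allowed).
#' @return factor with levels `sleep`, `wake` (`NA` propagated).
#' @export
classify_acrophase <- function(acrophase) {
  if (any(acrophase < 0 | acrophase >= 24, na.rm = TRUE))
    stop("acrophase must lie in [0, 24)")
  factor(ifelse(acrophase < 12, "sleep", "wake"), levels = c("sleep", "wake"))
}

#' Scan goodness-of-fit across candidate periods
#'
#' Refits the harmonic model at each candidate period and returns the R^2
#' profile; a 24 h peak indicates circadian periodicity (e.g., for actogram
#' spectra or any single series).
#'
#' @param y numeric series.
#' @param times observation times in hours.
#' @param periods candidate periods in hours (all > 0).
#' @return data.frame with columns `period` and `r2`; the attribute
#'   `best_period` holds the argmax.
#' @export
period_scan <- function(y, times, periods = 20:28) {
  stopifnot(all(periods > 0))
  r2 <- vapply(periods, function(p) fit_harmonic(y, times, period = p)$r2,
               numeric(1))
  out <- data.frame(period = periods, r2 = r2)
  attr(out, "best_period") <- periods[which.max(r2)]
  out
}
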