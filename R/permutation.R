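## Permutation tests for the experiment-wide oscillation signal.

## All permutations of 1..n (n small); used for exhaustive enumeration.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

new_perm_summary <- function(observed, n_perm, n_exceed, exhaustive = FALSE) {
  p <- n_exceed / n_perm
  structure(list(observed_stat = observed, n_perm = n_perm,
                 n_exceed = n_exceed, p = p,
                 floor_flag = n_exceed == 0,
                 p_label = if (n_exceed == 0) paste0("< ", format(1 / n_perm))
                           else format(p),
                 exhaustive = exhaustive),
            class = "perm_summary")
}

#' @export
print.perm_summary <- function(x, ...) {
  cat("Permutation test: observed = ", format(x$observed_stat),
      ", p ", if (x$floor_flag) x$p_label else paste0("= ", x$p_label),
      " (", x$n_perm, if (x$exhaustive) " exhaustive" else " random",
      " permutations)\n", sep = "")
  invisible(x)
}

#' Permutation test of the mean harmonic R-squared
#'
#' The observed statistic is the mean, over all sites (typically EVCs), of
#' the harmonic-regression R^2 against ZT. Each permutation shuffles the ZT
#' labels across samples -- one shuffle applied jointly to all sites, which
#' preserves inter-site correlation -- and recomputes the mean R^2. The
#' p-value is the fraction of permutations whose mean R^2 strictly exceeds
#' the observed value; when no permutation exceeds it the result is reported
#' as "< 1/n_perm".
#'
#' @param beta a collapsed [mod_beta()] object (one column per biological
#'   sample), or a plain sites x samples matrix if `zt` is given.
#' @param zt sampling times in hours (taken from `beta$samples$zt` when
#'   `beta` is a `mod_beta`).
#' @param n_perm number of random permutations (default 10000).
#' @param seed RNG seed for reproducibility.
#' @param period oscillation period in hours.
#' @param exhaustive if `TRUE`, enumerate all `n!` ZT relabelings instead of
#'   sampling (allowed for up to 8 samples); the p-value is then exact.
#' @return A `perm_summary` object (observed statistic, exceedance count,
#'   p-value, floor flag).
#' @export
permute_mean_r2 <- function(beta, zt = NULL, n_perm = 10000, seed = NULL,
                            period = 24, exhaustive = FALSE) {
  Y <- if (inherits(beta, "mod_beta")) beta$beta else as.matrix(beta)
  if (is.null(zt)) {
    if (!inherits(beta, "mod_beta")) stop("zt required for a plain matrix")
    zt <- beta$samples$zt
  }
  if (length(unique(zt %% period)) < 4)
    stop("fewer than 4 distinct ZT values")
  complete <- !apply(is.na(Y), 1, any)
  Y <- Y[complete, , drop = FALSE]
  if (!nrow(Y)) stop("no complete series to test")
  n <- ncol(Y)

  X <- harmonic_design(zt, period)
  H <- X %*% solve(crossprod(X), t(X))    # hat matrix; n is small
  ym <- rowMeans(Y)
  sst <- rowSums((Y - ym)^2)
  keep <- sst > .Machine$double.eps * pmax(1, rowSums(Y^2))
  mean_r2 <- function(cols) {
    Yp <- Y[, cols, drop = FALSE]
    rss <- rowSums((Yp - Yp %*% t(H))^2)
    r2 <- numeric(length(sst))
    r2[keep] <- pmin(pmax(1 - rss[keep] / sst[keep], 0), 1)
    mean(r2)
  }
  ## shuffling ZT labels is equivalent to applying the inverse shuffle to the
  ## sample columns with the design fixed
  observed <- mean_r2(seq_len(n))
  ## strictly greater, up to machine noise: a permutation whose statistic is
  ## analytically equal to the observed (e.g., a time reversal) is not an
  ## exceedance
  tol <- 1e-12
  if (exhaustive) {
    if (n > 8) stop("exhaustive enumeration limited to 8 samples")
    perms <- all_permutations(n)
    stats <- apply(perms, 1, mean_r2)
    return(new_perm_summary(observed, nrow(perms),
                            sum(stats > observed + tol), exhaustive = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  n_exceed <- 0L
  for (b in seq_len(n_perm))
    if (mean_r2(sample.int(n)) > observed + tol) n_exceed <- n_exceed + 1L
  new_perm_summary(observed, n_perm, n_exceed)
}
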