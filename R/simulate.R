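#' Configuration for the synthetic circadian methylation experiment
#'
#' Defaults emulate the structure of a targeted bisulfite/oxBS circadian
#' study: tissue collected every 2 h over 58 h (so Zeitgeber time wraps past
#' 24 h and several samples share a ZT), technical triplicates, ~1,800x mean
#' read depth per CpG, a planted oscillating fraction with peak-to-trough
#' amplitudes of a few percent (mean 0.045, SD 0.022 in beta units),
#' a bimodal acrophase distribution with sleep- and wake-phase modes, mC/hmC
#' antiphase partner sites, and aging slopes whose sign is coupled to the
#' acrophase class (sleep-phase sites tend to gain modification with age,
#' wake-phase sites to lose it). Three age cohorts (9, 15, 25 months) carry
#' 12/10/10 biological samples by default.
#'
#' @param n_sites number of CpG sites.
#' @param zt_grid collection hours since first sampling (ZT = hour mod 24).
#' @param cohorts data.frame with `age_months` and `n_biological`.
#' @param n_replicates technical replicates per biological sample.
#' @param mean_depth Poisson mean read depth per replicate.
#' @param min_depth floor applied to simulated depths.
#' @param frac_oscillating fraction of sites with a planted oscillation.
#' @param amplitude_mean,amplitude_sd,amplitude_min,amplitude_max truncated
#'   normal distribution of peak-to-trough amplitudes (beta units).
#' @param acrophase_centers,acrophase_kappa,acrophase_weight two von Mises
#'   mixture components for gene-level acrophases (hours; weight of the
#'   first component).
#' @param acrophase_site_jitter wrapped-normal SD (hours) of per-site
#'   acrophase jitter around the gene acrophase.
#' @param baseline_shape1,baseline_shape2 Beta distribution of baseline
#'   modification density.
#' @param sigma_biological SD of per-biological-sample noise (beta units).
#' @param frac_aging overall fraction of sites with a planted aging trend.
#' @param aging_osc_odds odds ratio of carrying an aging trend for
#'   oscillating vs non-oscillating sites (1 = independent). The per-class
#'   aging probabilities are solved so the overall fraction stays
#'   `frac_aging`. Residual oscillation variance dilutes the aging F-test at
#'   oscillating sites, so the odds ratio measured after detection is
#'   attenuated relative to this planted value.
#' @param aging_slope_mean,aging_slope_sd,aging_slope_min truncated normal
#'   distribution of |slope| (beta units per month).
#' @param acrophase_aging_coupling probability that an oscillating aging
#'   site follows the sleep-gain / wake-loss rule.
#' @param amplitude_aging_corr latent Gaussian correlation between a site's
#'   oscillation amplitude and its aging-slope magnitude (0 = independent).
#' @param hmc_fraction fraction of oscillating sites that are mC/hmC
#'   antiphase partners.
#' @param hmc_base baseline hmC level at partner sites (their hmC oscillates
#'   with twice the modC amplitude, in phase with modC, which puts mC in
#'   antiphase with hmC).
#' @param hmc_flat constant hmC level at non-partner sites.
#' @param frac_low_coverage fraction of sites forced to low depth (QC fodder).
#' @param sites_per_gene sites per simulated gene block.
#' @param mrna_lag_hours hours by which the mRNA acrophase precedes the
#'   modification nadir of its gene.
#' @param expr_base,expr_amp,expr_noise_sd expression mesor, peak-to-trough
#'   amplitude and noise SD (arbitrary units).
#' @param bs_nonconversion bisulfite non-conversion rate inflating beta
#'   toward 1 (default 0, i.e., off).
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_sites = 1000,
                       zt_grid = seq(0, 58, by = 2),
                       cohorts = data.frame(age_months = c(9, 15, 25),
                                            n_biological = c(12, 10, 10)),
                       n_replicates = 3,
                       mean_depth = 1800,
                       min_depth = 10,
                       frac_oscillating = 0.35,
                       amplitude_mean = 0.045,
                       amplitude_sd = 0.022,
                       amplitude_min = 0.005,
                       amplitude_max = 0.17,
                       acrophase_centers = c(6, 18),
                       acrophase_kappa = 2,
                       acrophase_weight = 0.5,
                       acrophase_site_jitter = 0.5,
                       baseline_shape1 = 20,
                       baseline_shape2 = 20,
                       sigma_biological = 0.01,
                       frac_aging = 0.15,
                       aging_osc_odds = 4,
                       aging_slope_mean = 0.003,
                       aging_slope_sd = 0.001,
                       aging_slope_min = 5e-4,
                       acrophase_aging_coupling = 0.9,
                       amplitude_aging_corr = 0.6,
                       hmc_fraction = 0.2,
                       hmc_base = 0.15,
                       hmc_flat = 0.05,
                       frac_low_coverage = 0,
                       sites_per_gene = 10,
                       mrna_lag_hours = 3,
                       expr_base = 5,
                       expr_amp = 1,
                       expr_noise_sd = 0.1,
                       bs_nonconversion = 0,
                       seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(cfg$frac_oscillating, cfg$frac_aging, cfg$hmc_fraction,
             cfg$acrophase_weight, cfg$acrophase_aging_coupling,
             cfg$frac_low_coverage, cfg$bs_nonconversion)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  stopifnot(cfg$n_sites >= 1, cfg$n_replicates >= 1, cfg$mean_depth > 0,
            nrow(cfg$cohorts) >= 1, all(cfg$cohorts$n_biological >= 1),
            length(cfg$zt_grid) >= 4, cfg$amplitude_min <= cfg$amplitude_max)
  structure(cfg, class = "sim_config")
}

## solve P(aging | osc) and P(aging | still) for a target overall rate f and
## odds ratio or_ between the classes, with P(osc) = q
aging_class_probs <- function(f, or_, q) {
  if (f <= 0 || f >= 1 || or_ == 1 || q %in% c(0, 1))
    return(c(osc = f, still = f))
  g <- function(p0) {
    p1 <- or_ * p0 / (1 + (or_ - 1) * p0)
    q * p1 + (1 - q) * p0 - f
  }
  p0 <- stats::uniroot(g, c(1e-12, 1 - 1e-12))$root
  c(osc = or_ * p0 / (1 + (or_ - 1) * p0), still = p0)
}

## truncated normal by resampling (bounds are wide relative to sd); falls
## back to clamping if the acceptance region is effectively unreachable
rtnorm <- function(n, mean, sd, lo, hi) {
  if (hi <= lo) return(rep((lo + hi) / 2, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(pmax(x, lo), hi)
}

## von Mises sampler (Best & Fisher rejection scheme); mu, output in radians
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      i <- i + 1L
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
    }
  }
  out
}

circular_mean_hours <- function(h, period = 24) {
  w <- 2 * pi * h / period
  (atan2(mean(sin(w)), mean(cos(w))) * period / (2 * pi)) %% period
}

#' Simulate a count-level circadian methylation experiment
#'
#' Generates matched BS and oxBS read-count data with known ground truth.
#' Per site and biological sample the latent total-modification density is
#' `clip(baseline + (A/2) cos(2 pi (ZT - phi)/24) + slope (age - age_min) +
#' biological noise)`; each technical replicate draws a Poisson read depth
#' (floored) and binomial methylated counts. oxBS counts are drawn from the
#' latent density minus the site's hmC component. At antiphase partner sites
#' the hmC component oscillates in phase with total modification at twice
#' its amplitude, so the residual mC oscillates in antiphase with hmC.
#'
#' @param config a [sim_config()].
#' @return list of class `osc_sim` with elements `bs` and `oxbs`
#'   ([mod_counts()] objects), `truth` (per-site planted parameters, with
#'   amplitudes updated to realized values after feasibility clipping),
#'   `genes` (gene intervals), and `config`.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  ns <- cfg$n_sites

  ## -- sites and gene blocks --------------------------------------------
  pos <- sort(sample.int(1.45e8, ns))
  gene <- paste0("gene", formatC(ceiling(seq_len(ns) / cfg$sites_per_gene),
                                 width = 4, flag = "0"))
  sites <- data.frame(site_id = sprintf("s%05d", seq_len(ns)),
                      chrom = "chr7", pos = pos, strand = "+", gene = gene)
  ug <- unique(gene)

  ## -- per-site truth ----------------------------------------------------
  comp <- stats::rbinom(length(ug), 1, cfg$acrophase_weight) + 1
  gene_phi <- (rvonmises(length(ug),
                         2 * pi * cfg$acrophase_centers[1] / 24,
                         cfg$acrophase_kappa) * 24 / (2 * pi)) %% 24
  phi2 <- (rvonmises(length(ug), 2 * pi * cfg$acrophase_centers[2] / 24,
                     cfg$acrophase_kappa) * 24 / (2 * pi)) %% 24
  gene_phi[comp == 2] <- phi2[comp == 2]
  names(gene_phi) <- ug

  baseline <- stats::rbeta(ns, cfg$baseline_shape1, cfg$baseline_shape2)
  is_osc <- stats::runif(ns) < cfg$frac_oscillating
  phi <- (gene_phi[gene] + stats::rnorm(ns, 0, cfg$acrophase_site_jitter)) %% 24
  phi[!is_osc] <- NA_real_
  amp_draw <- rtnorm(ns, cfg$amplitude_mean, cfg$amplitude_sd,
                     cfg$amplitude_min, cfg$amplitude_max)
  amp <- amp_draw
  amp[!is_osc] <- 0

  is_hmc <- is_osc & stats::runif(ns) < cfg$hmc_fraction
  ## feasibility: keep all latent densities inside (0, 1) with margin
  baseline[is_hmc] <- pmin(pmax(baseline[is_hmc],
                                cfg$hmc_base + amp[is_hmc] / 2 + 0.05), 0.9)
  amp[is_hmc] <- pmin(amp[is_hmc], cfg$hmc_base)        # keep hmC >= 0
  amp <- pmin(amp, 2 * pmin(baseline, 1 - baseline) - 0.02)
  amp <- pmax(amp, 0)
  amp[!is_osc] <- 0
  ## truth reflects realized parameters after feasibility clipping
  infeasible <- is_osc & amp <= 0
  is_osc[infeasible] <- FALSE
  is_hmc <- is_hmc & is_osc
  phi[!is_osc] <- NA_real_

  ## membership coupling: oscillating sites carry aging trends at
  ## aging_osc_odds times the odds of still sites, overall rate frac_aging
  q_osc <- mean(is_osc)
  p_aging <- aging_class_probs(cfg$frac_aging, cfg$aging_osc_odds, q_osc)
  is_aging <- stats::runif(ns) < ifelse(is_osc, p_aging["osc"],
                                        p_aging["still"])
  ## slope magnitude shares a latent Gaussian with the amplitude draw, so
  ## large-amplitude oscillators tend to carry large aging effects
  rho <- cfg$amplitude_aging_corr
  z_amp <- (amp_draw - cfg$amplitude_mean) / cfg$amplitude_sd
  z_slope <- rho * z_amp + sqrt(1 - rho^2) * stats::rnorm(ns)
  slope_mag <- pmax(cfg$aging_slope_mean + cfg$aging_slope_sd * z_slope,
                    cfg$aging_slope_min)
  follows <- stats::runif(ns) < cfg$acrophase_aging_coupling
  sleepish <- !is.na(phi) & phi < 12
  sgn <- ifelse(is_osc,
                ifelse(sleepish == follows, 1, -1),
                ifelse(stats::runif(ns) < 0.5, 1, -1))
  ## sleep & follows -> gain; wake & follows -> loss (and vice versa)
  slope <- ifelse(is_aging, sgn * slope_mag, 0)

  hmc_amp <- ifelse(is_hmc, 2 * amp, 0)
  hmc_level <- ifelse(is_hmc, cfg$hmc_base, cfg$hmc_flat)

  low_cov <- stats::runif(ns) < cfg$frac_low_coverage

  ## -- samples -----------------------------------------------------------
  age_min <- min(cfg$cohorts$age_months)
  bio <- do.call(rbind, lapply(seq_len(nrow(cfg$cohorts)), function(ci) {
    nb <- cfg$cohorts$n_biological[ci]
    hours <- if (nb <= length(cfg$zt_grid))
      cfg$zt_grid[round(seq(1, length(cfg$zt_grid), length.out = nb))]
    else  # more animals than grid points: cycle through the grid
      rep_len(cfg$zt_grid, nb)
    data.frame(age_months = cfg$cohorts$age_months[ci],
               biological_id = sprintf("a%02d_b%02d",
                                       cfg$cohorts$age_months[ci],
                                       seq_len(nb)),
               collection_hour = hours, zt = hours %% 24)
  }))

  make_samples <- function(assay) {
    s <- bio[rep(seq_len(nrow(bio)), each = cfg$n_replicates), ]
    s$replicate_index <- rep(seq_len(cfg$n_replicates), nrow(bio))
    s$assay <- assay
    s$tissue <- "tissue"
    s$sample_id <- paste(s$biological_id, assay,
                         paste0("r", s$replicate_index), sep = "_")
    rownames(s) <- NULL
    s[, c("sample_id", "biological_id", "replicate_index", "tissue",
          "age_months", "zt", "assay", "collection_hour")]
  }
  samp_bs <- make_samples("BS")
  samp_ox <- make_samples("oxBS")

  ## -- latent densities (shared biological noise across assays) ----------
  nb <- nrow(bio)
  oscw <- 2 * pi * (outer(rep(0, ns), bio$zt, `+`) -
                    matrix(ifelse(is.na(phi), 0, phi), ns, nb)) / 24
  osc_term <- (amp / 2) * cos(oscw)
  age_term <- outer(slope, bio$age_months - age_min)
  bio_noise <- matrix(stats::rnorm(ns * nb, 0, cfg$sigma_biological), ns, nb)
  eps <- 1e-3
  mu_modc <- pmin(pmax(baseline + osc_term + age_term + bio_noise, eps), 1 - eps)
  hmc_t <- hmc_level + (hmc_amp / 2) * cos(oscw)
  mu_mc <- pmin(pmax(mu_modc - hmc_t, eps), 1 - eps)
  if (cfg$bs_nonconversion > 0) {
    mu_modc <- mu_modc + cfg$bs_nonconversion * (1 - mu_modc)
    mu_mc <- mu_mc + cfg$bs_nonconversion * (1 - mu_mc)
  }

  draw_counts <- function(mu, samples) {
    nsamp <- nrow(samples)
    M <- U <- matrix(0L, ns, nsamp)
    bi <- match(samples$biological_id, bio$biological_id)
    for (j in seq_len(nsamp)) {
      depth <- pmax(stats::rpois(ns, cfg$mean_depth), cfg$min_depth)
      depth[low_cov] <- pmax(stats::rpois(sum(low_cov), 15), 1)
      m <- stats::rbinom(ns, depth, mu[, bi[j]])
      M[, j] <- m
      U[, j] <- depth - m
    }
    mod_counts(M, U, sites, samples)
  }
  bs <- draw_counts(mu_modc, samp_bs)
  oxbs <- draw_counts(mu_mc, samp_ox)

  truth <- data.frame(
    site_id = sites$site_id, gene = gene, baseline = baseline,
    is_oscillating = is_osc, amplitude = amp, acrophase = unname(phi),
    acrophase_class = ifelse(is.na(phi), NA,
                             ifelse(phi < 12, "sleep", "wake")),
    is_aging = is_aging, slope = slope,
    is_hmc_partner = is_hmc,
    hmc_level = hmc_level, hmc_amplitude = hmc_amp,
    hmc_acrophase = ifelse(is_hmc, unname(phi), NA_real_),
    mc_acrophase = ifelse(is_hmc, (unname(phi) + 12) %% 24,
                          ifelse(is_osc, unname(phi), NA_real_)),
    mc_amplitude = ifelse(is_hmc, amp, amp),
    low_coverage = low_cov, row.names = NULL)

  genes_df <- do.call(rbind, lapply(ug, function(g) {
    p <- sites$pos[sites$gene == g]
    data.frame(gene_id = g, chrom = "chr7", start = min(p), end = max(p) + 1L)
  }))

  structure(list(bs = bs, oxbs = oxbs, truth = truth, genes = genes_df,
                 config = cfg),
            class = "osc_sim")
}

#' Simulate matched circadian gene-expression time courses
#'
#' Genes containing oscillating sites get a sinusoidal mRNA profile whose
#' acrophase precedes the gene's modification nadir by `mrna_lag_hours`
#' (expression peaks first; the modification trough follows); other genes
#' are flat. Gaussian noise is added everywhere.
#'
#' @param sim an `osc_sim` from [simulate_experiment()].
#' @param expr_zt expression sampling hours (default: the simulation's
#'   collection grid).
#' @return list with `expr` (genes x timepoints matrix), `zt`, and
#'   `truth_genes` (per-gene circadian status, modification acrophase, mRNA
#'   acrophase, lag).
#' @export
simulate_expression <- function(sim, expr_zt = NULL) {
  stopifnot(inherits(sim, "osc_sim"))
  cfg <- sim$config
  if (is.null(expr_zt)) expr_zt <- cfg$zt_grid
  set.seed(cfg$seed + 1L)
  ug <- unique(sim$truth$gene)
  truth_genes <- do.call(rbind, lapply(ug, function(g) {
    tr <- sim$truth[sim$truth$gene == g, ]
    osc <- tr$is_oscillating
    if (any(osc)) {
      mod_phi <- circular_mean_hours(tr$acrophase[osc])
      mrna_phi <- (mod_phi + 12 - cfg$mrna_lag_hours) %% 24
      data.frame(gene_id = g, is_circadian = TRUE, mod_acrophase = mod_phi,
                 mrna_acrophase = mrna_phi, lag_hours = cfg$mrna_lag_hours)
    } else {
      data.frame(gene_id = g, is_circadian = FALSE, mod_acrophase = NA_real_,
                 mrna_acrophase = NA_real_, lag_hours = NA_real_)
    }
  }))
  expr <- t(vapply(seq_len(nrow(truth_genes)), function(i) {
    tg <- truth_genes[i, ]
    base <- rep(cfg$expr_base, length(expr_zt))
    if (tg$is_circadian)
      base <- base + (cfg$expr_amp / 2) *
        cos(2 * pi * (expr_zt - tg$mrna_acrophase) / 24)
    base + stats::rnorm(length(expr_zt), 0, cfg$expr_noise_sd)
  }, numeric(length(expr_zt))))
  rownames(expr) <- truth_genes$gene_id
  colnames(expr) <- paste0("ZT", expr_zt)
  list(expr = expr, zt = expr_zt, truth_genes = truth_genes)
}
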