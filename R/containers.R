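#' Construct a count matrix of methylated/unmethylated reads
#'
#' Bundles per-site, per-sample read counts from targeted bisulfite (or
#' oxidative bisulfite) sequencing together with site coordinates and sample
#' metadata. `M` holds methylated (cytosine) read counts, `U` unmethylated
#' (thymine) read counts; coverage at a cell is `M + U`.
#'
#' @param M integer matrix, sites x samples; methylated read counts.
#' @param U integer matrix, same dimensions; unmethylated read counts.
#' @param sites data.frame with columns `site_id`, `chrom`, `pos` (0-based),
#'   `strand`, and optionally `gene`. Row order must match `rownames(M)`.
#' @param samples data.frame with columns `sample_id`, `biological_id`,
#'   `replicate_index`, `tissue`, `age_months`, `zt`, `assay`. Row order must
#'   match `colnames(M)`.
#' @return An object of class `mod_counts`.
#' @export
mod_counts <- function(M, U, sites, samples) {
  M <- as.matrix(M)
  U <- as.matrix(U)
  obj <- structure(list(M = M, U = U, sites = sites, samples = samples),
                   class = "mod_counts")
  validate_mod_counts(obj)
}

validate_mod_counts <- function(x) {
  stopifnot(is.matrix(x$M), is.matrix(x$U))
  if (!identical(dim(x$M), dim(x$U)))
    stop("M and U matrices must have identical dimensions")
  if (anyNA(x$M) || anyNA(x$U))
    stop("count matrices must not contain missing values")
  if (any(x$M < 0) || any(x$U < 0))
    stop("read counts must be nonnegative")
  if (any(x$M != round(x$M)) || any(x$U != round(x$U)))
    stop("read counts must be integers")
  x$sites <- validate_sites(x$sites)
  x$samples <- validate_samples(x$samples)
  if (nrow(x$sites) != nrow(x$M))
    stop("site table has ", nrow(x$sites), " rows but count matrix has ",
         nrow(x$M))
  if (nrow(x$samples) != ncol(x$M))
    stop("sample table has ", nrow(x$samples), " rows but count matrix has ",
         ncol(x$M), " columns")
  rownames(x$M) <- rownames(x$U) <- x$sites$site_id
  colnames(x$M) <- colnames(x$U) <- x$samples$sample_id
  x
}

validate_sites <- function(sites) {
  sites <- as.data.frame(sites)
  need <- c("site_id", "chrom", "pos", "strand")
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("site table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id in site table: ",
         paste(unique(sites$site_id[duplicated(sites$site_id)]), collapse = ", "))
  if (any(sites$pos < 0)) stop("site positions must be >= 0")
  if (!all(sites$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  sites
}

validate_samples <- function(samples) {
  samples <- as.data.frame(samples)
  need <- c("sample_id", "biological_id", "replicate_index", "tissue",
            "age_months", "zt", "assay")
  miss <- setdiff(need, names(samples))
  if (length(miss))
    stop("sample table missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  key <- paste(samples$biological_id, samples$replicate_index, samples$assay)
  if (anyDuplicated(key))
    stop("(biological_id, replicate_index, assay) must uniquely identify a sample")
  if (any(samples$zt < 0 | samples$zt >= 24))
    stop("zt must lie in [0, 24)")
  if (any(samples$age_months <= 0))
    stop("age_months must be positive")
  if (!all(samples$assay %in% c("BS", "oxBS")))
    stop("assay must be 'BS' or 'oxBS'")
  if (any(samples$replicate_index < 1))
    stop("replicate_index must be >= 1")
  samples
}

#' @export
print.mod_counts <- function(x, ...) {
  cat("mod_counts: ", nrow(x$M), " sites x ", ncol(x$M), " samples\n", sep = "")
  cat("  assays: ", paste(unique(x$samples$assay), collapse = ", "),
      "; tissues: ", paste(unique(x$samples$tissue), collapse = ", "), "\n", sep = "")
  cat("  mean coverage: ", round(mean(x$M + x$U), 1), "\n", sep = "")
  invisible(x)
}

#' Construct a beta-value (modification density) matrix
#'
#' Holds per-site, per-sample modification densities with the metadata needed
#' downstream. The modality tag records what the densities measure: `modC`
#' (total modification, BS assay), `mC` (true 5-methylcytosine, oxBS assay) or
#' `hmC` (5-hydroxymethylcytosine, BS - oxBS difference, which may be
#' negative).
#'
#' @param beta numeric matrix, sites x samples. Values in `[0,1]` for
#'   `modC`/`mC`, `[-1,1]` for `hmC`. `NA` marks missing cells.
#' @param sites,samples see [mod_counts()].
#' @param modality one of `"modC"`, `"mC"`, `"hmC"`.
#' @return An object of class `mod_beta`.
#' @export
mod_beta <- function(beta, sites, samples, modality = c("modC", "mC", "hmC")) {
  modality <- match.arg(modality)
  beta <- as.matrix(beta)
  obj <- structure(list(beta = beta, sites = sites, samples = samples,
                        modality = modality,
                        value_range = if (modality == "hmC") c(-1, 1) else c(0, 1)),
                   class = "mod_beta")
  validate_mod_beta(obj)
}

validate_mod_beta <- function(x) {
  stopifnot(is.matrix(x$beta))
  x$sites <- validate_sites(x$sites)
  x$samples <- validate_samples(x$samples)
  if (nrow(x$sites) != nrow(x$beta) || nrow(x$samples) != ncol(x$beta))
    stop("beta matrix dimensions do not match site/sample tables")
  v <- x$beta[!is.na(x$beta)]
  if (length(v) && (any(v < x$value_range[1]) || any(v > x$value_range[2])))
    stop("beta values outside ", x$modality, " range [",
         x$value_range[1], ", ", x$value_range[2], "]")
  rownames(x$beta) <- x$sites$site_id
  colnames(x$beta) <- x$samples$sample_id
  x
}

#' @export
print.mod_beta <- function(x, ...) {
  cat("mod_beta (", x$modality, "): ", nrow(x$beta), " sites x ",
      ncol(x$beta), " samples\n", sep = "")
  cat("  missing cells: ", sum(is.na(x$beta)), "\n", sep = "")
  invisible(x)
}

#' Subset a count or beta object by sites and/or samples
#'
#' @param x a `mod_counts` or `mod_beta` object.
#' @param sites character vector of site_ids or logical/integer index.
#' @param samples character vector of sample_ids or logical/integer index.
#' @return An object of the same class restricted to the selection.
#' @export
subset_mod <- function(x, sites = NULL, samples = NULL) {
  ri <- seq_len(nrow(x$sites))
  ci <- seq_len(nrow(x$samples))
  if (!is.null(sites)) {
    ri <- if (is.character(sites)) match(sites, x$sites$site_id) else ri[sites]
    if (anyNA(ri)) stop("unknown site_id in subset")
  }
  if (!is.null(samples)) {
    ci <- if (is.character(samples)) match(samples, x$samples$sample_id) else ci[samples]
    if (anyNA(ci)) stop("unknown sample_id in subset")
  }
  if (inherits(x, "mod_counts")) {
    mod_counts(x$M[ri, ci, drop = FALSE], x$U[ri, ci, drop = FALSE],
               x$sites[ri, , drop = FALSE], x$samples[ci, , drop = FALSE])
  } else {
    mod_beta(x$beta[ri, ci, drop = FALSE], x$sites[ri, , drop = FALSE],
             x$samples[ci, , drop = FALSE], x$modality)
  }
}
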