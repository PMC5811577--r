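## Tabular I/O. All tables are TSV; output files carry a commented header line
## recording the tool version and parameters so results remain traceable.

output_header <- function(params = list()) {
  ver <- as.character(utils::packageVersion("oscmod"))
  extra <- if (length(params))
    paste0(" | ", paste(names(params), unlist(params), sep = "=", collapse = " "))
  else ""
  paste0("# oscmod v", ver, extra)
}

read_tsv_checked <- function(path, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  out <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed TSV in ", what, " file '", path, "': ",
                             conditionMessage(e)))
  out
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `biological_id`,
#'   `replicate_index`, `tissue`, `age_months`, `zt`, `assay` (and optionally
#'   `collection_hour`, the absolute hour since first sampling; `zt` is the
#'   collection hour modulo 24).
#' @return A validated data.frame.
#' @export
read_sample_meta <- function(path) {
  validate_samples(read_tsv_checked(path, "sample metadata"))
}

#' Read site coordinates from BED
#'
#' Standard 0-based half-open BED with columns chrom, start, end, name,
#' score, strand. Single-base CpG sites have `end = start + 1`; `pos` is the
#' 0-based start.
#'
#' @param path BED file path.
#' @return data.frame with columns `site_id`, `chrom`, `pos`, `strand`.
#' @export
read_sites_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(bed) < 6)
    stop("sites BED must have 6 columns (chrom, start, end, name, score, strand)")
  validate_sites(data.frame(site_id = bed[[4]], chrom = bed[[1]],
                            pos = as.integer(bed[[2]]), strand = bed[[6]],
                            stringsAsFactors = FALSE))
}

#' Write site coordinates as BED
#'
#' @param sites site table as in [mod_counts()].
#' @param path output path.
#' @export
write_sites_bed <- function(sites, path) {
  sites <- validate_sites(sites)
  bed <- data.frame(sites$chrom, sites$pos, sites$pos + 1L, sites$site_id,
                    ".", sites$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a read-count table with its metadata
#'
#' Accepts the long dialect (columns `site_id`, `sample_id`, `M`, `U`) or the
#' wide dialect (`site_id` plus paired columns `<sample>_M` / `<sample>_U`).
#' Every sample column must have a metadata row and every site a coordinate
#' row; unknown samples or sites are an error, never silently dropped.
#'
#' @param path counts TSV path.
#' @param meta_path sample metadata TSV path (see [read_sample_meta()]).
#' @param sites_path site BED path (see [read_sites_bed()]).
#' @return A [mod_counts()] object.
#' @export
read_counts <- function(path, meta_path, sites_path) {
  samples <- read_sample_meta(meta_path)
  sites <- read_sites_bed(sites_path)
  tab <- read_tsv_checked(path, "counts")
  long <- all(c("site_id", "sample_id", "M", "U") %in% names(tab))
  if (long) {
    tab$M <- check_count_col(tab$M, path, "M")
    tab$U <- check_count_col(tab$U, path, "U")
    site_ids <- unique(tab$site_id)
    sample_ids <- unique(tab$sample_id)
    check_known(sample_ids, samples$sample_id, "sample")
    check_known(site_ids, sites$site_id, "site")
    site_ids <- sites$site_id[sites$site_id %in% site_ids]
    sample_ids <- samples$sample_id[samples$sample_id %in% sample_ids]
    M <- U <- matrix(0L, length(site_ids), length(sample_ids),
                     dimnames = list(site_ids, sample_ids))
    idx <- cbind(match(tab$site_id, site_ids), match(tab$sample_id, sample_ids))
    if (anyDuplicated(idx))
      stop("duplicate (site_id, sample_id) entry in ", path)
    M[idx] <- tab$M
    U[idx] <- tab$U
  } else {
    if (!"site_id" %in% names(tab))
      stop("counts TSV must contain a 'site_id' column")
    if (anyDuplicated(tab$site_id))
      stop("duplicate site_id in counts table")
    mcols <- grep("_M$", names(tab), value = TRUE)
    ucols <- grep("_U$", names(tab), value = TRUE)
    sample_ids <- sub("_M$", "", mcols)
    if (!setequal(sample_ids, sub("_U$", "", ucols)))
      stop("wide counts TSV: every sample needs paired <sample>_M and <sample>_U columns")
    check_known(sample_ids, samples$sample_id, "sample")
    check_known(tab$site_id, sites$site_id, "site")
    sample_ids <- samples$sample_id[samples$sample_id %in% sample_ids]
    M <- sapply(paste0(sample_ids, "_M"),
                function(cn) check_count_col(tab[[cn]], path, cn))
    U <- sapply(paste0(sample_ids, "_U"),
                function(cn) check_count_col(tab[[cn]], path, cn))
    M <- matrix(M, nrow(tab), dimnames = list(tab$site_id, sample_ids))
    U <- matrix(U, nrow(tab), dimnames = list(tab$site_id, sample_ids))
  }
  keep_sites <- sites$site_id %in% rownames(M)
  keep_samp <- samples$sample_id %in% colnames(M)
  sites <- sites[keep_sites, , drop = FALSE]
  samples <- samples[keep_samp, , drop = FALSE]
  mod_counts(M[sites$site_id, samples$sample_id, drop = FALSE],
             U[sites$site_id, samples$sample_id, drop = FALSE],
             sites, samples)
}

check_count_col <- function(x, path, name) {
  x <- suppressWarnings(as.numeric(x))
  if (anyNA(x))
    stop("non-numeric value in column ", name, " of ", path)
  if (any(x < 0))
    stop("negative count in column ", name, " of ", path)
  if (any(x != round(x)))
    stop("non-integer count in column ", name, " of ", path)
  as.integer(x)
}

check_known <- function(found, known, what) {
  unknown <- setdiff(found, known)
  if (length(unknown))
    stop("unknown ", what, "(s) in counts table: ",
         paste(utils::head(unknown, 5), collapse = ", "),
         if (length(unknown) > 5) " ...")
  invisible(TRUE)
}

#' Write a count object as long-format TSV (plus metadata and BED)
#'
#' @param counts a [mod_counts()] object.
#' @param path output counts TSV.
#' @param meta_path optional output path for the sample metadata TSV.
#' @param sites_path optional output path for the site BED.
#' @param params named list recorded in the commented header line.
#' @export
write_counts <- function(counts, path, meta_path = NULL, sites_path = NULL,
                         params = list()) {
  long <- data.frame(
    site_id = rep(rownames(counts$M), times = ncol(counts$M)),
    sample_id = rep(colnames(counts$M), each = nrow(counts$M)),
    M = as.vector(counts$M), U = as.vector(counts$U))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params), con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    write_table_commented(counts$samples, meta_path, params)
  if (!is.null(sites_path))
    write_sites_bed(counts$sites, sites_path)
  invisible(path)
}

write_table_commented <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a beta matrix as TSV (sites x samples)
#'
#' @param beta a [mod_beta()] object.
#' @param path output path.
#' @param params named list recorded in the commented header line.
#' @export
write_beta <- function(beta, path, params = list()) {
  df <- data.frame(site_id = rownames(beta$beta), beta$beta,
                   check.names = FALSE)
  write_table_commented(df, path, c(list(modality = beta$modality), params))
}
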