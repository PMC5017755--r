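# GWAS summary-statistics input. Files are delimited text (tab or
# whitespace), optionally gzipped. Only four columns are interpreted --
# SNP id, chromosome, 1-based position, association p-value -- located via a
# configurable mapping; every other column is passed through untouched.

#' Column mapping for a GWAS summary file
#'
#' @param snp,chr,pos,p Column names (character) or 1-based column indices
#'   (numeric) of the SNP id, chromosome, position and p-value columns.
#' @return A list of class `gwas_columns`.
#' @export
gwas_columns <- function(snp = "SNP", chr = "CHR", pos = "POS", p = "P") {
  structure(list(snp = snp, chr = chr, pos = pos, p = p),
            class = "gwas_columns")
}

.resolve_col <- function(spec, nms, what) {
  if (is.numeric(spec)) {
    i <- as.integer(spec)
    if (i < 1L || i > length(nms)) stop("column index out of range for ", what)
    return(nms[i])
  }
  if (!spec %in% nms) {
    stop(sprintf("column '%s' (%s) not found; available: %s",
                 spec, what, paste(nms, collapse = ", ")))
  }
  spec
}

#' Read a GWAS summary-statistics file
#'
#' Reads the file with all original columns preserved and attaches
#' standardized working columns `.snp_id`, `.chromosome` (normalised, no
#' `"chr"` prefix), `.position` and `.p_value`. P-values of exactly zero are
#' clamped to the smallest positive double with a warning; rows whose
#' p-value or position cannot be parsed keep `NA` there and are skipped
#' (and counted) during scanning.
#'
#' @param path Delimited text file, `.gz` allowed.
#' @param columns A [gwas_columns()] mapping.
#' @return A `data.frame` of summary statistics.
#' @export
read_gwas <- function(path, columns = gwas_columns()) {
  if (!file.exists(path)) stop("GWAS summary file not found: ", path)
  d <- as.data.frame(data.table::fread(path, header = TRUE,
                                       showProgress = FALSE))
  if (nrow(d) == 0L) stop("GWAS summary file is empty: ", path)
  nms <- names(d)
  cs <- lapply(list(snp = columns$snp, chr = columns$chr,
                    pos = columns$pos, p = columns$p),
               .resolve_col, nms = nms, what = "summary column")
  as_gwas(d, snp = cs$snp, chr = cs$chr, pos = cs$pos, p = cs$p)
}

#' Standardize an in-memory GWAS summary table
#'
#' Same contract as [read_gwas()] for a `data.frame` already in memory.
#'
#' @param d A `data.frame` of summary statistics.
#' @param snp,chr,pos,p Names of the four interpreted columns in `d`.
#' @return `d` with working columns `.snp_id`, `.chromosome`, `.position`,
#'   `.p_value` appended.
#' @export
as_gwas <- function(d, snp = "SNP", chr = "CHR", pos = "POS", p = "P") {
  stopifnot(is.data.frame(d), all(c(snp, chr, pos, p) %in% names(d)))
  pv <- suppressWarnings(as.numeric(d[[p]]))
  n_zero <- sum(pv == 0, na.rm = TRUE)
  if (n_zero > 0L) {
    warning(sprintf(
      "as_gwas: %d p-value(s) of exactly 0 clamped to %g", n_zero,
      .Machine$double.xmin))
    pv[!is.na(pv) & pv == 0] <- .Machine$double.xmin
  }
  d$.snp_id <- as.character(d[[snp]])
  d$.chromosome <- norm_chrom(d[[chr]])
  d$.position <- suppressWarnings(as.integer(d[[pos]]))
  d$.p_value <- pv
  attr(d, "gwas_columns") <- c(snp = snp, chr = chr, pos = pos, p = p)
  d
}

# Minimum p-value per region (Inf where a region holds no valid SNP).
# Shared fast path for scanning, background-rate estimation and the
# resampling null: per chromosome the valid SNPs are sorted by position once
# and each region is reduced with two binary searches.
.region_min_p <- function(gwas, regions) {
  valid <- !is.na(gwas$.p_value) & !is.na(gwas$.position) &
    gwas$.p_value > 0 & gwas$.p_value <= 1
  g <- gwas[valid, c(".chromosome", ".position", ".p_value")]
  out <- rep(Inf, nrow(regions))
  for (ch in unique(regions$chromosome)) {
    sub <- g[g$.chromosome == ch, ]
    if (nrow(sub) == 0L) next
    ord <- order(sub$.position)
    pos <- sub$.position[ord]
    pv <- sub$.p_value[ord]
    ridx <- which(regions$chromosome == ch)
    # 1-based position q is inside a 0-based half-open region [s, e) iff
    # s < q <= e
    lo <- findInterval(regions$region_start[ridx], pos) + 1L
    hi <- findInterval(regions$region_end[ridx], pos)
    for (k in seq_along(ridx)) {
      if (lo[k] <= hi[k]) out[ridx[k]] <- min(pv[lo[k]:hi[k]])
    }
  }
  out
}
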