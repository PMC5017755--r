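# Independent-SNP store: MAF filtering and windowed pairwise-r2 greedy
# pruning of reference genotype panels, plus interval counting of retained
# SNPs. Retained positions are 1-based; region queries use half-open
# [start_bp, end_bp) intervals.

#' Pruning configuration
#'
#' Parameters of the windowed LD-pruning pass, mirroring the conventional
#' plink-style `--indep-pairwise <window> <step> <r2>` plus `--maf` setup.
#' Windows are counted in SNPs, not base pairs.
#'
#' @param window_size Window width in SNPs (default 50).
#' @param step Window advance in SNPs (default 5).
#' @param r2_threshold Pairwise squared-correlation limit above which one SNP
#'   of a pair is removed (default 0.2).
#' @param maf_min Minimum minor allele frequency; SNPs below it are removed
#'   before pruning (default 0.01).
#' @return A list of class `pruning_config`.
#' @export
pruning_config <- function(window_size = 50L, step = 5L,
                           r2_threshold = 0.2, maf_min = 0.01) {
  window_size <- as.integer(window_size); step <- as.integer(step)
  stopifnot(window_size >= 1L, step >= 1L, step <= window_size,
            r2_threshold >= 0, r2_threshold <= 1,
            maf_min >= 0, maf_min <= 0.5)
  structure(list(window_size = window_size, step = step,
                 r2_threshold = r2_threshold, maf_min = maf_min),
            class = "pruning_config")
}

#' Construct a genotype panel
#'
#' One reference panel for one chromosome: allele-dosage matrix (samples in
#' rows, SNPs in columns, entries 0/1/2 or `NA` for missing) with strictly
#' increasing 1-based SNP positions.
#'
#' @param ancestry Panel label, e.g. `"EUR"`.
#' @param chromosome Chromosome name (stored without a `"chr"` prefix).
#' @param positions Strictly increasing integer positions (1-based).
#' @param snp_ids Character vector of SNP identifiers, one per position.
#' @param dosages Numeric matrix, `length(positions)` columns.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(ancestry, chromosome, positions, snp_ids, dosages) {
  positions <- as.integer(positions)
  stopifnot(is.matrix(dosages),
            ncol(dosages) == length(positions),
            length(snp_ids) == length(positions),
            all(diff(positions) > 0L))
  vals <- dosages[!is.na(dosages)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  structure(list(ancestry = as.character(ancestry),
                 chromosome = norm_chrom(chromosome),
                 positions = positions,
                 snp_ids = as.character(snp_ids),
                 dosages = dosages),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %s chr%s, %d SNPs x %d samples\n",
              x$ancestry, x$chromosome, length(x$positions), nrow(x$dosages)))
  invisible(x)
}

#' Minor allele frequency of a dosage vector
#'
#' `MAF = min(f, 1 - f)` with `f = sum(dosages) / (2 * n)` over non-missing
#' entries.
#'
#' @param dosage_column Vector of allele counts in `{0, 1, 2, NA}`.
#' @return MAF in `[0, 0.5]`.
#' @export
allele_frequency <- function(dosage_column) {
  x <- dosage_column[!is.na(dosage_column)]
  if (length(x) == 0L) stop("allele_frequency: all genotypes missing")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Pairwise squared correlation of two dosage vectors
#'
#' Squared Pearson correlation over the pairwise-complete subset. Returns 0
#' when either vector is constant on that subset or fewer than two complete
#' pairs exist (no evidence of linkage).
#'
#' @param col_a,col_b Dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
dosage_r2 <- function(col_a, col_b) {
  if (length(col_a) != length(col_b)) stop("dosage_r2: length mismatch")
  ok <- !is.na(col_a) & !is.na(col_b)
  if (sum(ok) < 2L) return(0)
  a <- col_a[ok]; b <- col_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)^2
}

# Window r2 matrix with the same semantics as dosage_r2 (pairwise complete,
# constant/degenerate pairs -> 0).
.window_r2 <- function(mat) {
  r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  r[is.na(r)] <- 0
  r * r
}

#' LD-prune one chromosome of a genotype panel
#'
#' Greedy windowed pruning: SNPs with MAF below `maf_min` are removed first;
#' a window of `window_size` SNPs then slides along the remaining SNPs in
#' steps of `step` SNPs. Within each window, while any retained pair exceeds
#' `r2_threshold`, the pair with the highest r-squared is found and its
#' lower-MAF member removed (on a MAF tie, the member at the later position).
#' A SNP removed in any window stays removed. In the final set no pair of
#' SNPs that ever shared a window exceeds the threshold.
#'
#' @param panel A [genotype_panel()].
#' @param config A [pruning_config()].
#' @return Strictly increasing integer indices (into `panel$positions`) of
#'   the retained SNPs.
#' @export
prune_chromosome <- function(panel, config = pruning_config()) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(config, "pruning_config"))
  p <- ncol(panel$dosages)
  maf <- vapply(seq_len(p), function(j) {
    col <- panel$dosages[, j]
    if (all(is.na(col))) return(0)
    allele_frequency(col)
  }, numeric(1))

  keep <- which(maf >= config$maf_min)
  if (length(keep) == 0L) {
    warning("prune_chromosome: no SNPs pass the MAF filter")
    return(integer(0))
  }

  removed <- rep(FALSE, length(keep))
  nk <- length(keep)
  starts <- seq.int(1L, nk, by = config$step)
  for (ws in starts) {
    we <- min(ws + config$window_size - 1L, nk)
    if (we - ws < 1L) next
    win <- ws:we
    active <- win[!removed[win]]
    if (length(active) < 2L) next
    r2 <- .window_r2(panel$dosages[, keep[active], drop = FALSE])
    diag(r2) <- 0
    repeat {
      m <- which.max(r2)
      if (r2[m] <= config$r2_threshold) break
      ij <- arrayInd(m, dim(r2))
      i <- ij[1L]; j <- ij[2L]
      gi <- active[i]; gj <- active[j]
      # drop the lower-MAF member; on a tie, the later-positioned one
      drop_local <- if (maf[keep[gi]] < maf[keep[gj]]) i
                    else if (maf[keep[gj]] < maf[keep[gi]]) j
                    else max(i, j)
      removed[active[drop_local]] <- TRUE
      r2[drop_local, ] <- 0
      r2[, drop_local] <- 0
    }
  }
  keep[!removed]
}

#' Construct an independent-SNP store
#'
#' Holds the retained (post-pruning) SNP positions partitioned by ancestry
#' panel and chromosome, and answers interval-count queries.
#'
#' @param snps `data.frame` with columns `ancestry`, `chromosome`,
#'   `position` (1-based), `snp_id`. May have zero rows.
#' @param config Optional [pruning_config()] recorded for provenance.
#' @return An object of class `snp_store`.
#' @export
snp_store <- function(snps, config = NULL) {
  need <- c("ancestry", "chromosome", "position", "snp_id")
  stopifnot(is.data.frame(snps), all(need %in% names(snps)))
  snps$chromosome <- norm_chrom(snps$chromosome)
  snps <- snps[order(snps$ancestry, snps$chromosome, snps$position), ,
               drop = FALSE]
  rownames(snps) <- NULL
  index <- list()
  if (nrow(snps) > 0L) {
    for (anc in unique(snps$ancestry)) {
      sub <- snps[snps$ancestry == anc, , drop = FALSE]
      index[[anc]] <- lapply(split(sub$position, sub$chromosome), function(ps) {
        if (any(duplicated(ps))) stop("duplicate retained positions in store")
        sort(as.integer(ps))
      })
    }
  }
  structure(list(snps = snps, index = index, config = config),
            class = "snp_store")
}

#' @export
print.snp_store <- function(x, ...) {
  cat(sprintf("snp_store: %d independent SNPs, panels: %s\n",
              nrow(x$snps),
              if (length(x$index)) paste(names(x$index), collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Build the independent-SNP store from genotype panels
#'
#' Runs [prune_chromosome()] on each panel and assembles the retained SNPs
#' into an [snp_store()], optionally persisting it.
#'
#' @param panels A [genotype_panel()] or a list of them (one per chromosome
#'   and ancestry).
#' @param config A [pruning_config()].
#' @param destination Optional path for [write_snp_store()].
#' @return An `snp_store`.
#' @export
build_snp_store <- function(panels, config = pruning_config(),
                            destination = NULL) {
  if (inherits(panels, "genotype_panel")) panels <- list(panels)
  parts <- lapply(panels, function(pan) {
    idx <- prune_chromosome(pan, config)
    data.frame(ancestry = pan$ancestry,
               chromosome = pan$chromosome,
               position = pan$positions[idx],
               snp_id = pan$snp_ids[idx],
               stringsAsFactors = FALSE)
  })
  store <- snp_store(do.call(rbind, parts), config = config)
  if (!is.null(destination)) write_snp_store(store, destination)
  store
}

#' Count independent SNPs in a genomic interval
#'
#' Counts retained positions `q` with `start_bp <= q < end_bp` (1-based,
#' half-open) on one chromosome of one ancestry panel. An empty or absent
#' chromosome yields 0; an unknown ancestry is an error.
#'
#' @param store An [snp_store()].
#' @param ancestry Panel label.
#' @param chromosome Chromosome name (with or without `"chr"` prefix).
#' @param start_bp,end_bp Query interval, `start_bp <= end_bp`.
#' @return Integer count.
#' @export
count_independent <- function(store, ancestry, chromosome, start_bp, end_bp) {
  stopifnot(inherits(store, "snp_store"), start_bp <= end_bp)
  if (!ancestry %in% names(store$index)) {
    stop(sprintf("unknown ancestry '%s'; available: %s", ancestry,
                 paste(names(store$index), collapse = ", ")))
  }
  ps <- store$index[[ancestry]][[norm_chrom(chromosome)]]
  if (is.null(ps) || length(ps) == 0L) return(0L)
  # positions in [start_bp, end_bp)
  as.integer(findInterval(end_bp - 1, ps) - findInterval(start_bp - 1, ps))
}

#' Persist an independent-SNP store
#'
#' Flat tab-separated table (ancestry, chromosome, position, snp_id) with a
#' commented header recording the pruning parameters and the coordinate
#' convention.
#'
#' @param store An [snp_store()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_snp_store <- function(store, path) {
  stopifnot(inherits(store, "snp_store"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("# gentos snp store v1",
           "# positions are 1-based; interval queries are half-open [start, end)")
  if (!is.null(store$config)) {
    hdr <- c(hdr, sprintf("# pruning: window=%d step=%d r2=%g maf=%g",
                          store$config$window_size, store$config$step,
                          store$config$r2_threshold, store$config$maf_min))
  }
  writeLines(hdr, con)
  utils::write.table(store$snps, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an independent-SNP store
#'
#' @param path Path written by [write_snp_store()].
#' @return An `snp_store`.
#' @export
read_snp_store <- function(path) {
  if (!file.exists(path)) stop("snp store not found: ", path)
  snps <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE,
                            colClasses = c(position = "integer"))
  snp_store(snps)
}

#' Read a genotype panel from VCF
#'
#' Reads a VCF (plain or gzipped) with GT genotypes, keeps biallelic SNPs
#' (single-base REF and ALT), converts genotypes to allele dosages, and
#' returns one [genotype_panel()] per chromosome.
#'
#' @param path VCF file path.
#' @param ancestry Label to attach to the panels.
#' @return A list of `genotype_panel`, named by chromosome.
#' @export
read_vcf_panel <- function(path, ancestry) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  biallelic <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    !grepl(",", fix[, "ALT"], fixed = TRUE)
  if (!all(biallelic)) {
    message(sprintf("read_vcf_panel: dropped %d non-biallelic-SNP record(s)",
                    sum(!biallelic)))
  }
  gt <- vcfR::extract.gt(vcf)[biallelic, , drop = FALSE]
  alleles <- gsub("[|/]", "", gt)
  dos <- nchar(gsub("[^1]", "", alleles))
  dos[!alleles %in% c("00", "01", "10", "11")] <- NA_integer_
  dos <- matrix(as.integer(dos), nrow = nrow(gt),
                dimnames = dimnames(gt))
  chrom <- norm_chrom(fix[biallelic, "CHROM"])
  pos <- as.integer(fix[biallelic, "POS"])
  ids <- fix[biallelic, "ID"]
  out <- lapply(unique(chrom), function(ch) {
    sel <- which(chrom == ch)
    sel <- sel[order(pos[sel])]
    if (any(duplicated(pos[sel]))) stop("duplicate positions on chr", ch)
    genotype_panel(ancestry, ch, pos[sel], ids[sel],
                   t(dos[sel, , drop = FALSE]))
  })
  names(out) <- unique(chrom)
  out
}

#' Read a genotype panel from a dosage matrix file
#'
#' Tab-separated text: rows are samples, columns are SNPs, header cells are
#' `id:pos`. Missing genotypes are empty cells or `NA`.
#'
#' @param path File path.
#' @param ancestry Panel label.
#' @param chromosome Chromosome the file covers.
#' @return A `genotype_panel`.
#' @export
read_dosage_panel <- function(path, ancestry, chromosome) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- names(d)
  parts <- strsplit(hdr, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("dosage header cells must be 'id:pos'")
  ids <- vapply(parts, `[[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ord <- order(pos)
  genotype_panel(ancestry, chromosome, pos[ord], ids[ord],
                 as.matrix(d)[, ord, drop = FALSE])
}
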