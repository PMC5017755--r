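# The three-step candidate-gene prioritization core: resolve the candidate
# list against the gene store, flank gene spans into regions, derive the
# significance threshold from independent-SNP counts, and extract
# sub-threshold SNP associations from the summary file.

#' Resolve a candidate gene list against the gene store
#'
#' Duplicate symbols are collapsed (with a warning), symbols absent from the
#' store are filtered as `unmapped`, and genes on the sex chromosomes are
#' filtered as `gonosomal` when `exclude_gonosomes` is set (autosomal GWAS
#' summary files carry no X/Y statistics). Resolution order is
#' first-occurrence order of the input.
#'
#' @param symbols Character vector of gene symbols.
#' @param store A [gene_store()].
#' @param exclude_gonosomes Drop X/Y genes (default `TRUE`).
#' @param name Label for the list.
#' @return An object of class `candidate_list` with elements `name`,
#'   `requested_symbols`, `genes` (resolved gene models), `filtered`
#'   (symbol + reason), `n` (number resolved).
#' @export
resolve_candidates <- function(symbols, store, exclude_gonosomes = TRUE,
                               name = "candidates") {
  stopifnot(length(symbols) > 0L, inherits(store, "gene_store"))
  symbols <- as.character(symbols)
  dup <- duplicated(symbols)
  if (any(dup)) {
    warning(sprintf("resolve_candidates: collapsed %d duplicate symbol(s)",
                    sum(dup)))
  }
  uniq <- symbols[!dup]

  hit <- gene_lookup(store, uniq)
  filtered <- data.frame(gene_symbol = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  unmapped <- is.na(hit$start)
  if (any(unmapped)) {
    filtered <- rbind(filtered, data.frame(gene_symbol = uniq[unmapped],
                                           reason = "unmapped"))
  }
  keep <- !unmapped
  if (exclude_gonosomes) {
    gono <- keep & is_gonosome(hit$chromosome)
    if (any(gono)) {
      filtered <- rbind(filtered, data.frame(gene_symbol = uniq[gono],
                                             reason = "gonosomal"))
    }
    keep <- keep & !gono
  }
  genes <- hit[keep, , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) == 0L) {
    stop("resolve_candidates: no candidate genes left after filtering")
  }
  if (nrow(filtered) > 0L) {
    message(sprintf("resolve_candidates: filtered %d of %d symbol(s) (%s)",
                    nrow(filtered), length(uniq),
                    paste(sprintf("%s: %d", names(table(filtered$reason)),
                                  table(filtered$reason)), collapse = ", ")))
  }
  structure(list(name = name, requested_symbols = symbols, genes = genes,
                 filtered = filtered, n = nrow(genes)),
            class = "candidate_list")
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("candidate_list '%s': %d requested, %d resolved, %d filtered\n",
              x$name, length(x$requested_symbols), x$n, nrow(x$filtered)))
  invisible(x)
}

#' Define flanked gene regions
#'
#' Adds a symmetric flanking window (default 10 kb) to each resolved gene
#' span so regions cover exons, introns and proximal regulatory sequence.
#' Starts are clipped at 0; overlapping regions are kept separate (no
#' merging).
#'
#' @param x A `candidate_list` or a gene-model `data.frame`.
#' @param flank_bp Flank width in base pairs, added both up- and downstream
#'   (default 10000).
#' @return A `data.frame` of regions: `gene_symbol`, `chromosome`,
#'   `region_start`, `region_end` (0-based half-open), `flank_bp`, `m_g`
#'   (independent-SNP count, `NA` until filled by [compute_threshold()]).
#' @export
define_regions <- function(x, flank_bp = 10000L) {
  genes <- if (inherits(x, "candidate_list")) x$genes else x
  stopifnot(is.data.frame(genes), nrow(genes) > 0L, flank_bp >= 0)
  flank_bp <- as.integer(flank_bp)
  data.frame(
    gene_symbol = genes$gene_symbol,
    chromosome = norm_chrom(genes$chromosome),
    region_start = pmax(0L, genes$start - flank_bp),
    region_end = genes$end + flank_bp,
    flank_bp = flank_bp,
    m_g = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# regions are 0-based half-open; the snp store is queried 1-based half-open
.fill_m_g <- function(regions, snp_store, ancestry) {
  regions$m_g <- vapply(seq_len(nrow(regions)), function(i) {
    count_independent(snp_store, ancestry, regions$chromosome[i],
                      regions$region_start[i] + 1L,
                      regions$region_end[i] + 1L)
  }, integer(1))
  regions
}

#' Derive the significance threshold for a set of gene regions
#'
#' Four methods are available:
#' \describe{
#'   \item{`"bonferroni"`}{(default) per-gene threshold `alpha / m_g`, where
#'     `m_g` is the number of independent SNPs in that gene's region. Genes
#'     with `m_g = 0` are excluded from scanning with a warning.}
#'   \item{`"bonferroni_listwise"`}{one threshold `alpha / M` with
#'     `M = sum(m_g)` over all regions (overlapping regions are summed as-is,
#'     which is conservative). Required by the enrichment test, which needs a
#'     single fixed threshold.}
#'   \item{`"fdr"`}{Benjamini-Hochberg at level `fdr_q` over the p-values of
#'     all SNPs inside the candidate regions (requires `gwas`); the threshold
#'     is set so that exactly the BH-passing SNPs fall below it.}
#'   \item{`"fixed"`}{a user-supplied threshold `fixed_value`.}
#' }
#'
#' @param regions Regions from [define_regions()].
#' @param snp_store An [snp_store()] (needed for the Bonferroni methods).
#' @param ancestry Reference panel label in `snp_store`.
#' @param method One of `"bonferroni"`, `"bonferroni_listwise"`, `"fdr"`,
#'   `"fixed"`.
#' @param alpha Family-wise type-I error probability (default 0.05).
#' @param fixed_value Threshold for `method = "fixed"`, in (0, 1].
#' @param fdr_q FDR level for `method = "fdr"`.
#' @param gwas Summary table (see [as_gwas()]) for `method = "fdr"`.
#' @return An object of class `significance_threshold` with elements
#'   `method`, `alpha`, `M`, `per_gene` (named vector, per-gene mode),
#'   `value` (single threshold, other modes) and `regions` (with `m_g`
#'   filled in).
#' @export
compute_threshold <- function(regions, snp_store = NULL, ancestry = NULL,
                              method = c("bonferroni", "bonferroni_listwise",
                                         "fdr", "fixed"),
                              alpha = 0.05, fixed_value = NULL,
                              fdr_q = NULL, gwas = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(regions), nrow(regions) > 0L,
            alpha > 0, alpha <= 1)

  per_gene <- NULL
  value <- NULL
  M <- NA_integer_

  if (method %in% c("bonferroni", "bonferroni_listwise")) {
    if (is.null(snp_store) || is.null(ancestry)) {
      stop("Bonferroni methods need an snp_store and an ancestry label")
    }
    regions <- .fill_m_g(regions, snp_store, ancestry)
    M <- sum(regions$m_g)
    if (method == "bonferroni_listwise") {
      if (M == 0L) stop("no independent SNPs in any candidate region (M = 0)")
      value <- alpha / M
    } else {
      if (any(regions$m_g == 0L)) {
        warning(sprintf(
          "compute_threshold: %d gene(s) with no independent SNPs excluded from scanning",
          sum(regions$m_g == 0L)))
      }
      per_gene <- ifelse(regions$m_g > 0L, alpha / regions$m_g, NA_real_)
      names(per_gene) <- regions$gene_symbol
    }
  } else if (method == "fixed") {
    if (is.null(fixed_value) || fixed_value <= 0 || fixed_value > 1) {
      stop("method = 'fixed' needs fixed_value in (0, 1]")
    }
    value <- fixed_value
  } else { # fdr
    if (is.null(fdr_q) || is.null(gwas)) {
      stop("method = 'fdr' needs fdr_q and a gwas summary table")
    }
    ps <- .region_snp_pvalues(gwas, regions)
    value <- .bh_threshold(ps, fdr_q)
  }

  structure(list(method = method, alpha = alpha, M = M,
                 per_gene = per_gene, value = value, regions = regions,
                 fdr_q = fdr_q),
            class = "significance_threshold")
}

#' @export
print.significance_threshold <- function(x, ...) {
  cat("significance_threshold:", x$method, "\n")
  if (!is.na(x$M)) cat("  independent SNPs (M):", x$M, "\n")
  if (!is.null(x$value)) cat("  threshold:", format(x$value), "\n")
  if (!is.null(x$per_gene)) {
    cat(sprintf("  per-gene thresholds for %d gene(s), median %s\n",
                length(x$per_gene),
                format(stats::median(x$per_gene, na.rm = TRUE))))
  }
  invisible(x)
}

# all valid SNP p-values falling in any region (duplicated per region, as
# scanning emits them)
.region_snp_pvalues <- function(gwas, regions) {
  valid <- !is.na(gwas$.p_value) & !is.na(gwas$.position) &
    gwas$.p_value > 0 & gwas$.p_value <= 1
  g <- gwas[valid, c(".chromosome", ".position", ".p_value")]
  ps <- numeric(0)
  for (i in seq_len(nrow(regions))) {
    sel <- g$.chromosome == regions$chromosome[i] &
      g$.position > regions$region_start[i] &
      g$.position <= regions$region_end[i]
    ps <- c(ps, g$.p_value[sel])
  }
  ps
}

# Benjamini-Hochberg cutoff as a strict-< threshold: the returned value
# admits exactly the BH-passing p-values under p < value. With no passing
# p-value the smallest positive double is returned, which no valid p can
# undercut.
.bh_threshold <- function(ps, q) {
  if (length(ps) == 0L) return(.Machine$double.xmin)
  sp <- sort(ps)
  m <- length(sp)
  pass <- which(sp <= seq_len(m) * q / m)
  if (length(pass) == 0L) return(.Machine$double.xmin)
  cutoff <- sp[max(pass)]
  cutoff * (1 + .Machine$double.eps)
}

#' Extract sub-threshold SNP associations from a GWAS summary table
#'
#' Scans the summary statistics for SNPs that fall inside a candidate gene
#' region and whose p-value is strictly below the applicable threshold. A
#' SNP inside several overlapping regions is emitted once per gene. Rows
#' with unparseable p-values or positions are skipped and counted.
#'
#' @param gwas Summary table from [read_gwas()] / [as_gwas()].
#' @param regions Regions from [define_regions()]; if `threshold` carries
#'   `m_g`-filled regions those take precedence.
#' @param threshold A [compute_threshold()] result.
#' @return A `data.frame` of class `hit_table`: all original summary columns
#'   of each hit plus `gene_symbol`, `region_start`, `region_end`,
#'   `applied_threshold`, sorted by chromosome, position, gene. Attributes:
#'   `significant_genes` (symbols with >= 1 hit), `x` (their number), `n`
#'   (genes scanned), `n_skipped` (unparseable rows).
#' @export
scan_gwas <- function(gwas, regions = NULL, threshold) {
  stopifnot(inherits(threshold, "significance_threshold"))
  if (is.null(regions)) regions <- threshold$regions
  if (is.null(regions) || nrow(regions) == 0L) stop("scan_gwas: no regions")
  if (is.null(gwas$.p_value)) stop("scan_gwas: gwas must come from read_gwas()/as_gwas()")

  valid <- !is.na(gwas$.p_value) & !is.na(gwas$.position) &
    gwas$.p_value > 0 & gwas$.p_value <= 1
  n_skipped <- sum(!valid)
  if (n_skipped > 0L) {
    message(sprintf("scan_gwas: skipped %d row(s) with unparseable p-value or position",
                    n_skipped))
  }
  g <- gwas[valid, , drop = FALSE]

  thr_for_gene <- function(i) {
    if (!is.null(threshold$per_gene)) {
      unname(threshold$per_gene[regions$gene_symbol[i]])
    } else {
      threshold$value
    }
  }

  pieces <- vector("list", nrow(regions))
  scanned <- 0L
  for (i in seq_len(nrow(regions))) {
    thr <- thr_for_gene(i)
    if (is.na(thr)) next  # per-gene mode, m_g = 0
    scanned <- scanned + 1L
    sel <- g$.chromosome == regions$chromosome[i] &
      g$.position > regions$region_start[i] &
      g$.position <= regions$region_end[i] &
      g$.p_value < thr
    if (!any(sel)) next
    part <- g[sel, , drop = FALSE]
    part$gene_symbol <- regions$gene_symbol[i]
    part$region_start <- regions$region_start[i]
    part$region_end <- regions$region_end[i]
    part$applied_threshold <- thr
    pieces[[i]] <- part
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  hits <- if (length(pieces)) do.call(rbind, pieces) else {
    cbind(g[0, , drop = FALSE],
          data.frame(gene_symbol = character(0), region_start = integer(0),
                     region_end = integer(0), applied_threshold = numeric(0)))
  }
  if (nrow(hits) > 0L) {
    hits <- hits[order(hits$.chromosome, hits$.position, hits$gene_symbol), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  sig <- unique(hits$gene_symbol)
  structure(hits,
            class = c("hit_table", "data.frame"),
            significant_genes = sig,
            x = length(sig),
            n = scanned,
            n_skipped = n_skipped)
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("hit_table: %d SNP-gene hit row(s) across %d significant gene(s) (of %d scanned)\n",
              nrow(x), attr(x, "x"), attr(x, "n")))
  if (nrow(x) > 0L) print.data.frame(utils::head(x, 10L))
  invisible(x)
}

#' Write a hit table to TSV
#'
#' Emits the original summary columns plus the gene-annotation columns; the
#' internal working columns (dot-prefixed) are dropped.
#'
#' @param hits A `hit_table` from [scan_gwas()].
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  d <- as.data.frame(hits)
  d <- d[, !startsWith(names(d), "."), drop = FALSE]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
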