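# Gene store: canonical gene spans derived from refFlat annotation.
# Coordinates follow the refFlat native convention throughout the store:
# 0-based start, half-open end. Conversion to 1-based SNP positions happens
# only where regions are matched against SNPs.

#' Parse refFlat gene annotation
#'
#' Reads UCSC refFlat-format annotation into a transcript table. refFlat is
#' tab-delimited with at least six columns in fixed order: gene symbol,
#' transcript id, chromosome, strand, transcription start, transcription end.
#' Coordinates are preserved as in the file (0-based start, half-open end).
#' Gzip-compressed files are handled transparently.
#'
#' Malformed lines (too few fields, non-integer or inverted coordinates,
#' invalid strand) are skipped; one warning summarises how many were dropped.
#'
#' @param x Path to a refFlat file, or a character vector of refFlat lines.
#' @return A `data.frame` with columns `gene_symbol`, `transcript_id`,
#'   `chromosome`, `strand`, `tx_start`, `tx_end`, one row per valid
#'   transcript. The number of skipped lines is attached as attribute
#'   `"n_skipped"`.
#' @seealso [select_canonical()], [build_gene_store()]
#' @export
#' @examples
#' tx <- parse_refflat(c(
#'   "GENE1\tNM_001\tchr1\t+\t100\t500\t100\t500\t1\t100,\t500,",
#'   "GENE1\tNM_002\tchr1\t+\t100\t900\t100\t900\t1\t100,\t900,"
#' ))
#' nrow(tx)
parse_refflat <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    readLines(if (grepl("\\.gz$", x)) gzfile(x) else x)
  } else {
    as.character(x)
  }
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty refFlat input: no annotation lines found")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  ok <- nf >= 6L
  get <- function(i) vapply(fields[ok], `[[`, character(1), i)
  sym <- get(1L); txid <- get(2L); chrom <- get(3L); strand <- get(4L)
  start <- suppressWarnings(as.integer(get(5L)))
  end <- suppressWarnings(as.integer(get(6L)))

  valid <- !is.na(start) & !is.na(end) & start < end &
    strand %in% c("+", "-") & nzchar(chrom)
  n_skipped <- sum(!ok) + sum(!valid)
  if (n_skipped > 0L) {
    warning(sprintf("parse_refflat: skipped %d malformed line(s)", n_skipped))
  }

  out <- data.frame(
    gene_symbol = sym[valid],
    transcript_id = txid[valid],
    chromosome = chrom[valid],
    strand = strand[valid],
    tx_start = start[valid],
    tx_end = end[valid],
    stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

# Chromosome names are compared after stripping an optional "chr" prefix so
# that refFlat ("chr1") and typical summary files ("1") interoperate.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

is_gonosome <- function(chrom) norm_chrom(chrom) %in% c("X", "Y", "23", "24")

#' Select one canonical span per gene symbol
#'
#' Collapses a transcript table to one genomic span per gene symbol by
#' retaining the longest transcript. Genes whose transcripts map to more than
#' one chromosome are considered ambiguous and excluded entirely; they are
#' listed in the `"excluded"` attribute of the result. Length ties are broken
#' deterministically by the lexicographically smallest transcript id.
#'
#' @param transcripts A transcript table as returned by [parse_refflat()].
#' @return A `data.frame` of gene models with columns `gene_symbol`,
#'   `chromosome`, `strand`, `start`, `end`, `transcript_id`, `length`,
#'   sorted by symbol. Excluded genes (symbol + reason) are attached as
#'   attribute `"excluded"`.
#' @export
select_canonical <- function(transcripts) {
  stopifnot(is.data.frame(transcripts), nrow(transcripts) > 0L)
  tr <- transcripts
  tr$.chrom_norm <- norm_chrom(tr$chromosome)

  by_sym <- split(tr, tr$gene_symbol)
  ambiguous <- vapply(by_sym, function(d) length(unique(d$.chrom_norm)) > 1L,
                      logical(1))
  excluded <- data.frame(
    gene_symbol = names(by_sym)[ambiguous],
    reason = rep("multi_chromosome", sum(ambiguous)),
    stringsAsFactors = FALSE
  )
  if (nrow(excluded) > 0L) {
    message(sprintf("select_canonical: excluded %d gene(s) mapping to >1 chromosome",
                    nrow(excluded)))
  }

  keep <- by_sym[!ambiguous]
  rows <- lapply(keep, function(d) {
    len <- d$tx_end - d$tx_start
    cand <- which(len == max(len))
    pick <- cand[order(d$transcript_id[cand])][1L]
    data.frame(
      gene_symbol = d$gene_symbol[pick],
      chromosome = d$.chrom_norm[pick],
      strand = d$strand[pick],
      start = d$tx_start[pick],
      end = d$tx_end[pick],
      transcript_id = d$transcript_id[pick],
      length = len[pick],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$gene_symbol), , drop = FALSE]
  attr(out, "excluded") <- excluded
  out
}

#' Construct a gene store
#'
#' A gene store holds one canonical genomic span per gene symbol and the
#' total number of stored genes, which serves as the denominator of the
#' background significance rate in the enrichment test.
#'
#' @param genes A gene-model `data.frame` as returned by [select_canonical()].
#' @return An object of class `gene_store`.
#' @export
gene_store <- function(genes) {
  need <- c("gene_symbol", "chromosome", "strand", "start", "end",
            "transcript_id")
  stopifnot(is.data.frame(genes), all(need %in% names(genes)),
            nrow(genes) > 0L)
  dup <- unique(genes$gene_symbol[duplicated(genes$gene_symbol)])
  if (length(dup) > 0L) {
    stop("duplicate gene symbol(s) in gene store input: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) stop("gene store input has start >= end")
  genes <- genes[order(genes$gene_symbol), , drop = FALSE]
  attr(genes, "excluded") <- NULL
  attr(genes, "n_skipped") <- NULL
  genes$chromosome <- norm_chrom(genes$chromosome)
  genes$length <- genes$end - genes$start
  rownames(genes) <- NULL
  structure(list(genes = genes, total_genes = nrow(genes)),
            class = "gene_store")
}

#' @export
print.gene_store <- function(x, ...) {
  cat(sprintf("gene_store: %d genes on %d chromosome(s)\n",
              x$total_genes, length(unique(x$genes$chromosome))))
  invisible(x)
}

#' Look up gene models by symbol
#'
#' @param store A `gene_store`.
#' @param symbols Character vector of gene symbols.
#' @return A `data.frame` with one row per requested symbol, in request
#'   order; unknown symbols yield rows of `NA`.
#' @export
gene_lookup <- function(store, symbols) {
  stopifnot(inherits(store, "gene_store"))
  idx <- match(symbols, store$genes$gene_symbol)
  out <- store$genes[idx, , drop = FALSE]
  out$gene_symbol <- symbols
  rownames(out) <- NULL
  out
}

#' Persist a gene store to disk
#'
#' The on-disk format is a flat tab-separated table with a commented header,
#' one row per gene; [read_gene_store()] restores it exactly.
#'
#' @param store A `gene_store`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_gene_store <- function(store, path) {
  stopifnot(inherits(store, "gene_store"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# gentos gene store v1",
    "# coordinates: 0-based start, half-open end (refFlat convention)",
    sprintf("# total_genes: %d", store$total_genes)
  ), con)
  utils::write.table(store$genes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene store from disk
#'
#' @param path Path written by [write_gene_store()] / [build_gene_store()].
#' @return A `gene_store`.
#' @export
read_gene_store <- function(path) {
  if (!file.exists(path)) stop("gene store not found: ", path)
  genes <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE,
                             colClasses = c(start = "integer", end = "integer"))
  gene_store(genes)
}

#' Build and persist the gene store
#'
#' Validates the gene models (unique symbols, positive spans), writes the
#' store to `destination` (overwriting any previous store at that path), and
#' returns it.
#'
#' @param models Gene models from [select_canonical()].
#' @param destination File path for the persisted store, or `NULL` to skip
#'   persistence.
#' @return A `gene_store`.
#' @export
build_gene_store <- function(models, destination = NULL) {
  store <- gene_store(models)
  if (!is.null(destination)) write_gene_store(store, destination)
  store
}
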