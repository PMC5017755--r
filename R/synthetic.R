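# Synthetic fixtures at desk scale: a gene catalog over toy chromosomes in
# refFlat format, genotype panels with block-exchangeable LD (a latent
# haplotype per block plus flip noise), and GWAS summary files that are
# uniform-p under the null with optional planted low-p signals inside chosen
# genes. Every generator is a pure function of its configuration: the same
# seed gives byte-identical output.

#' Configuration of the synthetic data generators
#'
#' @param seed Master RNG seed; all generators derive from it.
#' @param n_chromosomes Number of toy chromosomes.
#' @param chrom_length_bp Length of each chromosome in bp.
#' @param n_genes Total genes in the catalog.
#' @param gene_length_range `(min, max)` gene length in bp.
#' @param n_snps_per_chrom Panel SNPs per chromosome.
#' @param n_samples Panel sample count (>= 2).
#' @param ld_block_size SNPs per LD block.
#' @param within_block_r Latent within-block dosage correlation in `[0, 1]`;
#'   pairwise dosage r approximates this value, so r-squared approximates
#'   its square.
#' @param planted_genes Optional `data.frame(gene_symbol, n_signals,
#'   p_value)` of signals to plant in summary files.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L, n_chromosomes = 2L,
                             chrom_length_bp = 1000000L, n_genes = 100L,
                             gene_length_range = c(5000L, 20000L),
                             n_snps_per_chrom = 2000L, n_samples = 60L,
                             ld_block_size = 10L, within_block_r = 0.8,
                             planted_genes = NULL) {
  stopifnot(n_chromosomes >= 1L, chrom_length_bp > 0L,
            length(gene_length_range) == 2L,
            gene_length_range[1] <= gene_length_range[2],
            n_snps_per_chrom >= 1L, ld_block_size >= 1L,
            within_block_r >= 0, within_block_r <= 1)
  if (n_genes < 1L) stop("n_genes must be >= 1")
  structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_bp = as.integer(chrom_length_bp),
                 n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 n_samples = as.integer(n_samples),
                 ld_block_size = as.integer(ld_block_size),
                 within_block_r = within_block_r,
                 planted_genes = planted_genes),
            class = "synthetic_config")
}

.derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 19937 + salt * 101) %% 2147483647)
}

#' Generate a synthetic gene catalog
#'
#' Places `n_genes` non-overlapping genes across the toy chromosomes, each
#' with 1-3 transcripts of which exactly one (known) is longest, and renders
#' them as refFlat lines. The truth table records the canonical span per
#' gene, i.e. what [select_canonical()] must recover.
#'
#' @param config A [synthetic_config()].
#' @return A list: `refflat` (character lines), `truth` (`data.frame` with
#'   `gene_symbol`, `chromosome`, `strand`, `start`, `end`,
#'   `transcript_id`), `config`.
#' @export
generate_gene_catalog <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.derive_seed(config$seed, 1))
  n_per <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))
  lines <- character(0)
  truth <- vector("list", config$n_genes)
  gi <- 0L
  tx_counter <- 0L
  for (ch in seq_len(config$n_chromosomes)) {
    n <- n_per[ch]
    if (n == 0L) next
    lens <- as.integer(round(stats::runif(n, config$gene_length_range[1],
                                          config$gene_length_range[2])))
    free <- config$chrom_length_bp - sum(lens) - (n + 1L)
    if (free < 0L) {
      stop("generate_gene_catalog: genes do not fit on chromosome ", ch,
           "; reduce n_genes or gene lengths")
    }
    u <- stats::runif(n + 1L)
    gaps <- 1L + as.integer(floor(u / sum(u) * free))
    starts <- cumsum(gaps)[seq_len(n)] + c(0L, cumsum(lens))[seq_len(n)]
    for (k in seq_len(n)) {
      gi <- gi + 1L
      sym <- sprintf("SG%04d", gi)
      s <- starts[k]; e <- s + lens[k]
      strand <- sample(c("+", "-"), 1L)
      tx_counter <- tx_counter + 1L
      canon_id <- sprintf("NM_%06d", tx_counter)
      tx <- list(c(canon_id, s, e))
      n_extra <- sample(0:2, 1L)
      for (jj in seq_len(n_extra)) {
        shrink_l <- sample.int(max(1L, lens[k] %/% 4L), 1L)
        shrink_r <- sample.int(max(1L, lens[k] %/% 4L), 1L)
        tx_counter <- tx_counter + 1L
        tx[[jj + 1L]] <- c(sprintf("NM_%06d", tx_counter),
                           s + shrink_l, e - shrink_r)
      }
      for (t in tx) {
        lines <- c(lines, sprintf("%s\t%s\tchr%d\t%s\t%s\t%s\t%s\t%s\t1\t%s,\t%s,",
                                  sym, t[1], ch, strand, t[2], t[3],
                                  t[2], t[3], t[2], t[3]))
      }
      truth[[gi]] <- data.frame(gene_symbol = sym, chromosome = as.character(ch),
                                strand = strand, start = s, end = e,
                                transcript_id = canon_id,
                                stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  list(refflat = lines, truth = truth, config = config)
}

#' Generate a block-LD genotype panel for one chromosome
#'
#' SNP positions are uniform draws without replacement (strictly
#' increasing). Dosages are built from two latent haplotype alleles per
#' sample and LD block; each SNP copies its latent allele and flips it with
#' probability `(1 - sqrt(r)) / 2`, which makes the within-block allele
#' correlation equal `r` in expectation while blocks stay independent.
#'
#' @param config A [synthetic_config()].
#' @param chromosome Chromosome index in `1:n_chromosomes`.
#' @param ancestry Panel label (default `"SYN"`).
#' @return A [genotype_panel()].
#' @export
generate_ld_panel <- function(config, chromosome = 1L, ancestry = "SYN") {
  stopifnot(inherits(config, "synthetic_config"),
            chromosome >= 1L, chromosome <= config$n_chromosomes)
  if (config$n_samples < 2L) stop("n_samples must be >= 2")
  set.seed(.derive_seed(config$seed, 1000 + chromosome))
  m <- config$n_snps_per_chrom
  if (m > config$chrom_length_bp) stop("more SNPs than positions available")
  pos <- sort(sample.int(config$chrom_length_bp, m))
  ns <- config$n_samples
  eps <- (1 - sqrt(config$within_block_r)) / 2
  dos <- matrix(0L, nrow = ns, ncol = m)
  block <- (seq_len(m) - 1L) %/% config$ld_block_size
  for (b in unique(block)) {
    cols <- which(block == b)
    f <- stats::runif(1, 0.1, 0.9)
    L1 <- stats::rbinom(ns, 1L, f)
    L2 <- stats::rbinom(ns, 1L, f)
    for (j in cols) {
      x1 <- abs(L1 - stats::rbinom(ns, 1L, eps))
      x2 <- abs(L2 - stats::rbinom(ns, 1L, eps))
      dos[, j] <- x1 + x2
    }
  }
  genotype_panel(ancestry, as.character(chromosome), pos,
                 sprintf("snp%d_%06d", chromosome, seq_len(m)), dos)
}

#' Generate uniform SNP positions for a summary file
#'
#' Convenience generator of strictly increasing 1-based positions per
#' chromosome, independent of any genotype panel (summary files typically
#' cover many more SNPs than a reference panel).
#'
#' @param config A [synthetic_config()].
#' @param n_per_chrom SNPs per chromosome.
#' @return Named list (chromosome -> integer positions).
#' @export
generate_snp_positions <- function(config, n_per_chrom) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.derive_seed(config$seed, 2))
  out <- lapply(seq_len(config$n_chromosomes), function(ch) {
    sort(sample.int(config$chrom_length_bp, n_per_chrom))
  })
  names(out) <- as.character(seq_len(config$n_chromosomes))
  out
}

#' Generate a GWAS summary file with optional planted signals
#'
#' One row per SNP; p-values are i.i.d. Uniform(0, 1) under the null. For
#' each planted gene, `n_signals` SNPs inside its (optionally flanked) span
#' are overwritten with the requested p-value; the truth table records
#' exactly which SNPs were planted where.
#'
#' @param catalog Result of [generate_gene_catalog()] (or its `truth`
#'   `data.frame`).
#' @param snp_positions Named list (chromosome -> strictly increasing
#'   1-based positions), e.g. from [generate_snp_positions()] or panel
#'   positions.
#' @param planted Optional `data.frame(gene_symbol, n_signals, p_value)`.
#' @param seed RNG seed for the p-values and signal placement.
#' @param flank_bp Flank added to gene spans when placing signals
#'   (default 0: inside the gene body).
#' @return A list: `gwas` (`data.frame` with columns SNP, CHR, POS, P),
#'   `truth` (`data.frame` of planted gene/SNP/p rows).
#' @export
generate_gwas_summary <- function(catalog, snp_positions, planted = NULL,
                                  seed = 1L, flank_bp = 0L) {
  truth_genes <- if (is.data.frame(catalog)) catalog else catalog$truth
  stopifnot(is.list(snp_positions), !is.null(names(snp_positions)))
  set.seed(.derive_seed(seed, 3))
  parts <- lapply(names(snp_positions), function(ch) {
    pos <- snp_positions[[ch]]
    data.frame(SNP = sprintf("rs%s_%06d", ch, seq_along(pos)),
               CHR = ch, POS = as.integer(pos),
               P = stats::runif(length(pos)),
               stringsAsFactors = FALSE)
  })
  gwas <- do.call(rbind, parts)
  truth <- data.frame(gene_symbol = character(0), snp_id = character(0),
                      p_value = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(planted) && nrow(planted) > 0L) {
    for (i in seq_len(nrow(planted))) {
      sym <- planted$gene_symbol[i]
      g <- truth_genes[truth_genes$gene_symbol == sym, ]
      if (nrow(g) != 1L) stop("planted gene not in catalog: ", sym)
      sel <- which(gwas$CHR == g$chromosome &
                     gwas$POS > max(0L, g$start - flank_bp) &
                     gwas$POS <= g$end + flank_bp)
      if (length(sel) < planted$n_signals[i]) {
        stop(sprintf(
          "gene %s spans too few SNPs (%d < %d); increase flank_bp or SNP density",
          sym, length(sel), planted$n_signals[i]))
      }
      pick <- sort(sample(sel, planted$n_signals[i]))
      gwas$P[pick] <- planted$p_value[i]
      truth <- rbind(truth, data.frame(gene_symbol = sym,
                                       snp_id = gwas$SNP[pick],
                                       p_value = planted$p_value[i]))
    }
  }
  rownames(gwas) <- NULL
  list(gwas = gwas, truth = truth)
}

#' Write refFlat lines to a file
#'
#' @param lines Character lines from [generate_gene_catalog()].
#' @param path Destination (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_refflat <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a GWAS summary table to TSV
#'
#' @param gwas `data.frame` (e.g. from [generate_gwas_summary()]).
#' @param path Destination (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(gwas, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as minimal VCF
#'
#' VCFv4.2 with GT-only genotypes (`0/0`, `0/1`, `1/1`, `./.`), fixed
#' REF/ALT alleles `A`/`G`.
#'
#' @param panel A [genotype_panel()].
#' @param path Destination (`.gz` for compressed output).
#' @return `path`, invisibly.
#' @export
write_vcf_panel <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  ns <- nrow(panel$dosages)
  samples <- sprintf("S%03d", seq_len(ns))
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  body <- vapply(seq_along(panel$positions), function(j) {
    d <- panel$dosages[, j]
    gts <- ifelse(is.na(d), "./.", gt_map[as.character(d)])
    paste(c(panel$chromosome, panel$positions[j], panel$snp_ids[j],
            "A", "G", ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", panel$chromosome),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  ), con)
  invisible(path)
}
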