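# Enrichment of significant candidate genes over chance. Whether a gene
# shows a significant GWAS signal is treated as a Bernoulli trial with
# success probability p estimated store-wide, so the number of significant
# genes on an n-gene list is Binomial(n, p) under the null; the enrichment
# p-value is the complementary cumulative (upper-tail) probability of the
# observed count. The binomial approximation is validated against a
# resampling null that redraws gene lists and recomputes the threshold for
# each draw.

#' Complementary cumulative binomial enrichment p-value
#'
#' `P(X >= x)` for `X ~ Binomial(n, p)`: the probability of observing at
#' least the attained number of significant genes by chance. Evaluated via
#' the binomial survival function, which keeps tiny tail probabilities
#' accurate where the literal `1 - sum(...)` form would cancel.
#'
#' @param n Candidate-list size (number of Bernoulli trials).
#' @param p Background per-gene significance probability in `[0, 1]`.
#' @param x Observed number of significant genes, `0 <= x <= n`.
#' @return The enrichment p-value in `[0, 1]`; `x = 0` gives 1.
#' @export
#' @examples
#' enrichment_pvalue(10, 0.1, 3)
enrichment_pvalue <- function(n, p, x) {
  stopifnot(length(n) == 1L, length(p) == 1L, length(x) == 1L)
  if (is.na(n) || is.na(p) || is.na(x)) stop("enrichment_pvalue: NA input")
  if (x < 0 || x > n) stop("enrichment_pvalue: x must be in [0, n]")
  if (p < 0 || p > 1) stop("enrichment_pvalue: p must be in [0, 1]")
  if (x == 0) return(1)
  stats::pbinom(x - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Background per-gene significance rate over the whole gene store
#'
#' Every gene in the store is flanked like a candidate and scanned at the
#' single fixed threshold of the analysed list; the background rate is the
#' proportion of genes with at least one sub-threshold SNP. When
#' `exclude_gonosomes` is set, X/Y genes are dropped from the universe so
#' numerator and denominator match the candidate-list filtering.
#'
#' @param store A [gene_store()].
#' @param gwas Summary table from [read_gwas()] / [as_gwas()].
#' @param threshold_value Single fixed significance threshold.
#' @param flank_bp Flank width applied to every store gene.
#' @param exclude_gonosomes Match the candidate-list gonosome filter
#'   (default `TRUE`).
#' @return A list: `p` (rate), `count` (significant genes), `total`
#'   (universe size).
#' @export
background_rate <- function(store, gwas, threshold_value,
                            flank_bp = 10000L, exclude_gonosomes = TRUE) {
  stopifnot(inherits(store, "gene_store"),
            threshold_value > 0, threshold_value <= 1)
  genes <- store$genes
  if (exclude_gonosomes) genes <- genes[!is_gonosome(genes$chromosome), ]
  if (nrow(genes) == 0L) stop("background_rate: empty gene universe")
  regions <- define_regions(genes, flank_bp)
  minp <- .region_min_p(gwas, regions)
  count <- sum(minp < threshold_value)
  list(p = count / nrow(genes), count = count, total = nrow(genes))
}

#' Resampling null distribution of the significant-gene count
#'
#' Each iteration draws `list_size` genes uniformly without replacement from
#' the store universe, derives that draw's threshold, scans the summary
#' statistics and records the number of genes with at least one
#' sub-threshold SNP. With `threshold = "listwise"` the list-wise Bonferroni
#' threshold `alpha / sum(m_g)` is recomputed for every draw (the reference
#' procedure, accounting for each draw's size and LD structure); with
#' `threshold = "fixed"` the supplied `fixed_value` is applied to all draws.
#'
#' @param store A [gene_store()].
#' @param gwas Summary table.
#' @param list_size Genes per draw.
#' @param iterations Number of draws (default 2000).
#' @param flank_bp Flank width in bp.
#' @param threshold `"listwise"` or `"fixed"`.
#' @param alpha Type-I error for the list-wise Bonferroni threshold.
#' @param fixed_value Threshold for `threshold = "fixed"`.
#' @param snp_store,ancestry Independent-SNP store and panel label
#'   (list-wise mode only).
#' @param seed RNG seed; identical seeds give identical draws.
#' @param exclude_gonosomes Restrict the universe as in [background_rate()].
#' @return Integer vector of `iterations` significant-gene counts.
#' @export
resampling_null <- function(store, gwas, list_size, iterations = 2000L,
                            flank_bp = 10000L,
                            threshold = c("listwise", "fixed"),
                            alpha = 0.05, fixed_value = NULL,
                            snp_store = NULL, ancestry = NULL,
                            seed = 1L, exclude_gonosomes = TRUE) {
  threshold <- match.arg(threshold)
  stopifnot(inherits(store, "gene_store"), iterations >= 1L)
  genes <- store$genes
  if (exclude_gonosomes) genes <- genes[!is_gonosome(genes$chromosome), ]
  if (list_size > nrow(genes)) {
    stop(sprintf("list_size (%d) exceeds the gene universe (%d)",
                 list_size, nrow(genes)))
  }
  regions <- define_regions(genes, flank_bp)
  minp <- .region_min_p(gwas, regions)
  if (threshold == "listwise") {
    if (is.null(snp_store) || is.null(ancestry)) {
      stop("listwise resampling needs snp_store and ancestry")
    }
    regions <- .fill_m_g(regions, snp_store, ancestry)
    m_g <- regions$m_g
  } else {
    if (is.null(fixed_value) || fixed_value <= 0 || fixed_value > 1) {
      stop("threshold = 'fixed' needs fixed_value in (0, 1]")
    }
  }

  set.seed(seed)
  counts <- integer(iterations)
  N <- nrow(genes)
  for (it in seq_len(iterations)) {
    idx <- sample.int(N, list_size)
    thr <- if (threshold == "listwise") {
      M <- sum(m_g[idx])
      if (M == 0L) NA_real_ else alpha / M
    } else {
      fixed_value
    }
    counts[it] <- if (is.na(thr)) 0L else sum(minp[idx] < thr)
  }
  counts
}

#' Simulated binomial null distribution
#'
#' Independent `Binomial(n, p)` draws of the significant-gene count, the
#' fast stand-in for the resampling null once the Bernoulli approximation is
#' accepted.
#'
#' @param n Candidate-list size.
#' @param p Background per-gene significance rate.
#' @param iterations Number of draws (default 2000).
#' @param seed RNG seed.
#' @return Integer vector of `iterations` counts.
#' @export
binomial_null_sim <- function(n, p, iterations = 2000L, seed = 1L) {
  stopifnot(n >= 0, p >= 0, p <= 1, iterations >= 1L)
  set.seed(seed)
  stats::rbinom(iterations, size = n, prob = p)
}

#' Quantile-quantile comparison of two null-count samples
#'
#' Pairs the order statistics of the two samples and reports the Spearman
#' rank correlation of the paired quantiles (average ranks for ties). Two
#' constant samples leave the ranks degenerate; the coefficient is then
#' `NaN` with a warning.
#'
#' @param counts_a,counts_b Equal-length numeric/integer samples.
#' @return A list of class `null_comparison`: `qq` (data.frame of paired
#'   sorted quantiles) and `spearman`.
#' @export
compare_nulls <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("compare_nulls: samples must have equal size")
  }
  qa <- sort(counts_a)
  qb <- sort(counts_b)
  rho <- suppressWarnings(stats::cor(qa, qb, method = "spearman"))
  if (is.na(rho)) {
    warning("compare_nulls: degenerate ranks (constant sample); Spearman undefined")
    rho <- NaN
  }
  structure(list(qq = data.frame(a = qa, b = qb), spearman = rho),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("null_comparison: %d paired quantiles, Spearman = %s\n",
              nrow(x$qq), format(x$spearman)))
  invisible(x)
}

#' @export
plot.null_comparison <- function(x, ...) {
  graphics::plot(x$qq$a, x$qq$b,
                 xlab = "resampling null quantiles",
                 ylab = "binomial null quantiles",
                 main = sprintf("QQ, Spearman = %.3f", x$spearman), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Run the enrichment test for a candidate list
#'
#' Orchestrates the full assessment at a single fixed threshold: scans the
#' candidate regions for the observed significant-gene count `x`, estimates
#' the store-wide background rate `p`, computes the complementary cumulative
#' binomial enrichment p-value, and optionally attaches null-count samples
#' (binomial simulation, threshold-recomputing resampling, or both).
#' A per-gene Bonferroni threshold is rejected: the background-rate
#' definition presumes one threshold shared by all genes, so use
#' `method = "bonferroni_listwise"` or `"fixed"` upstream.
#'
#' @param candidates A `candidate_list` from [resolve_candidates()].
#' @param gwas Summary table.
#' @param store The [gene_store()] (background universe).
#' @param threshold A [compute_threshold()] result with a single `value`.
#' @param flank_bp Flank width used for regions and background.
#' @param null One of `"none"`, `"binomial"`, `"resampling"`, `"both"`.
#' @param iterations Null iterations (default 2000).
#' @param seed RNG seed for the null samples.
#' @param snp_store,ancestry,alpha Passed to [resampling_null()] when the
#'   resampling null recomputes list-wise thresholds.
#' @param exclude_gonosomes Universe filter, as elsewhere.
#' @return An object of class `enrichment_result`.
#' @export
enrich <- function(candidates, gwas, store, threshold,
                   flank_bp = 10000L, null = c("binomial", "none",
                                               "resampling", "both"),
                   iterations = 2000L, seed = 1L,
                   snp_store = NULL, ancestry = NULL, alpha = 0.05,
                   exclude_gonosomes = TRUE) {
  null <- match.arg(null)
  stopifnot(inherits(candidates, "candidate_list"),
            inherits(store, "gene_store"),
            inherits(threshold, "significance_threshold"))
  if (is.null(threshold$value)) {
    stop("enrichment needs a single fixed threshold; use method = ",
         "'bonferroni_listwise', 'fixed' or 'fdr' in compute_threshold()")
  }
  regions <- threshold$regions
  if (is.null(regions)) regions <- define_regions(candidates, flank_bp)
  hits <- scan_gwas(gwas, regions, threshold)
  x <- attr(hits, "x")
  n <- candidates$n
  bg <- background_rate(store, gwas, threshold$value, flank_bp,
                        exclude_gonosomes)
  p_enr <- enrichment_pvalue(n, bg$p, x)

  null_counts <- list()
  if (null %in% c("binomial", "both")) {
    null_counts$binomial <- binomial_null_sim(n, bg$p, iterations, seed)
  }
  if (null %in% c("resampling", "both")) {
    null_counts$resampling <- resampling_null(
      store, gwas, n, iterations, flank_bp,
      threshold = if (threshold$method == "bonferroni_listwise") "listwise"
                  else "fixed",
      alpha = alpha, fixed_value = threshold$value,
      snp_store = snp_store, ancestry = ancestry, seed = seed,
      exclude_gonosomes = exclude_gonosomes)
  }

  structure(list(n = n, x = x, p = bg$p, p_enrichment = p_enr,
                 background_count = bg$count, background_total = bg$total,
                 threshold_used = threshold, hits = hits,
                 null_counts = null_counts, iterations = iterations,
                 seed = seed),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Candidate-gene enrichment\n")
  cat(sprintf("  list size n:           %d\n", x$n))
  cat(sprintf("  significant genes x:   %d\n", x$x))
  cat(sprintf("  background rate p:     %.4g (%d / %d genes)\n",
              x$p, x$background_count, x$background_total))
  cat(sprintf("  threshold (%s): %s\n", x$threshold_used$method,
              format(x$threshold_used$value)))
  cat(sprintf("  enrichment P(X >= x):  %.4g\n", x$p_enrichment))
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, ...) {
  print(object)
  for (nm in names(object$null_counts)) {
    cc <- object$null_counts[[nm]]
    cat(sprintf("  %s null: %d draws, mean %.2f, max %d\n",
                nm, length(cc), mean(cc), max(cc)))
  }
  invisible(object)
}

#' Plot an enrichment result
#'
#' Histogram of the null significant-gene counts with the binomial density
#' overlaid as connected dots and the observed count as a vertical line.
#'
#' @param x An `enrichment_result` holding at least one null-count sample.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.enrichment_result <- function(x, ...) {
  counts <- if (!is.null(x$null_counts$resampling)) x$null_counts$resampling
            else x$null_counts$binomial
  if (is.null(counts)) stop("no null counts to plot; rerun enrich() with null != 'none'")
  brk <- seq(-0.5, max(counts, x$x) + 1.5, by = 1)
  h <- graphics::hist(counts, breaks = brk, freq = FALSE,
                      xlab = "significant genes under the null",
                      main = sprintf("n = %d, p = %.3g, P(X >= %d) = %.3g",
                                     x$n, x$p, x$x, x$p_enrichment), ...)
  k <- 0:max(counts, x$x)
  graphics::lines(k, stats::dbinom(k, x$n, x$p), type = "o", pch = 16,
                  col = "steelblue")
  graphics::abline(v = x$x, lwd = 2)
  invisible(x)
}
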