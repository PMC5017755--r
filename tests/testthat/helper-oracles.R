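# Independent oracles, coded separately from the package implementation:
# plain-loop replays of the greedy pruning rule and direct term-by-term
# evaluation of the binomial tail.

oracle_maf <- function(col) {
  x <- col[!is.na(col)]
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

oracle_r2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(0)
  a <- a[ok]; b <- b[ok]
  da <- a - mean(a); db <- b - mean(b)
  if (sum(da^2) == 0 || sum(db^2) == 0) return(0)
  sum(da * db)^2 / (sum(da^2) * sum(db^2))
}

# Brute-force replay of the windowed greedy pruning rule: MAF filter, then
# windows of `window` SNPs advanced by `step`; in each window repeatedly
# locate the worst remaining pair (first occurrence in column-major order on
# ties) and drop its lower-MAF member (later position on a MAF tie).
oracle_prune <- function(dosages, window, step, r2_thr, maf_min) {
  p <- ncol(dosages)
  maf <- vapply(seq_len(p), function(j) {
    col <- dosages[, j]
    if (all(is.na(col))) 0 else oracle_maf(col)
  }, numeric(1))
  keep <- which(maf >= maf_min)
  if (length(keep) == 0L) return(integer(0))
  nk <- length(keep)
  removed <- rep(FALSE, nk)
  for (ws in seq(1L, nk, by = step)) {
    we <- min(ws + window - 1L, nk)
    if (we <= ws) next
    repeat {
      active <- (ws:we)[!removed[ws:we]]
      if (length(active) < 2L) break
      best <- 0; bi <- 0L; bj <- 0L
      for (cj in seq_along(active)) {
        for (ci in seq_along(active)) {
          if (ci == cj) next
          r2 <- oracle_r2(dosages[, keep[active[ci]]],
                          dosages[, keep[active[cj]]])
          if (r2 > best) { best <- r2; bi <- ci; bj <- cj }
        }
      }
      if (best <= r2_thr) break
      gi <- active[bi]; gj <- active[bj]
      drop <- if (maf[keep[gi]] < maf[keep[gj]]) gi
              else if (maf[keep[gj]] < maf[keep[gi]]) gj
              else max(gi, gj)
      removed[drop] <- TRUE
    }
  }
  keep[!removed]
}

# Direct enumeration of P(X >= x) for X ~ Binomial(n, p), summed term by
# term on the log scale (no 1 - CDF cancellation).
oracle_binom_tail <- function(n, p, x) {
  if (x == 0) return(1)
  if (p == 0) return(0)
  if (p == 1) return(1)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Random small genotype panel with LD structure, low-MAF columns and
# missingness, for pruning cross-checks.
random_panel <- function(seed, n_snps = 60L, n_samples = 40L) {
  cfg <- synthetic_config(seed = seed, n_chromosomes = 1L,
                          chrom_length_bp = 100000L, n_genes = 1L,
                          n_snps_per_chrom = n_snps, n_samples = n_samples,
                          ld_block_size = 5L, within_block_r = 0.6)
  panel <- generate_ld_panel(cfg, 1L)
  set.seed(seed + 7)
  # sprinkle missing genotypes and a couple of near-monomorphic columns
  miss <- matrix(runif(n_samples * n_snps) < 0.03, n_samples, n_snps)
  panel$dosages[miss] <- NA_integer_
  rare <- sample.int(n_snps, 2L)
  for (j in rare) {
    panel$dosages[, j] <- 0L
    panel$dosages[sample.int(n_samples, 1L), j] <- 1L
  }
  panel
}

# Small deterministic gene store used across prioritize/enrichment tests.
toy_store <- function() {
  genes <- data.frame(
    gene_symbol = c("G1", "G2", "G3", "G4", "GX"),
    chromosome = c("1", "1", "2", "2", "X"),
    strand = "+",
    start = c(50000L, 120000L, 30000L, 90000L, 10000L),
    end = c(60000L, 140000L, 40000L, 95000L, 20000L),
    transcript_id = sprintf("NM_%06d", 1:5),
    stringsAsFactors = FALSE
  )
  gene_store(genes)
}
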