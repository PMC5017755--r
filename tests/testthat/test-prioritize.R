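test_that("resolve_candidates collapses duplicates and records filter reasons", {
  store <- toy_store()
  expect_warning(cand <- resolve_candidates(c("G1", "G1", "G2"), store),
                 "duplicate")
  expect_equal(cand$genes$gene_symbol, c("G1", "G2"))
  expect_equal(cand$n, 2L)

  suppressMessages(cand2 <- resolve_candidates(c("G2", "NOPE", "GX", "G1"), store))
  expect_equal(cand2$genes$gene_symbol, c("G2", "G1"))  # first-occurrence order
  expect_equal(sort(cand2$filtered$reason), c("gonosomal", "unmapped"))

  suppressMessages(cand3 <- resolve_candidates(c("GX", "G1"), store,
                                               exclude_gonosomes = FALSE))
  expect_equal(cand3$n, 2L)

  expect_error(suppressMessages(resolve_candidates("NOPE", store)), "no candidate")
})

test_that("define_regions flanks and clips at zero", {
  genes <- data.frame(gene_symbol = c("A", "B"), chromosome = "1",
                      strand = "+", start = c(50000L, 5000L),
                      end = c(60000L, 8000L), transcript_id = c("t1", "t2"))
  r <- define_regions(genes)  # default flank 10 kb
  expect_equal(r$region_start, c(40000L, 0L))
  expect_equal(r$region_end, c(70000L, 18000L))
  r2 <- define_regions(genes, flank_bp = 0)
  expect_equal(r2$region_start, genes$start)
})

test_that("Bonferroni thresholds follow the independent-SNP counts", {
  store <- snp_store(data.frame(
    ancestry = "EUR",
    chromosome = "1",
    position = c(41000L, 42000L, 45000L, 45500L, 46000L,
                 62000L, 62100L, 62200L, 62300L, 62400L,
                 130000L, 131000L, 132000L, 133000L, 134000L,
                 135000L, 136000L, 137000L, 138000L, 139000L,
                 139100L, 139200L, 139300L, 139400L, 139500L,
                 139600L, 139700L, 139800L, 139900L, 139950L,
                 140100L, 140200L, 140300L, 140400L, 140500L,
                 140600L, 140700L, 140800L, 140900L, 141000L,
                 141100L, 141200L, 141300L, 141400L, 141500L,
                 141600L, 141700L, 141800L, 141900L, 141950L),
    snp_id = paste0("s", 1:50)))
  genes <- toy_store()$genes[1:2, ]  # G1 [50000,60000), G2 [120000,140000)
  regions <- define_regions(genes, flank_bp = 10000L)
  # G1 region [40000,70000): 10 SNPs; G2 region [110000,150000): 40 SNPs
  thr <- compute_threshold(regions, store, "EUR", method = "bonferroni_listwise")
  expect_equal(thr$regions$m_g, c(10L, 40L))
  expect_equal(thr$M, 50L)
  expect_equal(thr$value, 0.05 / 50)

  per <- compute_threshold(regions, store, "EUR", method = "bonferroni")
  expect_equal(unname(per$per_gene), c(0.05 / 10, 0.05 / 40))

  # a gene without independent SNPs is excluded from per-gene scanning
  genes0 <- rbind(genes, data.frame(gene_symbol = "G9", chromosome = "2",
                                    strand = "+", start = 1000L, end = 2000L,
                                    transcript_id = "NM_9", length = 1000L))
  expect_warning(per0 <- compute_threshold(define_regions(genes0, 0L),
                                           store, "EUR", method = "bonferroni"),
                 "no independent SNPs")
  expect_true(is.na(per0$per_gene[["G9"]]))
})

test_that("fixed thresholds validate and listwise shrinks as genes are added", {
  genes <- toy_store()$genes[1:2, ]
  regions <- define_regions(genes, 0L)
  thr <- compute_threshold(regions, method = "fixed", fixed_value = 1e-4)
  expect_equal(thr$value, 1e-4)
  expect_error(compute_threshold(regions, method = "fixed", fixed_value = 0),
               "fixed_value")

  store <- snp_store(data.frame(ancestry = "EUR", chromosome = "1",
                                position = seq(40000L, 150000L, by = 100L),
                                snp_id = paste0("s", 1:1101)))
  t1 <- compute_threshold(define_regions(genes[1, , drop = FALSE], 1000L),
                          store, "EUR", method = "bonferroni_listwise")
  t2 <- compute_threshold(define_regions(genes, 1000L),
                          store, "EUR", method = "bonferroni_listwise")
  expect_lt(t2$value, t1$value)
})

test_that("FDR threshold admits exactly the BH-passing region SNPs", {
  genes <- toy_store()$genes[1:2, ]
  regions <- define_regions(genes, 0L)
  set.seed(9)
  pos <- c(seq(50500L, 59500L, by = 500L), seq(120500L, 139500L, by = 500L))
  p <- runif(length(pos))
  p[1:4] <- c(1e-6, 2e-6, 5e-4, 0.2)
  gwas <- as_gwas(data.frame(SNP = paste0("r", seq_along(pos)), CHR = "1",
                             POS = pos, P = p))
  thr <- compute_threshold(regions, method = "fdr", fdr_q = 0.05, gwas = gwas)
  hits <- scan_gwas(gwas, regions, thr)
  # independent route: stats::p.adjust over the same SNP universe
  in_region <- (pos > 50000 & pos <= 60000) | (pos > 120000 & pos <= 140000)
  expected <- paste0("r", which(in_region))[
    p.adjust(p[in_region], "BH") <= 0.05]
  expect_setequal(hits$.snp_id, expected)

  # nothing passes -> threshold under the smallest valid p -> no hits
  gwas_hi <- as_gwas(data.frame(SNP = "a", CHR = "1", POS = 55000L, P = 0.9))
  thr0 <- compute_threshold(regions, method = "fdr", fdr_q = 0.05,
                            gwas = gwas_hi)
  expect_equal(nrow(scan_gwas(gwas_hi, regions, thr0)), 0L)
})

test_that("scan_gwas applies strict inequality, region bounds and per-gene emission", {
  genes <- data.frame(gene_symbol = c("A", "B"), chromosome = "1",
                      strand = "+", start = c(1000L, 1500L),
                      end = c(2000L, 2500L), transcript_id = c("t1", "t2"))
  regions <- define_regions(genes, 0L)
  thr <- compute_threshold(regions, method = "fixed", fixed_value = 1e-3)
  gwas <- as_gwas(data.frame(
    SNP = c("at_thr", "hit_overlap", "outside", "hit_a", "boundary"),
    CHR = "1",
    POS = c(1200L, 1800L, 5000L, 1100L, 1000L),
    P = c(1e-3, 1e-5, 1e-9, 5e-4, 1e-6),
    BETA = c(0.1, 0.2, 0.3, 0.4, 0.5)))
  hits <- scan_gwas(gwas, regions, thr)
  # p == threshold is not a hit; 'outside' is sub-threshold but unplaced;
  # position 1000 is outside the half-open region (q must satisfy s < q <= e)
  expect_false("at_thr" %in% hits$.snp_id)
  expect_false("outside" %in% hits$.snp_id)
  expect_false("boundary" %in% hits$.snp_id)
  # the overlap SNP is emitted once per gene and both genes become significant
  expect_equal(sum(hits$.snp_id == "hit_overlap"), 2L)
  expect_setequal(attr(hits, "significant_genes"), c("A", "B"))
  expect_equal(attr(hits, "x"), 2L)
  # pass-through column preserved
  expect_true("BETA" %in% names(hits))
  expect_true(all(hits$.p_value < hits$applied_threshold))
})

test_that("scanning is order-independent and skips unparseable rows", {
  genes <- toy_store()$genes[1:2, ]
  regions <- define_regions(genes, 10000L)
  thr <- compute_threshold(regions, method = "fixed", fixed_value = 0.05)
  set.seed(3)
  d <- data.frame(SNP = paste0("r", 1:300), CHR = "1",
                  POS = sample(30000:150000, 300), P = runif(300))
  d$P[5] <- NA
  suppressWarnings(gwas <- as_gwas(d))
  suppressMessages(h1 <- scan_gwas(gwas, regions, thr))
  suppressWarnings(gwas_shuf <- as_gwas(d[sample(nrow(d)), ]))
  suppressMessages(h2 <- scan_gwas(gwas_shuf, regions, thr))
  expect_equal(as.data.frame(h1), as.data.frame(h2))
  expect_equal(attr(h1, "n_skipped"), 1L)
})

test_that("p-values of zero are clamped on ingest", {
  expect_warning(g <- as_gwas(data.frame(SNP = "a", CHR = 1, POS = 10L, P = 0)),
                 "clamped")
  expect_equal(g$.p_value, .Machine$double.xmin)
})

test_that("a planted ultra-low p-value is always recovered under listwise Bonferroni", {
  cfg <- synthetic_config(seed = 77, n_genes = 40L, n_chromosomes = 2L,
                          chrom_length_bp = 1500000L)
  cat_out <- generate_gene_catalog(cfg)
  store <- gene_store(cat_out$truth)
  planted <- data.frame(gene_symbol = c("SG0003", "SG0021"), n_signals = 1L,
                        p_value = 1e-15)
  sim <- generate_gwas_summary(cat_out, generate_snp_positions(cfg, 5000L),
                               planted = planted, seed = 77)
  gwas <- as_gwas(sim$gwas)
  cand <- resolve_candidates(cat_out$truth$gene_symbol[1:30], store)
  regions <- define_regions(cand, 2000L)
  # any Bonferroni threshold with M <= 1e6 leaves 1e-15 significant
  thr <- compute_threshold(regions, method = "fixed", fixed_value = 0.05 / 1e6)
  hits <- scan_gwas(gwas, regions, thr)
  expect_true("SG0003" %in% attr(hits, "significant_genes"))
  expect_lte(attr(hits, "x"), cand$n)
})

test_that("hit tables round-trip to TSV without internal columns", {
  genes <- toy_store()$genes[1, , drop = FALSE]
  regions <- define_regions(genes, 0L)
  thr <- compute_threshold(regions, method = "fixed", fixed_value = 0.5)
  gwas <- as_gwas(data.frame(SNP = "a", CHR = "1", POS = 55000L, P = 0.01))
  hits <- scan_gwas(gwas, regions, thr)
  path <- file.path(tempdir(), "hits.tsv")
  write_hit_table(hits, path)
  back <- read.delim(path)
  expect_equal(back$gene_symbol, "G1")
  expect_false(any(startsWith(names(back), ".")))
  unlink(path)
})
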