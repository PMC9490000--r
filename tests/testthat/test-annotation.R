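toy_models <- function() {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
                      start = c(1000, 5000), end = c(3000, 8000),
                      strand = c("+", "-"))
  exons <- data.frame(gene_id = c("gA", "gA", "gB"), chrom = "chr1",
                      start = c(1000, 2500, 5000), end = c(1200, 3000, 5200))
  gene_models(genes, exons)
}

test_that("genic context follows exon > intron > intergenic precedence", {
  gm <- toy_models()
  cnvrs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                      start = c(1050, 1500, 100), end = c(1100, 2000, 900))
  expect_equal(classify_genic_context(cnvrs, gm),
               c("EXONIC", "INTRONIC", "INTERGENIC"))
})

test_that("genic context classes partition any CNVR set", {
  sg <- simulate_genome(2, 1e6, n_genes = 40, n_qtls = 5, seed = 5)
  set.seed(6)
  cnvrs <- data.frame(chrom = sample(sg$genome$chrom, 60, TRUE),
                      start = s <- sample.int(9e5, 60))
  cnvrs$end <- cnvrs$start + sample(c(800, 1600, 4000), 60, TRUE)
  ctx <- classify_genic_context(cnvrs, sg$genes)
  expect_equal(sum(table(ctx)), 60)
  expect_true(all(ctx %in% c("EXONIC", "INTRONIC", "INTERGENIC")))
})

test_that("gene overlap uses the shorter-feature fraction rule", {
  gm <- gene_models(
    data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 1000),
    data.frame(gene_id = "g", chrom = "chr1", start = 0, end = 100))
  # CNVR [0,600): overlap 600 >= 0.5 * 600 -> retained
  expect_equal(nrow(overlapping_genes(
    data.frame(chrom = "chr1", start = 0, end = 600), gm)), 1)
  # CNVR [900,2900): overlap 100 below half of either feature -> dropped
  expect_equal(nrow(overlapping_genes(
    data.frame(chrom = "chr1", start = 900, end = 2900), gm)), 0)
  # full containment always qualifies
  expect_equal(nrow(overlapping_genes(
    data.frame(chrom = "chr1", start = 200, end = 400), gm)), 1)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N = 20 background genes, term covers the first K = 5
  tm <- data.frame(gene_id = paste0("g", 1:5), term_id = "T1")
  bg <- paste0("g", 1:20)
  res <- enrichment_test(paste0("g", c(1, 2, 3, 10, 11)), tm, bg)
  expect_equal(res$p_value, 1126 / 15504)
  expect_equal(res$p_value, oracle_hyper_upper(3, 20, 5, 5))
  expect_equal(res$q_value, res$p_value)  # single term: BH identity

  # further random configurations against the enumeration oracle
  set.seed(42)
  for (i in 1:4) {
    N <- sample(10:22, 1); K <- sample(2:6, 1); n <- sample(3:7, 1)
    bg <- paste0("g", seq_len(N))
    tm <- data.frame(gene_id = paste0("g", seq_len(K)), term_id = "T")
    hits <- sample(bg, n)
    res <- enrichment_test(hits, tm, bg)
    k <- length(intersect(hits, tm$gene_id))
    expect_equal(res$p_value, oracle_hyper_upper(k, N, K, n),
                 tolerance = 1e-12)
  }
})

test_that("absent terms score p = 1 and BH keeps q monotone in p", {
  tm <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g4", "g5"),
                   term_id = c("T1", "T1", "T2", "T2", "T3", "T3"))
  bg <- paste0("g", 1:10)
  res <- enrichment_test(c("g1", "g2", "g6"), tm, bg)
  expect_equal(res$p_value[res$term_id == "T3"], 1)
  expect_true(all(diff(res$q_value[order(res$p_value)]) >= -1e-12))
  expect_error(enrichment_test("nope", tm, bg), "absent from the background")
  expect_equal(nrow(enrichment_test(character(), tm, bg)), 0)
})

test_that("QTL overlap is half-open and deduplicates both sides", {
  cnvrs <- data.frame(id = "c1", chrom = "chr1", start = 100, end = 200)
  qtls <- data.frame(chrom = "chr1", start = c(150, 200), end = c(300, 300),
                     id = c("q1", "q2"), trait = "growth")
  ov <- qtl_overlap(cnvrs, qtls)
  expect_equal(nrow(ov$pairs), 1)        # [100,200) does not touch [200,300)
  expect_equal(ov$pairs$qtl_id, "q1")

  qtls2 <- data.frame(chrom = "chr1", start = c(150, 180), end = c(300, 190),
                      id = c("q1", "q2"))
  ov2 <- qtl_overlap(cnvrs, qtls2)
  expect_equal(c(ov2$n_cnvrs, ov2$n_qtls), c(1L, 2L))
  expect_equal(nrow(ov2$pairs), 2)
})

test_that("cross-study overlap counts and percentages are reported", {
  ours <- data.frame(chrom = "chr1", start = c(0, 5000), end = c(1000, 6000))
  theirs <- data.frame(chrom = "chr1", start = c(500, 2000, 5500),
                       end = c(700, 3000, 5800))
  got <- cross_study_overlap(ours, theirs)
  expect_equal(got$n_overlapping, 2L)
  expect_equal(got$percentage, 66.67)

  disjoint <- data.frame(chrom = "chr2", start = 0, end = 100)
  expect_equal(cross_study_overlap(ours, disjoint)$percentage, 0)
  expect_error(cross_study_overlap(ours, theirs[0, ]), "empty")
})

test_that("GFF3 written by the simulator reads back identically", {
  sg <- simulate_genome(2, 5e5, n_genes = 15, n_qtls = 3, seed = 8)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(sg$genes, path)
  back <- read_gene_models(path)
  ord <- order(back$genes$gene_id)
  expect_equal(back$genes[ord, c("gene_id", "chrom", "start", "end")],
               sg$genes$genes[order(sg$genes$genes$gene_id),
                              c("gene_id", "chrom", "start", "end")],
               ignore_attr = TRUE)
  expect_equal(nrow(back$exons), nrow(sg$genes$exons))
})
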