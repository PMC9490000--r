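test_that("window classification applies both criteria conjunctively", {
  rd <- matrix(c(0.50, 0.70, 1.40, 1.60), 4, 1)
  st <- classify_windows(fake_norm(rd, stdev = 0.10))
  # 0.50 < 1 - 2*0.1 and < 0.65 -> LOSS; 0.70 passes the statistical but
  # not the empirical criterion; 1.40 and 1.60 pass both for GAIN
  expect_equal(as.integer(st), c(-1L, 0L, 1L, 1L))

  st2 <- classify_windows(fake_norm(matrix(1.40, 1, 1), stdev = 0.25))
  expect_equal(as.integer(st2), 0L)  # 1.40 > 1.35 but not > 1 + 2*0.25
})

test_that("candidate filter keeps windows by frequency or homozygous count", {
  params <- calling_params()
  # 24 individuals, 2 LOSS carriers: freq 0.083 >= 0.05
  rd <- matrix(1, 1, 24, dimnames = list(NULL, paste0("i", 1:24)))
  rd[1, 1:2] <- 0.5
  nm <- fake_norm(rd, stdev = 0.05)
  cand <- candidate_windows(classify_windows(nm, params), nm, params)
  expect_equal(cand$direction, "LOSS")
  expect_equal(cand$n_carriers, 2L)

  # a single non-homozygous carrier is dropped
  rd[1, 2] <- 1
  nm <- fake_norm(rd, stdev = 0.05)
  expect_equal(nrow(candidate_windows(classify_windows(nm, params), nm, params)), 0)

  # 80 individuals, 3 homozygous deletions: freq 0.0375 < 0.05 but hom >= 3
  rd80 <- matrix(1, 1, 80, dimnames = list(NULL, paste0("i", 1:80)))
  rd80[1, 1:3] <- 0.1
  nm80 <- fake_norm(rd80, stdev = 0.05)
  cand80 <- candidate_windows(classify_windows(nm80, params), nm80, params)
  expect_equal(cand80$n_hom, 3L)
  expect_lt(cand80$freq, 0.05)
})

test_that("adjacent candidate windows merge on significant correlation", {
  v <- rep(c(0.4, 0.5, 0.6), 8)
  rd <- rbind(v, v, rep(0.5, 24))        # rows 1-2 identical (r = 1)
  rd[3, 1:12] <- 0.45                    # row 3 ~ uncorrelated with row 2
  colnames(rd) <- paste0("i", 1:24)
  nm <- fake_norm(rd, stdev = 0.05, grid = tiny_grid(3))
  cand <- data.frame(window = 1:3, chrom = "chr1",
                     start = c(0, 800, 1600), end = c(800, 1600, 2400),
                     direction = "LOSS", n_carriers = 24, freq = 1, n_hom = 0)
  segs <- merge_adjacent_windows(cand, nm, 0.05)
  expect_equal(segs$n_windows, c(2L, 1L))
  expect_equal(segs$start, c(0, 1600))
})

test_that("the merge boundary at alpha matches the t-distribution", {
  for (case in list(list(r = 0.41, alpha = 0.05, merged = TRUE),
                    list(r = 0.40, alpha = 0.05, merged = FALSE),
                    list(r = 0.52, alpha = 0.01, merged = TRUE),
                    list(r = 0.50, alpha = 0.01, merged = FALSE))) {
    v <- vectors_with_cor(case$r, n = 24)
    expect_equal(cor(v$x, v$y), case$r, tolerance = 1e-12)
    p_impl <- pearson_t_pvalue(v$x, v$y)
    expect_equal(p_impl, two_sided_cor_p_numeric(case$r, 24),
                 tolerance = 1e-8)
    rd <- rbind(v$x, v$y)
    colnames(rd) <- paste0("i", 1:24)
    nm <- fake_norm(rd, stdev = 0.05, grid = tiny_grid(2))
    cand <- data.frame(window = 1:2, chrom = "chr1", start = c(0, 800),
                       end = c(800, 1600), direction = "GAIN",
                       n_carriers = 24, freq = 1, n_hom = 0)
    segs <- merge_adjacent_windows(cand, nm, case$alpha)
    expect_equal(nrow(segs) == 1, case$merged, info = paste("r =", case$r))
  }
})

test_that("zero-variance windows never merge", {
  rd <- rbind(rep(0.5, 8), rep(0.5, 8))
  rd[1, ] <- c(0.4, 0.5, 0.4, 0.5, 0.4, 0.5, 0.4, 0.5)
  colnames(rd) <- paste0("i", 1:8)
  nm <- fake_norm(rd, stdev = 0.05, grid = tiny_grid(2))
  cand <- data.frame(window = 1:2, chrom = "chr1", start = c(0, 800),
                     end = c(800, 1600), direction = "LOSS",
                     n_carriers = 8, freq = 1, n_hom = 0)
  expect_equal(nrow(merge_adjacent_windows(cand, nm, 0.05)), 2)
})

test_that("window merging equals the brute-force union-find oracle", {
  for (seed in 1:4) {
    panel <- sim_small_panel(seed, n_shared = 8, n_unique = 3, n_divergent = 1,
                             chrom_mb = 0.48)  # about 50 windows per chrom
    nm <- normalize_depth(panel$raw)
    cc <- call_cnvs(nm)
    if (nrow(cc$candidates) == 0) next
    segs <- cc$segments
    oracle <- oracle_merge_adjacent(cc$candidates, nm, 0.05)
    got <- segs[order(segs$chrom, segs$start, segs$direction),
                c("chrom", "start", "end", "direction")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle, ignore_attr = TRUE)
  }
})

test_that("individual events respect the calling thresholds", {
  # one 3-window GAIN segment carried by one individual out of 8
  rd <- matrix(1, 3, 8, dimnames = list(NULL, paste0("i", 1:8)))
  rd[, 1] <- 2.0
  nm <- fake_norm(rd, stdev = 0.1, grid = tiny_grid(3))
  segs <- data.frame(chrom = "chr1", start = 0, end = 2400,
                     direction = "GAIN", first_window = 1L, last_window = 3L,
                     n_windows = 3L)
  ev <- call_individual_events(segs, nm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$individual, "i1")
  expect_equal(ev$end - ev$start, 2400)
  expect_equal(ev$state, "GAIN")

  # empty segment table -> no events
  expect_equal(nrow(call_individual_events(segs[0, ], nm)), 0)

  pm <- data.frame(individual = paste0("i", 1:8), population = "popA")
  s <- summarize_events(ev, pm)
  expect_equal(s$mean_length_kb, 2.4)
})

test_that("no LOSS event reaches 0.65 and no GAIN event falls to 1.35", {
  panel <- sim_small_panel(21)
  res <- run_cnv_pipeline(panel$raw, panel$truth$popmap)
  expect_gt(nrow(res$events), 0)
  expect_true(all(res$events$mean_rd[res$events$state == "LOSS"] < 0.65))
  expect_true(all(res$events$mean_rd[res$events$state == "GAIN"] > 1.35))
})
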