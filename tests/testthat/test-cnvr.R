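# Helper: wrap explicit call coordinates + RD rows into the structures
# merge_calls_to_cnvrs() consumes.
calls_fixture <- function(spans, rd_rows, n_windows_each = 1) {
  grid <- tiny_grid(length(spans) * 2 + 4)
  rd <- do.call(rbind, rd_rows)
  colnames(rd) <- paste0("i", seq_len(ncol(rd)))
  nm <- fake_norm(rd, stdev = 0.05, grid = grid[seq_len(nrow(rd)), ])
  calls <- do.call(rbind, lapply(seq_along(spans), function(i) {
    data.frame(chrom = "chr1", start = spans[[i]][1], end = spans[[i]][2],
               direction = "GAIN", first_window = i, last_window = i,
               n_windows = 1L)
  }))
  list(calls = calls, norm = nm)
}

test_that("calls merge when the gap rule and the correlation both pass", {
  v <- 1 + 0.1 * scale(seq_len(24))[, 1]
  # gap 100 < 0.2 * 1900, identical RD vectors -> one CNVR spanning both
  fx <- calls_fixture(list(c(0, 1000), c(1100, 2000)), list(v, v))
  got <- merge_calls_to_cnvrs(fx$calls, fx$norm)
  expect_equal(nrow(got), 1)
  expect_equal(c(got$start, got$end), c(0, 2000))

  # gap 500 > 0.2 * 1900 -> never merged, even at r = 1
  fx2 <- calls_fixture(list(c(0, 1000), c(1500, 2400)), list(v, v))
  expect_equal(nrow(merge_calls_to_cnvrs(fx2$calls, fx2$norm)), 2)
})

test_that("the CNVR correlation boundary respects alpha = 0.01", {
  for (case in list(list(r = 0.52, merged = TRUE),
                    list(r = 0.50, merged = FALSE))) {
    v <- vectors_with_cor(case$r, 24)
    fx <- calls_fixture(list(c(0, 1000), c(1100, 2000)), list(v$x, v$y))
    got <- merge_calls_to_cnvrs(fx$calls, fx$norm, alpha = 0.01)
    expect_equal(nrow(got) == 1, case$merged, info = paste("r =", case$r))
  }
})

test_that("CNVR type reflects the directions of its constituent calls", {
  v <- 1 + 0.1 * scale(seq_len(24))[, 1]
  fx <- calls_fixture(list(c(0, 1000), c(1100, 2000)), list(v, v))
  fx$calls$direction <- c("GAIN", "LOSS")
  got <- merge_calls_to_cnvrs(fx$calls, fx$norm)
  expect_equal(got$type, "BOTH")
})

test_that("CNVR merging equals the brute-force pairwise fixpoint oracle", {
  for (seed in c(3, 9, 14)) {
    panel <- sim_small_panel(seed, n_shared = 10, n_unique = 3,
                             n_divergent = 1, chrom_mb = 0.6)
    nm <- normalize_depth(panel$raw)
    cc <- call_cnvs(nm)
    if (nrow(cc$segments) < 2 || nrow(cc$segments) > 30) next
    got <- merge_calls_to_cnvrs(cc$segments, nm)
    oracle <- oracle_merge_cnvrs(cc$segments, nm, 0.2, 0.01)
    expect_equal(got[order(got$chrom, got$start), c("chrom", "start", "end", "n_calls")],
                 oracle, ignore_attr = TRUE)
    # every input call lands in exactly one CNVR
    members <- unlist(strsplit(got$call_ids, ","))
    expect_setequal(as.integer(members), seq_len(nrow(cc$segments)))
  }
})

test_that("population set accounting gives the expected Venn structure", {
  one <- function(start, end) {
    data.frame(id = "x", chrom = "chr1", start = start, end = end,
               type = "GAIN", n_calls = 1L, call_ids = "1", n_windows = 1L)
  }
  # identical region in 3 populations -> one shared component
  sets <- population_cnvr_sets(list(A = one(0, 800), B = one(0, 800),
                                    C = one(0, 800)))
  expect_equal(sets$n_union, 1)
  expect_equal(sets$venn$populations, "A&B&C")

  # pairwise-disjoint regions -> all unique
  sets2 <- population_cnvr_sets(list(A = one(0, 800), B = one(1600, 2400),
                                     C = one(4000, 4800)))
  expect_equal(sets2$n_union, 3)
  expect_setequal(sets2$venn$populations, c("A", "B", "C"))

  # A and B overlap, C disjoint
  sets3 <- population_cnvr_sets(list(A = one(0, 800), B = one(400, 1200),
                                     C = one(4000, 4800)))
  expect_setequal(sets3$venn$populations, c("A&B", "C"))

  # Venn counts always sum to the union count
  expect_equal(sum(sets3$venn$n), sets3$n_union)
})

test_that("Venn counts are invariant to population ordering", {
  panel <- sim_small_panel(31)
  res <- run_cnv_pipeline(panel$raw, panel$truth$popmap)
  lst <- lapply(res$per_population, `[[`, "cnvrs")
  a <- population_cnvr_sets(lst)
  b <- population_cnvr_sets(rev(lst))
  expect_equal(a$venn[order(a$venn$populations), ],
               b$venn[order(b$venn$populations), ], ignore_attr = TRUE)
  expect_equal(a$n_union, b$n_union)
})

test_that("size bins partition the length distribution", {
  s <- summarize_sizes(c(1500, 2500, 9000))
  expect_equal(s$fraction[s$bin == "(1e+03,2e+03]"], 1 / 3)
  expect_equal(sum(s$fraction), 1)
  s2 <- summarize_sizes(rep(800, 10))
  expect_equal(max(s2$fraction), 1)
  expect_error(summarize_sizes(numeric()), "no regions")
})

test_that("chromosome count regression matches hand-computed OLS", {
  fit <- chromosome_count_regression(c(1, 2, 4), c(100, 200, 300))
  # longhand: slope = Sxy/Sxx = 300/20000, R^2 = 1 - SSres/SStot
  expect_equal(fit$slope, 0.015)
  expect_equal(fit$r_squared, 1 - (0.16667 / 4.66667), tolerance = 1e-4)

  exact <- chromosome_count_regression(c(1, 2, 3), c(100, 200, 300))
  expect_equal(exact$r_squared, 1)
  flat <- chromosome_count_regression(c(2, 2, 2), c(100, 200, 300))
  expect_equal(flat$r_squared, 0)
  expect_error(chromosome_count_regression(c(1, 2, 3), c(5, 5, 5)), "variance")
})
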