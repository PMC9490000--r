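# Small in-code fixtures shared across test files.

tiny_grid <- function(n_windows = 10, window_size = 800, chrom = "chr1") {
  make_window_grid(genome_layout(chrom, n_windows * window_size), window_size)
}

# A normalized depth matrix fabricated directly, so tests can pin the
# per-individual STDEV and RD values exactly.
fake_norm <- function(rd, stdev, grid = tiny_grid(nrow(rd))) {
  ids <- colnames(rd)
  if (is.null(ids)) {
    ids <- paste0("ind", seq_len(ncol(rd)))
    colnames(rd) <- ids
  }
  structure(list(windows = as.data.frame(grid), depth = rd,
                 individuals = ids,
                 scale_factors = rep(1, ncol(rd)),
                 stdev = stats::setNames(rep_len(stdev, ncol(rd)), ids)),
            class = c("norm_depth_matrix", "depth_matrix"))
}

# Two vectors of length n with Pearson correlation exactly r
# (orthogonalized construction), shifted into positive RD territory.
vectors_with_cor <- function(r, n = 24) {
  x <- seq_len(n)
  z <- (seq_len(n) %% 2) * 2 - 1        # alternating, near-orthogonal to x
  xs <- as.numeric(scale(x))
  zr <- residuals(lm(z ~ xs))           # exactly orthogonal to xs
  zs <- zr / sqrt(sum(zr^2) / (n - 1))
  y <- r * xs + sqrt(1 - r^2) * zs
  list(x = 1 + 0.1 * xs, y = 1 + 0.1 * y)
}

sim_small_panel <- function(seed, n_shared = 12, n_unique = 4, n_divergent = 3,
                            chrom_mb = 1.2, noise = "poisson", ...) {
  grid <- make_window_grid(genome_layout(paste0("chr", 1:2),
                                         rep(chrom_mb * 1e6, 2)), 800)
  truth <- simulate_populations(grid, n_shared = n_shared,
                                n_unique = n_unique,
                                n_divergent = n_divergent, seed = seed, ...)
  raw <- simulate_depth(truth, 7, noise, seed = seed + 1)
  list(grid = grid, truth = truth, raw = raw)
}
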