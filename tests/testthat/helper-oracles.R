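# Independent oracles the implementation is checked against.

# Student-t upper-tail probability by numeric integration of the density
# (no call to pt()).
t_tail_numeric <- function(t, df) {
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  stats::integrate(dens, t, Inf, rel.tol = 1e-10)$value
}

two_sided_cor_p_numeric <- function(r, n) {
  t <- abs(r) * sqrt((n - 2) / (1 - r^2))
  2 * t_tail_numeric(t, n - 2)
}

# Brute-force adjacent-window merging: test every physically adjacent
# candidate pair with cor.test() and take union-find components.
oracle_merge_adjacent <- function(candidates, norm, alpha, individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  rd <- norm$depth[, individuals, drop = FALSE]
  win <- norm$windows
  out <- list()
  for (dir in unique(candidates$direction)) {
    w <- sort(candidates$window[candidates$direction == dir])
    parent <- stats::setNames(seq_along(w), w)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(max(length(w) - 1, 0))) {
      a <- w[k]; b <- w[k + 1]
      if (b != a + 1 || win$chrom[a] != win$chrom[b] ||
          win$start[b] != win$end[a]) next
      if (sd(rd[a, ]) == 0 || sd(rd[b, ]) == 0) next
      if (isTRUE(all.equal(abs(cor(rd[a, ], rd[b, ])), 1))) {
        p <- 0
      } else {
        p <- stats::cor.test(rd[a, ], rd[b, ])$p.value
      }
      if (p < alpha) parent[find(k + 1)] <- find(k)
    }
    comp <- vapply(seq_along(w), find, integer(1))
    for (ix in split(seq_along(w), comp)) {
      out[[length(out) + 1]] <- data.frame(
        chrom = win$chrom[w[ix[1]]], start = win$start[w[ix[1]]],
        end = win$end[w[ix[length(ix)]]], direction = dir,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$direction), , drop = FALSE]
}

# Brute-force call-to-CNVR fixpoint: scan all region pairs (in reverse
# order, unlike the implementation) and merge any qualifying pair until
# none is left.
oracle_merge_cnvrs <- function(calls, norm, gap_fraction, alpha,
                               individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  rd <- norm$depth[, individuals, drop = FALSE]
  regions <- lapply(seq_len(nrow(calls)), function(i) i)
  rdvec <- function(members) {
    rows <- unique(unlist(mapply(seq, calls$first_window[members],
                                 calls$last_window[members],
                                 SIMPLIFY = FALSE)))
    colMeans(rd[rows, , drop = FALSE])
  }
  repeat {
    n <- length(regions)
    hit <- NULL
    if (n >= 2) {
      for (i in rev(seq_len(n - 1))) {
        for (j in rev(seq((i + 1), n))) {
          ci <- calls$chrom[regions[[i]][1]]
          cj <- calls$chrom[regions[[j]][1]]
          if (ci != cj) next
          si <- min(calls$start[regions[[i]]]); ei <- max(calls$end[regions[[i]]])
          sj <- min(calls$start[regions[[j]]]); ej <- max(calls$end[regions[[j]]])
          gap <- max(max(si, sj) - min(ei, ej), 0)
          if (gap >= gap_fraction * ((ei - si) + (ej - sj))) next
          a <- rdvec(regions[[i]]); b <- rdvec(regions[[j]])
          if (sd(a) == 0 || sd(b) == 0) next
          p <- if (isTRUE(all.equal(abs(cor(a, b)), 1))) 0 else
            stats::cor.test(a, b)$p.value
          if (p < alpha) { hit <- c(i, j); break }
        }
        if (!is.null(hit)) break
      }
    }
    if (is.null(hit)) break
    merged <- c(regions[[hit[1]]], regions[[hit[2]]])
    regions <- c(regions[-hit], list(merged))
  }
  out <- do.call(rbind, lapply(regions, function(m) {
    data.frame(chrom = calls$chrom[m[1]], start = min(calls$start[m]),
               end = max(calls$end[m]), n_calls = length(m),
               stringsAsFactors = FALSE)
  }))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
oracle_hyper_upper <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  in_term <- seq_len(K)                 # first K elements carry the term
  hits <- colSums(matrix(draws %in% in_term, nrow = n))
  mean(hits >= k)
}

# Variance decomposition for Vst written out longhand.
oracle_vst <- function(a, b) {
  ss <- function(x) sum((x - mean(x))^2) / (length(x) - 1)
  vt <- ss(c(a, b))
  (vt - (ss(a) * length(a) + ss(b) * length(b)) / (length(a) + length(b))) / vt
}
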