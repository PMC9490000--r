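# Internal helpers shared across stages.

# Population (ddof = 0) standard deviation; `sd()` uses n-1 which is not
# what the per-individual STDEV of normalized depth is defined as here.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Two-sided p-value for a Pearson correlation under the t distribution
#'
#' Used by both merging stages: two depth vectors are considered
#' significantly correlated when the two-sided p-value of
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' falls strictly below the chosen alpha.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @return the two-sided p-value, or `NA` when either vector has zero
#'   variance (correlation undefined; callers must not merge).
#' @examples
#' pearson_t_pvalue(1:6, c(2, 4, 5, 7, 9, 12))
#' @export
pearson_t_pvalue <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("correlation test requires at least 4 individuals")
  if (pop_sd(x) == 0 || pop_sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  if (!is.finite(r)) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# data.frame of half-open regions -> GRanges (1-based closed, as the
# Bioconductor stack expects).
regions_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Mean feature length in kilobases
#'
#' Reports total length / count in kb, rounded to 2 decimals — the unit
#' summary tables in this field print for mean CNV and CNVR sizes.
#'
#' @param total_length_bp summed feature length in base pairs.
#' @param count number of features (> 0).
#' @export
mean_length_kb <- function(total_length_bp, count) {
  if (count <= 0) stop("count must be positive")
  round(total_length_bp / count / 1000, 2)
}

#' Percentage of regions overlapped, to two decimals
#'
#' @param n_overlapping number of regions in the comparison set overlapped.
#' @param n_total size of the comparison set (> 0).
#' @export
overlap_percentage <- function(n_overlapping, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  round(100 * n_overlapping / n_total, 2)
}
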