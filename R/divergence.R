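#' Vst: population differentiation of copy number
#'
#' `Vst = (Vtotal - (Vpop1*Npop1 + Vpop2*Npop2)/Ntotal) / Vtotal`, the
#' copy-number analogue of Fst: 1 for a fixed difference between the two
#' populations, near 0 when the pooled distribution shows no
#' between-population structure.  All three variances are unbiased
#' sample variances (divisor n - 1); negative values, which arise when
#' within-population variance exceeds the pooled variance, are reported
#' as computed, not clamped.  When `Vtotal = 0` the statistic is
#' undefined and the record is flagged (`defined = FALSE`).
#'
#' @param values_pop1,values_pop2 per-individual values (mean normalized
#'   RD over a CNVR) for the two populations; each needs >= 2 values.
#' @return one-row data.frame: `vst`, `v_total`, `v_pop1`, `v_pop2`,
#'   `n_pop1`, `n_pop2`, `n_total`, `defined`.
#' @examples
#' vst(rep(1, 8), rep(2, 8))$vst # fixed difference -> 1
#' @export
vst <- function(values_pop1, values_pop2) {
  n1 <- length(values_pop1); n2 <- length(values_pop2)
  if (n1 < 2 || n2 < 2) stop("each population needs at least 2 values")
  v1 <- stats::var(values_pop1)
  v2 <- stats::var(values_pop2)
  vt <- stats::var(c(values_pop1, values_pop2))
  nt <- n1 + n2
  defined <- vt > 0
  v <- if (defined) (vt - (v1 * n1 + v2 * n2) / nt) / vt else NA_real_
  data.frame(vst = v, v_total = vt, v_pop1 = v1, v_pop2 = v2,
             n_pop1 = n1, n_pop2 = n2, n_total = nt, defined = defined)
}

#' Vst scan over a CNVR set for one population pair
#'
#' Each individual's value for a CNVR is the mean normalized RD over the
#' grid windows the region spans (`value = "log2"` uses
#' `log2(pmax(RD, eps))` instead, the array-era log-ratio convention).
#' Records are ranked by Vst (descending, undefined last); the
#' genome-wide mean is taken over defined records only.  Both selection
#' conventions in use — the top `top_k` regions and the top
#' `top_fraction` quantile — are returned.
#'
#' @param cnvrs data.frame `chrom`, `start`, `end`, ideally `id`.
#' @param norm the normalized depth matrix.
#' @param popmap data.frame `individual`, `population`.
#' @param pair character vector of two population names.
#' @param top_k number of top regions to flag (default 5).
#' @param top_fraction top quantile to flag (default 0.01).
#' @param value `"rd"` (default) or `"log2"`.
#' @param eps floor applied to RD before log2 (default 0.01).
#' @return list: `records` (per-CNVR Vst decomposition, ranked),
#'   `mean_vst`, `top_k`, `top_fraction` (data.frames of selected rows).
#' @export
vst_scan <- function(cnvrs, norm, popmap, pair, top_k = 5,
                     top_fraction = 0.01, value = c("rd", "log2"),
                     eps = 0.01) {
  value <- match.arg(value)
  stopifnot(length(pair) == 2)
  ids1 <- popmap$individual[popmap$population == pair[1]]
  ids2 <- popmap$individual[popmap$population == pair[2]]
  if (length(ids1) < 2 || length(ids2) < 2) {
    stop("both populations need at least 2 individuals")
  }
  miss <- setdiff(c(ids1, ids2), norm$individuals)
  if (length(miss)) stop("individuals absent from depth matrix: ",
                         paste(miss, collapse = ", "))
  ids <- if ("id" %in% names(cnvrs)) cnvrs$id else as.character(seq_len(nrow(cnvrs)))
  win <- norm$windows
  recs <- do.call(rbind, lapply(seq_len(nrow(cnvrs)), function(i) {
    rows <- which(win$chrom == cnvrs$chrom[i] &
                    win$start < cnvrs$end[i] & win$end > cnvrs$start[i])
    if (!length(rows)) return(NULL)
    m <- colMeans(norm$depth[rows, , drop = FALSE])
    if (value == "log2") m <- log2(pmax(m, eps))
    r <- vst(m[ids1], m[ids2])
    cbind(data.frame(cnvr_id = ids[i], chrom = cnvrs$chrom[i],
                     start = cnvrs$start[i], end = cnvrs$end[i],
                     pop1 = pair[1], pop2 = pair[2],
                     stringsAsFactors = FALSE), r)
  }))
  if (is.null(recs)) stop("no CNVR overlaps any grid window")
  recs <- recs[order(-ifelse(recs$defined, recs$vst, -Inf)), , drop = FALSE]
  rownames(recs) <- NULL
  defined <- recs[recs$defined, , drop = FALSE]
  k_frac <- ceiling(top_fraction * nrow(defined))
  list(records = recs,
       mean_vst = if (nrow(defined)) mean(defined$vst) else NA_real_,
       top_k = utils::head(defined, top_k),
       top_fraction = utils::head(defined, k_frac))
}
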