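#' Merge CNV calls into CNV regions (CNVRs)
#'
#' Two neighbouring calls on the same chromosome merge when (i) the gap
#' between them is less than `gap_fraction` of their combined length
#' (distance = bases between the end of the left call and the start of
#' the right one, 0 when they touch or overlap; combined length = sum of
#' the two region lengths) and (ii) the Pearson correlation of their
#' per-individual mean RD vectors is significant at two-sided
#' p < `alpha`.  Merging is a pairwise fixpoint: after every merge all
#' pairs are reconsidered with the merged region's RD recomputed over its
#' member windows, until no pair qualifies, so the result does not depend
#' on input order.  A pair whose correlation is undefined (constant RD)
#' never merges.
#'
#' @param calls a `cnv_segments` data.frame from
#'   [merge_adjacent_windows()] (both directions may be mixed).
#' @param norm the normalized depth matrix the calls were made from.
#' @param gap_fraction maximum gap as a fraction of combined length
#'   (default 0.2).
#' @param alpha correlation significance level (default 0.01, strict).
#' @param individuals analysis group (default all).
#' @return a `cnvr_set` data.frame: `id`, `chrom`, `start`, `end`,
#'   `type` (GAIN/LOSS/BOTH), `n_calls`, `call_ids` (comma-separated row
#'   indices of `calls`), `n_windows`.
#' @export
merge_calls_to_cnvrs <- function(calls, norm, gap_fraction = 0.2,
                                 alpha = 0.01, individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  rd <- norm$depth[, individuals, drop = FALSE]
  empty <- data.frame(id = character(), chrom = character(),
                      start = numeric(), end = numeric(), type = character(),
                      n_calls = integer(), call_ids = character(),
                      n_windows = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("cnvr_set", "data.frame")
  if (nrow(calls) == 0) return(empty)

  # region state: members = indices into `calls`
  regions <- lapply(seq_len(nrow(calls)), function(i) list(members = i))
  region_info <- function(reg) {
    m <- calls[reg$members, , drop = FALSE]
    rows <- unique(unlist(mapply(seq, m$first_window, m$last_window,
                                 SIMPLIFY = FALSE)))
    list(chrom = m$chrom[1], start = min(m$start), end = max(m$end),
         rows = rows, rdvec = colMeans(rd[rows, , drop = FALSE]),
         members = reg$members)
  }
  info <- lapply(regions, region_info)

  repeat {
    ord <- order(match(vapply(info, `[[`, "", "chrom"), unique(calls$chrom)),
                 vapply(info, `[[`, 0, "start"))
    info <- info[ord]
    n <- length(info)
    merged <- FALSE
    chroms <- vapply(info, `[[`, "", "chrom")
    starts <- vapply(info, `[[`, 0, "start")
    ends <- vapply(info, `[[`, 0, "end")
    lens <- ends - starts
    for (i in seq_len(max(n - 1, 0))) {
      for (j in seq(i + 1, n)) {
        if (chroms[j] != chroms[i]) break
        gap <- max(starts[j], starts[i]) - min(ends[i], ends[j])
        gap <- max(gap, 0)
        if (gap >= gap_fraction * (lens[i] + lens[j])) next
        p <- pearson_t_pvalue(info[[i]]$rdvec, info[[j]]$rdvec)
        if (is.na(p) || p >= alpha) next
        keep <- info[-c(i, j)]
        new <- region_info(list(members = c(info[[i]]$members,
                                            info[[j]]$members)))
        info <- c(keep, list(new))
        merged <- TRUE
        break
      }
      if (merged) break
    }
    if (!merged) break
  }

  ord <- order(match(vapply(info, `[[`, "", "chrom"), unique(calls$chrom)),
               vapply(info, `[[`, 0, "start"))
  info <- info[ord]
  out <- do.call(rbind, lapply(seq_along(info), function(k) {
    r <- info[[k]]
    dirs <- unique(calls$direction[r$members])
    data.frame(id = paste0("cnvr_", k), chrom = r$chrom, start = r$start,
               end = r$end,
               type = if (length(dirs) == 1) dirs else "BOTH",
               n_calls = length(r$members),
               call_ids = paste(sort(r$members), collapse = ","),
               n_windows = length(r$rows), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cnvr_set", "data.frame")
  out
}

#' Shared and population-specific CNVRs across populations
#'
#' CNVRs from different populations are treated as the same region when
#' they overlap by at least one base (`min_reciprocal` raises this to a
#' reciprocal-fraction rule for sensitivity analysis).  The union graph's
#' connected components, labelled by the populations contributing to
#' each, give the Venn counts: components sum to the union count by
#' construction.
#'
#' @param cnvr_list named list of per-population `cnvr_set` data.frames.
#' @param min_reciprocal minimum reciprocal overlap fraction for two
#'   regions to match (default 0: any >= 1 bp overlap).
#' @return list with `n_union`, `venn` (data.frame `populations`, `n`),
#'   and `union_cnvrs` (component spans with `type` and `populations`).
#' @export
population_cnvr_sets <- function(cnvr_list, min_reciprocal = 0) {
  if (is.null(names(cnvr_list)) || any(names(cnvr_list) == "")) {
    stop("cnvr_list must be a named list (one element per population)")
  }
  if (length(cnvr_list) < 2) stop("need at least 2 populations")
  all <- do.call(rbind, lapply(names(cnvr_list), function(p) {
    x <- as.data.frame(cnvr_list[[p]])
    if (nrow(x) == 0) return(NULL)
    x$population <- p
    x[, c("chrom", "start", "end", "type", "population")]
  }))
  if (is.null(all) || nrow(all) == 0) {
    return(list(n_union = 0L,
                venn = data.frame(populations = character(), n = integer()),
                union_cnvrs = data.frame(chrom = character(), start = numeric(),
                                         end = numeric(), type = character(),
                                         populations = character(),
                                         n_members = integer())))
  }
  gr <- regions_to_granges(all)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  keep <- qi < si
  qi <- qi[keep]; si <- si[keep]
  if (min_reciprocal > 0 && length(qi)) {
    ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr)[qi],
                                             IRanges::ranges(gr)[si]))
    frac_ok <- ov >= min_reciprocal * (all$end - all$start)[qi] &
      ov >= min_reciprocal * (all$end - all$start)[si]
    qi <- qi[frac_ok]; si <- si[frac_ok]
  }
  # union-find over regions
  parent <- seq_len(nrow(all))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(qi)) {
    a <- find(qi[k]); b <- find(si[k])
    if (a != b) parent[b] <- a
  }
  comp <- vapply(seq_len(nrow(all)), find, integer(1))
  split_idx <- split(seq_len(nrow(all)), comp)
  union_cnvrs <- do.call(rbind, lapply(split_idx, function(ix) {
    types <- unique(all$type[ix])
    data.frame(chrom = all$chrom[ix][1], start = min(all$start[ix]),
               end = max(all$end[ix]),
               type = if (length(types) == 1) types else "BOTH",
               populations = paste(sort(unique(all$population[ix])), collapse = "&"),
               n_members = length(ix), stringsAsFactors = FALSE)
  }))
  union_cnvrs <- union_cnvrs[order(match(union_cnvrs$chrom, unique(all$chrom)),
                                   union_cnvrs$start), , drop = FALSE]
  rownames(union_cnvrs) <- NULL
  venn_tab <- table(union_cnvrs$populations)
  venn <- data.frame(populations = names(venn_tab),
                     n = as.integer(venn_tab), stringsAsFactors = FALSE)
  list(n_union = nrow(union_cnvrs), venn = venn, union_cnvrs = union_cnvrs)
}

#' Default size-bin edges (bp) for CNV events and CNVRs
#'
#' Events are conventionally binned 0-2 / 2-4 / >4 kb and regions
#' <1 / 1-2 / 2-4 / 4-6 / 6-8 / >8 kb.
#' @name size_bins
#' @export
cnv_size_breaks <- c(0, 2000, 4000, Inf)

#' @rdname size_bins
#' @export
cnvr_size_breaks <- c(0, 1000, 2000, 4000, 6000, 8000, Inf)

#' Fraction of features per size bin
#'
#' @param lengths feature lengths in bp (non-empty).
#' @param breaks ascending bin edges covering all lengths; bins are
#'   left-open right-closed `(a, b]` so a 2000-bp feature falls in the
#'   1-2 kb bin.
#' @return data.frame `bin`, `n`, `fraction` (fractions sum to 1).
#' @export
summarize_sizes <- function(lengths, breaks = cnvr_size_breaks) {
  if (length(lengths) == 0) stop("no regions to summarize")
  cuts <- cut(lengths, breaks = breaks, include.lowest = TRUE)
  tab <- table(cuts)
  data.frame(bin = names(tab), n = as.integer(tab),
             fraction = as.numeric(tab) / length(lengths),
             stringsAsFactors = FALSE)
}

#' Regress per-chromosome CNVR counts on chromosome length
#'
#' Ordinary least squares of count on length (bp);
#' `R^2 = 1 - SSres/SStot`.
#'
#' @param counts CNVR count per chromosome.
#' @param lengths chromosome length per chromosome (same order).
#' @return list `slope`, `intercept`, `r_squared`.
#' @export
chromosome_count_regression <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("counts and lengths differ in length")
  if (length(counts) < 3) stop("need at least 3 chromosomes")
  if (stats::var(lengths) == 0) stop("chromosome lengths have zero variance")
  fit <- stats::lm(counts ~ lengths)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((counts - mean(counts))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       # constant counts carry no explainable variance: R^2 = 0
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot)
}

#' Table-style summary of one CNVR set
#'
#' @param cnvrs a `cnvr_set` data.frame.
#' @param genome the [genome_layout()] the regions live on (for the
#'   genome-fraction percentage); optional.
#' @return one-row data.frame: counts by type, total length (Mb), mean
#'   length (kb) and percentage of the genome covered.
#' @export
cnvr_summary <- function(cnvrs, genome = NULL) {
  tot <- sum(cnvrs$end - cnvrs$start)
  data.frame(
    n_cnvr = nrow(cnvrs),
    n_gain = sum(cnvrs$type == "GAIN"),
    n_loss = sum(cnvrs$type == "LOSS"),
    n_both = sum(cnvrs$type == "BOTH"),
    total_length_mb = round(tot / 1e6, 2),
    mean_length_kb = if (nrow(cnvrs)) mean_length_kb(tot, nrow(cnvrs)) else NA_real_,
    genome_fraction_pct = if (is.null(genome)) NA_real_ else
      round(100 * tot / sum(genome$length), 2)
  )
}
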