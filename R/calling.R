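#' Parameters for window classification and CNV calling
#'
#' Two conjunctive criteria define a CNV window for one individual: a
#' statistical one (normalized RD beyond `1 -/+ stdev_mult * STDEV` of that
#' individual) and an empirical one anchored on the expected RD of
#' heterozygous events (deletion RD < `del_cutoff`, duplication RD >
#' `dup_cutoff`; heterozygous states sit near 0.5 and 1.5).  Population
#' filtering keeps windows with carrier frequency >= `min_freq` or at
#' least `min_hom` homozygous carriers; homozygosity is read off RD
#' (`< hom_del_rd` for double deletion, `> hom_dup_rd` for a two-copy
#' gain — midpoints between the RD expected for copy numbers 0/1 and 3/4).
#'
#' @param del_cutoff empirical deletion RD ceiling (default 0.65).
#' @param dup_cutoff empirical duplication RD floor (default 1.35).
#' @param stdev_mult multiplier on the per-individual STDEV (default 2).
#' @param min_freq minimum carrier frequency (default 0.05).
#' @param min_hom minimum homozygous carriers (default 3).
#' @param hom_del_rd RD ceiling for a homozygous deletion (default 0.25).
#' @param hom_dup_rd RD floor for a homozygous duplication (default 1.75).
#' @param merge_alpha significance level for merging adjacent candidate
#'   windows by Pearson correlation (default 0.05, strict inequality).
#' @return a validated `calling_params` list.
#' @export
calling_params <- function(del_cutoff = 0.65, dup_cutoff = 1.35,
                           stdev_mult = 2, min_freq = 0.05, min_hom = 3,
                           hom_del_rd = 0.25, hom_dup_rd = 1.75,
                           merge_alpha = 0.05) {
  stopifnot(del_cutoff > 0, del_cutoff < 1, dup_cutoff > 1,
            stdev_mult > 0, min_freq > 0, min_freq <= 1, min_hom >= 1,
            hom_del_rd > 0, hom_del_rd < del_cutoff,
            hom_dup_rd > dup_cutoff,
            merge_alpha > 0, merge_alpha < 1)
  structure(list(del_cutoff = del_cutoff, dup_cutoff = dup_cutoff,
                 stdev_mult = stdev_mult, min_freq = min_freq,
                 min_hom = min_hom, hom_del_rd = hom_del_rd,
                 hom_dup_rd = hom_dup_rd, merge_alpha = merge_alpha),
            class = "calling_params")
}

#' Classify every (window, individual) cell as LOSS, NORMAL or GAIN
#'
#' LOSS iff RD < 1 - m*STDEV AND RD < del_cutoff; GAIN iff
#' RD > 1 + m*STDEV AND RD > dup_cutoff; otherwise NORMAL.  Both
#' criteria must hold (conjunctive).
#'
#' @param norm a [normalize_depth()] result.
#' @param params a [calling_params()].
#' @return an integer matrix (windows x individuals) coded
#'   -1 = LOSS, 0 = NORMAL, +1 = GAIN, class `window_states`.
#' @export
classify_windows <- function(norm, params = calling_params()) {
  if (!inherits(norm, "norm_depth_matrix")) stop("norm must be a normalized depth matrix")
  rd <- norm$depth
  lo <- rep(1 - params$stdev_mult * norm$stdev, each = nrow(rd))
  hi <- rep(1 + params$stdev_mult * norm$stdev, each = nrow(rd))
  states <- matrix(0L, nrow(rd), ncol(rd), dimnames = dimnames(rd))
  states[rd < lo & rd < params$del_cutoff] <- -1L
  states[rd > hi & rd > params$dup_cutoff] <- 1L
  class(states) <- c("window_states", class(states))
  states
}

#' Population-level candidate windows
#'
#' A window is a candidate in a direction iff, among the analysed
#' individuals, carrier frequency >= `min_freq` OR at least `min_hom`
#' carriers are homozygous in that direction.  Each direction is
#' evaluated separately, so a window can be both a GAIN and a LOSS
#' candidate (different carriers).
#'
#' @param states a [classify_windows()] matrix.
#' @param norm the matching normalized depth matrix.
#' @param params a [calling_params()].
#' @param individuals optional subset of individual ids defining the
#'   analysis group (default: all), e.g. one population at a time.
#' @return data.frame with one row per (window, direction) candidate:
#'   `window` (row index in `norm$windows`), `chrom`, `start`, `end`,
#'   `direction`, `n_carriers`, `freq`, `n_hom`.
#' @export
candidate_windows <- function(states, norm, params = calling_params(),
                              individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  miss <- setdiff(individuals, norm$individuals)
  if (length(miss)) stop("unknown individual(s): ", paste(miss, collapse = ", "))
  st <- states[, individuals, drop = FALSE]
  rd <- norm$depth[, individuals, drop = FALSE]
  n <- length(individuals)

  one_direction <- function(code, hom_mask, direction) {
    carriers <- rowSums(st == code)
    n_hom <- rowSums((st == code) & hom_mask)
    freq <- carriers / n
    keep <- carriers > 0 & (freq >= params$min_freq | n_hom >= params$min_hom)
    if (!any(keep)) return(NULL)
    idx <- which(keep)
    data.frame(window = idx,
               chrom = norm$windows$chrom[idx],
               start = norm$windows$start[idx],
               end = norm$windows$end[idx],
               direction = direction,
               n_carriers = carriers[idx],
               freq = freq[idx],
               n_hom = n_hom[idx],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_direction(-1L, rd < params$hom_del_rd, "LOSS"),
    one_direction(1L, rd > params$hom_dup_rd, "GAIN")
  )
  if (is.null(out)) {
    out <- data.frame(window = integer(), chrom = character(),
                      start = numeric(), end = numeric(),
                      direction = character(), n_carriers = integer(),
                      freq = numeric(), n_hom = integer())
  }
  out[order(out$window, out$direction), , drop = FALSE]
}

#' Merge adjacent candidate windows into calls by Pearson correlation
#'
#' Consecutive candidate windows of the same direction that are physically
#' adjacent on the grid are merged into one call when the Pearson
#' correlation of their across-individual RD vectors is significant at
#' two-sided p < alpha (t test, df = n - 2); merging is transitive left to
#' right.  A window pair whose correlation is undefined (zero variance) is
#' never merged.  Singleton candidates become single-window calls.
#'
#' @param candidates a [candidate_windows()] data.frame.
#' @param norm the normalized depth matrix.
#' @param alpha significance level (strict inequality).
#' @param individuals analysis group (default all; must match the group
#'   used for `candidates`).
#' @return a `cnv_segments` data.frame: `chrom`, `start`, `end`,
#'   `direction`, `first_window`, `last_window`, `n_windows`.
#' @export
merge_adjacent_windows <- function(candidates, norm, alpha = 0.05,
                                   individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  rd <- norm$depth[, individuals, drop = FALSE]
  win <- norm$windows
  segs <- list()
  for (dir in unique(candidates$direction)) {
    cw <- candidates[candidates$direction == dir, , drop = FALSE]
    cw <- cw[order(cw$window), , drop = FALSE]
    i <- 1
    while (i <= nrow(cw)) {
      first <- cw$window[i]
      last <- first
      while (i < nrow(cw)) {
        a <- cw$window[i]; b <- cw$window[i + 1]
        adjacent <- (b == a + 1) &&
          win$chrom[b] == win$chrom[a] && win$start[b] == win$end[a]
        if (!adjacent) break
        p <- pearson_t_pvalue(rd[a, ], rd[b, ])
        if (is.na(p) || p >= alpha) break
        last <- b
        i <- i + 1
      }
      segs[[length(segs) + 1]] <- data.frame(
        chrom = win$chrom[first], start = win$start[first],
        end = win$end[last], direction = dir,
        first_window = first, last_window = last,
        n_windows = last - first + 1L, stringsAsFactors = FALSE)
      i <- i + 1
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else {
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               direction = character(), first_window = integer(),
               last_window = integer(), n_windows = integer())
  }
  out <- out[order(match(out$chrom, unique(win$chrom)), out$start, out$direction), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cnv_segments", "data.frame")
  out
}

# Per-individual mean normalized RD over each segment's windows.
segment_mean_rd <- function(segments, norm, individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  rd <- norm$depth[, individuals, drop = FALSE]
  t(vapply(seq_len(nrow(segments)), function(i) {
    rows <- segments$first_window[i]:segments$last_window[i]
    colMeans(rd[rows, , drop = FALSE])
  }, numeric(length(individuals))))
}

#' Per-individual CNV events from merged calls
#'
#' For every (segment, individual) pair an event is emitted when the
#' individual's segment-mean RD passes the window-classification
#' thresholds (conjunctive statistical + empirical criteria, using that
#' individual's STDEV).
#'
#' @param segments a [merge_adjacent_windows()] result.
#' @param norm the normalized depth matrix.
#' @param params a [calling_params()].
#' @param individuals analysis group (default all).
#' @return data.frame of events: `individual`, `chrom`, `start`, `end`,
#'   `state` (GAIN/LOSS), `mean_rd`, `segment` (row index into
#'   `segments`).
#' @export
call_individual_events <- function(segments, norm, params = calling_params(),
                                   individuals = NULL) {
  if (is.null(individuals)) individuals <- norm$individuals
  empty <- data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(), state = character(),
                      mean_rd = numeric(), segment = integer())
  if (nrow(segments) == 0) return(empty)
  m <- segment_mean_rd(segments, norm, individuals)
  sdv <- norm$stdev[individuals]
  out <- list()
  for (j in seq_along(individuals)) {
    rdj <- m[, j]
    loss <- rdj < 1 - params$stdev_mult * sdv[j] & rdj < params$del_cutoff
    gain <- rdj > 1 + params$stdev_mult * sdv[j] & rdj > params$dup_cutoff
    hit <- which(loss | gain)
    if (!length(hit)) next
    out[[length(out) + 1]] <- data.frame(
      individual = individuals[j],
      chrom = segments$chrom[hit], start = segments$start[hit],
      end = segments$end[hit],
      state = ifelse(loss[hit], "LOSS", "GAIN"),
      mean_rd = rdj[hit], segment = hit, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' One-call window-to-segment stage for one analysis group
#'
#' Runs [classify_windows()], [candidate_windows()] and
#' [merge_adjacent_windows()] for one set of individuals.
#'
#' @inheritParams candidate_windows
#' @return list with `candidates` and `segments`.
#' @export
call_cnvs <- function(norm, params = calling_params(), individuals = NULL) {
  states <- classify_windows(norm, params)
  cand <- candidate_windows(states, norm, params, individuals)
  segs <- merge_adjacent_windows(cand, norm, params$merge_alpha, individuals)
  list(candidates = cand, segments = segs)
}

#' Per-population summary of individual CNV events
#'
#' @param events a [call_individual_events()] data.frame (any number of
#'   populations pooled).
#' @param popmap data.frame `individual`, `population`.
#' @return data.frame per population: event count, gains, losses, total
#'   length (Mb) and mean length (kb).
#' @export
summarize_events <- function(events, popmap) {
  pops <- unique(popmap$population)
  rows <- lapply(pops, function(p) {
    ids <- popmap$individual[popmap$population == p]
    ev <- events[events$individual %in% ids, , drop = FALSE]
    tot <- sum(ev$end - ev$start)
    data.frame(population = p, n_events = nrow(ev),
               n_gain = sum(ev$state == "GAIN"),
               n_loss = sum(ev$state == "LOSS"),
               total_length_mb = round(tot / 1e6, 2),
               mean_length_kb = if (nrow(ev)) mean_length_kb(tot, nrow(ev)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
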