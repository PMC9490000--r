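#' Genome layout: ordered chromosomes and their lengths
#'
#' @param chrom character vector of unique chromosome names, in the order
#'   windows should be emitted.
#' @param length positive integer length (bp) per chromosome.
#' @return a `genome_layout` data.frame with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2400, 2000))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0) stop("genome layout is empty")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("chromosome lengths must be positive")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' Read a genome layout from a two-column TSV (or a FASTA .fai)
#'
#' Only the first two columns (`chrom`, `length`) are used, so a samtools
#' `.fai` index is accepted as-is.
#'
#' @param path file path.
#' @export
read_genome_layout <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("genome layout file needs at least 2 columns")
  genome_layout(tab[[1]], tab[[2]])
}

#' Tile a genome into fixed, non-overlapping windows
#'
#' Each chromosome contributes `floor(length / window_size)` windows of
#' exactly `window_size` bp; the trailing partial window is dropped, as
#' fixed-width sliding-window CNV callers do.  Coordinates are 0-based
#' half-open.
#'
#' @param genome a [genome_layout()].
#' @param window_size window width in bp (default 800, the conventional
#'   read-depth CNV window for ~7x resequencing panels).
#' @return a `window_grid` data.frame with columns `chrom`, `start`, `end`
#'   and attribute `window_size`.
#' @examples
#' make_window_grid(genome_layout("chr1", 2400), 800)
#' @export
make_window_grid <- function(genome, window_size = 800) {
  if (!inherits(genome, "genome_layout")) genome <- genome_layout(genome$chrom, genome$length)
  window_size <- as.integer(window_size)
  if (is.na(window_size) || window_size < 1) stop("window_size must be a positive integer")
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    n <- floor(genome$length[i] / window_size)
    if (n == 0) return(NULL)
    start <- (seq_len(n) - 1) * window_size
    data.frame(chrom = genome$chrom[i], start = start,
               end = start + window_size, stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  if (is.null(grid)) {
    grid <- data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  rownames(grid) <- NULL
  structure(grid, class = c("window_grid", "data.frame"),
            window_size = window_size)
}

#' Construct a raw depth matrix bound to a window grid
#'
#' @param grid a [make_window_grid()] result (rows define windows).
#' @param depth numeric matrix, `nrow(grid)` x individuals, of mean
#'   per-window depth (reads-per-base equivalents, all finite and >= 0).
#' @param individuals individual identifiers (default: `colnames(depth)`).
#' @return a `depth_matrix` object: list with `windows`, `depth`,
#'   `individuals`.
#' @export
depth_matrix <- function(grid, depth, individuals = colnames(depth)) {
  depth <- as.matrix(depth)
  if (nrow(depth) != nrow(grid)) {
    stop("depth matrix has ", nrow(depth), " rows but the grid has ",
         nrow(grid), " windows")
  }
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(depth)))
  if (anyDuplicated(individuals)) stop("individual ids must be unique")
  if (any(!is.finite(depth))) stop("depth values must be finite")
  if (any(depth < 0)) stop("depth values must be >= 0")
  colnames(depth) <- individuals
  structure(
    list(windows = as.data.frame(grid), depth = depth,
         individuals = as.character(individuals)),
    class = "depth_matrix"
  )
}

#' @export
print.depth_matrix <- function(x, ...) {
  kind <- if (inherits(x, "norm_depth_matrix")) "normalized" else "raw"
  cat(sprintf("<%s depth matrix> %d windows x %d individuals\n",
              kind, nrow(x$depth), ncol(x$depth)))
  invisible(x)
}

#' Read a per-window depth matrix from TSV
#'
#' Expected dialect: tab-separated, header
#' `chrom start end <id1> ... <idN>`, starts 0-based, optional leading `#`
#' comment lines.  Every grid window must be present (keyed by
#' `chrom`/`start`); missing windows are an error, never imputed.
#'
#' @param path file path.
#' @param grid the window grid the matrix must align to.
#' @return a [depth_matrix()].
#' @export
read_depth_matrix <- function(path, grid) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(tab)[1:3])) {
    stop("depth TSV must start with columns chrom, start, end")
  }
  ids <- names(tab)[-(1:3)]
  if (length(ids) == 0) stop("depth TSV names no individuals")
  key_file <- paste(tab$chrom, tab$start)
  key_grid <- paste(grid$chrom, grid$start)
  idx <- match(key_grid, key_file)
  if (anyNA(idx)) {
    miss <- which(is.na(idx))[1]
    stop(sprintf("depth TSV is missing grid window %s:%d-%d",
                 grid$chrom[miss], grid$start[miss], grid$end[miss]))
  }
  vals <- as.matrix(tab[idx, ids, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- NULL
  if (any(!is.finite(vals))) stop("depth TSV contains non-numeric or non-finite values")
  if (any(vals < 0)) stop("depth TSV contains negative values")
  depth_matrix(grid, vals, ids)
}

#' Write a depth matrix in the TSV dialect [read_depth_matrix()] consumes
#'
#' @param x a `depth_matrix`.
#' @param path output path.
#' @export
write_depth_matrix <- function(x, path) {
  out <- cbind(x$windows[, c("chrom", "start", "end")],
               as.data.frame(x$depth, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Drop windows with systematically low coverage
#'
#' Windows whose across-individual mean raw depth falls below
#' `min_fraction` of the grand mean are removed before normalization;
#' such windows sit in unmappable or absent sequence and only generate
#' artifact calls.
#'
#' @param raw a raw [depth_matrix()].
#' @param min_fraction fraction of the grand-mean depth below which a
#'   window is dropped (default 0.1).
#' @export
filter_low_coverage <- function(raw, min_fraction = 0.1) {
  wmean <- rowMeans(raw$depth)
  keep <- wmean >= min_fraction * mean(wmean)
  out <- raw
  out$windows <- raw$windows[keep, , drop = FALSE]
  rownames(out$windows) <- NULL
  out$depth <- raw$depth[keep, , drop = FALSE]
  out
}

#' Normalize raw depth to copy-number scale
#'
#' Each individual's column is divided by that individual's median raw
#' depth (global, or per chromosome), putting the diploid baseline at
#' normalized RD = 1.0: a heterozygous deletion then sits near 0.5 and a
#' single-copy gain near 1.5.  The median — not the mean — is the
#' normalizer so the CNV windows themselves cannot drag the baseline.
#' The per-individual STDEV of the normalized column (population
#' standard deviation, ddof = 0) is recorded for the statistical calling
#' criterion.
#'
#' @param raw a raw [depth_matrix()].
#' @param mode `"global-median"` (default) or `"per-chromosome-median"`
#'   (useful when sex chromosomes should be scaled separately).
#' @return a `norm_depth_matrix`: the input with `depth` replaced by
#'   normalized RD plus fields `scale_factors` and `stdev`.
#' @examples
#' g <- make_window_grid(genome_layout("chr1", 4000), 800)
#' raw <- depth_matrix(g, matrix(7, 5, 2))
#' normalize_depth(raw)$stdev
#' @export
normalize_depth <- function(raw, mode = c("global-median", "per-chromosome-median")) {
  mode <- match.arg(mode)
  depth <- raw$depth
  if (mode == "global-median") {
    med <- apply(depth, 2, stats::median)
    bad <- which(med <= 0)
    if (length(bad)) {
      stop("zero median raw depth for individual(s): ",
           paste(raw$individuals[bad], collapse = ", "))
    }
    norm <- sweep(depth, 2, med, "/")
    scale_factors <- med
  } else {
    norm <- depth
    chroms <- unique(raw$windows$chrom)
    scale_factors <- matrix(NA_real_, length(chroms), ncol(depth),
                            dimnames = list(chroms, raw$individuals))
    for (ch in chroms) {
      rows <- raw$windows$chrom == ch
      med <- apply(depth[rows, , drop = FALSE], 2, stats::median)
      bad <- which(med <= 0)
      if (length(bad)) {
        stop("zero median raw depth on ", ch, " for individual(s): ",
             paste(raw$individuals[bad], collapse = ", "))
      }
      norm[rows, ] <- sweep(depth[rows, , drop = FALSE], 2, med, "/")
      scale_factors[ch, ] <- med
    }
  }
  out <- raw
  out$depth <- norm
  out$scale_factors <- scale_factors
  out$stdev <- apply(norm, 2, pop_sd)
  names(out$stdev) <- raw$individuals
  class(out) <- c("norm_depth_matrix", "depth_matrix")
  out
}
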