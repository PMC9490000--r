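#' Read gene models from GFF3
#'
#' Gene spans come from `type == "gene"` records (attribute `ID`), exons
#' from `type == "exon"` records linked by `Parent` (either directly to
#' the gene or through an mRNA whose `Parent` is the gene).  Coordinates
#' are converted from GFF3 1-based closed to the package's 0-based
#' half-open convention.  Strand is kept but ignored by the overlap
#' stages: CNVs are unstranded.
#'
#' @param path GFF3 file path.
#' @return a `gene_models` list with data.frames `genes`
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`) and `exons`
#'   (`gene_id`, `chrom`, `start`, `end`).
#' @export
read_gene_models <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  is_gene <- gff$type == "gene"
  genes_gr <- gff[is_gene]
  gene_ids <- as.character(genes_gr$ID)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = as.character(GenomicRanges::seqnames(genes_gr)),
    start = GenomicRanges::start(genes_gr) - 1L,
    end = GenomicRanges::end(genes_gr),
    strand = as.character(GenomicRanges::strand(genes_gr)),
    stringsAsFactors = FALSE)
  # map transcript IDs to gene IDs so exon Parents resolve either way
  tx <- gff[gff$type %in% c("mRNA", "transcript")]
  tx_parent <- vapply(as.list(tx$Parent), function(p) p[1] %||% NA_character_,
                      character(1))
  tx_map <- stats::setNames(tx_parent, as.character(tx$ID))
  ex_gr <- gff[gff$type == "exon"]
  parent <- vapply(as.list(ex_gr$Parent), function(p) p[1] %||% NA_character_,
                   character(1))
  resolved <- ifelse(parent %in% names(tx_map), tx_map[parent], parent)
  exons <- data.frame(
    gene_id = unname(resolved),
    chrom = as.character(GenomicRanges::seqnames(ex_gr)),
    start = GenomicRanges::start(ex_gr) - 1L,
    end = GenomicRanges::end(ex_gr),
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Bundle gene and exon tables into a gene-models object
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), optional `strand`.
#' @param exons data.frame `gene_id`, `chrom`, `start`, `end`; every exon
#'   must fall within its gene's span.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)),
            all(c("gene_id", "chrom", "start", "end") %in% names(exons)))
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  if (anyNA(span$gene_id)) stop("exon references unknown gene id")
  if (any(exons$start < span$start | exons$end > span$end)) {
    stop("exon outside its gene span")
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' Classify CNVRs by genic context
#'
#' EXONIC if the region overlaps any exon base, else INTRONIC if it
#' overlaps any gene span, else INTERGENIC (precedence
#' exon > intron > intergenic).  The three classes partition any CNVR
#' set.
#'
#' @param cnvrs data.frame with `chrom`, `start`, `end` (half-open).
#' @param genes a [gene_models()] object.
#' @return character vector, one of `"EXONIC"`, `"INTRONIC"`,
#'   `"INTERGENIC"` per region.
#' @export
classify_genic_context <- function(cnvrs, genes) {
  if (nrow(cnvrs) == 0) return(character())
  cg <- regions_to_granges(cnvrs)
  out <- rep("INTERGENIC", nrow(cnvrs))
  if (nrow(genes$genes)) {
    in_gene <- GenomicRanges::countOverlaps(cg, regions_to_granges(genes$genes)) > 0
    out[in_gene] <- "INTRONIC"
  }
  if (nrow(genes$exons)) {
    in_exon <- GenomicRanges::countOverlaps(cg, regions_to_granges(genes$exons)) > 0
    out[in_exon] <- "EXONIC"
  }
  out
}

#' Genes overlapping CNVRs
#'
#' A gene is retained for a region when the overlap covers at least
#' `min_fraction` of the shorter of the two features, so complete
#' containment of either feature always qualifies.
#'
#' @param cnvrs data.frame with `chrom`, `start`, `end` and ideally `id`.
#' @param genes a [gene_models()] object.
#' @param min_fraction minimum overlap as a fraction of the shorter
#'   feature (default 0.5).
#' @return data.frame `cnvr_id`, `gene_id`, `overlap_bp`, `fraction`.
#' @export
overlapping_genes <- function(cnvrs, genes, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  empty <- data.frame(cnvr_id = character(), gene_id = character(),
                      overlap_bp = numeric(), fraction = numeric())
  if (nrow(cnvrs) == 0 || nrow(genes$genes) == 0) return(empty)
  ids <- if ("id" %in% names(cnvrs)) cnvrs$id else as.character(seq_len(nrow(cnvrs)))
  cg <- regions_to_granges(cnvrs)
  gg <- regions_to_granges(genes$genes)
  hits <- GenomicRanges::findOverlaps(cg, gg)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(cg)[qi],
                                           IRanges::ranges(gg)[si]))
  shorter <- pmin(cnvrs$end[qi] - cnvrs$start[qi],
                  genes$genes$end[si] - genes$genes$start[si])
  frac <- ov / shorter
  keep <- frac >= min_fraction
  data.frame(cnvr_id = ids[qi][keep], gene_id = genes$genes$gene_id[si][keep],
             overlap_bp = ov[keep], fraction = frac[keep],
             stringsAsFactors = FALSE)
}

#' Read a two-column gene-to-term map
#'
#' TSV with columns `gene_id`, `term_id` and optionally `term_name`.
#' @param path file path.
#' @export
read_term_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("gene_id", "term_id") %in% names(tab)))
  tab
}

#' Hypergeometric term enrichment with BH FDR correction
#'
#' For each term with `K` genes in the background, a set of `n` genes
#' containing `k` term members gets the upper-tail hypergeometric
#' p-value `P(X >= k)` given `N` background genes; q-values are
#' Benjamini-Hochberg across all tested terms.
#'
#' @param gene_set character vector of gene ids (must be a subset of the
#'   background).
#' @param term_map data.frame `gene_id`, `term_id`, optional `term_name`.
#' @param background character vector of background gene ids
#'   (default: all genes in `term_map`).
#' @return data.frame per term: `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`, sorted by p.
#' @export
enrichment_test <- function(gene_set, term_map, background = NULL) {
  if (is.null(background)) background <- unique(term_map$gene_id)
  background <- unique(background)
  gene_set <- unique(gene_set)
  if (length(gene_set) == 0) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(), q_value = numeric()))
  }
  extra <- setdiff(gene_set, background)
  if (length(extra)) {
    stop("gene set contains genes absent from the background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  tm <- term_map[term_map$gene_id %in% background, , drop = FALSE]
  N <- length(background)
  n <- length(gene_set)
  terms <- unique(tm$term_id)
  names_tab <- if ("term_name" %in% names(tm)) {
    tm$term_name[match(terms, tm$term_id)]
  } else terms
  res <- do.call(rbind, lapply(seq_along(terms), function(i) {
    members <- unique(tm$gene_id[tm$term_id == terms[i]])
    K <- length(members)
    k <- length(intersect(members, gene_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = terms[i], term_name = names_tab[i], k = k, K = K,
               n = n, N = N, p_value = p, stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read QTL intervals from a BED-like TSV
#'
#' Columns `chrom`, `start`, `end` (0-based half-open), `id` and
#' optionally `trait`; a header line is required.
#' @param path file path.
#' @export
read_qtl_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("chrom", "start", "end", "id") %in% names(tab)))
  if (any(tab$end <= tab$start)) stop("QTL with end <= start")
  tab
}

#' Intersect CNVRs with QTL intervals
#'
#' A (CNVR, QTL) pair is reported when the two intervals overlap by at
#' least one base (half-open coordinates on both sides).
#'
#' @param cnvrs data.frame `chrom`, `start`, `end`, ideally `id`.
#' @param qtls data.frame from [read_qtl_table()].
#' @return list: `pairs` (data.frame `cnvr_id`, `qtl_id`, `trait`),
#'   `n_cnvrs` and `n_qtls` (distinct counts on each side).
#' @export
qtl_overlap <- function(cnvrs, qtls) {
  empty <- list(pairs = data.frame(cnvr_id = character(), qtl_id = character(),
                                   trait = character()),
                n_cnvrs = 0L, n_qtls = 0L)
  if (nrow(cnvrs) == 0 || nrow(qtls) == 0) return(empty)
  ids <- if ("id" %in% names(cnvrs)) cnvrs$id else as.character(seq_len(nrow(cnvrs)))
  hits <- GenomicRanges::findOverlaps(regions_to_granges(cnvrs),
                                      regions_to_granges(qtls))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  pairs <- data.frame(
    cnvr_id = ids[qi], qtl_id = as.character(qtls$id[si]),
    trait = if ("trait" %in% names(qtls)) qtls$trait[si] else NA_character_,
    stringsAsFactors = FALSE)
  list(pairs = pairs, n_cnvrs = length(unique(pairs$cnvr_id)),
       n_qtls = length(unique(pairs$qtl_id)))
}

#' Overlap of an external CNVR set with this study's regions
#'
#' Counts how many regions of the comparison set (`theirs`) overlap
#' (>= 1 bp) at least one region of `ours`, and reports that count as a
#' percentage of the comparison set to two decimals — the convention
#' cross-study CNVR comparison tables use.
#'
#' @param ours data.frame `chrom`, `start`, `end` — this study's CNVRs.
#' @param theirs data.frame `chrom`, `start`, `end` — the external set
#'   (same assembly coordinates); must be non-empty.
#' @return list `n_overlapping`, `n_total`, `percentage`.
#' @export
cross_study_overlap <- function(ours, theirs) {
  if (nrow(theirs) == 0) stop("comparison region set is empty")
  n_ov <- if (nrow(ours) == 0) 0L else {
    # the two studies may cover disjoint chromosome sets; that is a
    # legitimate comparison, not a coordinate mix-up worth a warning
    suppressWarnings(
      sum(GenomicRanges::countOverlaps(regions_to_granges(theirs),
                                       regions_to_granges(ours)) > 0))
  }
  list(n_overlapping = as.integer(n_ov), n_total = nrow(theirs),
       percentage = overlap_percentage(n_ov, nrow(theirs)))
}
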