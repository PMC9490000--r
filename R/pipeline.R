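#' Run the full CNV analysis pipeline
#'
#' Orchestrates the stages end to end: low-coverage window removal,
#' median normalization, per-population window classification, candidate
#' filtering, correlation merging into calls and per-individual events,
#' call-to-CNVR merging, cross-population shared/unique accounting and,
#' when the resources are supplied, genic annotation, term enrichment,
#' QTL intersection and pairwise Vst scans.
#'
#' @param raw a raw [depth_matrix()] (e.g. from [read_depth_matrix()] or
#'   [simulate_depth()]).
#' @param popmap data.frame `individual`, `population`; every individual
#'   must be a column of `raw`.
#' @param params a [calling_params()].
#' @param gap_fraction,cnvr_alpha call-to-CNVR merge rule (see
#'   [merge_calls_to_cnvrs()]).
#' @param min_coverage_fraction low-coverage window filter (see
#'   [filter_low_coverage()]); 0 disables.
#' @param normalize_mode passed to [normalize_depth()].
#' @param genes optional [gene_models()].
#' @param qtls optional QTL data.frame ([read_qtl_table()]).
#' @param term_map optional gene-to-term map ([read_term_map()]).
#' @param output_dir optional directory: per-stage TSV artifacts and a
#'   JSON summary are written there.
#' @return a `cnv_pipeline` list: `norm`, `popmap`, `params`,
#'   `per_population` (candidates, segments, events, cnvrs per
#'   population), `events` (pooled), `sets` (Venn accounting),
#'   `union_cnvrs`, and when inputs allow `genic_context`,
#'   `gene_overlaps`, `enrichment`, `qtl`, `vst` (one scan per
#'   population pair).
#' @export
run_cnv_pipeline <- function(raw, popmap, params = calling_params(),
                             gap_fraction = 0.2, cnvr_alpha = 0.01,
                             min_coverage_fraction = 0.1,
                             normalize_mode = "global-median",
                             genes = NULL, qtls = NULL, term_map = NULL,
                             output_dir = NULL) {
  if (missing(popmap) || is.null(popmap)) {
    stop("population map (popmap) is required")
  }
  stopifnot(all(c("individual", "population") %in% names(popmap)))
  miss <- setdiff(popmap$individual, raw$individuals)
  if (length(miss)) stop("popmap names individuals absent from the depth ",
                         "matrix: ", paste(miss, collapse = ", "))

  filt <- if (min_coverage_fraction > 0) {
    filter_low_coverage(raw, min_coverage_fraction)
  } else raw
  norm <- normalize_depth(filt, normalize_mode)

  pops <- unique(popmap$population)
  per_population <- lapply(stats::setNames(pops, pops), function(p) {
    ids <- popmap$individual[popmap$population == p]
    cc <- call_cnvs(norm, params, ids)
    events <- call_individual_events(cc$segments, norm, params, ids)
    cnvrs <- merge_calls_to_cnvrs(cc$segments, norm, gap_fraction,
                                  cnvr_alpha, ids)
    list(candidates = cc$candidates, segments = cc$segments,
         events = events, cnvrs = cnvrs)
  })
  events <- do.call(rbind, lapply(per_population, `[[`, "events"))
  rownames(events) <- NULL

  sets <- if (length(pops) >= 2) {
    population_cnvr_sets(lapply(per_population, `[[`, "cnvrs"))
  } else NULL
  union_cnvrs <- if (!is.null(sets)) {
    u <- sets$union_cnvrs
    if (nrow(u)) u$id <- paste0("ucnvr_", seq_len(nrow(u)))
    u
  } else {
    per_population[[1]]$cnvrs
  }

  res <- list(norm = norm, popmap = popmap, params = params,
              per_population = per_population, events = events,
              sets = sets, union_cnvrs = union_cnvrs)

  if (!is.null(genes) && nrow(union_cnvrs)) {
    res$genic_context <- classify_genic_context(union_cnvrs, genes)
    res$gene_overlaps <- overlapping_genes(union_cnvrs, genes)
    if (!is.null(term_map) && nrow(res$gene_overlaps)) {
      res$enrichment <- enrichment_test(unique(res$gene_overlaps$gene_id),
                                        term_map)
    }
  }
  if (!is.null(qtls) && nrow(union_cnvrs)) {
    res$qtl <- qtl_overlap(union_cnvrs, qtls)
  }
  if (length(pops) >= 2 && nrow(union_cnvrs)) {
    prs <- utils::combn(pops, 2, simplify = FALSE)
    res$vst <- lapply(prs, function(pr) {
      vst_scan(union_cnvrs, norm, popmap, pr)
    })
    names(res$vst) <- vapply(prs, paste, "", collapse = "_vs_")
  }
  class(res) <- "cnv_pipeline"
  if (!is.null(output_dir)) write_pipeline_artifacts(res, output_dir)
  res
}

write_pipeline_artifacts <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tsv(res$events, "events.tsv")
  for (p in names(res$per_population)) {
    tsv(res$per_population[[p]]$cnvrs, paste0("cnvr_", p, ".tsv"))
  }
  if (!is.null(res$sets)) {
    tsv(res$union_cnvrs, "cnvr_union.tsv")
    tsv(res$sets$venn, "venn.tsv")
  }
  if (!is.null(res$vst)) {
    for (pr in names(res$vst)) {
      tsv(res$vst[[pr]]$records, paste0("vst_", pr, ".tsv"))
    }
  }
  report <- make_summary_report(res)
  jsonlite::write_json(report, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(output_dir)
}

#' Summary tables for a pipeline run
#'
#' Every number is recomputed from the per-region artifacts held in the
#' result object, so the tables stay consistent with the emitted files:
#' per-population event and CNVR summaries (counts, gain/loss split,
#' total Mb, mean kb, genome fraction), size-bin fractions, Venn counts,
#' per-chromosome counts with the count-on-length regression, genic
#' context partition, QTL overlap counts and per-pair mean Vst with the
#' top regions.
#'
#' @param res a [run_cnv_pipeline()] result.
#' @param genome optional [genome_layout()] for genome-fraction and the
#'   per-chromosome regression.
#' @return a named list of data.frames / scalars.
#' @export
make_summary_report <- function(res, genome = NULL) {
  out <- list()
  out$events <- summarize_events(res$events, res$popmap)
  out$cnvrs <- do.call(rbind, lapply(names(res$per_population), function(p) {
    cbind(population = p,
          cnvr_summary(res$per_population[[p]]$cnvrs, genome))
  }))
  if (nrow(res$events)) {
    out$event_size_bins <- summarize_sizes(res$events$end - res$events$start,
                                           cnv_size_breaks)
  }
  if (nrow(res$union_cnvrs)) {
    out$cnvr_size_bins <- summarize_sizes(
      res$union_cnvrs$end - res$union_cnvrs$start, cnvr_size_breaks)
    out$no_regions <- FALSE
  } else {
    out$no_regions <- TRUE
  }
  if (!is.null(res$sets)) {
    out$venn <- res$sets$venn
    out$n_union_cnvrs <- res$sets$n_union
  }
  if (!is.null(genome) && nrow(res$union_cnvrs)) {
    counts <- table(factor(res$union_cnvrs$chrom, levels = genome$chrom))
    out$per_chromosome <- data.frame(chrom = genome$chrom,
                                     length = genome$length,
                                     n_cnvr = as.integer(counts))
    if (nrow(genome) >= 3 && stats::var(genome$length) > 0) {
      out$chromosome_regression <-
        chromosome_count_regression(out$per_chromosome$n_cnvr,
                                    out$per_chromosome$length)
    }
  }
  if (!is.null(res$genic_context)) {
    tab <- table(factor(res$genic_context,
                        levels = c("EXONIC", "INTRONIC", "INTERGENIC")))
    out$genic_context <- data.frame(context = names(tab),
                                    n = as.integer(tab))
  }
  if (!is.null(res$qtl)) {
    out$qtl <- data.frame(n_cnvrs = res$qtl$n_cnvrs,
                          n_qtls = res$qtl$n_qtls,
                          n_pairs = nrow(res$qtl$pairs))
  }
  if (!is.null(res$vst)) {
    out$vst <- do.call(rbind, lapply(names(res$vst), function(pr) {
      v <- res$vst[[pr]]
      data.frame(pair = pr, mean_vst = v$mean_vst,
                 top_vst = if (nrow(v$top_k)) v$top_k$vst[1] else NA_real_,
                 top_cnvr = if (nrow(v$top_k)) v$top_k$cnvr_id[1] else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
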