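#' Simulate a genome with gene models and QTL intervals
#'
#' Chromosome lengths, non-overlapping gene spans (1-10 exons each,
#' placed uniformly) and independently placed QTL intervals, all
#' reproducible from the seed.  Emulates the scale of a resequencing
#' panel's reference without any download.
#'
#' @param n_chromosomes number of chromosomes (default 3).
#' @param lengths chromosome length(s) in bp, recycled (default 2e6).
#' @param n_genes genes to place (default 100).
#' @param n_qtls QTL intervals to place (default 20).
#' @param gene_length_range span range for genes in bp.
#' @param qtl_length_range span range for QTLs in bp.
#' @param seed RNG seed.
#' @return a `sim_genome` list: `genome` ([genome_layout()]), `genes`
#'   ([gene_models()]), `qtls` (QTL data.frame).
#' @export
simulate_genome <- function(n_chromosomes = 3, lengths = 2e6,
                            n_genes = 100, n_qtls = 20,
                            gene_length_range = c(2000, 10000),
                            qtl_length_range = c(20000, 100000),
                            seed = NULL) {
  lengths <- rep_len(lengths, n_chromosomes)
  genome <- genome_layout(paste0("chr", seq_len(n_chromosomes)), lengths)
  with_seed(seed, {
    placed <- vector("list", n_genes)
    occupied <- lapply(genome$chrom, function(x) cbind(start = numeric(0), end = numeric(0)))
    names(occupied) <- genome$chrom
    for (g in seq_len(n_genes)) {
      ok <- FALSE
      for (try in 1:200) {
        ci <- sample.int(n_chromosomes, 1, prob = genome$length)
        len <- round(stats::runif(1, gene_length_range[1], gene_length_range[2]))
        if (genome$length[ci] <= len) next
        start <- floor(stats::runif(1, 0, genome$length[ci] - len))
        occ <- occupied[[ci]]
        if (nrow(occ) == 0 || all(start + len <= occ[, 1] | start >= occ[, 2])) {
          occupied[[ci]] <- rbind(occ, c(start, start + len))
          placed[[g]] <- data.frame(gene_id = sprintf("gene%03d", g),
                                    chrom = genome$chrom[ci], start = start,
                                    end = start + len,
                                    strand = sample(c("+", "-"), 1),
                                    stringsAsFactors = FALSE)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", n_genes, " non-overlapping genes; ",
                    "reduce n_genes or enlarge the genome")
    }
    genes <- do.call(rbind, placed)
    exons <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      n_ex <- sample.int(10, 1)
      span <- genes$end[i] - genes$start[i]
      block <- span / n_ex
      do.call(rbind, lapply(seq_len(n_ex), function(e) {
        b0 <- genes$start[i] + (e - 1) * block
        w <- max(10, round(stats::runif(1, 0.1, 0.6) * block))
        s <- floor(stats::runif(1, b0, b0 + block - w))
        data.frame(gene_id = genes$gene_id[i], chrom = genes$chrom[i],
                   start = s, end = min(s + w, genes$end[i]),
                   stringsAsFactors = FALSE)
      }))
    }))
    qtls <- do.call(rbind, lapply(seq_len(n_qtls), function(q) {
      ci <- sample.int(n_chromosomes, 1, prob = genome$length)
      len <- min(round(stats::runif(1, qtl_length_range[1], qtl_length_range[2])),
                 genome$length[ci] - 1)
      start <- floor(stats::runif(1, 0, genome$length[ci] - len))
      data.frame(chrom = genome$chrom[ci], start = start, end = start + len,
                 id = sprintf("QTL%03d", q),
                 trait = sample(c("growth", "milk_yield", "immune",
                                  "fecal_egg_count", "carcass"), 1),
                 stringsAsFactors = FALSE)
    }))
    structure(list(genome = genome, genes = gene_models(genes, exons),
                   qtls = qtls), class = "sim_genome")
  })
}

#' Plant multi-population CNVRs and draw a truth set
#'
#' Plants grid-aligned CNVRs mirroring the structure of a three-ecotype
#' resequencing panel: regions shared by all populations, regions unique
#' to one, and a few designated divergent regions fixed in one population
#' and absent elsewhere.  Duplications outnumber deletions
#' `gain_loss_ratio`:1 and region sizes follow an L-shaped (truncated
#' geometric) distribution over `min_windows`..`max_windows` windows.
#' Carriers get integer copy numbers (LOSS: 0 or 1; GAIN: 3 or 4);
#' divergent regions are two-copy gains (copy number 4) in every carrier
#' so the planted difference is fixed.
#'
#' @param grid a [make_window_grid()] result.
#' @param populations named integer vector of population sizes
#'   (default `c(pop1 = 8, pop2 = 8, pop3 = 8)`).
#' @param n_shared CNVRs carried in all populations (default 30).
#' @param n_unique CNVRs unique to each population (default 8 per
#'   population).
#' @param n_divergent divergent CNVRs, assigned round-robin to
#'   populations (default 3).
#' @param gain_loss_ratio duplications per deletion (default 3).
#' @param size_geom_p geometric parameter of the L-shaped size
#'   distribution (default 0.65, putting ~88% of regions at 1-2
#'   windows).
#' @param min_windows,max_windows region size bounds in windows
#'   (defaults 1 and 10: 0.8-8 kb on an 800-bp grid).
#' @param carrier_freq_range per-population carrier-frequency range for
#'   non-divergent regions (default 0.25-0.9).
#' @param divergent_freqs carrier frequencies (focal, other) for
#'   divergent regions (default `c(1, 0)`).
#' @param hom_prob probability that a carrier is homozygous (copy number
#'   0 or 4 rather than 1 or 3; default 0.3).
#' @param buffer_windows unplanted windows required between regions
#'   (default 2).
#' @param max_retries placement retries per region before erroring.
#' @param seed RNG seed.
#' @return a `cnv_truth` list: `regions` (with per-population
#'   frequencies and a `divergent` flag), `copy_number` (regions x
#'   individuals integer matrix), `popmap`, `grid`, `seed`.
#' @export
simulate_populations <- function(grid,
                                 populations = c(pop1 = 8, pop2 = 8, pop3 = 8),
                                 n_shared = 30, n_unique = 8, n_divergent = 3,
                                 gain_loss_ratio = 3, size_geom_p = 0.65,
                                 min_windows = 1, max_windows = 10,
                                 carrier_freq_range = c(0.25, 0.9),
                                 divergent_freqs = c(1, 0), hom_prob = 0.3,
                                 buffer_windows = 2, max_retries = 100,
                                 seed = NULL) {
  stopifnot(length(populations) >= 1, all(populations >= 2),
            !is.null(names(populations)))
  pops <- names(populations)
  individuals <- unlist(lapply(pops, function(p) {
    paste0(p, "_", seq_len(populations[[p]]))
  }))
  popmap <- data.frame(
    individual = individuals,
    population = rep(pops, times = populations),
    stringsAsFactors = FALSE)

  n_regions <- n_shared + n_unique * length(pops) + n_divergent
  kinds <- c(rep("shared", n_shared),
             rep(pops, each = n_unique),
             if (n_divergent > 0) paste0("div:", pops[(seq_len(n_divergent) - 1) %% length(pops) + 1]))

  chrom_windows <- split(seq_len(nrow(grid)), grid$chrom)
  chrom_windows <- chrom_windows[unique(grid$chrom)]

  with_seed(seed, {
    size_probs <- stats::dgeom(0:(max_windows - min_windows), size_geom_p)
    size_probs <- size_probs / sum(size_probs)
    free <- rep(TRUE, nrow(grid))
    regions <- vector("list", n_regions)
    cn <- matrix(2L, n_regions, length(individuals),
                 dimnames = list(NULL, individuals))
    for (i in seq_len(n_regions)) {
      divergent <- startsWith(kinds[i], "div:")
      k <- if (divergent) max(min_windows, 3) else
        min_windows + sample.int(length(size_probs), 1, prob = size_probs) - 1
      type <- if (divergent) "GAIN" else
        if (stats::runif(1) < gain_loss_ratio / (gain_loss_ratio + 1)) "GAIN" else "LOSS"
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        ci <- sample.int(length(chrom_windows), 1,
                         prob = lengths(chrom_windows))
        wins <- chrom_windows[[ci]]
        if (length(wins) < k) next
        off <- sample.int(length(wins) - k + 1, 1)
        rows <- wins[off:(off + k - 1)]
        guard <- wins[max(1, off - buffer_windows):
                        min(length(wins), off + k - 1 + buffer_windows)]
        if (!all(free[guard])) next
        free[guard] <- FALSE
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place planted region ", i,
                        " after ", max_retries, " retries")

      freqs <- stats::setNames(numeric(length(pops)), pops)
      if (kinds[i] == "shared") {
        freqs[] <- stats::runif(1, carrier_freq_range[1], carrier_freq_range[2])
      } else if (divergent) {
        focal <- sub("^div:", "", kinds[i])
        freqs[] <- divergent_freqs[2]
        freqs[focal] <- divergent_freqs[1]
      } else {
        freqs[kinds[i]] <- stats::runif(1, carrier_freq_range[1],
                                        carrier_freq_range[2])
      }
      for (p in pops) {
        n_p <- populations[[p]]
        n_carriers <- round(freqs[p] * n_p)
        if (n_carriers == 0) next
        ids <- popmap$individual[popmap$population == p]
        carriers <- sample(ids, n_carriers)
        cn[i, carriers] <- if (divergent) 4L else if (type == "GAIN") {
          ifelse(stats::runif(n_carriers) < hom_prob, 4L, 3L)
        } else {
          ifelse(stats::runif(n_carriers) < hom_prob, 0L, 1L)
        }
      }
      regions[[i]] <- cbind(
        data.frame(id = sprintf("truth_%03d", i),
                   chrom = grid$chrom[rows[1]],
                   start = grid$start[rows[1]], end = grid$end[rows[k]],
                   type = type, n_windows = k, divergent = divergent,
                   first_window = rows[1], last_window = rows[k],
                   stringsAsFactors = FALSE),
        stats::setNames(as.data.frame(as.list(freqs)), paste0("freq_", pops)))
    }
    regions <- if (n_regions == 0) {
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), type = character(), n_windows = integer(),
                 divergent = logical(), first_window = integer(),
                 last_window = integer())
    } else do.call(rbind, regions)
    rownames(cn) <- regions$id
    structure(list(regions = regions, copy_number = cn, popmap = popmap,
                   grid = grid, seed = seed),
              class = "cnv_truth")
  })
}

#' Draw a raw depth matrix from a truth set
#'
#' Per window and individual the expected depth is
#' `mean_depth * copy_number / 2` (diploid baseline `mean_depth`).
#' Noise models operate on the aggregated base count of the window,
#' `X ~ Poisson(mean_depth * window_size * cn/2)` with depth
#' `X / window_size` — the standard depth-of-coverage model — or a
#' negative binomial with the same mean and dispersion `phi`
#' (`Var = mu + phi * mu^2`) for overdispersed coverage; `"none"`
#' returns the expectation exactly, for deterministic tests.
#'
#' @param truth a [simulate_populations()] truth set.
#' @param mean_depth diploid mean depth (default 7, typical of a
#'   low-coverage resequencing panel).
#' @param noise `"poisson"` (default), `"negbin"` or `"none"`.
#' @param dispersion negative-binomial dispersion phi (default 0.1).
#' @param seed RNG seed.
#' @return a raw [depth_matrix()] on the truth set's grid.
#' @export
simulate_depth <- function(truth, mean_depth = 7,
                           noise = c("poisson", "negbin", "none"),
                           dispersion = 0.1, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(mean_depth > 0)
  grid <- truth$grid
  wsize <- attr(grid, "window_size")
  if (is.null(wsize)) wsize <- grid$end[1] - grid$start[1]
  individuals <- colnames(truth$copy_number)
  cnmat <- matrix(2, nrow(grid), length(individuals),
                  dimnames = list(NULL, individuals))
  for (i in seq_len(nrow(truth$regions))) {
    rows <- truth$regions$first_window[i]:truth$regions$last_window[i]
    cnmat[rows, ] <- rep(truth$copy_number[i, ], each = length(rows))
  }
  mu <- mean_depth * wsize * cnmat / 2
  with_seed(seed, {
    counts <- switch(noise,
      poisson = matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu)),
      negbin = matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                      nrow(mu), ncol(mu)),
      none = mu)
    depth_matrix(grid, counts / wsize, individuals)
  })
}

#' Sensitivity and precision of called CNVRs against a truth set
#'
#' A truth region is recovered when any called region overlaps it by
#' >= 1 bp; a called region is a true positive when it overlaps any
#' truth region.
#'
#' @param cnvrs called regions (`chrom`, `start`, `end`).
#' @param truth a `cnv_truth` object (or its `regions` data.frame).
#' @return list `sensitivity`, `precision`, `n_truth`, `n_called`.
#' @export
recovery_stats <- function(cnvrs, truth) {
  tr <- if (inherits(truth, "cnv_truth")) truth$regions else truth
  if (nrow(tr) == 0) stop("empty truth set")
  if (nrow(cnvrs) == 0) {
    return(list(sensitivity = 0, precision = NA_real_,
                n_truth = nrow(tr), n_called = 0L))
  }
  tg <- regions_to_granges(tr)
  cg <- regions_to_granges(cnvrs)
  list(sensitivity = mean(GenomicRanges::countOverlaps(tg, cg) > 0),
       precision = mean(GenomicRanges::countOverlaps(cg, tg) > 0),
       n_truth = nrow(tr), n_called = nrow(cnvrs))
}

#' Write simulated resources in the formats the pipeline consumes
#'
#' `write_gff3()` emits gene/mRNA-free two-level GFF3 (gene + exon
#' records); `write_popmap()` and `write_truth_regions()` are plain
#' TSVs; [write_depth_matrix()] covers the depth TSV.
#'
#' @param models a [gene_models()] object.
#' @param path output path.
#' @name sim_writers
#' @export
write_gff3 <- function(models, path) {
  g <- models$genes
  e <- models$exons
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end),
    strand = if ("strand" %in% names(g)) g$strand else "*",
    type = "gene", ID = g$gene_id)
  gr_ex <- GenomicRanges::GRanges(
    e$chrom, IRanges::IRanges(e$start + 1L, e$end),
    strand = if ("strand" %in% names(g)) g$strand[match(e$gene_id, g$gene_id)] else "*",
    type = "exon",
    ID = paste0(e$gene_id, ".exon", stats::ave(seq_len(nrow(e)), e$gene_id,
                                               FUN = seq_along)))
  gr_ex$Parent <- as(e$gene_id, "CharacterList")
  gr_gene$Parent <- as(rep(list(character(0)), length(gr_gene)), "CharacterList")
  rtracklayer::export(c(gr_gene, gr_ex), path, format = "gff3")
  invisible(path)
}

#' @param popmap data.frame `individual`, `population`.
#' @rdname sim_writers
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a population map TSV (`individual<TAB>population`)
#' @param path file path.
#' @export
read_popmap <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("individual", "population") %in% names(tab)))
  tab
}

#' @param truth a `cnv_truth` object.
#' @rdname sim_writers
#' @export
write_truth_regions <- function(truth, path) {
  out <- cbind(truth$regions, as.data.frame(truth$copy_number))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
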