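#' Read a qPCR Ct table
#'
#' TSV with columns `sample`, `assay`, `replicate`, `ct_target`,
#' `ct_reference` — one row per technical replicate, target and
#' reference-gene Ct measured on the same plate.
#' @param path file path.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("sample", "assay", "replicate", "ct_target",
                  "ct_reference") %in% names(tab)))
  if (any(!is.finite(tab$ct_target)) || any(!is.finite(tab$ct_reference)) ||
      any(tab$ct_target <= 0) || any(tab$ct_reference <= 0)) {
    stop("Ct values must be finite and positive")
  }
  tab
}

#' Copy number from qPCR Ct values by the 2^-ddCt method
#'
#' Technical replicates are averaged (mean Ct) per (sample, assay), then
#' `dCt = Ct_target - Ct_reference`, `ddCt = dCt_sample -
#' dCt_calibrator` (per assay), relative quantity `2^-ddCt`, and
#' estimated copy number `reference_copy_number * 2^-ddCt`.  Assumes
#' perfect amplification efficiency (factor 2 per cycle), as the method
#' does; the calibrator is a sample of known (diploid) copy number.
#'
#' @param ct a Ct table as from [read_ct_table()].
#' @param calibrator sample id to use as the ddCt calibrator; must have
#'   Ct values for every assay present.
#' @param reference_copy_number copy number assigned to the calibrator
#'   (default 2).
#' @return data.frame per (sample, assay): `dct`, `ddct`,
#'   `relative_quantity`, `copy_number`.
#' @export
ddct_copy_number <- function(ct, calibrator, reference_copy_number = 2) {
  key <- interaction(ct$sample, ct$assay, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(d) {
    data.frame(sample = d$sample[1], assay = d$assay[1],
               dct = mean(d$ct_target) - mean(d$ct_reference),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  for (a in unique(agg$assay)) {
    if (!any(agg$assay == a & agg$sample == calibrator)) {
      stop("calibrator '", calibrator, "' has no Ct values for assay '", a, "'")
    }
  }
  cal <- agg[agg$sample == calibrator, ]
  agg$ddct <- agg$dct - cal$dct[match(agg$assay, cal$assay)]
  agg$relative_quantity <- 2^(-agg$ddct)
  agg$copy_number <- reference_copy_number * agg$relative_quantity
  agg[order(agg$assay, agg$sample), , drop = FALSE]
}

#' Concordance of qPCR copy-number estimates with sequencing calls
#'
#' Estimates are classified GAIN when copy number > `gain_cutoff`, LOSS
#' when < `loss_cutoff`, else NORMAL (cutoffs at the integer midpoints
#' 2.5 and 1.5 by default) and compared with the sequencing-predicted
#' state per (sample, assay).
#'
#' @param estimates a [ddct_copy_number()] result.
#' @param predicted data.frame `sample`, `assay`, `state`
#'   (GAIN/LOSS/NORMAL) from the sequencing pipeline.
#' @param gain_cutoff,loss_cutoff classification cutoffs (2.5 / 1.5).
#' @return data.frame per shared (sample, assay): both classifications
#'   and an `agree` flag, plus attribute `by_assay` summarising
#'   agreement counts per assay.
#' @export
qpcr_concordance <- function(estimates, predicted, gain_cutoff = 2.5,
                             loss_cutoff = 1.5) {
  m <- merge(estimates, predicted, by = c("sample", "assay"))
  if (nrow(m) == 0) {
    out <- data.frame(sample = character(), assay = character(),
                      copy_number = numeric(), qpcr_state = character(),
                      predicted_state = character(), agree = logical())
    attr(out, "by_assay") <- data.frame(assay = character(), n = integer(),
                                        n_agree = integer())
    return(out)
  }
  m$qpcr_state <- ifelse(m$copy_number > gain_cutoff, "GAIN",
                         ifelse(m$copy_number < loss_cutoff, "LOSS", "NORMAL"))
  m$predicted_state <- m$state
  m$agree <- m$qpcr_state == m$predicted_state
  out <- m[, c("sample", "assay", "copy_number", "qpcr_state",
               "predicted_state", "agree")]
  by_assay <- do.call(rbind, lapply(split(out, out$assay), function(d) {
    data.frame(assay = d$assay[1], n = nrow(d), n_agree = sum(d$agree),
               stringsAsFactors = FALSE)
  }))
  rownames(by_assay) <- NULL
  attr(out, "by_assay") <- by_assay
  out
}
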