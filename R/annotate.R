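#' @include AllClasses.R coordinates.R liftover.R
NULL

annotationColumns <- c(
  "gene_id", "gene_name", "transcript_biotype", "tx_len",
  "cds_start", "cds_end", "transcript_metacoordinate",
  "abs_cds_start", "abs_cds_end", "up_junc_dist", "down_junc_dist",
  "tx_end_dist")

#' Annotate sites with isoform-specific positional information
#'
#' Appends 12 annotation columns to each BED3+ record, computed on the
#' isoform named in column 1 (the feature's representative position is its
#' 5' base, column 2):
#'
#' \describe{
#'   \item{gene_id, gene_name, transcript_biotype}{gene metadata from the
#'     annotation; empty string when the GTF lacks the attribute.}
#'   \item{tx_len}{transcript length in nt.}
#'   \item{cds_start, cds_end}{0-based transcript coordinates of the first
#'     and last ORF base (stop codon included); `NA` for noncoding
#'     isoforms.}
#'   \item{transcript_metacoordinate}{position rescaled onto the 0-3
#'     metatranscript axis (5'UTR 0-1, ORF 1-2, 3'UTR 2-3); `NA` for
#'     noncoding isoforms. See [metacoordinate()].}
#'   \item{abs_cds_start, abs_cds_end}{signed nt distance to the start /
#'     stop codon landmark (negative = 5' of it). See [codonDistances()].}
#'   \item{up_junc_dist, down_junc_dist}{nt to the nearest upstream /
#'     downstream splice junction, 1-anchored; `NA` when no junction
#'     exists on that side. See [junctionDistances()].}
#'   \item{tx_end_dist}{nt from the site to the transcript's final base.}
#' }
#'
#' @inheritParams liftoverSites
#' @return data.frame of input columns followed by the 12 annotation
#'   columns, in input order, with [runStats()] attached.
#' @examples
#' gtf <- tempfile(fileext = ".gtf"); bed <- tempfile(fileext = ".bed")
#' ann <- simulateTranscriptome(nGenes = 2, seed = 1, gtfPath = gtf)
#' sim <- simulateSites(ann, nSites = 20, seed = 2, bedPath = bed)
#' head(annotateSites(readSites(bed), ann))
#' @export
annotateSites <- function(sites, annotation, stripVersions = FALSE,
                          onMissing = c("skip", "fail")) {
  onMissing <- match.arg(onMissing)
  stats <- emptyRunStats()
  stats["total"] <- nrow(sites)
  res <- resolveModels(sites, annotation, stripVersions, onMissing)
  stats["missing_transcript"] <- sum(lengths(res$byTx[res$missing]))
  out <- list()
  for (tid in setdiff(names(res$byTx), res$missing)) {
    m <- res$models[[tid]]
    rows <- res$byTx[[tid]]
    len <- transcriptLength(m)
    ok <- sites$end[rows] <= len & sites$start[rows] >= 0L
    stats["out_of_range"] <- stats["out_of_range"] + sum(!ok)
    rows <- rows[ok]
    if (!length(rows)) next
    p <- sites$start[rows]
    jd <- junctionDistances(m, p)
    cd <- codonDistances(m, p)
    out[[tid]] <- data.frame(
      row = rows,
      gene_id = m@geneId, gene_name = m@geneName,
      transcript_biotype = m@biotype,
      tx_len = len,
      cds_start = m@cdsTxStart, cds_end = m@cdsTxEnd,
      transcript_metacoordinate = metacoordinate(regionLengths(m), p),
      abs_cds_start = cd$toStart, abs_cds_end = cd$toStop,
      up_junc_dist = jd$up, down_junc_dist = jd$down,
      tx_end_dist = len - 1L - p,
      stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, out)
  if (is.null(ann)) {
    ann <- as.data.frame(
      c(list(row = integer()),
        stats::setNames(rep(list(logical()), length(annotationColumns)),
                        annotationColumns)))
  }
  ann <- ann[order(ann$row), , drop = FALSE]
  result <- cbind(sites[ann$row, , drop = FALSE],
                  ann[, -1L, drop = FALSE])
  rownames(result) <- NULL
  stats["emitted"] <- nrow(result)
  attr(result, "header") <- attr(sites, "header")
  attr(result, "stats") <- stats
  result
}
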