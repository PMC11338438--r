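#' @include AllClasses.R coordinates.R bed.R
NULL

emptyRunStats <- function() {
  c(total = 0L, emitted = 0L, missing_transcript = 0L,
    out_of_range = 0L, junction_spanning = 0L, non_numeric_filtered = 0L)
}

#' Per-run record accounting
#'
#' Every input record is counted exactly once as emitted or in one skip
#' category; [liftoverSites()] and [annotateSites()] attach these counts to
#' their result.
#'
#' @param x a result of [liftoverSites()] or [annotateSites()].
#' @return named integer vector with elements `total`, `emitted`,
#'   `missing_transcript`, `out_of_range`, `junction_spanning` and
#'   `non_numeric_filtered`.
#' @export
runStats <- function(x) attr(x, "stats")

resolveModels <- function(sites, annotation, stripVersions, onMissing) {
  byTx <- split(seq_len(nrow(sites)), sites$transcript)
  models <- lapply(names(byTx), function(tid)
    lookupTranscript(annotation, tid, stripVersions = stripVersions))
  names(models) <- names(byTx)
  missing <- names(byTx)[vapply(models, is.null, logical(1))]
  if (length(missing) && identical(onMissing, "fail"))
    stop(sprintf("transcript '%s' not found in the annotation", missing[1L]))
  list(byTx = byTx, models = models, missing = missing)
}

#' Lift transcript-coordinate sites to genomic coordinates
#'
#' Transposes each BED3+ record from transcript to genome coordinates by
#' walking the transcript's exon chain: the genomic interval spans from the
#' mapped position of the first to that of the last transcript base of the
#' feature. The result is a BED6+n table: genomic `chrom`, `start`, `end`,
#' `name` (the source transcript id), `score` (`"."`) and `strand` in
#' columns 1-6, followed by every input column unchanged, so the original
#' record can be reconstructed exactly from columns 7 onward.
#'
#' Features whose ends fall on different exons are emitted as a single
#' interval spanning the intervening intron(s) and counted as
#' junction-spanning with a warning.
#'
#' @param sites data.frame from [readSites()].
#' @param annotation a [TranscriptomeAnnotation-class].
#' @param stripVersions fall back to version-stripped transcript id
#'   matching (see [lookupTranscript()]).
#' @param onMissing `"skip"` drops (and counts) records whose transcript is
#'   absent from the annotation; `"fail"` stops at the first one.
#' @return data.frame of lifted records in input order, with [runStats()]
#'   attached.
#' @examples
#' gtf <- tempfile(fileext = ".gtf"); bed <- tempfile(fileext = ".bed")
#' ann <- simulateTranscriptome(nGenes = 2, seed = 1, gtfPath = gtf)
#' sim <- simulateSites(ann, nSites = 20, seed = 2, bedPath = bed)
#' head(liftoverSites(readSites(bed), ann))
#' @export
liftoverSites <- function(sites, annotation, stripVersions = FALSE,
                          onMissing = c("skip", "fail")) {
  onMissing <- match.arg(onMissing)
  stats <- emptyRunStats()
  stats["total"] <- nrow(sites)
  res <- resolveModels(sites, annotation, stripVersions, onMissing)
  stats["missing_transcript"] <-
    sum(lengths(res$byTx[res$missing]))
  keepIdx <- integer(); out <- vector("list", length(res$byTx))
  for (tid in setdiff(names(res$byTx), res$missing)) {
    m <- res$models[[tid]]
    rows <- res$byTx[[tid]]
    len <- transcriptLength(m)
    ok <- sites$end[rows] <= len & sites$start[rows] >= 0L
    stats["out_of_range"] <- stats["out_of_range"] + sum(!ok)
    rows <- rows[ok]
    if (!length(rows)) next
    p1 <- sites$start[rows]; p2 <- sites$end[rows] - 1L
    g1 <- txToGenomic(m, p1); g2 <- txToGenomic(m, p2)
    cum0 <- c(0L, m@cumLengths[-length(m@cumLengths)])
    spanning <- findInterval(p1, cum0) != findInterval(p2, cum0)
    stats["junction_spanning"] <- stats["junction_spanning"] + sum(spanning)
    out[[tid]] <- data.frame(
      row = rows,
      chrom = g1$chrom,
      start = pmin(g1$pos, g2$pos),
      end = pmax(g1$pos, g2$pos) + 1L,
      name = tid, score = ".", strand = g1$strand,
      stringsAsFactors = FALSE)
    keepIdx <- c(keepIdx, rows)
  }
  if (stats["junction_spanning"] > 0L)
    warning(sprintf("%d junction-spanning feature(s) emitted as single intervals",
                    stats["junction_spanning"]))
  bed6 <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(bed6))
    bed6 <- data.frame(row = integer(), chrom = character(),
                       start = integer(), end = integer(),
                       name = character(), score = character(),
                       strand = character(), stringsAsFactors = FALSE)
  bed6 <- bed6[order(bed6$row), , drop = FALSE]
  orig <- sites[bed6$row, , drop = FALSE]
  names(orig)[1:3] <- c("transcript", "tx_start", "tx_end")
  result <- cbind(bed6[, -1L, drop = FALSE], orig)
  rownames(result) <- NULL
  stats["emitted"] <- nrow(result)
  attr(result, "header") <- attr(sites, "header")
  attr(result, "stats") <- stats
  result
}
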