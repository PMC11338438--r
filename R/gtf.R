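#' @include AllClasses.R coordinates.R
NULL

# Light validation pass over raw GTF lines so that malformed records are
# reported with their line number; the actual parsing is delegated to
# rtracklayer::import below.
validateGtfLines <- function(lines) {
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(invisible(NULL))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stop(sprintf("malformed GTF line %d: expected 9 tab-separated fields, got %d",
                 idx[which(nf < 9L)[1L]], nf[nf < 9L][1L]))
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  ends   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L)))
  if (anyNA(starts) || anyNA(ends))
    stop(sprintf("malformed GTF line %d: non-integer coordinates",
                 idx[which(is.na(starts) | is.na(ends))[1L]]))
  if (any(starts > ends))
    stop(sprintf("malformed GTF line %d: start > end",
                 idx[which(starts > ends)[1L]]))
  invisible(NULL)
}

readTextLines <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

newTranscriptModel <- function(transcriptId, geneId, geneName, biotype,
                               chrom, strand, exonStarts, exonEnds,
                               cdsTxStart = NA_integer_,
                               cdsTxEnd = NA_integer_, check = TRUE) {
  S4Vectors::new2("TranscriptModel",
      transcriptId = transcriptId, geneId = geneId,
      geneName = geneName, biotype = biotype,
      chrom = chrom, strand = strand,
      exonStarts = as.integer(exonStarts), exonEnds = as.integer(exonEnds),
      cumLengths = cumsum(as.integer(exonEnds) - as.integer(exonStarts) + 1L),
      cdsTxStart = as.integer(cdsTxStart), cdsTxEnd = as.integer(cdsTxEnd),
      check = check)
}

# Assemble a TranscriptomeAnnotation from a named list of models plus
# skip counters; builds the version-stripped secondary index.
newAnnotation <- function(models, stats = integer()) {
  ids <- vapply(models, function(m) m@transcriptId, character(1))
  names(models) <- ids
  stripped <- stripTxVersion(ids)
  strippedIndex <- split(unname(ids), stripped)
  new("TranscriptomeAnnotation", models = models,
      strippedIndex = strippedIndex,
      stats = vapply(stats, as.integer, integer(1)))
}

#' Parse a GTF2 gene annotation into transcript models
#'
#' Reads exon, CDS and stop_codon records (via
#' \link[rtracklayer]{import}), groups them by `transcript_id`, orders each
#' transcript's exons 5'-to-3' by strand (file order is not trusted), and
#' derives the transcript-coordinate ORF span as the union of the CDS
#' records extended by any stop_codon records. Transcripts carrying CDS but
#' no exon records, or with overlapping exons, are skipped with a warning
#' and counted in the returned object's `stats`.
#'
#' @param path path to a GTF2 file, plain or gzip-compressed. Coordinates
#'   are 1-based inclusive as the format requires; comment lines (`#`) are
#'   skipped. Attributes must include `transcript_id` and `gene_id`;
#'   `gene_name` and `transcript_biotype` (or `transcript_type`) are kept
#'   when present, otherwise stored as empty strings.
#' @return a [TranscriptomeAnnotation-class].
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' sim <- simulateTranscriptome(nGenes = 2, seed = 1, gtfPath = gtf)
#' parseGTF(gtf)
#' @export
parseGTF <- function(path) {
  lines <- readTextLines(path)
  validateGtfLines(lines)
  if (!any(nzchar(trimws(lines)) & !grepl("^#", lines)))
    return(newAnnotation(list()))
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS", "stop_codon")
  # flatten to plain vectors once; the per-transcript loop below then
  # works free of S4 overhead
  type <- type[keep]
  chrom <- as.character(GenomicRanges::seqnames(gr))[keep]
  gstart <- GenomicRanges::start(gr)[keep]
  gend <- GenomicRanges::end(gr)[keep]
  strand <- as.character(GenomicRanges::strand(gr))[keep]
  txId <- as.character(md$transcript_id)[keep]
  geneId <- as.character(md$gene_id)[keep]
  geneName <- if ("gene_name" %in% colnames(md))
    as.character(md$gene_name)[keep] else character(length(type))
  biotypeCol <- intersect(c("transcript_biotype", "transcript_type"),
                          colnames(md))
  biotype <- if (length(biotypeCol))
    as.character(md[[biotypeCol[1L]]])[keep] else character(length(type))
  ok <- !is.na(txId)
  idxByTx <- split(seq_along(type)[ok], txId[ok])
  skipped <- c(cds_without_exon = 0L, overlapping_exons = 0L)
  models <- vector("list", length(idxByTx))
  names(models) <- names(idxByTx)
  isExon <- type == "exon"
  for (tid in names(idxByTx)) {
    idx <- idxByTx[[tid]]
    ei <- idx[isExon[idx]]
    if (length(ei) == 0L) {
      skipped["cds_without_exon"] <- skipped["cds_without_exon"] + 1L
      warning(sprintf("transcript %s has CDS but no exon records; skipped",
                      tid))
      next
    }
    str <- strand[ei[1L]]
    ord <- order(gstart[ei], decreasing = identical(str, "-"))
    es <- gstart[ei][ord]; ee <- gend[ei][ord]
    so <- sort(es); eo <- sort(ee)
    if (length(es) > 1L && any(so[-1L] <= eo[-length(eo)])) {
      skipped["overlapping_exons"] <- skipped["overlapping_exons"] + 1L
      warning(sprintf("transcript %s has overlapping exons; skipped", tid))
      next
    }
    model <- newTranscriptModel(
      transcriptId = tid,
      geneId   = firstAttr(geneId[idx]),
      geneName = firstAttr(geneName[idx]),
      biotype  = firstAttr(biotype[idx]),
      chrom = chrom[ei[1L]], strand = str,
      exonStarts = es, exonEnds = ee, check = FALSE)
    ci <- idx[!isExon[idx]]
    if (length(ci)) {
      ends0 <- c(gstart[ci] - 1L, gend[ci] - 1L)
      txPos <- genomicToTx(model, ends0)
      if (anyNA(txPos)) {
        warning(sprintf(
          "transcript %s has CDS outside its exons; CDS dropped", tid))
      } else {
        model@cdsTxStart <- min(txPos)
        model@cdsTxEnd <- max(txPos)
      }
    }
    models[[tid]] <- model
  }
  newAnnotation(Filter(Negate(is.null), models), skipped)
}

firstAttr <- function(x) {
  x <- as.character(x)
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x)) x[1L] else ""
}
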