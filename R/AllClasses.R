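#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- new2
NULL

#' TranscriptModel: one isoform's exon chain and coding span
#'
#' A `TranscriptModel` holds everything needed to map between a transcript's
#' own coordinate system and the genome: the ordered exon chain, the strand,
#' the cumulative exon lengths, and (for coding isoforms) the transcript
#' coordinates of the open reading frame. The ORF span is the union of the
#' annotation's CDS records extended by its stop_codon records, so
#' `cdsTxEnd()` points at the last base of the stop codon (Ensembl GTF
#' dialect, where CDS records exclude the stop codon).
#'
#' Exon spans are kept in transcript (5'-to-3') order: for a minus-strand
#' transcript the first exon is the one with the highest genomic
#' coordinates. They are stored as plain 1-based inclusive integer vectors
#' so that thousands of models can be built cheaply when parsing a
#' full annotation; the [exons()] accessor materialises them as a
#' \link[GenomicRanges]{GRanges}. All exported coordinate mapping uses
#' 0-based half-open coordinates, matching BED.
#'
#' @slot transcriptId,geneId,geneName,biotype single strings; `geneName`
#'   and `biotype` may be empty when the GTF lacks the attribute.
#' @slot chrom,strand single strings; strand is `"+"` or `"-"`.
#' @slot exonStarts,exonEnds 1-based inclusive genomic exon spans in
#'   transcript order.
#' @slot cumLengths integer vector, `cumLengths[i]` = total exonic length
#'   of exons `1..i`; the last element is the transcript length.
#' @slot cdsTxStart,cdsTxEnd 0-based transcript coordinates of the first
#'   and last ORF base (stop codon included), or `NA` for noncoding
#'   isoforms.
#'
#' @seealso [parseGTF()], [txToGenomic()], [regionLengths()]
#' @export
setClass("TranscriptModel",
  representation(
    transcriptId = "character",
    geneId       = "character",
    geneName     = "character",
    biotype      = "character",
    chrom        = "character",
    strand       = "character",
    exonStarts   = "integer",
    exonEnds     = "integer",
    cumLengths   = "integer",
    cdsTxStart   = "integer",
    cdsTxEnd     = "integer"
  ),
  prototype(
    transcriptId = "tx", geneId = "", geneName = "", biotype = "",
    chrom = "chr", strand = "+", exonStarts = 1L, exonEnds = 1L,
    cumLengths = 1L, cdsTxStart = NA_integer_, cdsTxEnd = NA_integer_
  )
)

setValidity("TranscriptModel", function(object) {
  msgs <- character()
  s <- object@exonStarts; e <- object@exonEnds
  n <- length(s)
  if (n < 1L || length(e) != n)
    msgs <- c(msgs, "exonStarts/exonEnds must be non-empty and equal length")
  if (length(object@transcriptId) != 1L || !nzchar(object@transcriptId))
    msgs <- c(msgs, "transcriptId must be a non-empty string")
  if (!object@strand %in% c("+", "-"))
    msgs <- c(msgs, "strand must be '+' or '-'")
  if (n >= 1L && length(e) == n) {
    if (any(s > e) || any(s < 1L))
      msgs <- c(msgs, "exon spans must satisfy 1 <= start <= end")
    if (n > 1L) {
      ok <- if (object@strand == "+") all(diff(s) > 0) else all(diff(s) < 0)
      if (!ok)
        msgs <- c(msgs, "exons must be in 5'-to-3' transcript order")
      o <- order(s)
      if (any(s[o][-1L] <= e[o][-n]))
        msgs <- c(msgs, "exons overlap on the genome")
    }
    cl <- object@cumLengths
    if (length(cl) != n || any(cl != cumsum(e - s + 1L)))
      msgs <- c(msgs, "cumLengths must be the cumulative exon widths")
    cs <- object@cdsTxStart; ce <- object@cdsTxEnd
    if (is.na(cs) != is.na(ce))
      msgs <- c(msgs, "cdsTxStart and cdsTxEnd must both be NA or both set")
    if (!is.na(cs) && length(cl) == n &&
        !(cs >= 0L && cs <= ce && ce < cl[n]))
      msgs <- c(msgs, "CDS span must satisfy 0 <= start <= end < length")
  }
  if (length(msgs)) msgs else TRUE
})

#' TranscriptomeAnnotation: a set of transcript models with id lookup
#'
#' Container returned by [parseGTF()] and [simulateTranscriptome()]. Models
#' are retrievable by exact transcript id, or (via
#' `lookupTranscript(..., stripVersions = TRUE)`) by version-stripped id,
#' which accommodates inputs whose ids carry Ensembl-style ".N" suffixes the
#' annotation lacks, or vice versa.
#'
#' @slot models named list of [TranscriptModel-class] objects, named by
#'   transcript id.
#' @slot strippedIndex named list mapping each version-stripped id to the
#'   character vector of full ids sharing it (used to detect ambiguity).
#' @slot stats named integer vector of parser bookkeeping (e.g. transcripts
#'   skipped for having CDS but no exon records).
#' @export
setClass("TranscriptomeAnnotation",
  representation(
    models        = "list",
    strippedIndex = "list",
    stats         = "integer"
  )
)

setValidity("TranscriptomeAnnotation", function(object) {
  msgs <- character()
  if (length(object@models)) {
    ids <- vapply(object@models, function(m) m@transcriptId, character(1))
    if (!identical(unname(ids), names(object@models)))
      msgs <- c(msgs, "models must be named by their own transcriptId")
    for (st in names(object@strippedIndex)) {
      full <- object@strippedIndex[[st]]
      if (!all(stripTxVersion(full) == st))
        msgs <- c(msgs, "strippedIndex entry inconsistent with its key")
    }
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TranscriptModel", function(object) {
  rl <- regionLengths(object)
  cds <- if (is.na(object@cdsTxStart)) "noncoding" else
    sprintf("ORF [%d,%d] (5'UTR %d / ORF %d / 3'UTR %d nt)",
            object@cdsTxStart, object@cdsTxEnd, rl[1L], rl[2L], rl[3L])
  cat(sprintf("TranscriptModel %s (%s%s)\n", object@transcriptId,
              object@geneId,
              if (nzchar(object@geneName)) paste0("/", object@geneName) else ""),
      sprintf("  %s:%s, %d exon(s), length %d nt, %s\n",
              object@chrom, object@strand, length(object@exonStarts),
              transcriptLength(object), cds),
      sep = "")
})

setMethod("show", "TranscriptomeAnnotation", function(object) {
  n <- length(object@models)
  nc <- sum(vapply(object@models, function(m) !is.na(m@cdsTxStart), logical(1)))
  cat(sprintf("TranscriptomeAnnotation: %d transcript model(s) (%d coding)\n",
              n, nc))
  if (length(object@stats) && any(object@stats > 0L)) {
    kept <- object@stats[object@stats > 0L]
    cat("  skipped:", paste(names(kept), kept, sep = "=", collapse = ", "),
        "\n")
  }
})
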