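#' @include AllClasses.R
NULL

#' Strip a trailing Ensembl-style version suffix from transcript ids
#'
#' Removes a final ".N" (digits only) from each id; ids without such a
#' suffix are returned unchanged.
#'
#' @param ids character vector of transcript ids.
#' @return character vector of the same length.
#' @examples
#' stripTxVersion(c("ENST00000367770.8", "TX1"))
#' @export
stripTxVersion <- function(ids) sub("\\.[0-9]+$", "", ids)

#' Accessors for TranscriptModel
#'
#' @param model a [TranscriptModel-class].
#' @return `transcriptLength()`: integer transcript length in nt.
#'   `exons()`: the exon `GRanges` in transcript order. `cdsTxStart()` /
#'   `cdsTxEnd()`: 0-based transcript coordinate of the first / last ORF
#'   base, `NA` for noncoding isoforms.
#' @name TranscriptModel-accessors
NULL

#' @rdname TranscriptModel-accessors
#' @export
transcriptLength <- function(model) model@cumLengths[length(model@cumLengths)]

#' @rdname TranscriptModel-accessors
#' @export
exons <- function(model) {
  GenomicRanges::GRanges(
    model@chrom,
    IRanges::IRanges(model@exonStarts, model@exonEnds),
    strand = model@strand)
}

#' @rdname TranscriptModel-accessors
#' @export
cdsTxStart <- function(model) model@cdsTxStart

#' @rdname TranscriptModel-accessors
#' @export
cdsTxEnd <- function(model) model@cdsTxEnd

#' 5'UTR / ORF / 3'UTR lengths of a transcript
#'
#' The ORF includes the stop codon. Components always sum to the transcript
#' length; either UTR may be 0 nt.
#'
#' @param model a [TranscriptModel-class].
#' @return integer vector `c(utr5, orf, utr3)`, or `c(NA, NA, NA)` for a
#'   noncoding transcript.
#' @examples
#' ann <- simulateTranscriptome(nGenes = 1, seed = 1)
#' regionLengths(lookupTranscript(ann, names(ann@models)[1]))
#' @export
regionLengths <- function(model) {
  len <- transcriptLength(model)
  cs <- model@cdsTxStart
  if (is.na(cs)) return(c(utr5 = NA_integer_, orf = NA_integer_,
                          utr3 = NA_integer_))
  orf <- model@cdsTxEnd - cs + 1L
  c(utr5 = cs, orf = orf, utr3 = len - cs - orf)
}

#' Map transcript coordinates to genomic coordinates
#'
#' Walks the exon chain: transcript base 0 is the 5'-most transcribed base,
#' which for a minus-strand transcript is the highest genomic coordinate of
#' its 5'-most exon. Vectorised over `p`.
#'
#' @param model a [TranscriptModel-class].
#' @param p integer vector of 0-based transcript positions, each in
#'   `[0, transcriptLength(model))`.
#' @return data.frame with columns `chrom`, `pos` (0-based genomic
#'   position) and `strand`, one row per element of `p`.
#' @examples
#' ann <- simulateTranscriptome(nGenes = 1, seed = 1)
#' m <- ann@models[[1]]
#' txToGenomic(m, 0:4)
#' @export
txToGenomic <- function(model, p) {
  p <- as.integer(p)
  len <- transcriptLength(model)
  bad <- is.na(p) | p < 0L | p >= len
  if (any(bad))
    stop(sprintf("transcript position out of range for %s (length %d): %s",
                 model@transcriptId, len,
                 paste(p[bad], collapse = ", ")))
  cum0 <- c(0L, model@cumLengths[-length(model@cumLengths)])
  idx <- findInterval(p, cum0)
  off <- p - cum0[idx]
  pos <- if (model@strand == "+") (model@exonStarts[idx] - 1L) + off
         else                     (model@exonEnds[idx] - 1L) - off
  data.frame(chrom = model@chrom, pos = pos, strand = model@strand,
             stringsAsFactors = FALSE)
}

#' Map genomic coordinates back to transcript coordinates
#'
#' Inverse of [txToGenomic()]: returns `NA` for positions that are intronic
#' or outside the transcript's exons. Vectorised over `g`.
#'
#' @param model a [TranscriptModel-class].
#' @param g integer vector of 0-based genomic positions.
#' @return integer vector of 0-based transcript positions, `NA` where
#'   unmapped.
#' @export
genomicToTx <- function(model, g) {
  g <- as.integer(g)
  s0 <- model@exonStarts - 1L    # 0-based inclusive
  e0 <- model@exonEnds           # 0-based exclusive
  cum0 <- c(0L, model@cumLengths[-length(model@cumLengths)])
  out <- rep(NA_integer_, length(g))
  for (i in seq_along(s0)) {
    hit <- !is.na(g) & g >= s0[i] & g < e0[i]
    if (any(hit)) {
      out[hit] <- if (model@strand == "+") cum0[i] + (g[hit] - s0[i])
                  else            cum0[i] + ((e0[i] - 1L) - g[hit])
    }
  }
  out
}

#' Metatranscript coordinate of a transcript position
#'
#' Linearly rescales a position on a coding transcript onto the virtual
#' metatranscript axis: the 5'UTR spans [0,1), the ORF [1,2) and the 3'UTR
#' [2,3), so `floor()` of the value identifies the region. The first ORF
#' base maps to exactly 1 and the first 3'UTR base to exactly 2; with
#' 0-based positions the final transcript base stays strictly below 3.
#'
#' @param regions integer vector `c(utr5, orf, utr3)` as returned by
#'   [regionLengths()]; the ORF length must be positive.
#' @param p integer vector of 0-based transcript positions.
#' @return numeric vector in `[0, 3)`; `NA` if `regions` is the noncoding
#'   sentinel.
#' @examples
#' metacoordinate(c(50, 150, 150), c(25, 50, 275))  # 0.5, 1.0, 2.5
#' @export
metacoordinate <- function(regions, p) {
  if (anyNA(regions)) return(rep(NA_real_, length(p)))
  L5 <- regions[[1L]]; Lc <- regions[[2L]]; L3 <- regions[[3L]]
  stopifnot(Lc > 0)
  p <- as.integer(p)
  len <- L5 + Lc + L3
  if (any(p < 0L | p >= len, na.rm = TRUE))
    stop("transcript position out of range for metacoordinate")
  ifelse(p < L5, p / L5,
    ifelse(p < L5 + Lc, 1 + (p - L5) / Lc,
                        2 + (p - L5 - Lc) / L3))
}

#' Distances to the nearest splice junctions
#'
#' Junctions are the boundaries between consecutive exons; in transcript
#' coordinates a junction sits between base `J - 1` and base `J`, where `J`
#' is a cumulative exon length. Distances are 1-anchored: a base
#' immediately flanking a junction on either side has distance 1. `NA`
#' means no junction exists on that side (single-exon transcripts give
#' `NA`, `NA`).
#'
#' @param model a [TranscriptModel-class].
#' @param p integer vector of 0-based transcript positions.
#' @return data.frame with integer columns `up` and `down` (nt to the
#'   nearest upstream / downstream junction).
#' @export
junctionDistances <- function(model, p) {
  p <- as.integer(p)
  len <- transcriptLength(model)
  if (any(p < 0L | p >= len, na.rm = TRUE))
    stop(sprintf("transcript position out of range for %s",
                 model@transcriptId))
  J <- model@cumLengths[-length(model@cumLengths)]
  if (length(J) == 0L)
    return(data.frame(up = rep(NA_integer_, length(p)),
                      down = rep(NA_integer_, length(p))))
  # nearest J <= p upstream, nearest J > p downstream
  idx <- findInterval(p, J)               # number of junctions with J <= p
  up <- ifelse(idx >= 1L, p - J[pmax(idx, 1L)] + 1L, NA_integer_)
  down <- ifelse(idx < length(J), J[pmin(idx + 1L, length(J))] - p,
                 NA_integer_)
  data.frame(up = as.integer(up), down = as.integer(down))
}

#' Signed distances to the start and stop codon
#'
#' Distances are in nt along the transcript, negative 5' of the landmark
#' and positive 3' of it; 0 means the position is the landmark base itself.
#' The start-codon landmark is the first ORF base and the stop-codon
#' landmark the last stop-codon base.
#'
#' @param model a [TranscriptModel-class].
#' @param p integer vector of 0-based transcript positions.
#' @return data.frame with integer columns `toStart` and `toStop`, all `NA`
#'   for noncoding transcripts.
#' @export
codonDistances <- function(model, p) {
  p <- as.integer(p)
  if (is.na(model@cdsTxStart))
    return(data.frame(toStart = rep(NA_integer_, length(p)),
                      toStop = rep(NA_integer_, length(p))))
  data.frame(toStart = p - model@cdsTxStart, toStop = p - model@cdsTxEnd)
}

#' Retrieve a transcript model by id
#'
#' Exact id match is always tried first; with `stripVersions = TRUE` a
#' failed exact match falls back to comparing ids with trailing ".N"
#' version suffixes removed from both sides.
#'
#' @param annotation a [TranscriptomeAnnotation-class].
#' @param txId single transcript id.
#' @param stripVersions fall back to version-stripped matching.
#' @return a [TranscriptModel-class], or `NULL` when not found.
#' @export
lookupTranscript <- function(annotation, txId, stripVersions = FALSE) {
  m <- annotation@models[[txId]]
  if (!is.null(m)) return(m)
  if (!stripVersions) return(NULL)
  st <- stripTxVersion(txId)
  cand <- annotation@strippedIndex[[st]]
  if (is.null(cand)) return(NULL)
  if (length(cand) > 1L)
    stop(sprintf("transcript id '%s' is ambiguous after version stripping: %s",
                 txId, paste(cand, collapse = ", ")))
  annotation@models[[cand]]
}
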