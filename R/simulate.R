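#' @include gtf.R
NULL

# --- independent brute-force oracles ---------------------------------------
#
# These deliberately avoid the package's arithmetic mapping code: genomic
# positions come from naive per-base enumeration of the exon chain, and
# distances from explicit minimisation over the junction list. The truth
# tables produced by simulateSites() are computed with these, so they can
# serve as an external check on txToGenomic()/annotateSites().

bruteGenomicPositions <- function(model) {
  unlist(lapply(seq_along(model@exonStarts), function(i) {
    s0 <- model@exonStarts[i] - 1L
    e0 <- model@exonEnds[i] - 1L
    if (model@strand == "+") seq.int(s0, e0) else seq.int(e0, s0)
  }), use.names = FALSE)
}

bruteJunctionDistances <- function(model, p) {
  J <- model@cumLengths[-length(model@cumLengths)]
  up <- NA_integer_; down <- NA_integer_
  for (j in J) {
    if (j <= p) {
      d <- p - j + 1L
      if (is.na(up) || d < up) up <- d
    } else {
      d <- j - p
      if (is.na(down) || d < down) down <- d
    }
  }
  c(up = up, down = down)
}

bruteMetacoordinate <- function(model, p) {
  if (is.na(model@cdsTxStart)) return(NA_real_)
  len <- transcriptLength(model)
  # label every base with its region, then interpolate within the region
  lab <- rep.int(c(0L, 1L, 2L),
                 c(model@cdsTxStart,
                   model@cdsTxEnd - model@cdsTxStart + 1L,
                   len - model@cdsTxEnd - 1L))
  r <- lab[p + 1L]
  inRegion <- which(lab == r)
  r + (match(p + 1L, inRegion) - 1L) / length(inRegion)
}

# --- transcriptome generator -----------------------------------------------

randInt <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

# genomic blocks (1-based inclusive) covering transcript range [p0, p1]
txRangeToBlocks <- function(model, p0, p1) {
  cum <- model@cumLengths
  cum0 <- c(0L, cum[-length(cum)])
  blocks <- list()
  for (i in seq_along(cum)) {
    lo <- max(p0, cum0[i]); hi <- min(p1, cum[i] - 1L)
    if (lo > hi) next
    if (model@strand == "+") {
      s0 <- model@exonStarts[i] - 1L
      blocks[[length(blocks) + 1L]] <-
        c(s0 + (lo - cum0[i]) + 1L, s0 + (hi - cum0[i]) + 1L)
    } else {
      e0 <- model@exonEnds[i] - 1L
      blocks[[length(blocks) + 1L]] <-
        c(e0 - (hi - cum0[i]) + 1L, e0 - (lo - cum0[i]) + 1L)
    }
  }
  do.call(rbind, blocks)
}

gtfAttr <- function(geneId, txId, geneName, biotype) {
  sprintf(paste0('gene_id "%s"; transcript_id "%s"; gene_name "%s"; ',
                 'transcript_biotype "%s";'),
          geneId, txId, geneName, biotype)
}

#' Simulate a transcriptome annotation with known structure
#'
#' Generates a deterministic, seeded set of genes tiled along one virtual
#' chromosome (`chrS`, 1000-nt intergenic gaps). All isoforms of a gene
#' share the gene's exon chain but draw independent 5'UTR/3'UTR (hence
#' CDS) boundaries, so genes with two or more coding isoforms routinely
#' contain genomic positions that are CDS in one isoform and UTR in
#' another — the situation that makes isoform-resolved annotation matter.
#' A fraction of isoforms is left noncoding.
#'
#' The annotation object is constructed directly from the generator's
#' interval arithmetic; the optional GTF (exon + CDS + stop_codon records,
#' Ensembl dialect: CDS excludes the stop codon) is an independent
#' serialisation of the same structure, so `parseGTF(gtfPath)` must
#' reproduce the returned object — a round-trip exercised in the tests.
#'
#' @param nGenes number of genes.
#' @param isoformsPerGene,exonsPerTranscript,exonLen,intronLen,utr5Len,utr3Len
#'   integer ranges `c(min, max)` sampled uniformly per gene/transcript.
#' @param strandProb probability that a gene is on the plus strand.
#' @param noncodingProb probability that an isoform carries no ORF.
#' @param seed integer seed; identical arguments and seed give
#'   byte-identical GTF output.
#' @param gtfPath if non-`NULL`, write the GTF there (first line records
#'   the seed as a comment).
#' @return a [TranscriptomeAnnotation-class].
#' @export
simulateTranscriptome <- function(nGenes = 50L,
                                  isoformsPerGene = c(1L, 3L),
                                  exonsPerTranscript = c(1L, 8L),
                                  exonLen = c(80L, 400L),
                                  intronLen = c(100L, 2000L),
                                  utr5Len = c(10L, 300L),
                                  utr3Len = c(50L, 500L),
                                  strandProb = 0.5,
                                  noncodingProb = 0.1,
                                  seed = 1L,
                                  gtfPath = NULL) {
  stopifnot(nGenes >= 1L, exonLen[1L] >= 1L, intronLen[1L] >= 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  cursor <- 1000L
  models <- list()
  gtfChunks <- list(sprintf("#! txmeta simulated transcriptome; seed=%d",
                            seed))
  for (g in seq_len(nGenes)) {
    geneId <- sprintf("GENE%03d", g)
    geneName <- sprintf("SYN%03d", g)
    strand <- if (stats::runif(1) < strandProb) "+" else "-"
    nExon <- randInt(1L, exonsPerTranscript)
    widths <- randInt(nExon, exonLen)
    gaps <- if (nExon > 1L) randInt(nExon - 1L, intronLen) else integer()
    starts <- cursor + cumsum(c(0L, widths[-nExon] + gaps))
    ends <- starts + widths - 1L
    cursor <- ends[nExon] + 1000L
    txOrd <- if (strand == "+") seq_len(nExon) else rev(seq_len(nExon))
    len <- sum(widths)
    for (iso in seq_len(randInt(1L, isoformsPerGene))) {
      txId <- sprintf("%s.T%d", geneId, iso)
      coding <- stats::runif(1) >= noncodingProb
      cs <- NA_integer_; ce <- NA_integer_
      if (coding) {
        u5 <- min(randInt(1L, utr5Len), len - 7L)
        u3 <- min(randInt(1L, utr3Len), len - u5 - 6L)
        orf <- len - u5 - u3
        orf <- orf - orf %% 3L           # keep the ORF in frame
        if (orf >= 6L && u5 >= 0L) {
          cs <- u5; ce <- u5 + orf - 1L
        }
      }
      biotype <- if (is.na(cs)) "lncRNA" else "protein_coding"
      model <- newTranscriptModel(txId, geneId, geneName, biotype,
                                  "chrS", strand,
                                  starts[txOrd], ends[txOrd], cs, ce,
                                  check = FALSE)
      models[[txId]] <- model
      attrs <- gtfAttr(geneId, txId, geneName, biotype)
      gtfChunks[[length(gtfChunks) + 1L]] <- sprintf(
        "chrS\tsim\texon\t%d\t%d\t.\t%s\t.\t%s",
        starts, ends, strand, attrs)
      if (!is.na(cs)) {
        cdsB <- txRangeToBlocks(model, cs, ce - 3L)
        stopB <- txRangeToBlocks(model, ce - 2L, ce)
        gtfChunks[[length(gtfChunks) + 1L]] <-
          c(sprintf("chrS\tsim\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                    cdsB[, 1L], cdsB[, 2L], strand, attrs),
            sprintf("chrS\tsim\tstop_codon\t%d\t%d\t.\t%s\t0\t%s",
                    stopB[, 1L], stopB[, 2L], strand, attrs))
      }
    }
  }
  if (!is.null(gtfPath))
    writeLines(unlist(gtfChunks, use.names = FALSE), gtfPath)
  newAnnotation(models)
}

#' Simulate RNA feature sites with a brute-force truth table
#'
#' Draws sites on the transcripts of `annotation` under one of three
#' positional models and assigns each a ground-truth label plus a
#' simulated stoichiometry percentage: positives are drawn uniformly above
#' `threshold`, negatives below, so filtering at `> threshold` recovers
#' the labels exactly.
#'
#' \describe{
#'   \item{`uniform`}{transcripts sampled proportional to length,
#'     positions uniform; every site positive with `positiveRateOutside`.}
#'   \item{`junction_depleted`}{positions uniform, but a site within
#'     `zone` nt of its nearest splice junction (on either side) is
#'     positive with `positiveRateInside`, others with
#'     `positiveRateOutside` — mimicking the exclusion of m6A from the
#'     vicinity of exon-exon junctions.}
#'   \item{`codon_enriched`}{positive sites are placed around
#'     `anchor` codon + `offset` nt (Gaussian, sd `sdNt`), negative sites
#'     uniformly, concentrating the positive proportion at the offset.}
#' }
#'
#' The companion truth table stores, for every site, the expected outputs
#' of the annotation pipeline (genomic position, metacoordinate, codon and
#' junction distances) computed by naive per-base enumeration of the exon
#' chain — an oracle independent of the package's mapping arithmetic.
#'
#' @param annotation a [TranscriptomeAnnotation-class].
#' @param nSites number of sites to draw.
#' @param siteModel positional model, see above.
#' @param zone half-width in nt of the junction-proximal depletion zone.
#' @param positiveRateInside,positiveRateOutside positive-site
#'   probabilities inside/outside the zone (`junction_depleted`) or the
#'   overall positive rate (`codon_enriched`, `uniform` use
#'   `positiveRateOutside`).
#' @param anchor,offset,sdNt placement of positives for `codon_enriched`.
#' @param threshold stoichiometry cutoff (percent) separating simulated
#'   positives from negatives.
#' @param seed integer seed; outputs are byte-identical given identical
#'   arguments.
#' @param bedPath,truthPath optional paths to write the BED3+ site file
#'   (columns: transcript, start, end, truth label, stoichiometry) and the
#'   tab-separated truth table.
#' @return list with elements `sites` (data.frame as [readSites()] would
#'   return) and `truth` (data.frame).
#' @export
simulateSites <- function(annotation, nSites = 1000L,
                          siteModel = c("uniform", "junction_depleted",
                                        "codon_enriched"),
                          zone = 200L,
                          positiveRateInside = 0,
                          positiveRateOutside = 0.3,
                          anchor = c("stop", "start"),
                          offset = 50L, sdNt = 20L,
                          threshold = 10,
                          seed = 1L,
                          bedPath = NULL, truthPath = NULL) {
  siteModel <- match.arg(siteModel)
  anchor <- match.arg(anchor)
  stopifnot(length(annotation@models) > 0L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  models <- annotation@models
  lens <- vapply(models, transcriptLength, integer(1))
  if (siteModel == "codon_enriched") {
    codingIds <- names(models)[!vapply(models, function(m)
      is.na(m@cdsTxStart), logical(1))]
    stopifnot(length(codingIds) > 0L)
  }
  pool <- if (siteModel == "codon_enriched") codingIds else names(models)
  txPick <- sample(pool, nSites, replace = TRUE,
                   prob = lens[pool] / sum(lens[pool]))
  pos <- integer(nSites); label <- logical(nSites)
  for (i in seq_len(nSites)) {
    m <- models[[txPick[i]]]
    len <- transcriptLength(m)
    if (siteModel == "codon_enriched") {
      label[i] <- stats::runif(1) < positiveRateOutside
      if (label[i]) {
        a <- if (anchor == "start") m@cdsTxStart else m@cdsTxEnd
        p <- a + offset + as.integer(round(stats::rnorm(1, 0, sdNt)))
        pos[i] <- min(max(p, 0L), len - 1L)
      } else pos[i] <- sample.int(len, 1L) - 1L
    } else {
      pos[i] <- sample.int(len, 1L) - 1L
      if (siteModel == "junction_depleted") {
        jd <- bruteJunctionDistances(m, pos[i])
        inside <- !is.na(jd["up"]) && jd["up"] <= zone ||
                  !is.na(jd["down"]) && jd["down"] <= zone
        rate <- if (inside) positiveRateInside else positiveRateOutside
        label[i] <- stats::runif(1) < rate
      } else {
        label[i] <- stats::runif(1) < positiveRateOutside
      }
    }
  }
  stoich <- ifelse(label,
                   stats::runif(nSites, threshold + 1e-6, 100),
                   stats::runif(nSites, 0, threshold))
  basePos <- new.env(parent = emptyenv())   # per-transcript enumeration cache
  gpos <- integer(nSites); chrom <- character(nSites)
  strands <- character(nSites); meta <- numeric(nSites)
  absStart <- rep(NA_integer_, nSites); absEnd <- rep(NA_integer_, nSites)
  upJ <- integer(nSites); downJ <- integer(nSites)
  for (i in seq_len(nSites)) {
    tid <- txPick[i]; m <- models[[tid]]; p <- pos[i]
    if (is.null(basePos[[tid]])) basePos[[tid]] <- bruteGenomicPositions(m)
    gpos[i] <- basePos[[tid]][p + 1L]
    jd <- bruteJunctionDistances(m, p)
    upJ[i] <- jd[["up"]]; downJ[i] <- jd[["down"]]
    chrom[i] <- m@chrom; strands[i] <- m@strand
    meta[i] <- bruteMetacoordinate(m, p)
    if (!is.na(m@cdsTxStart)) {
      absStart[i] <- p - m@cdsTxStart
      absEnd[i] <- p - m@cdsTxEnd
    }
  }
  truth <- data.frame(
    transcript = txPick, pos = pos, chrom = chrom, gpos = gpos,
    strand = strands, meta = meta,
    abs_cds_start = absStart, abs_cds_end = absEnd,
    up_junc_dist = upJ, down_junc_dist = downJ,
    label = label, stoich = stoich, stringsAsFactors = FALSE)
  sites <- data.frame(transcript = txPick, start = pos, end = pos + 1L,
                      label = ifelse(label, "pos", "neg"),
                      stoich = sprintf("%.3f", stoich),
                      stringsAsFactors = FALSE)
  if (!is.null(bedPath)) {
    writeLines(c(sprintf("#! txmeta simulated sites; seed=%d", seed),
                 do.call(paste, c(sites, sep = "\t"))), bedPath)
  }
  if (!is.null(truthPath))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(sites = sites, truth = truth)
}
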