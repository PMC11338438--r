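# Two hand-constructed transcripts used throughout the unit tests.
#
# TX1: chr1, '+', exons 101-200 / 301-450 / 601-700 (1-based inclusive),
#      CDS 151-200 + 301-397, stop codon 398-400.
#      Transcript length 350; exon1 covers transcript 0-99, exon2 100-249,
#      exon3 250-349. The ORF starts 50 nt into exon1 (transcript 50) and
#      ends at the last stop-codon base: genomic 400 = transcript
#      100 + (400-301) = 199. Regions: 5'UTR 50, ORF 150, 3'UTR 150.
# TX2: chr2, '-', exons 1001-1100 / 1201-1300; noncoding, length 200.
#      Transcript base 0 is genomic 1300 (1-based) = 1299 (0-based).

toyGtfLines <- function() {
  a1 <- 'gene_id "G1"; transcript_id "TX1"; gene_name "GENEONE"; transcript_biotype "protein_coding";'
  a2 <- 'gene_id "G2"; transcript_id "TX2";'
  c(sprintf("chr1\ttest\texon\t%d\t%d\t.\t+\t.\t%s",
            c(101L, 301L, 601L), c(200L, 450L, 700L), a1),
    sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t+\t0\t%s",
            c(151L, 301L), c(200L, 397L), a1),
    sprintf("chr1\ttest\tstop_codon\t398\t400\t.\t+\t0\t%s", a1),
    sprintf("chr2\ttest\texon\t%d\t%d\t.\t-\t.\t%s",
            c(1001L, 1201L), c(1100L, 1300L), a2))
}

toyGtfFile <- function(lines = toyGtfLines()) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

toyAnnotation <- function(lines = toyGtfLines()) {
  parseGTF(toyGtfFile(lines))
}

writeBed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# naive per-base genomic enumeration, independent of the package's
# mapping arithmetic (test-local duplicate of the fixture oracle)
enumerateGenomic <- function(model) {
  out <- integer(0)
  for (i in seq_along(model@exonStarts)) {
    s0 <- model@exonStarts[i] - 1L
    e0 <- model@exonEnds[i] - 1L
    out <- c(out, if (model@strand == "+") s0:e0 else e0:s0)
  }
  out
}

newAnnotationForTest <- function(m) {
  txmeta:::newAnnotation(stats::setNames(list(m), m@transcriptId))
}

randomAnnotation <- function(seed, nGenes = 40) {
  simulateTranscriptome(nGenes = nGenes, isoformsPerGene = c(1L, 3L),
                        seed = seed)
}
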