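test_that("metacoordinate rescales each region linearly onto [0,3)", {
  reg <- c(50L, 150L, 150L)
  expect_equal(metacoordinate(reg, 25L), 0.5)
  expect_equal(metacoordinate(reg, 50L), 1.0)     # first ORF base
  expect_equal(metacoordinate(reg, 200L), 2.0)    # first 3'UTR base
  expect_equal(metacoordinate(reg, 275L), 2.5)
  expect_equal(metacoordinate(reg, 0L), 0)
  expect_lt(metacoordinate(reg, 349L), 3)         # final base stays < 3
  expect_true(is.na(metacoordinate(c(NA, NA, NA), 10L)))
  expect_error(metacoordinate(reg, 350L), "out of range")
})

test_that("metacoordinate handles degenerate zero-length UTRs", {
  expect_equal(metacoordinate(c(0L, 100L, 0L), 0L), 1.0)
  expect_equal(metacoordinate(c(0L, 100L, 0L), 99L), 1.99)
})

test_that("metacoordinate is strictly increasing and floor() identifies the region", {
  models <- randomAnnotation(seed = 9)@models
  coding <- Filter(function(m) !is.na(cdsTxStart(m)), models)
  for (m in coding[1:15]) {
    rl <- regionLengths(m)
    p <- seq_len(transcriptLength(m)) - 1L
    meta <- metacoordinate(rl, p)
    expect_true(all(diff(meta) > 0))
    expect_true(all(meta >= 0 & meta < 3))
    region <- floor(meta)
    expect_identical(region < 1, p < rl[[1L]])
    expect_identical(region == 1, p >= rl[[1L]] & p < rl[[1L]] + rl[[2L]])
  }
})

test_that("junction distances match the toy transcript and are 1-anchored", {
  tx1 <- lookupTranscript(toyAnnotation(), "TX1")
  jd <- junctionDistances(tx1, c(90L, 110L, 99L, 100L))
  expect_identical(jd$up, c(NA_integer_, 11L, NA_integer_, 1L))
  expect_identical(jd$down, c(10L, 140L, 1L, 150L))
})

test_that("single-exon transcripts have no junction distances", {
  lines <- "chr1\tt\texon\t1\t100\t.\t+\t.\tgene_id \"G\"; transcript_id \"T\";"
  m <- lookupTranscript(toyAnnotation(lines), "T")
  jd <- junctionDistances(m, c(0L, 50L, 99L))
  expect_true(all(is.na(jd$up)) && all(is.na(jd$down)))
})

test_that("junction distances equal the brute-force minimum on random transcripts", {
  models <- randomAnnotation(seed = 202, nGenes = 50)@models
  expect_gte(length(models), 50L)
  for (m in models) {
    J <- m@cumLengths[-length(m@cumLengths)]
    p <- seq_len(transcriptLength(m)) - 1L
    jd <- junctionDistances(m, p)
    bruteUp <- vapply(p, function(q) {
      d <- q - J[J <= q] + 1L
      if (length(d)) min(d) else NA_integer_
    }, integer(1))
    bruteDown <- vapply(p, function(q) {
      d <- J[J > q] - q
      if (length(d)) min(d) else NA_integer_
    }, integer(1))
    expect_identical(jd$up, bruteUp)
    expect_identical(jd$down, bruteDown)
  }
})

test_that("codon distances are signed offsets from the ORF boundaries", {
  ann <- toyAnnotation()
  tx1 <- lookupTranscript(ann, "TX1")
  cd <- codonDistances(tx1, c(50L, 210L))
  expect_identical(cd$toStart, c(0L, 160L))
  expect_identical(cd$toStop, c(-149L, 11L))
  tx2 <- lookupTranscript(ann, "TX2")
  expect_true(all(is.na(codonDistances(tx2, 0L))))
})

test_that("abs_cds_end - abs_cds_start is constant at -(orf_len - 1)", {
  models <- randomAnnotation(seed = 31)@models
  coding <- Filter(function(m) !is.na(cdsTxStart(m)), models)
  for (m in coding[1:20]) {
    p <- sample.int(transcriptLength(m), 5L) - 1L
    cd <- codonDistances(m, p)
    orfLen <- regionLengths(m)[["orf"]]
    expect_true(all(cd$toStop - cd$toStart == -(orfLen - 1L)))
  }
})

test_that("annotateSites composes the per-site annotations correctly", {
  ann <- toyAnnotation()
  bed <- writeBed("TX1\t275\t276\t0.9")
  out <- annotateSites(readSites(bed), ann)
  expect_equal(out$transcript_metacoordinate, 2.5)
  expect_identical(out$abs_cds_start, 225L)
  expect_identical(out$abs_cds_end, 76L)
  expect_identical(out$up_junc_dist, 26L)
  expect_true(is.na(out$down_junc_dist))
  expect_identical(out$tx_len, 350L)
  expect_identical(out$cds_start, 50L)
  expect_identical(out$cds_end, 199L)
  expect_identical(out$tx_end_dist, 350L - 1L - 275L)
  expect_identical(out$gene_id, "G1")
})

test_that("annotate output has input + 12 columns and NA-propagates on noncoding", {
  ann <- toyAnnotation()
  bed <- writeBed(c("TX1\t10\t11\t0.86\textra", "TX2\t150\t151\t0.2\tmore"))
  sites <- readSites(bed)
  out <- annotateSites(sites, ann)
  expect_identical(ncol(out), ncol(sites) + 12L)
  nc <- out[out$transcript == "TX2", ]
  expect_identical(nc$gene_id, "G2")
  expect_true(is.na(nc$transcript_metacoordinate))
  expect_true(is.na(nc$abs_cds_start) && is.na(nc$abs_cds_end))
  expect_identical(nc$up_junc_dist, 51L)   # TX2 junction at tx coord 100
  expect_true(is.na(nc$down_junc_dist))
  # losslessness: the first n columns are the input, byte for byte
  dest <- withr::local_tempfile()
  writeSiteTable(out, dest)
  rebuilt <- vapply(strsplit(readLines(dest), "\t", fixed = TRUE),
                    function(f) paste(f[1:5], collapse = "\t"), "")
  expect_identical(rebuilt, c("TX1\t10\t11\t0.86\textra",
                              "TX2\t150\t151\t0.2\tmore"))
})

test_that("annotateSites matches the generator's brute-force truth table", {
  ann <- randomAnnotation(seed = 404)
  sim <- simulateSites(ann, nSites = 400, seed = 405)
  out <- annotateSites(sim$sites, ann)
  expect_identical(nrow(out), 400L)
  expect_equal(out$transcript_metacoordinate, sim$truth$meta)
  expect_identical(out$abs_cds_start, sim$truth$abs_cds_start)
  expect_identical(out$abs_cds_end, sim$truth$abs_cds_end)
  expect_identical(out$up_junc_dist, sim$truth$up_junc_dist)
  expect_identical(out$down_junc_dist, sim$truth$down_junc_dist)
})

test_that("annotateSites skips and counts missing transcripts", {
  ann <- toyAnnotation()
  lines <- c(sprintf("TX1\t%d\t%d\tx", 0:8 * 30, 0:8 * 30 + 1),
             "TXgone\t5\t6\tx")
  out <- annotateSites(readSites(writeBed(lines)), ann)
  expect_identical(nrow(out), 9L)
  expect_identical(runStats(out)[["missing_transcript"]], 1L)
})
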