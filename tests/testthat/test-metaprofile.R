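metaFrame <- function(meta, value) {
  data.frame(transcript = "T", start = seq_along(meta), end = seq_along(meta) + 1,
             transcript_metacoordinate = meta, stoich = value)
}

test_that("default segmentation is 120 bins of width 0.025 spanning [0,3]", {
  tab <- binMetaTranscript(metaFrame(c(0, 1.5, 2.999), c(1, 20, 50)),
                           "stoich", ">", 10)
  expect_identical(nrow(tab), 120L)
  expect_equal(unique(round(diff(tab$axis_value), 10)), 0.025)
  expect_equal(tab$axis_value[1], 0.0125)
  expect_equal(tab$axis_value[120], 3 - 0.0125)
})

test_that("bin assignment follows the floor rule with clamping", {
  tab <- binMetaTranscript(metaFrame(c(0.5, 0, 2.999), c(99, 99, 99)),
                           "stoich", ">", 10)
  expect_identical(which(tab$n_total > 0), c(1L, 21L, 120L))  # bins 0, 20, 119
})

test_that("per-bin proportion is positives over tested sites", {
  x <- metaFrame(rep(0.5, 4), c(20, 5, 5, 5))   # one of four passes > 10
  tab <- binMetaTranscript(x, "stoich", ">", 10)
  expect_identical(tab$n_total[21], 4L)
  expect_identical(tab$n_positive[21], 1L)
  expect_equal(tab$proportion[21], 0.25)
  expect_true(all(is.na(tab$proportion[tab$n_total == 0])))
})

test_that("sites with NA metacoordinate or non-numeric values are excluded", {
  x <- metaFrame(c(0.5, NA, 0.5), c("20", "30", "oops"))
  tab <- binMetaTranscript(x, "stoich", ">", 10)
  expect_identical(sum(tab$n_total), 1L)
  pred <- evalPredicate(x, "stoich", ">", 10)
  expect_identical(attr(pred, "nonNumeric"), 1L)
})

test_that("binning conserves counts and is invariant under shuffling", {
  ann <- randomAnnotation(seed = 11)
  sim <- simulateSites(ann, nSites = 500, seed = 12)
  out <- annotateSites(sim$sites, ann)
  tab <- binMetaTranscript(out, "stoich", ">", 10)
  expect_identical(sum(tab$n_total),
                   sum(!is.na(out$transcript_metacoordinate)))
  set.seed(1)
  tab2 <- binMetaTranscript(out[sample(nrow(out)), ], "stoich", ">", 10)
  expect_equal(tab, tab2)
})

test_that("complementary predicates partition every bin", {
  ann <- randomAnnotation(seed = 21)
  sim <- simulateSites(ann, nSites = 400, seed = 22)
  out <- annotateSites(sim$sites, ann)
  gt <- binMetaTranscript(out, "stoich", ">", 10)
  le <- binMetaTranscript(out, "stoich", "<=", 10)
  expect_identical(gt$n_total, le$n_total)
  expect_identical(gt$n_positive, gt$n_total - le$n_positive)
})

test_that("unknown filter columns name the available ones", {
  expect_error(binMetaTranscript(metaFrame(0.5, 1), "nope", ">", 1),
               "available columns.*stoich")
  expect_error(evalPredicate(metaFrame(0.5, 1), 99, ">", 1), "out of range")
})

test_that("junction profiles key each site to its nearest junction once", {
  x <- data.frame(up_junc_dist = c(11L, NA, 400L),
                  down_junc_dist = c(250L, 7L, NA),
                  val = c(50, 50, 50))
  prof <- junctionProfile(x, "val", ">", 10, window = 300)
  up <- prof$upstream; dn <- prof$downstream
  expect_identical(nrow(up), 300L)
  expect_identical(nrow(dn), 300L)
  expect_identical(up$n_total[up$axis_value == -11], 1L)
  expect_identical(sum(up$n_total), 1L)     # 400 is beyond the window
  expect_identical(dn$n_total[dn$axis_value == 250], 1L)
  expect_identical(dn$n_total[dn$axis_value == 7], 1L)
  expect_identical(sum(dn$n_total), 2L)
})

test_that("codon profiles differ from each other only by the keying column", {
  x <- data.frame(abs_cds_start = c(-20L, 5L, 300L),
                  abs_cds_end = c(11L, -40L, NA), val = c(50, 5, 50))
  st <- codonProfile(x, "val", ">", 10, window = 100, anchor = "start")
  sp <- codonProfile(x, "val", ">", 10, window = 100, anchor = "stop")
  expect_identical(nrow(st), 201L)
  expect_identical(st$n_total[st$axis_value == -20], 1L)
  expect_identical(st$n_positive[st$axis_value == 5], 0L)
  expect_identical(sum(st$n_total), 2L)     # +300 outside the window
  expect_identical(sp$n_total[sp$axis_value == 11], 1L)
  expect_identical(sum(sp$n_total), 2L)
})

test_that("codon-enriched fixtures put the positive mode at the set offset", {
  ann <- randomAnnotation(seed = 61, nGenes = 60)
  sim <- simulateSites(ann, nSites = 3000, siteModel = "codon_enriched",
                       anchor = "stop", offset = 50L, sdNt = 10L,
                       positiveRateOutside = 0.5, seed = 62)
  out <- annotateSites(sim$sites, ann)
  tab <- codonProfile(out, "stoich", ">", 10, window = 100, anchor = "stop")
  agg <- stats::aggregate(
    cbind(n_positive, n_total) ~ floor(axis_value / 20), data = tab, sum)
  prop <- agg$n_positive / agg$n_total
  expect_identical(which.max(prop), which(agg[[1]] == 2))  # offsets 40..59
})

test_that("LOESS recovers a constant signal exactly", {
  tab <- data.frame(axis_value = seq(0, 3, length.out = 40),
                    n_positive = 4L, n_total = 10L, proportion = 0.4)
  tr <- loessTrend(tab, span = 0.5)
  expect_true(all(abs(tr$fit - 0.4) < 1e-6))
  expect_true(all(tr$ci_low <= tr$fit & tr$fit <= tr$ci_high))
})

test_that("LOESS fit of a monotone ramp is monotone", {
  tab <- data.frame(axis_value = seq(0, 3, length.out = 60),
                    n_positive = 1L, n_total = 2L,
                    proportion = seq(0.1, 0.9, length.out = 60))
  tr <- loessTrend(tab, span = 0.5)
  expect_true(all(diff(tr$fit) > 0))
})

test_that("LOESS is skipped with a warning on tiny tables", {
  tab <- data.frame(axis_value = 1:5, n_positive = 1L, n_total = 2L,
                    proportion = 0.5)
  expect_warning(tr <- loessTrend(tab), "fewer than 10")
  expect_null(tr)
})

test_that("junction-depleted fixtures are recovered as a depleted fitted zone", {
  ann <- simulateTranscriptome(nGenes = 60, exonsPerTranscript = c(2L, 5L),
                               exonLen = c(500L, 1500L), seed = 71)
  sim <- simulateSites(ann, nSites = 6000, siteModel = "junction_depleted",
                       zone = 200L, positiveRateInside = 0,
                       positiveRateOutside = 0.3, seed = 72)
  out <- annotateSites(sim$sites, ann)
  prof <- junctionProfile(out, "stoich", ">", 10, window = 300)
  for (side in c("upstream", "downstream")) {
    tab <- prof[[side]]
    tr <- loessTrend(tab, span = 0.5)
    inZone <- abs(tr$axis_value) <= 200
    expect_lt(mean(tr$fit[inZone]), 0.5 * mean(tr$fit[!inZone]))
  }
})
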