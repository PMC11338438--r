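#' @include annotate.R
NULL

#' Evaluate a significance predicate on an annotated site table
#'
#' Sites are classed as "positive" when the value in `column` satisfies
#' `cmp threshold` — e.g. stoichiometry `> 10` reproduces the common
#' "modified at >10%" cutoff. Records whose value in the column is not
#' numeric are excluded from both numerator and denominator of every
#' downstream proportion and counted.
#'
#' @param x data.frame of annotated sites ([annotateSites()] output).
#' @param column column name, or 1-based column index.
#' @param cmp one of `">"`, `">="`, `"<"`, `"<="`, `"=="`.
#' @param threshold numeric cutoff.
#' @return logical vector, `NA` where the value is non-numeric, with the
#'   non-numeric count in attribute `nonNumeric`.
#' @export
evalPredicate <- function(x, column, cmp = c(">", ">=", "<", "<=", "=="),
                          threshold) {
  cmp <- match.arg(cmp)
  if (is.numeric(column)) {
    if (column < 1 || column > ncol(x))
      stop(sprintf("filter column index %d out of range (1..%d)",
                   column, ncol(x)))
    v <- x[[column]]
  } else {
    if (!column %in% names(x))
      stop(sprintf("filter column '%s' not found; available columns: %s",
                   column, paste(names(x), collapse = ", ")))
    v <- x[[column]]
  }
  v <- suppressWarnings(as.numeric(v))
  res <- do.call(cmp, list(v, threshold))
  attr(res, "nonNumeric") <- sum(is.na(v))
  res
}

newProfileTable <- function(axis, positive, total) {
  data.frame(axis_value = axis, n_positive = as.integer(positive),
             n_total = as.integer(total),
             proportion = ifelse(total > 0, positive / total, NA_real_))
}

profileFromKeys <- function(keys, pos, axisValues) {
  keep <- !is.na(keys) & !is.na(pos) & keys %in% axisValues
  tot <- table(factor(keys[keep], levels = axisValues))
  p <- table(factor(keys[keep & pos], levels = axisValues))
  newProfileTable(axisValues, as.vector(p), as.vector(tot))
}

#' Bin sites along the metatranscript axis
#'
#' Segments the 0-3 metatranscript axis into `nBins` equal bins (the
#' default, 120 bins of width 0.025, matches the conventional metagene
#' segmentation) and computes, per bin, the proportion of sites passing
#' the significance predicate among all sites with a numeric predicate
#' value. Sites on noncoding isoforms (`NA` metacoordinate) are excluded.
#' The bin containing a metacoordinate `m` is `floor(m / (3/nBins))`,
#' clamped to the last bin; reported `axis_value` is the bin midpoint.
#'
#' @inheritParams evalPredicate
#' @param nBins number of bins spanning the axis.
#' @return ProfileTable: data.frame with columns `axis_value`,
#'   `n_positive`, `n_total`, `proportion` (`NA` where `n_total` is 0),
#'   one row per bin in increasing axis order.
#' @export
binMetaTranscript <- function(x, column, cmp, threshold, nBins = 120L) {
  stopifnot(nBins >= 1L)
  pos <- evalPredicate(x, column, cmp, threshold)
  meta <- x$transcript_metacoordinate
  width <- 3 / nBins
  bin <- pmin(floor(meta / width), nBins - 1L)
  mid <- (seq_len(nBins) - 0.5) * width
  keep <- !is.na(meta) & !is.na(pos)
  tot <- tabulate(bin[keep] + 1L, nbins = nBins)
  p <- tabulate(bin[keep & pos] + 1L, nbins = nBins)
  newProfileTable(mid, p, tot)
}

#' Proportion-positive profile around splice junctions
#'
#' Builds two 1-nt-resolution profiles of the significance proportion at
#' offsets from each site's nearest splice junction: upstream offsets
#' `-window..-1` (the site lies downstream of that junction, at
#' `up_junc_dist` nt) and downstream offsets `1..window` (`down_junc_dist`
#' nt before the next junction). Each site contributes to at most one cell
#' per side; sites with no junction on a side, or farther than `window`,
#' are excluded from that side.
#'
#' @inheritParams evalPredicate
#' @param window profile half-width in nt.
#' @return list with ProfileTable elements `upstream` and `downstream`.
#' @export
junctionProfile <- function(x, column, cmp, threshold, window = 300L) {
  stopifnot(window >= 1L)
  pos <- evalPredicate(x, column, cmp, threshold)
  list(
    upstream = profileFromKeys(-x$up_junc_dist, pos,
                               seq(-window, -1L)),
    downstream = profileFromKeys(x$down_junc_dist, pos,
                                 seq(1L, window)))
}

#' Proportion-positive profile around the start or stop codon
#'
#' 1-nt-resolution profile of the significance proportion at signed
#' distances from the start codon (first ORF base) or stop codon (last
#' stop-codon base), restricted to `[-window, window]`. Sites on
#' noncoding isoforms are excluded.
#'
#' @inheritParams junctionProfile
#' @param anchor `"start"` or `"stop"` codon.
#' @return ProfileTable keyed by signed nt offset.
#' @export
codonProfile <- function(x, column, cmp, threshold, window = 100L,
                         anchor = c("stop", "start")) {
  anchor <- match.arg(anchor)
  stopifnot(window >= 1L)
  pos <- evalPredicate(x, column, cmp, threshold)
  keys <- if (anchor == "start") x$abs_cds_start else x$abs_cds_end
  profileFromKeys(keys, pos, seq(-window, window))
}

#' LOESS trend with 95% confidence band for a profile table
#'
#' Fits a locally weighted regression of the per-bin proportion on the
#' axis value and derives a pointwise 95% confidence band from the fit's
#' standard errors (normal approximation). Rows with `NA` proportion are
#' excluded. With fewer than 10 usable rows no trend is fitted and `NULL`
#' is returned with a warning (plots then show points only).
#'
#' @param table ProfileTable from [binMetaTranscript()],
#'   [junctionProfile()] or [codonProfile()].
#' @param span LOESS smoothing span in (0, 1].
#' @return data.frame with columns `axis_value`, `fit` (raw local
#'   regression value), `ci_low`, `ci_high`, and `fit_clipped` (`fit`
#'   truncated to the [0, 1] proportion scale for display), or `NULL`.
#' @export
loessTrend <- function(table, span = 0.3) {
  stopifnot(span > 0, span <= 1)
  use <- table[!is.na(table$proportion), , drop = FALSE]
  if (nrow(use) < 10L) {
    warning("fewer than 10 usable rows; LOESS trend skipped")
    return(NULL)
  }
  fit <- stats::loess(proportion ~ axis_value, data = use, span = span,
                      degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(fit, newdata = use["axis_value"], se = TRUE)
  z <- stats::qnorm(0.975)
  data.frame(axis_value = use$axis_value,
             fit = as.numeric(pr$fit),
             ci_low = as.numeric(pr$fit - z * pr$se.fit),
             ci_high = as.numeric(pr$fit + z * pr$se.fit),
             fit_clipped = pmin(pmax(as.numeric(pr$fit), 0), 1))
}
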