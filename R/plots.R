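#' @include metaprofile.R
#' @import ggplot2
NULL

profilePanel <- function(table, trend, xlab, ylab) {
  pts <- table[!is.na(table$proportion), , drop = FALSE]
  p <- ggplot(pts, aes(x = .data$axis_value, y = .data$proportion)) +
    geom_point(size = 0.8, colour = "grey30", alpha = 0.7) +
    labs(x = xlab, y = ylab) +
    theme_classic(base_size = 11)
  if (!is.null(trend)) {
    tr <- trend
    tr$ci_low <- pmin(pmax(tr$ci_low, 0), 1)
    tr$ci_high <- pmin(pmax(tr$ci_high, 0), 1)
    p <- p +
      geom_ribbon(data = tr,
                  aes(x = .data$axis_value, ymin = .data$ci_low,
                      ymax = .data$ci_high),
                  inherit.aes = FALSE, fill = "#c23b22", alpha = 0.25) +
      geom_line(data = tr,
                aes(x = .data$axis_value, y = .data$fit_clipped),
                inherit.aes = FALSE, colour = "#c23b22", linewidth = 0.8)
  }
  p
}

saveProfileOutputs <- function(plot, table, path, tablePath) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("png", "svg", "pdf"))
    stop(sprintf("unsupported plot format '.%s' (use png, svg or pdf)", ext))
  ggsave(path, plot = plot, width = 7, height = 4, dpi = 150)
  if (is.null(tablePath))
    tablePath <- paste0(tools::file_path_sans_ext(path), ".tsv")
  utils::write.table(table, tablePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(plot = path, table = tablePath))
}

#' Metatranscript distribution plot
#'
#' Plots the per-bin proportion of significant sites along the 0-3
#' metatranscript axis, with a LOESS trend and 95% confidence band, and
#' dashed separators at 1 and 2 delimiting the 5'UTR, ORF and 3'UTR
#' segments. The binned table is written as tab-separated text alongside
#' the image.
#'
#' @inheritParams binMetaTranscript
#' @param path output image path (`.png`, `.svg` or `.pdf`).
#' @param span LOESS span (see [loessTrend()]).
#' @param tablePath path for the companion table; default replaces the
#'   image extension with `.tsv`.
#' @return invisibly, the paths written (`plot`, `table`).
#' @export
plotMetaTranscript <- function(x, path, column, cmp, threshold,
                               nBins = 120L, span = 0.3,
                               tablePath = NULL) {
  tab <- binMetaTranscript(x, column, cmp, threshold, nBins = nBins)
  if (all(is.na(tab$proportion)))
    stop("no sites with a defined metacoordinate; nothing to plot")
  trend <- loessTrend(tab, span = span)
  lab <- data.frame(x = c(0.5, 1.5, 2.5), lab = c("5'UTR", "ORF", "3'UTR"))
  p <- profilePanel(tab, trend, "metatranscript position",
                    "proportion of significant sites") +
    geom_vline(xintercept = c(1, 2), linetype = "dashed",
               colour = "grey55") +
    scale_x_continuous(breaks = 0:3,
                       sec.axis = dup_axis(breaks = lab$x,
                                           labels = lab$lab, name = NULL))
  saveProfileOutputs(p, tab, path, tablePath)
}

#' Metajunction distribution plot
#'
#' Two-panel plot of the proportion of significant sites at 1-nt offsets
#' from the nearest upstream (left panel) and downstream (right panel)
#' splice junction, each with a LOESS trend and 95% band. The two profile
#' tables are written as one tab-separated file (column `side`).
#'
#' @inheritParams junctionProfile
#' @inheritParams plotMetaTranscript
#' @export
plotMetaJunction <- function(x, path, column, cmp, threshold,
                             window = 300L, span = 0.5,
                             tablePath = NULL) {
  prof <- junctionProfile(x, column, cmp, threshold, window = window)
  if (all(is.na(c(prof$upstream$proportion, prof$downstream$proportion))))
    stop("no sites within the junction window; nothing to plot")
  panels <- lapply(c("upstream", "downstream"), function(side) {
    tab <- prof[[side]]
    trend <- if (sum(!is.na(tab$proportion)) >= 10L)
      loessTrend(tab, span = span) else NULL
    profilePanel(tab, trend,
                 sprintf("nt to %s junction", side),
                 "proportion of significant sites") +
      geom_vline(xintercept = 0, linetype = "dashed", colour = "grey55")
  })
  combined <- cbind(rbind(cbind(side = "upstream", prof$upstream),
                          cbind(side = "downstream", prof$downstream)))
  p <- patchSideBySide(panels[[1L]], panels[[2L]])
  saveProfileOutputs(p, combined, path, tablePath)
}

# two ggplots on one page without imposing a composition dependency at
# runtime; uses patchwork when available, otherwise gtable via gridExtra-
# free cbind of the grobs
patchSideBySide <- function(a, b) {
  if (requireNamespace("patchwork", quietly = TRUE))
    return(patchwork::wrap_plots(a, b, ncol = 2))
  ga <- ggplotGrob(a); gb <- ggplotGrob(b)
  g <- cbind(ga, gb, size = "first")
  class(g) <- c("sideBySideGrob", class(g))
  g
}

#' @export
#' @method print sideBySideGrob
print.sideBySideGrob <- function(x, ...) {
  grid::grid.newpage(); grid::grid.draw(x); invisible(x)
}

#' Metacodon distribution plot
#'
#' Proportion of significant sites at 1-nt signed offsets from the start
#' or stop codon, with LOESS trend and 95% band; the profile table is
#' written alongside the image.
#'
#' @inheritParams codonProfile
#' @inheritParams plotMetaTranscript
#' @export
plotMetaCodon <- function(x, path, column, cmp, threshold,
                          window = 100L, anchor = c("stop", "start"),
                          span = 0.5, tablePath = NULL) {
  anchor <- match.arg(anchor)
  tab <- codonProfile(x, column, cmp, threshold, window = window,
                      anchor = anchor)
  if (all(is.na(tab$proportion)))
    stop("no sites within the codon window; nothing to plot")
  trend <- if (sum(!is.na(tab$proportion)) >= 10L)
    loessTrend(tab, span = span) else NULL
  p <- profilePanel(tab, trend,
                    sprintf("nt to %s codon", anchor),
                    "proportion of significant sites") +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey55")
  saveProfileOutputs(p, tab, path, tablePath)
}
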