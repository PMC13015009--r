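#' Paint projected segments along scaled chromosomes
#'
#' Draws each query chromosome as a horizontal bar scaled to its length,
#' with projected segments as ticks at their forward-strand coordinates
#' and optional segmental-duplication / centromeric-satellite tracks as
#' shaded layers. Every rendered glyph is duplicated into a
#' machine-readable sidecar table so plotted coordinates can be checked
#' without image comparison.
#'
#' @param segments segment data frame (as in a `"projection_result"` or
#'   [read_projection_tsv()]): needs `qName`, `qForwardStart`,
#'   `qForwardEnd`.
#' @param sizes [chrom_sizes()] for the painted assembly; chromosomes
#'   are drawn in table order.
#' @param sd_track,censat_track optional [genomic_intervals()] shading
#'   layers.
#' @param file optional PNG path; `NULL` draws on the active device,
#'   `NA` skips drawing entirely (sidecar only).
#' @param sidecar optional TSV path for the glyph-coordinate table.
#' @param main plot title.
#' @return The sidecar data frame (columns `glyph`, `chrom`, `xStart`,
#'   `xEnd`, `y`), invisibly.
#' @export
paint_chromosomes <- function(segments, sizes, sd_track = NULL,
                              censat_track = NULL, file = NULL,
                              sidecar = NULL, main = "chromosome painting") {
  unknown <- setdiff(unique(segments$qName), names(sizes))
  if (length(unknown))
    stop_validation("segment qName(s) not in chrom.sizes: ",
                    paste(unknown, collapse = ", "))
  chroms <- names(sizes)
  ypos <- stats::setNames(rev(seq_along(chroms)), chroms)
  rows <- list(data.frame(glyph = "chromosome", chrom = chroms,
                          xStart = 0, xEnd = as.numeric(sizes),
                          y = unname(ypos[chroms]),
                          stringsAsFactors = FALSE))
  track_rows <- function(track, glyph) {
    tr <- track[track$chrom %in% chroms, , drop = FALSE]
    if (nrow(tr) == 0) return(NULL)
    tr <- tr[order(tr$chrom, tr$start, tr$end), , drop = FALSE]
    data.frame(glyph = glyph, chrom = tr$chrom, xStart = tr$start,
               xEnd = tr$end, y = unname(ypos[tr$chrom]),
               stringsAsFactors = FALSE)
  }
  if (!is.null(sd_track)) rows <- c(rows, list(track_rows(sd_track, "sd")))
  if (!is.null(censat_track))
    rows <- c(rows, list(track_rows(censat_track, "censat")))
  if (nrow(segments)) {
    seg <- segments[order(segments$qName, segments$qForwardStart,
                          segments$qForwardEnd), , drop = FALSE]
    rows <- c(rows, list(data.frame(glyph = "segment", chrom = seg$qName,
                                    xStart = seg$qForwardStart,
                                    xEnd = seg$qForwardEnd,
                                    y = unname(ypos[seg$qName]),
                                    stringsAsFactors = FALSE)))
  }
  coords <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(coords) <- NULL
  if (!is.null(sidecar))
    utils::write.table(coords, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  draw <- is.null(file) || !is.na(file)
  if (draw) {
    if (!is.null(file)) {
      grDevices::png(file, width = 1000,
                     height = 160 + 60 * length(chroms), res = 110)
      on.exit(grDevices::dev.off(), add = TRUE)
    }
    op <- graphics::par(mar = c(4, 6, 3, 1))
    on.exit(graphics::par(op), add = TRUE)
    graphics::plot(NA, xlim = c(0, max(as.numeric(sizes))),
                   ylim = c(0.5, length(chroms) + 0.5),
                   xlab = "position (bp)", ylab = "", yaxt = "n",
                   main = main, bty = "n")
    graphics::axis(2, at = unname(ypos), labels = names(ypos), las = 2,
                   tick = FALSE)
    for (g in seq_len(nrow(coords))) {
      r <- coords[g, ]
      switch(r$glyph,
        chromosome = graphics::rect(r$xStart, r$y - 0.15, r$xEnd,
                                    r$y + 0.15, col = "grey92",
                                    border = "grey40"),
        sd = graphics::rect(r$xStart, r$y - 0.15, r$xEnd, r$y + 0.15,
                            col = "#9ecae1", border = NA),
        censat = graphics::rect(r$xStart, r$y - 0.15, r$xEnd, r$y + 0.15,
                                col = "#fc9272", border = NA),
        segment = graphics::segments(r$xStart, r$y - 0.28, r$xStart,
                                     r$y + 0.28, col = "#54278f",
                                     lwd = 2))
    }
  }
  invisible(coords)
}
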