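#' Read a BED3+ interval track
#'
#' Intervals are kept in the native BED convention: 0-based half-open.
#' Column 4, when present, is captured as the interval name.
#'
#' @param path path to a BED file (tab- or space-separated, `#` comments
#'   and `track`/`browser` lines skipped).
#' @param track_label label recorded on the returned intervals (e.g.
#'   `"SD"` or `"censat"`).
#' @return Data frame of class `"genomic_intervals"` with columns
#'   `chrom`, `start`, `end`, `name`, `trackLabel`.
#' @export
read_bed <- function(path, track_label = NA_character_) {
  if (!file.exists(path)) stop_usage("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", trimws(lines))
  idx <- which(keep)
  if (!length(idx)) return(genomic_intervals(character(0), numeric(0),
                                             numeric(0),
                                             track_label = track_label))
  parts <- strsplit(trimws(lines[idx]), "\t|\\s+")
  short <- which(lengths(parts) < 3)
  if (length(short))
    stop_parse("BED line ", idx[short[1]], ": fewer than 3 columns")
  chrom <- vapply(parts, `[[`, character(1), 1)
  s_str <- vapply(parts, `[[`, character(1), 2)
  e_str <- vapply(parts, `[[`, character(1), 3)
  bad <- which(!grepl("^[0-9]+$", s_str) | !grepl("^[0-9]+$", e_str))
  if (length(bad))
    stop_parse("BED line ", idx[bad[1]], ": non-integer coordinate")
  start <- as.numeric(s_str); end <- as.numeric(e_str)
  rev <- which(start >= end)
  if (length(rev))
    stop_validation("BED line ", idx[rev[1]], ": start >= end (",
                    fmt_int(start[rev[1]]), " >= ", fmt_int(end[rev[1]]), ")")
  name <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 4) parts[[i]][4] else NA_character_,
    character(1))
  genomic_intervals(chrom, start, end, name, track_label = track_label)
}

#' Construct an interval track (0-based half-open)
#'
#' @param chrom,start,end vectors of equal length; `start < end`
#'   required, half-open.
#' @param name optional labels.
#' @param track_label source-track label.
#' @return Data frame of class `"genomic_intervals"`.
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              track_label = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) && any(start < 0 | start >= end))
    stop_validation("intervals require 0 <= start < end")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), length(start)),
                   trackLabel = rep_len(as.character(track_label),
                                        length(start)),
                   stringsAsFactors = FALSE)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Write intervals as BED4
#' @param intervals a [genomic_intervals()] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  nm <- ifelse(is.na(intervals$name), ".", intervals$name)
  writeLines(paste(intervals$chrom, fmt_int(intervals$start),
                   fmt_int(intervals$end), nm, sep = "\t"), path)
  invisible(path)
}

# half-open intervals -> 1-based closed IRanges (per chromosome)
.iranges_on <- function(track, chrom) {
  on <- track[track$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(start = on$start + 1, end = on$end)
}

#' Does a locus overlap any interval of a track?
#'
#' Half-open semantics: abutting intervals (`locus end == track start`)
#' do not overlap. Strand is ignored.
#'
#' @param locus single-row [genomic_intervals()] (or list with `chrom`,
#'   `start`, `end`).
#' @param track a [genomic_intervals()] data frame.
#' @return Logical.
#' @export
overlaps_any <- function(locus, track) {
  ir <- .iranges_on(track, locus$chrom[1])
  if (length(ir) == 0) return(FALSE)
  lr <- IRanges::IRanges(start = locus$start[1] + 1, end = locus$end[1])
  IRanges::countOverlaps(lr, ir) > 0
}

#' Distance from a locus to the nearest interval of a track
#'
#' 0 if the locus overlaps any same-chromosome interval, otherwise the
#' minimum gap in bp (abutting half-open intervals have gap 0); `NA`
#' when the track has no interval on the locus chromosome.
#'
#' @inheritParams overlaps_any
#' @return Distance in bp, or `NA_real_`.
#' @export
distance_to_track <- function(locus, track) {
  ir <- .iranges_on(track, locus$chrom[1])
  if (length(ir) == 0) return(NA_real_)
  lr <- IRanges::IRanges(start = locus$start[1] + 1, end = locus$end[1])
  min(IRanges::distance(rep(lr, length(ir)), ir))
}

#' Classify one locus against SD / censat tracks and chromosome ends
#'
#' A locus is *pericentromeric* when its distance to the nearest
#' centromeric-satellite interval is at most `peri_threshold`,
#' *subtelomeric* when its distance to the nearer chromosome end is at
#' most `telo_threshold`, *both* when both hold, *interior* otherwise.
#' The thresholds have no canonical value in the literature; they are
#' explicit, reportable parameters (default 5 Mb each).
#'
#' @param locus single-row [genomic_intervals()].
#' @param sd_track segmental-duplication intervals.
#' @param censat_track centromeric-satellite intervals.
#' @param sizes [chrom_sizes()] for the assembly.
#' @param peri_threshold,telo_threshold distances in bp.
#' @return One-row data frame: `locusName`, `chrom`, `start`, `end`,
#'   `sdOverlap`, `censatOverlap`, `distanceToCensat`,
#'   `distanceToChromEnd`, `boundaryClass`.
#' @export
classify_locus <- function(locus, sd_track, censat_track, sizes,
                           peri_threshold = 5e6, telo_threshold = 5e6) {
  chrom <- locus$chrom[1]
  if (!chrom %in% names(sizes))
    stop_validation("locus chromosome '", chrom, "' not in chrom.sizes")
  L <- unname(sizes[chrom])
  if (locus$end[1] > L)
    stop_validation("locus ", chrom, ":", fmt_int(locus$start[1]), "-",
                    fmt_int(locus$end[1]), " extends beyond chromosome length ",
                    fmt_int(L))
  d_cen <- distance_to_track(locus, censat_track)
  d_end <- min(locus$start[1], L - locus$end[1])
  peri <- !is.na(d_cen) && d_cen <= peri_threshold
  telo <- d_end <= telo_threshold
  cls <- if (peri && telo) "both" else if (peri) "pericentromeric" else
    if (telo) "subtelomeric" else "interior"
  data.frame(locusName = if (is.na(locus$name[1]))
               paste0(chrom, ":", fmt_int(locus$start[1]), "-",
                      fmt_int(locus$end[1])) else locus$name[1],
             chrom = chrom, start = locus$start[1], end = locus$end[1],
             sdOverlap = overlaps_any(locus, sd_track),
             censatOverlap = overlaps_any(locus, censat_track),
             distanceToCensat = d_cen,
             distanceToChromEnd = d_end,
             boundaryClass = cls,
             stringsAsFactors = FALSE)
}

#' Genome-context table for a set of loci
#'
#' Applies [classify_locus()] to each locus and attaches summary counts
#' (number of loci, number overlapping SDs, counts per boundary class).
#'
#' @param loci [genomic_intervals()] of annotated loci.
#' @param sd_track,censat_track,sizes,peri_threshold,telo_threshold see
#'   [classify_locus()].
#' @return Object of class `"locus_context"`: list with `table` (one
#'   row per locus) and `summary`.
#' @export
context_table <- function(loci, sd_track, censat_track, sizes,
                          peri_threshold = 5e6, telo_threshold = 5e6) {
  rows <- lapply(seq_len(nrow(loci)), function(i)
    classify_locus(loci[i, , drop = FALSE], sd_track, censat_track, sizes,
                   peri_threshold, telo_threshold))
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(locusName = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0),
               sdOverlap = logical(0), censatOverlap = logical(0),
               distanceToCensat = numeric(0),
               distanceToChromEnd = numeric(0),
               boundaryClass = character(0), stringsAsFactors = FALSE)
  cls <- factor(tab$boundaryClass,
                levels = c("pericentromeric", "subtelomeric", "both",
                           "interior"))
  structure(list(table = tab,
                 summary = list(nLoci = nrow(tab),
                                nSdOverlap = sum(tab$sdOverlap),
                                nCensatOverlap = sum(tab$censatOverlap),
                                byBoundaryClass = table(cls)),
                 peri_threshold = peri_threshold,
                 telo_threshold = telo_threshold),
            class = "locus_context")
}

#' @export
print.locus_context <- function(x, ...) {
  s <- x$summary
  cat(sprintf("locus context: %d loci (peri threshold %s bp, telo threshold %s bp)\n",
              s$nLoci, fmt_int(x$peri_threshold), fmt_int(x$telo_threshold)))
  cat(sprintf("  within SD blocks   : %d/%d\n", s$nSdOverlap, s$nLoci))
  cat(sprintf("  overlapping censat : %d/%d\n", s$nCensatOverlap, s$nLoci))
  bc <- s$byBoundaryClass
  cat("  boundary classes   :",
      paste(sprintf("%s=%d", names(bc), as.integer(bc)), collapse = "  "),
      "\n")
  invisible(x)
}

#' Write a locus-context table and summary to TSV
#' @param ctx a `"locus_context"` object.
#' @param table_path,summary_path output paths (either may be `NULL`).
#' @return `ctx`, invisibly.
#' @export
write_context_tsv <- function(ctx, table_path, summary_path = NULL) {
  if (!is.null(table_path))
    utils::write.table(ctx$table, table_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(summary_path)) {
    bc <- ctx$summary$byBoundaryClass
    sm <- data.frame(
      metric = c("nLoci", "nSdOverlap", "nCensatOverlap",
                 paste0("n_", names(bc))),
      value = c(ctx$summary$nLoci, ctx$summary$nSdOverlap,
                ctx$summary$nCensatOverlap, as.integer(bc)))
    utils::write.table(sm, summary_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(ctx)
}
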