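#' Rebuild a projection result from a segment table
#'
#' Lets dispersion statistics be computed from a segments TSV (see
#' [read_projection_tsv()]) without re-running the projection.
#'
#' @param segments segment data frame.
#' @param window the [genomic_window()] the segments were projected
#'   from.
#' @return A `"projection_result"`.
#' @export
as_projection_result <- function(segments, window) {
  structure(list(window = window, segments = segments,
                 excluded = data.frame(qName = character(0),
                                       chainId = numeric(0),
                                       reason = character(0)),
                 mode = NA_character_, min_aligned = NA_real_),
            class = "projection_result")
}

#' Normalized accumulated chain-mapped coverage
#'
#' The sum of chain-mapped aligned lengths over all segments, normalized
#' by the window length: `sum(L_chain) / L_window`. Multi-mapping is
#' allowed — overlapping segments contribute additively — so the ratio
#' can exceed 1.
#'
#' @param result a `"projection_result"`.
#' @return Dimensionless ratio (0 for an empty projection).
#' @export
accumulated_coverage <- function(result) {
  sum(result$segments$alignedBases) / window_length(result$window)
}

#' Per-qName alignment burdens
#'
#' Sums `alignedBases` over each distinct query chromosome (`qName`) and
#' sorts descending by burden; ties are broken by qName lexicographic
#' order so Top-K group membership is deterministic.
#'
#' @param result a `"projection_result"`.
#' @return Data frame with columns `qName`, `alignedBases`,
#'   `nSegments`, sorted descending by `alignedBases`.
#' @export
qname_burdens <- function(result) {
  seg <- result$segments
  if (nrow(seg) == 0)
    return(data.frame(qName = character(0), alignedBases = numeric(0),
                      nSegments = integer(0), stringsAsFactors = FALSE))
  ab <- tapply(seg$alignedBases, seg$qName, sum)
  ns <- tapply(seg$alignedBases, seg$qName, length)
  df <- data.frame(qName = names(ab), alignedBases = as.numeric(ab),
                   nSegments = as.integer(ns), stringsAsFactors = FALSE)
  df <- df[order(-df$alignedBases, df$qName), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Number of distinct query chromosomes with chain-mapped hits
#'
#' The dispersion count: how many distinct `qName`s carry at least one
#' chain-mapped block for the window.
#'
#' @param result a `"projection_result"`.
#' @return Non-negative integer.
#' @export
distinct_qname_count <- function(result) {
  length(unique(result$segments$qName))
}

#' Top-K burden decomposition
#'
#' Fraction of the total aligned base pairs contributed by rank groups
#' of query chromosomes ordered by burden. The default grouping is
#' Top1, Top2-3, Top4-5 and the remainder.
#'
#' @param burdens output of [qname_burdens()] (sorted descending).
#' @param groups named list of rank index vectors; entries with value
#'   `NULL` collect all remaining ranks.
#' @return Named numeric vector of fractions summing to 1 when the
#'   total burden is positive; all zeros (with a message) otherwise.
#' @export
topk_decomposition <- function(burdens,
                               groups = list(Top1 = 1, `Top2-3` = 2:3,
                                             `Top4-5` = 4:5,
                                             others = NULL)) {
  total <- sum(burdens$alignedBases)
  out <- stats::setNames(numeric(length(groups)), names(groups))
  if (total == 0) {
    message("topk_decomposition: empty burden table; all fractions 0")
    return(out)
  }
  used <- integer(0)
  rest_at <- NULL
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (is.null(idx)) { rest_at <- g; next }
    idx <- idx[idx <= nrow(burdens)]
    out[g] <- sum(burdens$alignedBases[idx]) / total
    used <- c(used, idx)
  }
  if (!is.null(rest_at)) {
    rest <- setdiff(seq_len(nrow(burdens)), used)
    out[rest_at] <- sum(burdens$alignedBases[rest]) / total
  }
  out
}

#' Fraction of coverage in the single largest chromosomal block
#'
#' @param burdens output of [qname_burdens()].
#' @return `burdens$alignedBases[1] / total`; 0 when empty.
#' @export
largest_block_fraction <- function(burdens) {
  total <- sum(burdens$alignedBases)
  if (total == 0) return(0)
  burdens$alignedBases[1] / total
}

#' Distribution of per-segment aligned lengths
#'
#' Descriptive summary of the aligned-length of each chain-mapped
#' segment; fragmented dispersal shows up as many short segments, intact
#' transfer as few long ones.
#'
#' @param result a `"projection_result"`.
#' @return List with `count`, `min`, `median`, `max` and the full
#'   `lengths` vector (`min`/`median`/`max` are `NA` when empty).
#' @export
alignment_length_distribution <- function(result) {
  len <- result$segments$alignedBases
  list(count = length(len),
       min = if (length(len)) min(len) else NA_real_,
       median = if (length(len)) stats::median(len) else NA_real_,
       max = if (length(len)) max(len) else NA_real_,
       lengths = len)
}

#' Summarize dispersion of one window in one species
#'
#' Composes [accumulated_coverage()], [distinct_qname_count()],
#' [qname_burdens()], [topk_decomposition()] and
#' [largest_block_fraction()] into one per-(species, window) record.
#' An empty projection yields a zero-valued summary rather than a
#' missing record, so species with no detectable homology stay in
#' comparative tables.
#'
#' @param result a `"projection_result"`.
#' @param species species / assembly label for the record.
#' @return Object of class `"dispersion_summary"`.
#' @export
summarize_dispersion <- function(result, species = NA_character_) {
  burdens <- qname_burdens(result)
  frac <- suppressMessages(topk_decomposition(burdens))
  structure(list(species = species,
                 windowId = result$window$id,
                 windowLength = window_length(result$window),
                 accumulatedCoverage = accumulated_coverage(result),
                 nDistinctQNames = distinct_qname_count(result),
                 top1Fraction = largest_block_fraction(burdens),
                 topKFractions = frac,
                 totalAlignedBases = sum(result$segments$alignedBases),
                 nSegments = nrow(result$segments),
                 burdens = burdens),
            class = "dispersion_summary")
}

#' @export
print.dispersion_summary <- function(x, ...) {
  cat(sprintf("dispersion of %s in %s\n", x$windowId, x$species))
  cat(sprintf("  accumulated coverage : %.4f (%s aligned bp / %s bp window)\n",
              x$accumulatedCoverage, fmt_int(x$totalAlignedBases),
              fmt_int(x$windowLength)))
  cat(sprintf("  distinct qNames      : %d\n", x$nDistinctQNames))
  cat(sprintf("  largest-block frac.  : %.4f\n", x$top1Fraction))
  cat("  Top-K fractions      :",
      paste(sprintf("%s=%.3f", names(x$topKFractions), x$topKFractions),
            collapse = "  "), "\n")
  invisible(x)
}

#' Flatten dispersion summaries into a comparative table
#'
#' @param summaries list of `"dispersion_summary"` objects (one per
#'   species or regime).
#' @return Data frame, one row per (species, window).
#' @export
dispersion_table <- function(summaries) {
  if (inherits(summaries, "dispersion_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(species = s$species, windowId = s$windowId,
               windowLength = s$windowLength,
               accumulatedCoverage = s$accumulatedCoverage,
               nDistinctQNames = s$nDistinctQNames,
               top1Fraction = s$top1Fraction,
               top23Fraction = unname(s$topKFractions["Top2-3"]),
               top45Fraction = unname(s$topKFractions["Top4-5"]),
               othersFraction = unname(s$topKFractions["others"]),
               totalAlignedBases = s$totalAlignedBases,
               nSegments = s$nSegments,
               stringsAsFactors = FALSE)
  }))
}
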