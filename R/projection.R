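#' Define a genomic query window
#'
#' A window is an interval on a reference assembly with an explicit
#' coordinate convention. Genome-browser coordinates are 1-based
#' inclusive (`chr7:56524206-56610877` has length end - start + 1);
#' chain and BED coordinates are 0-based half-open. Keeping the
#' convention on the object removes off-by-one ambiguity: all internal
#' arithmetic converts to half-open first.
#'
#' @param chrom reference sequence name.
#' @param start,end interval bounds under `convention`.
#' @param convention `"one-based-inclusive"` (default, browser style) or
#'   `"zero-based-half-open"` (BED/chain style).
#' @param assembly optional assembly label.
#' @param id optional window identifier; defaults to
#'   `"chrom:start-end"`.
#' @return An object of class `"genomic_window"`.
#' @examples
#' w <- genomic_window("chr7", 56524206, 56610877)
#' window_length(w)  # 86672
#' @export
genomic_window <- function(chrom, start, end,
                           convention = c("one-based-inclusive",
                                          "zero-based-half-open"),
                           assembly = NA_character_, id = NULL) {
  convention <- match.arg(convention)
  start <- as.numeric(start); end <- as.numeric(end)
  if (is.na(start) || is.na(end)) stop_validation("window bounds must be numeric")
  if (convention == "one-based-inclusive") {
    if (!(start >= 1 && start <= end))
      stop_validation("one-based-inclusive window requires 1 <= start <= end")
  } else {
    if (!(start >= 0 && start < end))
      stop_validation("zero-based-half-open window requires 0 <= start < end")
  }
  if (is.null(id))
    id <- paste0(chrom, ":", fmt_int(start), "-", fmt_int(end))
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 convention = convention, assembly = assembly, id = id),
            class = "genomic_window")
}

#' Parse a browser-style window string
#'
#' @param spec a string like `"chr7:56524206-56610877"` (1-based
#'   inclusive; commas in numbers are tolerated).
#' @param assembly optional assembly label.
#' @return A [genomic_window()].
#' @export
parse_window <- function(spec, assembly = NA_character_) {
  spec <- gsub(",", "", spec)
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  if (length(m) != 4)
    stop_usage("cannot parse window '", spec, "'; expected chrom:start-end")
  genomic_window(m[2], as.numeric(m[3]), as.numeric(m[4]),
                 convention = "one-based-inclusive", assembly = assembly)
}

#' Window length in bp
#'
#' `end - start + 1` under the 1-based inclusive convention,
#' `end - start` under 0-based half-open; the two agree for the same
#' physical interval.
#'
#' @param window a [genomic_window()].
#' @return Length in bp.
#' @export
window_length <- function(window) {
  if (window$convention == "one-based-inclusive")
    window$end - window$start + 1
  else
    window$end - window$start
}

#' Convert a window between coordinate conventions
#'
#' 1-based inclusive `[s, e]` maps to 0-based half-open `[s - 1, e)`;
#' length is preserved and the round trip is the identity.
#'
#' @param window a [genomic_window()].
#' @param target `"one-based-inclusive"` or `"zero-based-half-open"`.
#' @return A [genomic_window()] under `target`.
#' @export
convert_convention <- function(window,
                               target = c("zero-based-half-open",
                                          "one-based-inclusive")) {
  target <- match.arg(target)
  if (window$convention == target) return(window)
  if (target == "zero-based-half-open") {
    genomic_window(window$chrom, window$start - 1, window$end,
                   convention = target, assembly = window$assembly,
                   id = window$id)
  } else {
    genomic_window(window$chrom, window$start + 1, window$end,
                   convention = target, assembly = window$assembly,
                   id = window$id)
  }
}

#' @export
print.genomic_window <- function(x, ...) {
  cat(sprintf("genomic_window %s [%s] (%s, %s bp)\n", x$id,
              x$convention,
              if (is.na(x$assembly)) "assembly unset" else x$assembly,
              fmt_int(window_length(x))))
  invisible(x)
}

#' Clip one chain to a query window
#'
#' Walks the chain's gapless blocks with parallel reference and query
#' cursors. Each block's reference interval is intersected with the
#' window; a non-empty intersection contributes its length to
#' `alignedBases` and the corresponding query sub-interval (offsets map
#' 1:1 within a gapless block) extends the query extent. The query
#' extent is reported on the forward strand via
#' [to_forward_query_interval()].
#'
#' @param chain a [chain()] (same reference naming as the window).
#' @param window a [genomic_window()]; converted to half-open
#'   internally.
#' @param mode `"gapless"` (default): `alignedBases` counts only
#'   gapless-block bases overlapping the window. `"span"`: an
#'   alternative accounting in which `alignedBases` is the overlap of
#'   the chain's whole reference span with the window (gaps included),
#'   exposed for sensitivity analysis; a chain still contributes only
#'   when at least one gapless block overlaps the window.
#' @return A one-row data frame with columns `chainId`, `qName`,
#'   `qStrand`, `qForwardStart`, `qForwardEnd`, `alignedBases`,
#'   `nBlocks`, or `NULL` when no block overlaps the window (including
#'   when the chain is on a different reference sequence).
#' @export
clip_chain_to_window <- function(chain, window, mode = c("gapless", "span")) {
  mode <- match.arg(mode)
  win <- convert_convention(window, "zero-based-half-open")
  if (chain$tName != win$chrom) return(NULL)
  validate_chain(chain)
  ws <- win$start; we <- win$end
  if (chain$tEnd <= ws || chain$tStart >= we) return(NULL)
  b <- chain$blocks
  t <- chain$tStart; q <- chain$qStart
  aligned <- 0; nb <- 0L
  q_lo <- Inf; q_hi <- -Inf
  for (i in seq_len(nrow(b))) {
    sz <- b$size[i]
    os <- max(t, ws); oe <- min(t + sz, we)
    if (oe > os) {
      aligned <- aligned + (oe - os)
      nb <- nb + 1L
      q_lo <- min(q_lo, q + (os - t))
      q_hi <- max(q_hi, q + (oe - t))
    }
    t <- t + sz + b$dt[i]
    q <- q + sz + b$dq[i]
  }
  if (nb == 0L) return(NULL)
  if (mode == "span")
    aligned <- min(chain$tEnd, we) - max(chain$tStart, ws)
  fwd <- to_forward_query_interval(q_lo, q_hi, chain$qSize, chain$qStrand)
  data.frame(chainId = chain$id, qName = chain$qName, qStrand = chain$qStrand,
              qForwardStart = fwd[1], qForwardEnd = fwd[2],
              alignedBases = aligned, nBlocks = nb,
              stringsAsFactors = FALSE)
}

#' Project a window through a chain collection
#'
#' Collects every chain with at least one gapless block overlapping the
#' window, without enforcing one-to-one orthology: multi-mapping chains
#' (several chains onto the same query chromosome, overlapping or not)
#' are all retained and never merged. Chains whose `qName` is absent
#' from `sizes` — e.g. unplaced scaffolds when `sizes` lists only
#' assembled chromosomes — are excluded *after* overlap detection and
#' reported in `excluded`, so the filter is auditable.
#'
#' @param chains a `"chain_set"` or list of [chain()] objects.
#' @param window a [genomic_window()].
#' @param sizes a [chrom_sizes()] for the query assembly; its names are
#'   the allowed `qName`s.
#' @param min_aligned minimum `alignedBases` for a chain to count as a
#'   hit (default 1 bp).
#' @param mode accounting mode passed to [clip_chain_to_window()].
#' @return An object of class `"projection_result"`: a list with
#'   `window`, `segments` (data frame, one row per contributing chain:
#'   `windowId`, `chainId`, `qName`, `qStrand`, `qForwardStart`,
#'   `qForwardEnd`, `alignedBases`, `nBlocks`) and `excluded` (data
#'   frame `qName`, `chainId`, `reason`). Empty segments are valid.
#' @export
project_window <- function(chains, window, sizes, min_aligned = 1,
                           mode = c("gapless", "span")) {
  mode <- match.arg(mode)
  if (length(sizes) == 0) stop_usage("allowed qName table (chrom.sizes) is empty")
  segs <- list()
  excl <- list()
  for (ch in chains) {
    seg <- clip_chain_to_window(ch, window, mode = mode)
    if (is.null(seg) || seg$alignedBases < min_aligned) next
    if (!seg$qName %in% names(sizes)) {
      excl[[length(excl) + 1L]] <- data.frame(
        qName = seg$qName, chainId = seg$chainId,
        reason = "qName not an assembled chromosome in chrom.sizes",
        stringsAsFactors = FALSE)
      next
    }
    segs[[length(segs) + 1L]] <- seg
  }
  seg_df <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chainId = numeric(0), qName = character(0),
               qStrand = character(0), qForwardStart = numeric(0),
               qForwardEnd = numeric(0), alignedBases = numeric(0),
               nBlocks = integer(0), stringsAsFactors = FALSE)
  seg_df <- cbind(data.frame(windowId = rep(window$id, nrow(seg_df)),
                             stringsAsFactors = FALSE), seg_df)
  excl_df <- if (length(excl)) do.call(rbind, excl) else
    data.frame(qName = character(0), chainId = numeric(0),
               reason = character(0), stringsAsFactors = FALSE)
  structure(list(window = window, segments = seg_df, excluded = excl_df,
                 mode = mode, min_aligned = min_aligned),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf("projection of %s: %d segment(s) on %d qName(s); %d excluded chain(s)\n",
              x$window$id, nrow(x$segments),
              length(unique(x$segments$qName)), nrow(x$excluded)))
  invisible(x)
}

#' Write projection segments to TSV
#' @param result a `"projection_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_projection_tsv <- function(result, path) {
  utils::write.table(result$segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a projection TSV written by [write_projection_tsv()]
#' @param path input path.
#' @return Segment data frame.
#' @export
read_projection_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("windowId", "chainId", "qName", "qForwardStart", "qForwardEnd",
            "alignedBases", "nBlocks")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_parse("projection TSV missing column(s): ", paste(miss, collapse = ", "))
  df
}
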