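#' Construct a pairwise alignment chain
#'
#' A chain records one pairwise alignment between a reference sequence
#' (the `t` side, always on the forward strand) and a query sequence
#' (the `q` side, forward or reverse strand), as an ordered series of
#' gapless blocks separated by gaps on either side. Coordinates follow
#' the UCSC chain convention: 0-based half-open, with query coordinates
#' strand-local (reverse-strand positions count from the far end of the
#' query sequence).
#'
#' @param score integer alignment score.
#' @param tName,tSize reference sequence name and length (bp).
#' @param tStart,tEnd reference span, 0-based half-open.
#' @param qName,qSize query sequence name and length (bp).
#' @param qStrand `"+"` or `"-"`.
#' @param qStart,qEnd query span in strand-local coordinates, 0-based
#'   half-open.
#' @param id integer chain identifier, unique within a file.
#' @param blocks data frame with columns `size` (gapless aligned length,
#'   bp), `dt` (gap on the reference before the next block) and `dq`
#'   (gap on the query before the next block); `dt` and `dq` are 0 on
#'   the final row.
#' @return An object of class `"chain"`.
#' @seealso [read_chain_file()], [validate_chain()]
#' @export
chain <- function(score, tName, tSize, tStart, tEnd,
                  qName, qSize, qStrand, qStart, qEnd, id, blocks) {
  obj <- structure(
    list(score = as.numeric(score),
         tName = as.character(tName), tSize = as.numeric(tSize),
         tStrand = "+",
         tStart = as.numeric(tStart), tEnd = as.numeric(tEnd),
         qName = as.character(qName), qSize = as.numeric(qSize),
         qStrand = as.character(qStrand),
         qStart = as.numeric(qStart), qEnd = as.numeric(qEnd),
         id = as.numeric(id),
         blocks = data.frame(size = as.numeric(blocks$size),
                             dt = as.numeric(blocks$dt),
                             dq = as.numeric(blocks$dq))),
    class = "chain")
  obj
}

#' Validate a chain's internal consistency
#'
#' Checks the chain-format arithmetic: block sizes plus reference gaps
#' must tile the reference span exactly, and block sizes plus query gaps
#' must tile the query span (`sum(size + dt) == tEnd - tStart` and
#' `sum(size + dq) == qEnd - qStart`), alongside the coordinate bounds
#' `0 <= tStart < tEnd <= tSize` and `0 <= qStart < qEnd <= qSize`.
#'
#' @param x a [chain()] object.
#' @return `x`, invisibly; signals a validation error otherwise.
#' @export
validate_chain <- function(x) {
  if (!inherits(x, "chain")) stop_validation("not a chain object")
  b <- x$blocks
  who <- paste0("chain id ", fmt_int(x$id))
  if (nrow(b) < 1) stop_validation(who, ": no alignment blocks")
  if (any(b$size < 1)) stop_validation(who, ": block size < 1")
  if (any(b$dt < 0) || any(b$dq < 0)) stop_validation(who, ": negative gap")
  if (b$dt[nrow(b)] != 0 || b$dq[nrow(b)] != 0)
    stop_validation(who, ": final block must have dt = dq = 0")
  if (!(x$tStart >= 0 && x$tStart < x$tEnd && x$tEnd <= x$tSize))
    stop_validation(who, ": reference span violates 0 <= tStart < tEnd <= tSize")
  if (!(x$qStart >= 0 && x$qStart < x$qEnd && x$qEnd <= x$qSize))
    stop_validation(who, ": query span violates 0 <= qStart < qEnd <= qSize")
  if (!x$qStrand %in% c("+", "-"))
    stop_validation(who, ": qStrand must be '+' or '-'")
  t_sum <- sum(b$size + b$dt)
  q_sum <- sum(b$size + b$dq)
  if (t_sum != x$tEnd - x$tStart)
    stop_validation(who, ": run sum over reference (", fmt_int(t_sum),
                    ") != tEnd - tStart (", fmt_int(x$tEnd - x$tStart), ")")
  if (q_sum != x$qEnd - x$qStart)
    stop_validation(who, ": run sum over query (", fmt_int(q_sum),
                    ") != qEnd - qStart (", fmt_int(x$qEnd - x$qStart), ")")
  invisible(x)
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("chain %s: %s:%s-%s (+) -> %s:%s-%s (%s), %d block(s), %s aligned bp\n",
              fmt_int(x$id), x$tName, fmt_int(x$tStart), fmt_int(x$tEnd),
              x$qName, fmt_int(x$qStart), fmt_int(x$qEnd), x$qStrand,
              nrow(x$blocks), fmt_int(sum(x$blocks$size))))
  invisible(x)
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("chain_set with %d chain(s)\n", length(x)))
  if (length(x) > 0) {
    qn <- unique(vapply(x, `[[`, character(1), "qName"))
    cat("  qNames:", paste(utils::head(qn, 8), collapse = ", "),
        if (length(qn) > 8) "..." else "", "\n")
  }
  invisible(x)
}

as_chain_set <- function(chains) structure(chains, class = "chain_set")

#' Read a UCSC chain file
#'
#' Parses a chain-format text file: header lines starting with the
#' `chain` keyword followed by 11 whitespace-separated fields and an id,
#' then block lines of three integers (`size dt dq`), a final line with
#' a single integer, and a blank-line record separator. Lines starting
#' with `#` are skipped. Every chain is checked against the run-sum
#' invariants (see [validate_chain()]).
#'
#' @param path path to a chain file.
#' @param strict if `TRUE` (default) any invalid chain aborts the read;
#'   if `FALSE`, invalid chains are skipped with a warning (tolerant
#'   parsing for occasionally truncated real-world files).
#' @param min_score optional minimum chain score; chains scoring below
#'   it are dropped. Default `NULL` applies no score filter.
#' @return A `"chain_set"`: list of [chain()] objects in file order.
#'   An empty file yields an empty set.
#' @export
read_chain_file <- function(path, strict = TRUE, min_score = NULL) {
  if (!file.exists(path)) stop_usage("chain file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) { i <- i + 1L; next }
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (toks[1] != "chain")
      stop_parse("line ", i, ": expected chain header, got '", ln, "'")
    if (length(toks) != 13)
      stop_parse("line ", i, ": malformed chain header (", length(toks) - 1,
                 " fields, expected 12)")
    num <- suppressWarnings(as.numeric(toks[c(2, 4, 6, 7, 9, 11, 12, 13)]))
    if (anyNA(num))
      stop_parse("line ", i, ": non-numeric field in chain header")
    header_line <- i
    i <- i + 1L
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    closed <- FALSE
    while (i <= n && nzchar(trimws(lines[i]))) {
      if (startsWith(trimws(lines[i]), "#")) { i <- i + 1L; next }
      bt <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (anyNA(bt) || !(length(bt) %in% c(1, 3)))
        stop_parse("line ", i, ": malformed block line '", lines[i], "'")
      if (closed)
        stop_parse("line ", i, ": block line after chain terminator")
      if (length(bt) == 3) {
        sizes <- c(sizes, bt[1]); dts <- c(dts, bt[2]); dqs <- c(dqs, bt[3])
      } else {
        sizes <- c(sizes, bt[1]); dts <- c(dts, 0); dqs <- c(dqs, 0)
        closed <- TRUE
      }
      i <- i + 1L
    }
    if (!closed)
      stop_parse("line ", header_line, ": chain id ", fmt_int(num[8]),
                 " lacks a single-integer terminator line")
    ch <- chain(score = num[1], tName = toks[3], tSize = num[2],
                tStart = num[3], tEnd = num[4],
                qName = toks[8], qSize = num[5], qStrand = toks[10],
                qStart = num[6], qEnd = num[7], id = num[8],
                blocks = data.frame(size = sizes, dt = dts, dq = dqs))
    ok <- TRUE
    if (strict) {
      validate_chain(ch)
    } else {
      ok <- tryCatch({ validate_chain(ch); TRUE },
                     chaindisp_validation_error = function(e) {
                       warning("skipping invalid chain: ", conditionMessage(e),
                               call. = FALSE)
                       FALSE
                     })
    }
    if (ok && !is.null(min_score) && ch$score < min_score) ok <- FALSE
    if (ok) chains[[length(chains) + 1L]] <- ch
  }
  ids <- vapply(chains, `[[`, numeric(1), "id")
  if (anyDuplicated(ids))
    stop_validation("duplicate chain id(s): ",
                    paste(fmt_int(unique(ids[duplicated(ids)])), collapse = ", "))
  as_chain_set(chains)
}

#' Write chains to a UCSC chain file
#'
#' Emits a canonical chain-format file (tab-separated block lines, one
#' blank line after each chain). All chains are validated before any
#' output is written; re-reading the file with [read_chain_file()]
#' reproduces the input field-for-field.
#'
#' @param chains a `"chain_set"` or list of [chain()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chain_file <- function(chains, path) {
  for (ch in chains) validate_chain(ch)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", fmt_int(ch$score), ch$tName, fmt_int(ch$tSize),
                     ch$tStrand, fmt_int(ch$tStart), fmt_int(ch$tEnd),
                     ch$qName, fmt_int(ch$qSize), ch$qStrand,
                     fmt_int(ch$qStart), fmt_int(ch$qEnd), fmt_int(ch$id)),
               con)
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1)
      writeLines(paste(fmt_int(b$size[-nb]), fmt_int(b$dt[-nb]),
                       fmt_int(b$dq[-nb]), sep = "\t"), con)
    writeLines(fmt_int(b$size[nb]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a chrom.sizes table
#'
#' Reads the UCSC-style two-column TSV (sequence name, integer length in
#' bp) used to restrict chromosome-level summaries to assembled
#' chromosomes and to scale chromosome drawings.
#'
#' @param path path to a two-column TSV with no header row.
#' @param assembly optional assembly label attached as an attribute.
#' @return A named numeric vector of class `"chrom_sizes"` mapping
#'   sequence name to length.
#' @export
read_chrom_sizes <- function(path, assembly = NA_character_) {
  if (!file.exists(path)) stop_usage("chrom.sizes file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0)
    return(chrom_sizes(numeric(0), assembly = assembly))
  parts <- strsplit(lines, "\t|\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop_parse("chrom.sizes row ", bad[1], ": expected 2 columns")
  nm <- vapply(parts, `[[`, character(1), 1)
  lenstr <- vapply(parts, `[[`, character(1), 2)
  notint <- which(!grepl("^[0-9]+$", lenstr))
  if (length(notint))
    stop_parse("chrom.sizes row ", notint[1], ": non-integer length '",
               lenstr[notint[1]], "'")
  len <- as.numeric(lenstr)
  chrom_sizes(stats::setNames(len, nm), assembly = assembly)
}

#' Construct a chrom.sizes object
#'
#' @param sizes named numeric vector of sequence lengths (bp).
#' @param assembly optional assembly label.
#' @return A `"chrom_sizes"` object.
#' @export
chrom_sizes <- function(sizes, assembly = NA_character_) {
  if (length(sizes) > 0) {
    if (is.null(names(sizes)) || any(!nzchar(names(sizes))))
      stop_validation("chrom.sizes entries must be named")
    if (anyDuplicated(names(sizes)))
      stop_validation("duplicate sequence name(s): ",
                      paste(unique(names(sizes)[duplicated(names(sizes))]),
                            collapse = ", "))
    if (any(sizes < 1)) stop_validation("sequence lengths must be >= 1")
  }
  structure(as.numeric(sizes), names = names(sizes),
            assembly = assembly, class = "chrom_sizes")
}

#' Write a chrom.sizes table
#' @param sizes a [chrom_sizes()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(paste(names(sizes), fmt_int(unclass(sizes)), sep = "\t"), path)
  invisible(path)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat(sprintf("chrom_sizes (%s): %d sequence(s)\n",
              attr(x, "assembly"), length(x)))
  if (length(x))
    print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Convert a strand-local query interval to forward-strand coordinates
#'
#' Chain query coordinates are strand-local: on the reverse strand,
#' position 0 is the last base of the forward sequence. Chromosome-level
#' summaries are strand-free, so strand-local intervals are reflected to
#' the forward strand before aggregation: a reverse-strand interval
#' `[s, e)` on a sequence of length `L` becomes `[L - e, L - s)`. The
#' reflection preserves interval length and is its own inverse.
#'
#' @param qStart,qEnd strand-local interval, 0-based half-open.
#' @param qSize query sequence length (bp).
#' @param qStrand `"+"` (identity) or `"-"` (reflection).
#' @return Numeric vector `c(start, end)` on the forward strand.
#' @export
to_forward_query_interval <- function(qStart, qEnd, qSize, qStrand) {
  if (!(qStart >= 0 && qStart < qEnd && qEnd <= qSize))
    stop_validation("query interval [", fmt_int(qStart), ",", fmt_int(qEnd),
                    ") outside [0,", fmt_int(qSize), ")")
  if (qStrand == "+") c(qStart, qEnd) else c(qSize - qEnd, qSize - qStart)
}
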