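#' Construct a paired tissue-expression object
#'
#' Holds per-tissue median expression for two loci (e.g. a processed
#' pseudogene and its propagated copy) in matched order. Units are
#' arbitrary but must be consistent between the two loci; the module is
#' unit-agnostic.
#'
#' @param tissue tissue labels.
#' @param x,y per-tissue expression for the first- and second-named
#'   locus; equal length `>= 3`, finite, non-negative.
#' @param x_label,y_label locus names. The first-named locus (`x`) is
#'   the regression predictor.
#' @return Object of class `"expression_pair"`.
#' @export
expression_pair <- function(tissue, x, y, x_label = "locusX",
                            y_label = "locusY") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(tissue) != length(x) || length(x) != length(y))
    stop_validation("tissue, x and y must have equal length")
  if (length(x) < 3)
    stop_validation("at least 3 tissues are required")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop_validation("expression values must be finite and non-missing")
  if (any(x < 0) || any(y < 0))
    stop_validation("expression values must be non-negative")
  structure(list(tissue = as.character(tissue), x = x, y = y,
                 x_label = x_label, y_label = y_label),
            class = "expression_pair")
}

#' Read a tissue/locus-pair expression TSV
#'
#' @param path TSV with a header row; first column is the tissue label,
#'   the next two columns are the two loci (column names become the
#'   locus labels).
#' @return An [expression_pair()].
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_usage("expression TSV not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 3)
    stop_parse("expression TSV needs >= 3 columns (tissue, locusX, locusY)")
  expression_pair(df[[1]], df[[2]], df[[3]],
                  x_label = names(df)[2], y_label = names(df)[3])
}

#' Write an expression pair to TSV
#' @param pair an [expression_pair()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(pair, path) {
  df <- data.frame(tissue = pair$tissue, x = pair$x, y = pair$y,
                   check.names = FALSE)
  names(df)[2:3] <- c(pair$x_label, pair$y_label)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (average ranks for
#' ties). Undefined (with a warning) when either vector has zero rank
#' variance.
#'
#' @param pair an [expression_pair()].
#' @return Correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
spearman_rho <- function(pair) {
  if (stats::var(rank(pair$x)) == 0 || stats::var(rank(pair$y)) == 0) {
    warning("spearman_rho undefined: zero rank variance", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pair$x, pair$y, method = "spearman")
}

#' Pearson product-moment correlation
#'
#' @param pair an [expression_pair()].
#' @return Correlation in `[-1, 1]`, or `NA` when either vector has
#'   zero variance (with a warning).
#' @export
pearson_r <- function(pair) {
  if (stats::var(pair$x) == 0 || stats::var(pair$y) == 0) {
    warning("pearson_r undefined: zero variance", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(pair$x, pair$y, method = "pearson")
}

#' Ordinary-least-squares slope of y on x
#'
#' Regresses the second-named locus on the first-named locus:
#' `cov(x, y) / var(x)`. Orientation matters for the slope, so the
#' predictor is fixed by the pair's construction order.
#'
#' @param pair an [expression_pair()].
#' @return Slope, or `NA` when `var(x) == 0` (with a warning).
#' @export
ols_slope <- function(pair) {
  if (stats::var(pair$x) == 0) {
    warning("ols_slope undefined: zero variance in predictor", call. = FALSE)
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(pair$y ~ pair$x))[2])
}

#' Leave-one-tissue-out minimum Spearman correlation
#'
#' Recomputes [spearman_rho()] n times, each time dropping one tissue,
#' and returns the minimum — a robustness summary showing whether the
#' concordance hinges on a single tissue. Degenerate subsamples (zero
#' rank variance) are excluded with a warning.
#'
#' @param pair an [expression_pair()] with at least 4 tissues.
#' @return Minimum Spearman correlation over the n subsamples.
#' @export
leave_one_out_min_spearman <- function(pair) {
  n <- length(pair$x)
  if (n < 4) stop_validation("leave-one-out requires at least 4 tissues")
  vals <- vapply(seq_len(n), function(i) {
    sub <- expression_pair(pair$tissue[-i], pair$x[-i], pair$y[-i],
                           pair$x_label, pair$y_label)
    suppressWarnings(spearman_rho(sub))
  }, numeric(1))
  if (anyNA(vals))
    warning(sum(is.na(vals)),
            " degenerate leave-one-out subsample(s) excluded", call. = FALSE)
  if (all(is.na(vals))) return(NA_real_)
  min(vals, na.rm = TRUE)
}

#' Expression concordance for a locus pair
#'
#' One-stop summary: Spearman and Pearson correlations, OLS slope of
#' the second locus on the first, and the leave-one-tissue-out minimum
#' Spearman.
#'
#' @param pair an [expression_pair()].
#' @return Object of class `"concordance_result"` with fields `n`,
#'   `spearmanRho`, `pearsonR`, `olsSlope`, `lotoMinSpearman`,
#'   `xLabel`, `yLabel`.
#' @export
expression_concordance <- function(pair) {
  structure(list(n = length(pair$x),
                 spearmanRho = spearman_rho(pair),
                 pearsonR = pearson_r(pair),
                 olsSlope = ols_slope(pair),
                 lotoMinSpearman = if (length(pair$x) >= 4)
                   leave_one_out_min_spearman(pair) else NA_real_,
                 xLabel = pair$x_label, yLabel = pair$y_label),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("expression concordance: %s (predictor) vs %s, n = %d tissues\n",
              x$xLabel, x$yLabel, x$n))
  cat(sprintf("  Spearman rho            : %.3f\n", x$spearmanRho))
  cat(sprintf("  Pearson r               : %.3f\n", x$pearsonR))
  cat(sprintf("  OLS slope (%s on %s): %.3f\n", x$yLabel, x$xLabel,
              x$olsSlope))
  cat(sprintf("  leave-one-out min rho   : %.3f\n", x$lotoMinSpearman))
  invisible(x)
}

#' Write a concordance result as a single-row TSV
#' @param result a `"concordance_result"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concordance_tsv <- function(result, path) {
  df <- data.frame(xLabel = result$xLabel, yLabel = result$yLabel,
                   n = result$n, spearmanRho = result$spearmanRho,
                   pearsonR = result$pearsonR, olsSlope = result$olsSlope,
                   lotoMinSpearman = result$lotoMinSpearman)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
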