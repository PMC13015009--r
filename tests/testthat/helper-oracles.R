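# Independent brute-force oracles. These deliberately avoid the package's
# block-arithmetic / interval-index / stats::cor code paths.

# per-base liftover: enumerate every aligned reference position of a chain,
# keep those inside the half-open window, and report the count plus the
# forward-strand query extent of the kept positions.
oracle_clip <- function(chain, win_start, win_end) {
  b <- chain$blocks
  t <- chain$tStart
  q <- chain$qStart
  tpos <- numeric(0)
  qpos <- numeric(0)
  for (i in seq_len(nrow(b))) {
    tpos <- c(tpos, seq(t, t + b$size[i] - 1))
    qpos <- c(qpos, seq(q, q + b$size[i] - 1))
    t <- t + b$size[i] + b$dt[i]
    q <- q + b$size[i] + b$dq[i]
  }
  keep <- tpos >= win_start & tpos < win_end
  if (!any(keep))
    return(NULL)
  ql <- qpos[keep]
  fwd <- if (chain$qStrand == "+") ql else chain$qSize - 1 - ql
  list(aligned = sum(keep),
       q_forward_start = min(fwd), q_forward_end = max(fwd) + 1)
}

# quadratic interval oracles on half-open intervals
oracle_overlaps <- function(chrom, s, e, track) {
  any(track$chrom == chrom & track$start < e & track$end > s)
}

oracle_distance <- function(chrom, s, e, track) {
  on <- track[track$chrom == chrom, , drop = FALSE]
  if (nrow(on) == 0) return(NA_real_)
  gaps <- vapply(seq_len(nrow(on)), function(i) {
    if (on$start[i] < e && on$end[i] > s) 0
    else if (on$start[i] >= e) on$start[i] - e
    else s - on$end[i]
  }, numeric(1))
  min(gaps)
}

# average ranks by counting, then the product-moment correlation by
# explicit sums (no rank(), no cor())
oracle_rank <- function(x) {
  vapply(x, function(xi) (sum(x < xi) + sum(x <= xi) + 1) / 2, numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

oracle_spearman <- function(x, y) oracle_pearson(oracle_rank(x), oracle_rank(y))

oracle_slope <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

oracle_loto_min <- function(x, y) {
  min(vapply(seq_along(x), function(i)
    oracle_spearman(x[-i], y[-i]), numeric(1)))
}

# random expression fixture with ties (values rounded to one decimal)
random_tied_pair <- function(n) {
  x <- round(exp(rnorm(n, 0, 1)), 1)
  y <- round(x * exp(rnorm(n, 0, 0.4)), 1)
  # guard against degenerate rank variance in tiny samples
  while (length(unique(x)) < 2 || length(unique(y)) < 2) {
    x <- round(exp(rnorm(n, 0, 1)), 1)
    y <- round(x * exp(rnorm(n, 0, 0.4)), 1)
  }
  expression_pair(sprintf("t%02d", seq_len(n)), x, y)
}

# small constructed projection result
make_result <- function(qnames, aligned, window_len = 1000,
                        qstart = NULL) {
  win <- genomic_window("chrW", 0, window_len,
                        convention = "zero-based-half-open", id = "w")
  n <- length(qnames)
  if (is.null(qstart)) qstart <- seq_len(n) * 10
  seg <- data.frame(windowId = rep("w", n),
                    chainId = seq_len(n), qName = qnames,
                    qStrand = rep("+", n),
                    qForwardStart = qstart,
                    qForwardEnd = qstart + pmax(aligned, 1),
                    alignedBases = aligned, nBlocks = rep(1L, n),
                    stringsAsFactors = FALSE)
  as_projection_result(seg, win)
}
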