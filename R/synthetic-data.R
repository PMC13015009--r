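# All generators draw from an explicitly seeded local RNG stream and
# restore the caller's random state, so identical seeds give
# byte-identical files and the global session RNG is never disturbed.
with_seed <- function(seed, code) {
  if (!is_count(seed))
    stop_usage("seed must be a single non-negative integer")
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# sample one integer from 0:(n-1); safe for n == 1
sample0 <- function(n) sample.int(n, 1) - 1

# sample one integer from lo:hi inclusive; safe when lo == hi
sample_range <- function(lo, hi) lo + sample0(hi - lo + 1)

#' Configure a synthetic dispersal simulation
#'
#' Describes an SD-mediated dispersal regime: a reference window whose
#' content is copied onto `n_targets` query chromosomes as
#' `fragments_per_target` chain-mapped fragments each, with tunable
#' fragment length, internal gap rate, strand, and a number of decoy
#' chains that overlap nothing.
#'
#' @param window_length length of the reference query window (bp).
#' @param n_targets number K of target chromosomes receiving fragments
#'   (0 allowed: only decoys are emitted).
#' @param fragments_per_target number F of fragments per target
#'   chromosome (scalar, or a vector of length K).
#' @param fragment_length_range bounds (bp) for the gapless aligned
#'   length of each fragment; the lower bound must not exceed
#'   `window_length`.
#' @param gap_rate probability-like rate controlling how many internal
#'   dt/dq gaps a fragment's chain carries (0 = gap-free).
#' @param decoy_chains number of chains placed outside the window
#'   (they must never be projected).
#' @param reverse_strand_prob probability a fragment lands on the
#'   reverse strand of its target chromosome.
#' @param seed RNG seed; identical seeds give identical output.
#' @return A `"dispersal_config"` list.
#' @export
dispersal_config <- function(window_length = 20000, n_targets = 6,
                             fragments_per_target = 3,
                             fragment_length_range = c(500, 3000),
                             gap_rate = 0.2, decoy_chains = 3,
                             reverse_strand_prob = 0.3, seed = 1) {
  if (!is_count(n_targets)) stop_validation("n_targets must be a count >= 0")
  if (any(fragments_per_target < 1))
    stop_validation("fragments_per_target must be >= 1")
  if (n_targets > 0 && length(fragments_per_target) != 1 &&
      length(fragments_per_target) != n_targets)
    stop_validation("fragments_per_target must be scalar or length n_targets")
  if (fragment_length_range[1] < 1)
    stop_validation("fragment lengths must be >= 1")
  if (fragment_length_range[1] > window_length)
    stop_validation("infeasible config: minimum fragment length (",
                    fmt_int(fragment_length_range[1]),
                    ") exceeds window length (", fmt_int(window_length), ")")
  structure(list(window_length = window_length, n_targets = n_targets,
                 fragments_per_target = fragments_per_target,
                 fragment_length_range = fragment_length_range,
                 gap_rate = gap_rate, decoy_chains = decoy_chains,
                 reverse_strand_prob = reverse_strand_prob, seed = seed),
            class = "dispersal_config")
}

#' Named preset dispersal regimes
#'
#' Six regimes crossing target-chromosome count (few = 4, many = 12)
#' with fragmentation level (low: 2 long fragments per target; medium:
#' 5 mid-length; high: 10 short), mimicking the qualitative contrast
#' between lineages with reduced fragmentation (few large chromosomal
#' blocks) and pronounced dispersion (many chromosomes carrying small
#' fragments).
#'
#' @param seed seed applied to every preset.
#' @return Named list of [dispersal_config()] objects.
#' @export
dispersal_presets <- function(seed = 1) {
  frag <- list(
    low    = list(f = 2,  range = c(3000, 8000), gap = 0.05),
    medium = list(f = 5,  range = c(800, 2500),  gap = 0.2),
    high   = list(f = 10, range = c(150, 700),   gap = 0.4))
  targets <- c(few = 4, many = 12)
  out <- list()
  for (tn in names(targets)) {
    for (fn in names(frag)) {
      out[[paste(tn, "targets", fn, "frag", sep = "_")]] <-
        dispersal_config(window_length = 20000, n_targets = targets[[tn]],
                         fragments_per_target = frag[[fn]]$f,
                         fragment_length_range = frag[[fn]]$range,
                         gap_rate = frag[[fn]]$gap, decoy_chains = 3,
                         reverse_strand_prob = 0.3, seed = seed)
    }
  }
  out
}

#' Simulate an SD-mediated dispersal with exact ground truth
#'
#' Emits a chain collection describing a reference window dispersed
#' across target chromosomes, the target chrom.sizes table, the query
#' window, and a truth ledger recording, per chain, the exact number of
#' gapless aligned bases falling inside the window (all fragment blocks
#' are placed inside the window, so the truth is known by
#' construction). Decoy chains are placed strictly before the window on
#' the reference and must never be projected.
#'
#' @param config a [dispersal_config()].
#' @return List with elements `chains` (a `"chain_set"`), `sizes`
#'   (target [chrom_sizes()]), `window` (the reference
#'   [genomic_window()]), and `truth` (list: `per_chain` data frame,
#'   `per_qname` data frame, `accumulated_coverage`,
#'   `n_distinct_qnames`, `decoy_chain_ids`, `config`).
#' @export
simulate_dispersal <- function(config) {
  stopifnot(inherits(config, "dispersal_config"))
  with_seed(config$seed, {
    W <- config$window_length
    K <- config$n_targets
    win_start <- W  # reference layout: [0, W) decoy zone, [W, 2W) window
    ref_name <- "chrREF"
    ref_len <- 3 * W
    n_chroms <- max(K, 1)
    q_names <- sprintf("tchr%d", seq_len(n_chroms))
    q_size <- max(1e6, 4 * W)
    sizes <- chrom_sizes(stats::setNames(rep(q_size, n_chroms), q_names),
                         assembly = "synthetic-target")
    fpt <- rep_len(config$fragments_per_target, max(K, 0))
    chains <- list()
    truth_rows <- list()
    next_id <- 1
    for (k in seq_len(K)) {
      for (f in seq_len(fpt[k])) {
        A <- sample_range(config$fragment_length_range[1],
                          min(config$fragment_length_range[2], W))
        n_gaps <- min(stats::rbinom(1, 4, config$gap_rate), A - 1)
        sizes_blk <- if (n_gaps == 0) A else
          diff(c(0, sort(sample(A - 1, n_gaps)), A))
        budget <- W - A
        if (n_gaps > 0) {
          dt <- sample.int(min(50, max(1, budget %/% n_gaps)) + 1,
                           n_gaps, replace = TRUE) - 1
          dq <- sample.int(51, n_gaps, replace = TRUE) - 1
          dq[dt == 0 & dq == 0] <- 1
        } else {
          dt <- numeric(0); dq <- numeric(0)
        }
        t_span <- A + sum(dt)
        t_start <- win_start + sample0(W - t_span + 1)
        q_span <- A + sum(dq)
        q_start <- sample0(q_size - q_span + 1)
        strand <- if (stats::runif(1) < config$reverse_strand_prob) "-" else "+"
        ch <- chain(score = 1000 + A, tName = ref_name, tSize = ref_len,
                    tStart = t_start, tEnd = t_start + t_span,
                    qName = q_names[k], qSize = q_size, qStrand = strand,
                    qStart = q_start, qEnd = q_start + q_span, id = next_id,
                    blocks = data.frame(size = sizes_blk,
                                        dt = c(dt, 0), dq = c(dq, 0)))
        validate_chain(ch)
        fwd <- to_forward_query_interval(q_start, q_start + q_span,
                                         q_size, strand)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          chainId = next_id, qName = q_names[k], qStrand = strand,
          alignedBases = A, qForwardStart = fwd[1], qForwardEnd = fwd[2],
          stringsAsFactors = FALSE)
        chains[[length(chains) + 1L]] <- ch
        next_id <- next_id + 1
      }
    }
    decoy_ids <- numeric(0)
    for (d in seq_len(config$decoy_chains)) {
      A <- sample_range(10, min(500, win_start - 1))
      t_start <- sample0(win_start - A + 1)
      if (t_start + A > win_start) t_start <- win_start - A
      q_start <- sample0(q_size - A + 1)
      ch <- chain(score = 100, tName = ref_name, tSize = ref_len,
                  tStart = t_start, tEnd = t_start + A,
                  qName = q_names[sample.int(n_chroms, 1)], qSize = q_size,
                  qStrand = "+", qStart = q_start, qEnd = q_start + A,
                  id = next_id,
                  blocks = data.frame(size = A, dt = 0, dq = 0))
      validate_chain(ch)
      decoy_ids <- c(decoy_ids, next_id)
      chains[[length(chains) + 1L]] <- ch
      next_id <- next_id + 1
    }
    per_chain <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(chainId = numeric(0), qName = character(0),
                 qStrand = character(0), alignedBases = numeric(0),
                 qForwardStart = numeric(0), qForwardEnd = numeric(0),
                 stringsAsFactors = FALSE)
    per_qname <- if (nrow(per_chain)) {
      ab <- tapply(per_chain$alignedBases, per_chain$qName, sum)
      ns <- tapply(per_chain$alignedBases, per_chain$qName, length)
      df <- data.frame(qName = names(ab), alignedBases = as.numeric(ab),
                       nSegments = as.integer(ns), stringsAsFactors = FALSE)
      df <- df[order(-df$alignedBases, df$qName), , drop = FALSE]
      rownames(df) <- NULL
      df
    } else data.frame(qName = character(0), alignedBases = numeric(0),
                      nSegments = integer(0), stringsAsFactors = FALSE)
    window <- genomic_window(ref_name, win_start, win_start + W,
                             convention = "zero-based-half-open",
                             assembly = "synthetic-reference",
                             id = "simwindow")
    truth <- list(per_chain = per_chain, per_qname = per_qname,
                  accumulated_coverage = sum(per_chain$alignedBases) / W,
                  n_distinct_qnames = length(unique(per_chain$qName)),
                  decoy_chain_ids = decoy_ids, config = unclass(config))
    list(chains = as_chain_set(chains), sizes = sizes, window = window,
         truth = truth)
  })
}

#' Write a simulated dispersal to files
#'
#' @param sim output of [simulate_dispersal()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the written paths (`chains`,
#'   `chrom_sizes`, `window`, `truth`), invisibly.
#' @export
write_dispersal_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chains = file.path(dir, "dispersal.chain"),
             chrom_sizes = file.path(dir, "target.chrom.sizes"),
             window = file.path(dir, "window.bed"),
             truth = file.path(dir, "truth.json"))
  write_chain_file(sim$chains, paths["chains"])
  write_chrom_sizes(sim$sizes, paths["chrom_sizes"])
  w0 <- convert_convention(sim$window, "zero-based-half-open")
  writeLines(paste(w0$chrom, fmt_int(w0$start), fmt_int(w0$end), w0$id,
                   sep = "\t"), paths["window"])
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Simulate random chains against a reference sequence
#'
#' Unconstrained chain generator for property testing: chains may
#' straddle any window boundary, carry internal dt/dq gaps, and sit on
#' either query strand. All emitted chains satisfy the chain run-sum
#' invariants.
#'
#' @param n number of chains.
#' @param t_name,t_size reference sequence name and length.
#' @param q_names candidate query chromosome names.
#' @param q_size query chromosome length (shared).
#' @param max_blocks maximum gapless blocks per chain.
#' @param block_size_range bounds for gapless block lengths (bp).
#' @param gap_range bounds for internal dt/dq gap lengths (bp).
#' @param reverse_strand_prob probability of a reverse-strand query.
#' @param seed RNG seed.
#' @return A `"chain_set"` of `n` chains with ids `1:n`.
#' @export
simulate_random_chains <- function(n, t_name = "chrREF", t_size = 50000,
                                   q_names = c("tchr1", "tchr2", "tchr3"),
                                   q_size = 1e6, max_blocks = 5,
                                   block_size_range = c(1, 2000),
                                   gap_range = c(0, 500),
                                   reverse_strand_prob = 0.5, seed = 1) {
  with_seed(seed, {
    chains <- vector("list", n)
    for (i in seq_len(n)) {
      repeat {
        nb <- sample_range(1, max_blocks)
        sz <- vapply(seq_len(nb), function(j)
          sample_range(block_size_range[1], block_size_range[2]), numeric(1))
        dt <- c(vapply(seq_len(max(nb - 1, 0)), function(j)
          sample_range(gap_range[1], gap_range[2]), numeric(1)), 0)
        dq <- c(vapply(seq_len(max(nb - 1, 0)), function(j)
          sample_range(gap_range[1], gap_range[2]), numeric(1)), 0)
        if (nb > 1) {
          z <- which(dt[-nb] == 0 & dq[-nb] == 0)
          dq[z] <- 1
        }
        t_span <- sum(sz + dt)
        q_span <- sum(sz + dq)
        if (t_span <= t_size && q_span <= q_size) break
      }
      t_start <- sample0(t_size - t_span + 1)
      q_start <- sample0(q_size - q_span + 1)
      strand <- if (stats::runif(1) < reverse_strand_prob) "-" else "+"
      chains[[i]] <- chain(score = 1000, tName = t_name, tSize = t_size,
                           tStart = t_start, tEnd = t_start + t_span,
                           qName = q_names[sample.int(length(q_names), 1)],
                           qSize = q_size, qStrand = strand,
                           qStart = q_start, qEnd = q_start + q_span,
                           id = i,
                           blocks = data.frame(size = sz, dt = dt, dq = dq))
      validate_chain(chains[[i]])
    }
    as_chain_set(chains)
  })
}

#' Simulate a genome-context fixture with planted classifications
#'
#' Builds SD, censat and locus BED tracks on a small synthetic genome
#' with loci planted at known distances from censat intervals and
#' chromosome ends, including distances exactly at and one bp beyond
#' the classification thresholds, plus a half-open SD abutment case.
#' The truth ledger records each locus's expected overlap flags,
#' distances and boundary class, all derived from the construction
#' arithmetic.
#'
#' @param chrom_lengths named vector of chromosome lengths; each must be
#'   at least `6 * max(peri_threshold, telo_threshold)`.
#' @param peri_threshold,telo_threshold classification thresholds (bp)
#'   the plants straddle.
#' @param n_random_interior extra interior loci placed at seeded random
#'   safe positions per chromosome.
#' @param seed RNG seed.
#' @return List with `loci`, `sd_track`, `censat_track`
#'   ([genomic_intervals()]), `sizes` ([chrom_sizes()]), and `truth`
#'   (data frame of expected classifications).
#' @export
simulate_context_fixture <- function(chrom_lengths = c(chrA = 6e7,
                                                       chrB = 9e7,
                                                       chrC = 1.2e8),
                                     peri_threshold = 5e6,
                                     telo_threshold = 5e6,
                                     n_random_interior = 2, seed = 1) {
  if (peri_threshold < 1.5e6 || telo_threshold < 1.5e6)
    stop_validation("thresholds below 1.5 Mb do not fit the planted layout")
  if (any(chrom_lengths / 2 <= peri_threshold + telo_threshold + 7.2e6))
    stop_validation("chromosome lengths too short for the planted layout; ",
                    "need length/2 > peri + telo + 7.2 Mb")
  with_seed(seed, {
    len <- 1e4  # planted locus length
    censat <- list(); loci <- list(); sd <- list(); truth <- list()
    add_censat <- function(chrom, s, e)
      censat[[length(censat) + 1L]] <<- data.frame(chrom = chrom, start = s,
                                                   end = e)
    add_locus <- function(chrom, s, e, name, sd_overlap, censat_overlap,
                          d_cen, d_end, cls) {
      loci[[length(loci) + 1L]] <<- data.frame(chrom = chrom, start = s,
                                               end = e, name = name)
      truth[[length(truth) + 1L]] <<- data.frame(
        locusName = name, chrom = chrom, start = s, end = e,
        sdOverlap = sd_overlap, censatOverlap = censat_overlap,
        distanceToCensat = d_cen, distanceToChromEnd = d_end,
        boundaryClass = cls, stringsAsFactors = FALSE)
    }
    add_sd <- function(chrom, s, e)
      sd[[length(sd) + 1L]] <<- data.frame(chrom = chrom, start = s, end = e)
    chroms <- names(chrom_lengths)
    for (ci in seq_along(chroms)) {
      chrom <- chroms[ci]
      L <- chrom_lengths[[ci]]
      cs <- L / 2 - 1e6; ce <- L / 2 + 1e6  # central censat block
      add_censat(chrom, cs, ce)
      if (ci %% 3 == 1) {
        # pericentromeric plants (far from both ends)
        s1 <- cs + 1000
        add_locus(chrom, s1, s1 + len, paste0(chrom, "_peri_overlap"),
                  sd_overlap = TRUE, censat_overlap = TRUE, d_cen = 0,
                  d_end = min(s1, L - s1 - len), cls = "pericentromeric")
        add_sd(chrom, s1 - 5000, s1 + len + 5000)
        s2 <- ce + peri_threshold
        add_locus(chrom, s2, s2 + len, paste0(chrom, "_peri_at_threshold"),
                  sd_overlap = TRUE, censat_overlap = FALSE,
                  d_cen = peri_threshold, d_end = min(s2, L - s2 - len),
                  cls = "pericentromeric")
        add_sd(chrom, s2 - 2000, s2 + len + 2000)
        s3 <- ce + peri_threshold + 1
        add_locus(chrom, s3 + 3e6, s3 + 3e6 + len,
                  paste0(chrom, "_interior_beyond_peri"),
                  sd_overlap = FALSE, censat_overlap = FALSE,
                  d_cen = peri_threshold + 1 + 3e6,
                  d_end = min(s3 + 3e6, L - s3 - 3e6 - len), cls = "interior")
        # half-open abutment: SD ends exactly where the locus starts
        # (placed 2 Mb past the peri plants so no other SD reaches it)
        s4 <- ce + peri_threshold + 2e6
        add_locus(chrom, s4, s4 + len, paste0(chrom, "_interior_sd_abut"),
                  sd_overlap = FALSE, censat_overlap = FALSE,
                  d_cen = peri_threshold + 2e6,
                  d_end = min(s4, L - s4 - len), cls = "interior")
        add_sd(chrom, s4 - 1e6, s4)
      } else if (ci %% 3 == 2) {
        # subtelomeric plants (censat is central, far away)
        s1 <- 1e6
        add_locus(chrom, s1, s1 + len, paste0(chrom, "_telo_left"),
                  sd_overlap = TRUE, censat_overlap = FALSE,
                  d_cen = cs - s1 - len, d_end = s1, cls = "subtelomeric")
        add_sd(chrom, s1 - 1000, s1 + len + 1000)
        s2 <- telo_threshold
        add_locus(chrom, s2, s2 + len, paste0(chrom, "_telo_at_threshold"),
                  sd_overlap = FALSE, censat_overlap = FALSE,
                  d_cen = cs - s2 - len, d_end = s2, cls = "subtelomeric")
        s3 <- telo_threshold + 1
        add_locus(chrom, s3, s3 + len, paste0(chrom, "_interior_beyond_telo"),
                  sd_overlap = FALSE, censat_overlap = FALSE,
                  d_cen = cs - s3 - len, d_end = s3, cls = "interior")
        e4 <- L - 2e6
        add_locus(chrom, e4 - len, e4, paste0(chrom, "_telo_right"),
                  sd_overlap = FALSE, censat_overlap = FALSE,
                  d_cen = e4 - len - ce, d_end = L - e4, cls = "subtelomeric")
      } else {
        # both-class plant: a second censat block near the chromosome start
        add_censat(chrom, 2e6, 2.5e6)
        s1 <- 5e5
        add_locus(chrom, s1, s1 + len, paste0(chrom, "_both"),
                  sd_overlap = TRUE, censat_overlap = FALSE,
                  d_cen = 2e6 - s1 - len, d_end = s1, cls = "both")
        add_sd(chrom, s1 - 1000, s1 + len + 1000)
      }
      # seeded random interior extras, placed in the censat-free right arm
      # past every planted SD and locus
      lo <- ce + peri_threshold + 4e6
      hi <- L - telo_threshold - 2e6
      for (r in seq_len(n_random_interior)) {
        s <- lo + sample0(hi - lo - len)
        # right arm: nearest censat interval ends at ce (chrC's extra
        # censat is left of the central block and always farther)
        add_locus(chrom, s, s + len,
                  paste0(chrom, "_interior_rand", r),
                  sd_overlap = FALSE, censat_overlap = FALSE,
                  d_cen = s - ce, d_end = min(s, L - s - len),
                  cls = "interior")
      }
      # decoy SDs that overlap no locus (safe zone just right of censat)
      add_sd(chrom, ce + 1e5, ce + 2e5)
    }
    bind <- function(lst) do.call(rbind, lst)
    cen_df <- bind(censat); sd_df <- bind(sd); loci_df <- bind(loci)
    list(loci = genomic_intervals(loci_df$chrom, loci_df$start, loci_df$end,
                                  loci_df$name, track_label = "loci"),
         sd_track = genomic_intervals(sd_df$chrom, sd_df$start, sd_df$end,
                                      track_label = "SD"),
         censat_track = genomic_intervals(cen_df$chrom, cen_df$start,
                                          cen_df$end,
                                          track_label = "censat"),
         sizes = chrom_sizes(chrom_lengths, assembly = "synthetic"),
         truth = bind(truth),
         peri_threshold = peri_threshold, telo_threshold = telo_threshold)
  })
}

#' Write a context fixture to BED / chrom.sizes / JSON files
#' @param fx output of [simulate_context_fixture()].
#' @param dir output directory.
#' @return Named vector of written paths, invisibly.
#' @export
write_context_files <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(loci = file.path(dir, "loci.bed"),
             sd = file.path(dir, "sd.bed"),
             censat = file.path(dir, "censat.bed"),
             chrom_sizes = file.path(dir, "genome.chrom.sizes"),
             truth = file.path(dir, "truth.json"))
  write_bed(fx$loci, paths["loci"])
  write_bed(fx$sd_track, paths["sd"])
  write_bed(fx$censat_track, paths["censat"])
  write_chrom_sizes(fx$sizes, paths["chrom_sizes"])
  jsonlite::write_json(fx$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(paths)
}

#' Simulate a correlated tissue-expression pair
#'
#' Log-normal shared-signal model: `x = exp(N(0, shared_scale))` per
#' tissue, `y = true_slope * x * exp(N(0, noise_scale))`. With
#' `noise_scale = 0` the pair is perfectly concordant (Spearman 1) and
#' the OLS slope equals `true_slope` exactly.
#'
#' @param n_tissues number of tissues (>= 4).
#' @param shared_scale sd (log scale) of the shared expression factor.
#' @param noise_scale sd (log scale) of the multiplicative noise on y.
#' @param true_slope multiplicative factor linking y to x.
#' @param seed RNG seed.
#' @param x_label,y_label locus names.
#' @return List with `pair` (an [expression_pair()]) and `truth`
#'   (settings plus the realized Spearman correlation).
#' @export
simulate_expression_pair <- function(n_tissues = 54, shared_scale = 1,
                                     noise_scale = 0.1, true_slope = 1,
                                     seed = 1, x_label = "locusX",
                                     y_label = "locusY") {
  if (n_tissues < 4) stop_validation("n_tissues must be >= 4")
  if (shared_scale <= 0 || noise_scale < 0)
    stop_validation("scales must be positive (noise_scale may be 0)")
  with_seed(seed, {
    x <- exp(stats::rnorm(n_tissues, 0, shared_scale))
    y <- true_slope * x * exp(stats::rnorm(n_tissues, 0, noise_scale))
    pair <- expression_pair(sprintf("tissue%02d", seq_len(n_tissues)), x, y,
                            x_label = x_label, y_label = y_label)
    list(pair = pair,
         truth = list(n_tissues = n_tissues, shared_scale = shared_scale,
                      noise_scale = noise_scale, true_slope = true_slope,
                      seed = seed,
                      realized_spearman = stats::cor(x, y,
                                                     method = "spearman")))
  })
}
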