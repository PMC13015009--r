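gapfree_chain <- function(tStart = 100, tEnd = 400, qStart = 200,
                          qStrand = "+", id = 1, tName = "chrT",
                          qName = "chrQ") {
  len <- tEnd - tStart
  chain(1000, tName, 10000, tStart, tEnd, qName, 5000, qStrand,
        qStart, qStart + len, id,
        data.frame(size = len, dt = 0, dq = 0))
}

test_that("browser-coordinate window length matches the printed censat_7_2 size", {
  w <- parse_window("chr7:56524206-56610877")
  expect_identical(window_length(w), 86672)
  expect_identical(window_length(convert_convention(w)), 86672)
  w2 <- genomic_window("chrX", 100, 101, "zero-based-half-open")
  expect_identical(window_length(w2), 1)
})

test_that("coordinate-convention conversion is exact and self-inverse", {
  w <- genomic_window("chr7", 56524206, 56610877)
  h <- convert_convention(w, "zero-based-half-open")
  expect_equal(c(h$start, h$end), c(56524205, 56610877))
  expect_equal(convert_convention(h, "one-based-inclusive")[c("start", "end")],
               w[c("start", "end")])
  b <- convert_convention(genomic_window("chr1", 1, 1), "zero-based-half-open")
  expect_equal(c(b$start, b$end), c(0, 1))
})

test_that("window strings with commas parse; junk does not", {
  w <- parse_window("chr7:56,524,206-56,610,877")
  expect_identical(window_length(w), 86672)
  expect_error(parse_window("chr7;100-200"), class = "chaindisp_usage_error")
})

test_that("gap-free clipping follows 1:1 offset arithmetic and half-open bounds", {
  ch <- gapfree_chain()
  win <- genomic_window("chrT", 150, 250, "zero-based-half-open")
  seg <- clip_chain_to_window(ch, win)
  expect_equal(seg$alignedBases, 100)
  expect_equal(c(seg$qForwardStart, seg$qForwardEnd), c(250, 350))
  expect_equal(seg$nBlocks, 1L)
  # position 400 is not covered by t:[100,400)
  expect_null(clip_chain_to_window(
    ch, genomic_window("chrT", 400, 500, "zero-based-half-open")))
  # other reference sequence: silently no segment
  expect_null(clip_chain_to_window(
    ch, genomic_window("chrZ", 150, 250, "zero-based-half-open")))
})

test_that("reverse-strand extents are reported on the forward strand", {
  ch <- gapfree_chain(qStrand = "-")
  win <- genomic_window("chrT", 100, 400, "zero-based-half-open")
  seg <- clip_chain_to_window(ch, win)
  expect_equal(seg$alignedBases, 300)
  expect_equal(c(seg$qForwardStart, seg$qForwardEnd), c(4500, 4800))
})

test_that("block arithmetic equals the per-base liftover oracle on random chains", {
  withr::local_seed(101)
  for (inst in 1:40) {
    t_size <- 30000
    wlen <- sample.int(10000, 1)
    ws <- sample.int(t_size - wlen, 1)
    win <- genomic_window("chrREF", ws, ws + wlen, "zero-based-half-open")
    cs <- simulate_random_chains(sample.int(12, 1), t_size = t_size,
                                 seed = inst)
    for (ch in cs) {
      seg <- clip_chain_to_window(ch, win)
      orc <- oracle_clip(ch, ws, ws + wlen)
      if (is.null(orc)) {
        expect_null(seg)
      } else {
        expect_equal(seg$alignedBases, orc$aligned)
        expect_equal(seg$qForwardStart, orc$q_forward_start)
        expect_equal(seg$qForwardEnd, orc$q_forward_end)
      }
    }
  }
})

test_that("enlarging a window never loses aligned bases or segments", {
  cs <- simulate_random_chains(25, t_size = 30000, seed = 7)
  sizes <- chrom_sizes(c(tchr1 = 1e6, tchr2 = 1e6, tchr3 = 1e6))
  win_small <- genomic_window("chrREF", 12000, 16000, "zero-based-half-open")
  win_big <- genomic_window("chrREF", 8000, 22000, "zero-based-half-open")
  ps <- project_window(cs, win_small, sizes)
  pb <- project_window(cs, win_big, sizes)
  expect_gte(nrow(pb$segments), nrow(ps$segments))
  joint <- merge(ps$segments, pb$segments, by = "chainId")
  expect_true(all(joint$alignedBases.y >= joint$alignedBases.x))
})

test_that("aligned bases are additive over any split of the window", {
  withr::local_seed(55)
  cs <- simulate_random_chains(30, t_size = 30000, seed = 9)
  for (rep in 1:10) {
    ws <- sample.int(20000, 1)
    wlen <- sample(2:8000, 1)
    cut <- ws + sample.int(wlen - 1, 1)
    whole <- genomic_window("chrREF", ws, ws + wlen, "zero-based-half-open")
    left <- genomic_window("chrREF", ws, cut, "zero-based-half-open")
    right <- genomic_window("chrREF", cut, ws + wlen, "zero-based-half-open")
    for (ch in cs) {
      g <- function(w) {
        s <- clip_chain_to_window(ch, w)
        if (is.null(s)) 0 else s$alignedBases
      }
      expect_equal(g(left) + g(right), g(whole))
    }
  }
})

test_that("gap-free chains clip identically under either strand representation", {
  withr::local_seed(77)
  for (i in 1:25) {
    span <- sample.int(2000, 1)
    ts <- sample.int(8000 - span, 1)
    qs <- sample.int(5000 - span, 1)
    plus <- gapfree_chain(ts, ts + span, qs, "+", id = 1)
    # same aligned forward interval, represented on the reverse strand
    minus <- chain(1000, "chrT", 10000, ts, ts + span, "chrQ", 5000, "-",
                   5000 - (qs + span), 5000 - qs, 2,
                   data.frame(size = span, dt = 0, dq = 0))
    ws <- sample.int(9000, 1)
    win <- genomic_window("chrT", ws, ws + sample.int(1000, 1),
                          "zero-based-half-open")
    a <- clip_chain_to_window(plus, win)
    b <- clip_chain_to_window(minus, win)
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      # a partial window lands on the mirrored end of the reverse-strand
      # copy, so only count and extent length are representation-free
      expect_equal(a$alignedBases, b$alignedBases)
      expect_equal(a$qForwardEnd - a$qForwardStart,
                   b$qForwardEnd - b$qForwardStart)
    }
    # a window covering the whole chain gives the identical forward extent
    full <- genomic_window("chrT", 0, 10000, "zero-based-half-open")
    af <- clip_chain_to_window(plus, full)
    bf <- clip_chain_to_window(minus, full)
    expect_equal(c(af$qForwardStart, af$qForwardEnd), c(qs, qs + span))
    expect_equal(c(bf$qForwardStart, bf$qForwardEnd), c(qs, qs + span))
  }
})

test_that("span accounting counts gapped reference overlap, never less than gapless", {
  ch <- chain(1000, "chrT", 10000, 100, 500, "chrQ", 5000, "+", 0, 300,
              1, data.frame(size = c(100, 100), dt = c(200, 0),
                            dq = c(100, 0)))
  win <- genomic_window("chrT", 100, 500, "zero-based-half-open")
  expect_equal(clip_chain_to_window(ch, win)$alignedBases, 200)
  expect_equal(clip_chain_to_window(ch, win, mode = "span")$alignedBases, 400)
})

test_that("projection keeps multi-mapping, filters qNames after overlap, reports exclusions", {
  win <- genomic_window("chrT", 0, 300, "zero-based-half-open")
  a <- gapfree_chain(0, 300, 100, id = 1, qName = "chrA")
  b <- gapfree_chain(0, 300, 100, id = 2, qName = "chrB")
  a2 <- gapfree_chain(0, 300, 400, id = 3, qName = "chrA")
  sizes <- chrom_sizes(c(chrA = 5000))
  res <- project_window(list(a, b, a2), win, sizes)
  expect_equal(nrow(res$segments), 2)           # both chrA chains retained
  expect_equal(res$excluded$qName, "chrB")
  expect_equal(res$excluded$chainId, 2)
  expect_false(any(res$segments$qName %in% res$excluded$qName))
  # no chain touches the window -> empty everything, not an error
  far <- genomic_window("chrT", 5000, 6000, "zero-based-half-open")
  empty <- project_window(list(a, b), far, sizes)
  expect_equal(nrow(empty$segments), 0)
  expect_equal(nrow(empty$excluded), 0)
})

test_that("projection of a simulated dispersal equals the truth ledger exactly", {
  sim <- simulate_dispersal(dispersal_config(n_targets = 7,
                                             fragments_per_target = 4,
                                             gap_rate = 0.3,
                                             reverse_strand_prob = 0.5,
                                             seed = 42))
  res <- project_window(sim$chains, sim$window, sim$sizes)
  seg <- res$segments[order(res$segments$chainId), ]
  tru <- sim$truth$per_chain[order(sim$truth$per_chain$chainId), ]
  expect_equal(seg$chainId, tru$chainId)
  expect_equal(seg$qName, tru$qName)
  expect_equal(seg$alignedBases, tru$alignedBases)
  expect_equal(seg$qForwardStart, tru$qForwardStart)
  expect_equal(seg$qForwardEnd, tru$qForwardEnd)
})

test_that("projection TSVs round-trip through write and read", {
  sim <- simulate_dispersal(dispersal_config(seed = 8))
  res <- project_window(sim$chains, sim$window, sim$sizes)
  f <- withr::local_tempfile()
  write_projection_tsv(res, f)
  back <- read_projection_tsv(f)
  expect_equal(back$alignedBases, res$segments$alignedBases)
  expect_equal(back$qName, res$segments$qName)
  writeLines("windowId\tchainId", f)
  expect_error(read_projection_tsv(f), "missing column",
               class = "chaindisp_parse_error")
})
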