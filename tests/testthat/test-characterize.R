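test_that("priority wins over overlap size in annotation stacking", {
  ts <- mk_tx(list(c(1, 1000)))   # exonic length 1000
  ests <- annotation_track("EST", GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 100)), 1L)         # exactly 10%
  transmap <- annotation_track("TransMap", GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(101, 1000)), 4L)      # 90%
  lab <- annotate_by_priority(ts, list(transmap, ests))
  expect_equal(unname(lab), "EST")                 # ranks reorder the stack
  expect_equal(unname(annotate_by_priority(ts, list(ests))), "EST")
  # 9.9% only -> Unannotated (threshold is >= 10%)
  ests99 <- annotation_track("EST", GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 99)), 1L)
  expect_equal(unname(annotate_by_priority(ts, list(ests99))), "Unannotated")
  expect_equal(unname(annotate_by_priority(ts, list())), "Unannotated")
  expect_error(annotate_by_priority(ts, list(ests), min_frac = 0),
               "min_frac")
})

test_that("stacking labels are a pure function of overlap fractions", {
  set.seed(51)
  for (rep in 1:5) {
    chains <- lapply(1:30, function(i) {
      s <- sample(1:4000, 1)
      GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + sample(50:300, 1)),
                             strand = "+")
    })
    names(chains) <- sprintf("p%02d", 1:30)
    ts <- transcript_set(chains)
    tracks <- list(annotation_track("A", rand_gr(15), 1L),
                   annotation_track("B", rand_gr(15), 2L))
    got <- annotate_by_priority(ts, tracks)
    exlen <- exonic_length(ts)
    want <- vapply(seq_len(30), function(i) {
      fa <- bf_overlap_length(ts$exons[[i]], tracks[[1]]$intervals) / exlen[i]
      fb <- bf_overlap_length(ts$exons[[i]], tracks[[2]]$intervals) / exlen[i]
      if (fa >= 0.10) "A" else if (fb >= 0.10) "B" else "Unannotated"
    }, character(1))
    expect_equal(unname(got), unname(want))
  }
})

test_that("EST support needs a single shared nucleotide", {
  ts <- mk_tx(list(c(100, 300)), list(c(1000, 1200)))
  spl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(300, 400))  # 1 bp
  out <- est_support(ts, spl)
  expect_equal(unname(out$spliced), c(TRUE, FALSE))
  expect_equal(out$spliced_rate, 0.5)
})

test_that("repeat flags are strict at 5% of exonic length", {
  ts <- mk_tx(list(c(1, 1000)))
  at <- function(n) GenomicRanges::GRanges("chr1", IRanges::IRanges(1, n))
  expect_false(repeat_overlap_flags(ts, at(50))$flag[[1]])  # exactly 5%
  expect_true(repeat_overlap_flags(ts, at(51))$flag[[1]])
})

test_that("ribosome association is any exonic footprint overlap", {
  ts <- mk_tx(list(c(100, 300)), list(c(1000, 1200)))
  fp <- GenomicRanges::GRanges("chr1", IRanges::IRanges(150, 180))
  out <- ribosome_association(ts, fp)
  expect_equal(unname(out$flag), c(TRUE, FALSE))
  expect_equal(out$rate, 0.5)
})

test_that("CAGE distances are absolute TSS-to-cluster base differences", {
  # TSS at 101 (0-based 100), cluster covering 0-based [200,210)
  ts <- mk_tx(list(c(101, 1500)))
  cage <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 210))
  expect_equal(unname(cage_min_distances(ts, cage)), 100)
  # TSS inside a cluster -> 0
  expect_equal(unname(cage_min_distances(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(50, 150)))), 0)
  # min over clusters at 50 and 500
  two <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(151, 601), c(160, 610)))
  expect_equal(unname(cage_min_distances(ts, two)), 50)
  # no cluster on the chromosome -> Inf
  expect_equal(unname(cage_min_distances(ts, GenomicRanges::GRanges(
    "chr9", IRanges::IRanges(1, 10)))), Inf)
  # exhaustive-min oracle on random clusters
  set.seed(52)
  cl <- rand_gr(40, max_pos = 100000, max_w = 50)
  d <- cage_min_distances(ts, cl)
  tss <- 101
  want <- min(ifelse(tss >= GenomicRanges::start(cl) & tss <= GenomicRanges::end(cl), 0,
                     pmin(abs(tss - GenomicRanges::start(cl)),
                          abs(tss - GenomicRanges::end(cl)))))
  expect_equal(unname(d), want)
})

test_that("conservation scores average element scores over exonic bases", {
  ts <- mk_tx(list(c(1, 100)))
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50), score = 0.8)
  expect_equal(unname(conservation_score(ts, el)), 0.40)
  expect_equal(unname(conservation_score(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(500, 600), score = 0.9))), 0)
  full <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), score = 1)
  expect_equal(unname(conservation_score(ts, full)), 1.0)
  expect_error(conservation_score(ts, GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 10), score = 1.2)), "\\[0, 1]")

  # invariance to splitting an element into contiguous equal-score pieces
  split2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 26), c(25, 50)),
                                   score = 0.8)
  expect_equal(conservation_score(ts, split2), conservation_score(ts, el))
  expect_equal(conservation_score(ts, split2, stat = "median"),
               conservation_score(ts, el, stat = "median"))
})

test_that("the per-base median matches an explicit base expansion", {
  set.seed(53)
  ts <- mk_tx(list(c(1, 60), c(101, 140)))    # 100 exonic bases
  el <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(11, 121), c(40, 130)),
                               score = c(0.9, 0.4))
  got <- conservation_score(ts, el, stat = "median")
  per_base <- rep(0, 200)
  per_base[11:40] <- 0.9; per_base[121:130] <- 0.4
  exonic <- per_base[c(1:60, 101:140)]
  expect_equal(unname(got), stats::median(exonic))
  # and the mean against the same expansion
  expect_equal(unname(conservation_score(ts, el)), mean(exonic))
})

test_that("chromatin TSS windows are half-open at +window", {
  ts <- mk_tx(list(c(10000, 12000)))          # TSS 10000, '+'
  at <- function(p) list(M = GenomicRanges::GRanges("chr1", IRanges::IRanges(p, p)))
  expect_true(chromatin_mark_rate(ts, at(14999))$flags[1, "M"])
  expect_false(chromatin_mark_rate(ts, at(15000))$flags[1, "M"])
  expect_false(chromatin_mark_rate(ts, at(15001))$flags[1, "M"])
  expect_true(chromatin_mark_rate(ts, at(5000))$flags[1, "M"])
  expect_error(chromatin_mark_rate(ts, at(1), window = 0), "window")

  # monotone non-decreasing in window size
  set.seed(54)
  peaks <- list(M = rand_gr(50, max_pos = 200000, max_w = 400))
  chains <- lapply(1:20, function(i) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(i * 9000, i * 9000 + 1000), strand = "+"))
  names(chains) <- sprintf("w%02d", 1:20)
  tsr <- transcript_set(chains)
  r1 <- chromatin_mark_rate(tsr, peaks, window = 2000)$rates
  r2 <- chromatin_mark_rate(tsr, peaks, window = 5000)$rates
  r3 <- chromatin_mark_rate(tsr, peaks, window = 10000)$rates
  expect_true(r1 <= r2 && r2 <= r3)
})

test_that("the body-fraction criterion flags 50% peak coverage", {
  ts <- mk_tx(list(c(1, 1000)))
  half <- list(M = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500)))
  less <- list(M = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 499)))
  expect_true(chromatin_mark_rate(ts, half, criterion = "body_fraction")$flags[1, 1])
  expect_false(chromatin_mark_rate(ts, less, criterion = "body_fraction")$flags[1, 1])
})

test_that("nearest coding gene breaks ties deterministically", {
  gs <- gene_set(list(
    A = GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000), strand = "+"),
    B = GenomicRanges::GRanges("chr1", IRanges::IRanges(5000, 6000), strand = "+"),
    C = GenomicRanges::GRanges("chr1", IRanges::IRanges(7000, 8000), strand = "+")),
    "coding")
  ts <- mk_tx(list(c(2101, 2200)), list(c(6450, 6550)), list(c(1500, 1600)))
  nn <- nearest_coding_gene(ts, gs)
  # gaps: t1 -> A at 100; t2 tied between B and C at 449 -> B (smaller
  # start); t3 inside A -> distance 0
  expect_equal(nn$gene_id, c("A", "B", "A"))
  expect_equal(nn$distance[1], 100)
  expect_equal(nn$distance[2], 449)
  expect_equal(nn$distance[3], 0)
  # rerun equality for the tied case
  expect_identical(nearest_coding_gene(ts, gs), nn)
})

test_that("expression-matched sampling matches the reference distribution", {
  set.seed(55)
  ref <- rlnorm(400, log(3), 1)
  pool <- rlnorm(600, log(3), 1)
  # pool == reference at n = |reference|: bin masses match
  idx <- expression_matched_sample(ref, ref, length(ref), seed = 9)
  br <- unique(quantile(log10(ref + 1e-3), probs = seq(0, 1, 0.1)))
  mr <- tabulate(findInterval(log10(ref + 1e-3), br, all.inside = TRUE),
                 length(br) - 1) / length(ref)
  ms <- tabulate(findInterval(log10(ref[idx] + 1e-3), br, all.inside = TRUE),
                 length(br) - 1) / length(idx)
  expect_lt(max(abs(mr - ms)), 0.08)
  # determinism under seed
  expect_identical(expression_matched_sample(pool, ref, 100, seed = 7),
                   expression_matched_sample(pool, ref, 100, seed = 7))
  # median log-expression tracks the reference across seeds
  meds <- vapply(1:20, function(s) {
    i <- expression_matched_sample(pool, ref, 300, seed = s)
    median(log10(pool[i] + 1e-3))
  }, numeric(1))
  expect_true(all(abs(meds - median(log10(ref + 1e-3))) < 0.25))
  # empty-bin fallback is reported, not fatal
  tight_pool <- rep(1, 50)
  expect_message(expression_matched_sample(tight_pool, ref, 50, seed = 1),
                 "fell back")
})
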