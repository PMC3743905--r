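test_that("GTF exon coordinates follow the 1-based closed convention", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "T"; transcript_id "T";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\tgene_id "T"; transcript_id "T";'),
    gtf)
  ts <- read_transcripts_gtf(gtf)
  expect_equal(length(ts), 1L)
  expect_equal(unname(GenomicRanges::start(ts$exons[[1]])), c(101, 301))
  expect_equal(unname(GenomicRanges::end(ts$exons[[1]])), c(200, 400))
  expect_equal(unname(exonic_length(ts)), 200)
  sp <- tx_spans(ts)
  expect_equal(GenomicRanges::width(sp), 300)
  expect_equal(unname(tx_tss(ts)), 101)
})

test_that("TSS is strand-aware and unstranded transcripts warn", {
  ts <- mk_tx(list(c(101, 200), c(301, 400)), strand = "-")
  expect_equal(unname(tx_tss(ts)), 400)
  tsu <- mk_tx(list(c(101, 200)), strand = "*")
  expect_warning(v <- tx_tss(tsu), "unstranded")
  expect_equal(unname(v), 101)
})

test_that("GTF round trip preserves a 50-transcript fixture field by field", {
  set.seed(11)
  chains <- lapply(1:50, function(i) {
    n_ex <- sample(1:4, 1)
    s <- cumsum(sample(200:900, n_ex))
    w <- sample(50:200, n_ex, replace = TRUE)
    GenomicRanges::GRanges(sample(c("chr1", "chr2"), 1),
                           IRanges::IRanges(s, s + w - 1),
                           strand = sample(c("+", "-"), 1))
  })
  names(chains) <- sprintf("TX%02d", 1:50)
  expr <- matrix(round(rlnorm(100), 4), 50, 2,
                 dimnames = list(names(chains), c("E14", "ES")))
  ts <- transcript_set(chains, class_code = sample(c("u", "i", "j", "x"), 50,
                                                   replace = TRUE),
                       cpc_score = round(rnorm(50, -3), 4), expr = expr,
                       stages = rep(list(c("E14", "ES")), 50))
  gtf <- tempfile(fileext = ".gtf"); tab <- tempfile(fileext = ".tsv")
  write_transcripts_gtf(ts, gtf, tab)
  back <- read_transcripts_gtf(gtf, tab)
  i <- match(tx_ids(ts), tx_ids(back))
  expect_false(anyNA(i))
  expect_identical(lapply(back$exons[i], GenomicRanges::ranges),
                   lapply(ts$exons, GenomicRanges::ranges))
  expect_equal(back$class_code[i], ts$class_code)
  expect_equal(back$cpc_score[i], ts$cpc_score)
  expect_equal(unname(back$expr[i, ]), unname(ts$expr))
  expect_identical(back$stages[i], ts$stages)
})

test_that("malformed GTF and invalid transcripts raise informative errors", {
  bad <- tempfile(fileext = ".gtf")
  writeLines(c('chr1\tsrc\texon\t101\t200\t.\t+\t.\tgene_id "T"; transcript_id "T";',
               "chr1 only-three fields"), bad)
  expect_error(read_transcripts_gtf(bad), "line 2")
  expect_error(mk_tx(list(c(1, 100), c(50, 150))), "non-overlapping")
  expect_error(transcript_set(list(GenomicRanges::GRanges(
    c("chr1", "chr2"), IRanges::IRanges(1:2, 10:11)))), "unique names")
})

test_that("BED round trips keep coordinates, scores, and strand", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t10\tx\t0.8\t+", bed)
  tr <- read_bed(bed)
  expect_equal(GenomicRanges::start(tr$intervals), 1)
  expect_equal(GenomicRanges::end(tr$intervals), 10)
  expect_equal(tr$intervals$score, 0.8)
  expect_equal(as.character(GenomicRanges::strand(tr$intervals)), "+")

  empty <- tempfile(fileext = ".bed"); file.create(empty)
  expect_equal(length(read_bed(empty)$intervals), 0L)

  set.seed(3)
  gr <- rand_gr(1000, max_pos = 1e6)
  gr$score <- round(runif(1000), 3)
  gr$name <- sprintf("iv%04d", seq_along(gr))
  out <- tempfile(fileext = ".bed")
  write_bed(annotation_track("t", gr), out)
  back <- read_bed(out)$intervals
  expect_equal(length(back), 1000L)
  expect_identical(GenomicRanges::ranges(sort(back)),
                   GenomicRanges::ranges(sort(gr)))
  expect_equal(sort(back)$score, sort(gr)$score)
})

test_that("invalid BED intervals are rejected", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t10\tx", bed)
  expect_error(read_bed(bed), "invalid BED")
})

test_that("overlap_length matches its examples and the per-base oracle", {
  # [0,10) vs [5,15) in 0-based half-open is 1-10 vs 6-15 here
  expect_equal(overlap_length(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)),
                              GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 15))), 5)
  ex <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 21), c(10, 30)))
  expect_equal(overlap_length(ex, GenomicRanges::GRanges("chr1", IRanges::IRanges(9, 22))), 4)
  expect_equal(overlap_length(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10)),
                              GenomicRanges::GRanges("chr1", IRanges::IRanges(50, 60))), 0)
  set.seed(21)
  for (rep in 1:20) {
    a <- rand_gr(sample(1:8, 1), chrom = sample(c("chr1", "chr2"), 1))
    b <- rand_gr(sample(1:8, 1), chrom = sample(c("chr1", "chr2"), 1))
    expect_equal(overlap_length(a, b), bf_overlap_length(a, b))
  }
})

test_that("exonic_overlap_bp agrees with per-transcript brute force", {
  set.seed(22)
  ts <- mk_tx(list(c(1, 100), c(301, 400)), list(c(1000, 1499)),
              list(c(2000, 2050), c(2100, 2200), c(2400, 2500)))
  track <- rand_gr(30, max_pos = 3000)
  got <- exonic_overlap_bp(ts$exons, track)
  want <- vapply(seq_along(ts$exons), function(i)
    bf_overlap_length(ts$exons[[i]], track), numeric(1))
  expect_equal(unname(got), want)
})

test_that("interval_distance uses the gap/adjacency convention", {
  g <- function(s, e, ch = "chr1") GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
  expect_equal(interval_distance(g(1, 10), g(16, 20)), 5)
  expect_equal(interval_distance(g(1, 10), g(11, 20)), 0)   # book-ended
  expect_equal(interval_distance(g(1, 10), g(6, 8)), 0)     # containment
  expect_equal(interval_distance(g(1, 10), g(1, 10, "chr2")), Inf)
  set.seed(23)
  for (rep in 1:40) {
    a <- rand_gr(1, max_pos = 200, max_w = 50)
    b <- rand_gr(1, max_pos = 200, max_w = 50)
    touches <- bf_overlap_length(a, b) > 0 ||
      GenomicRanges::end(a) + 1 == GenomicRanges::start(b) ||
      GenomicRanges::end(b) + 1 == GenomicRanges::start(a)
    expect_equal(interval_distance(a, b) == 0, touches)
  }
})

test_that("gene introns are the gaps of the union-exon model", {
  gs <- gene_set(list(G1 = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 201, 501), c(100, 300, 600)),
    strand = "+")), "coding")
  intr <- gene_introns(gs)[["G1"]]
  expect_equal(unname(GenomicRanges::start(intr)), c(101, 301))
  expect_equal(unname(GenomicRanges::end(intr)), c(200, 500))
  expect_true(all(GenomicRanges::width(intr) >= 1))
})
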