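test_that("merge_redundant collapses identical exon chains and pools support", {
  grl <- list(
    A = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 301), c(100, 400)), strand = "+"),
    B = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 301), c(100, 400)), strand = "+"),
    C = GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1500), strand = "+"))
  expr <- matrix(c(1, 5, 2, 4, 2, 3), 3, 2,
                 dimnames = list(c("A", "B", "C"), c("E14", "E15")))
  ts <- transcript_set(grl, class_code = c("u", "u", "u"),
                       cpc_score = rep(-2, 3), expr = expr,
                       stages = list("E14", "E15", "E14"))
  out <- merge_redundant(ts)
  expect_equal(tx_ids(out), c("A", "C"))
  expect_equal(unname(out$expr["A", ]), c(5, 4))   # max-merged
  expect_equal(out$stages[[1]], c("E14", "E15"))   # unioned

  # no duplicates: identity
  expect_identical(tx_ids(merge_redundant(ts[c(1, 3)])), c("A", "C"))
})

test_that("merge_redundant removes exactly the planted duplicates", {
  set.seed(31)
  base <- lapply(1:80, function(i) {
    s <- i * 5000 + cumsum(sample(200:500, 2))
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + 99), strand = "+")
  })
  names(base) <- sprintf("a%03d", 1:80)
  dup <- base[sample(80, 20)]
  names(dup) <- paste0(names(dup), "_x")
  ts <- transcript_set(c(base, dup))
  out <- merge_redundant(ts)
  expect_equal(length(out), 80L)
  expect_true(all(grepl("^a[0-9]+$", tx_ids(out))))  # representatives stable
})

test_that("length filter is strict at the 200 nt boundary", {
  ts <- mk_tx(list(c(1, 200)), list(c(1001, 1201)), list(c(2001, 2100)))
  out <- filter_min_length(ts)             # exonic lengths 200, 201, 100
  expect_equal(tx_ids(out), "t02")
  set.seed(32)
  lens <- sample(150:260, 10)
  grl <- lapply(seq_along(lens), function(i)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(i * 1000, i * 1000 + lens[i] - 1),
                           strand = "+"))
  names(grl) <- sprintf("m%02d", seq_along(lens))
  tsr <- transcript_set(grl)
  expect_equal(length(filter_min_length(tsr)), sum(lens > 200))
})

test_that("single-exon models need support from two stages", {
  grl <- list(
    s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300), strand = "+"),
    s2 = GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 1300), strand = "+"),
    m1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2000, 2500), c(2100, 2600)), strand = "+"))
  ts <- transcript_set(grl, stages = list("E14", c("E14", "E17"), "E15"))
  expect_equal(tx_ids(filter_single_exon(ts)), c("s2", "m1"))
})

test_that("the noise threshold derives from the mapping rate by nearest rank", {
  thr <- derive_noise_threshold(1:100, 0.84)
  expect_equal(as.numeric(thr), 16)
  expect_equal(attr(thr, "percentile"), 16)
  thr0 <- derive_noise_threshold(c(5, 2, 9), 1.0)
  expect_equal(as.numeric(thr0), 2)                 # minimum, nothing removed
  expect_error(derive_noise_threshold(numeric(0), 0.84), "non-empty")
  expect_error(derive_noise_threshold(1:10, 1.5), "\\(0, 1]")
  # nearest-rank against a sort-and-index oracle on random draws
  set.seed(33)
  for (rep in 1:10) {
    v <- rlnorm(sample(20:200, 1))
    rate <- runif(1, 0.5, 0.99)
    s <- sort(v)
    expect_equal(as.numeric(derive_noise_threshold(v, rate)),
                 s[max(1, ceiling((1 - rate) * length(v)))])
  }
})

test_that("expression filter keeps max-over-stages >= threshold", {
  expr <- matrix(c(0.29, 0.1, 0.3, 0.0, 2, 1), 3, 2, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("E14", "E15")))
  grl <- lapply(1:3, function(i)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(i * 1000, i * 1000 + 300), strand = "+"))
  names(grl) <- c("a", "b", "c")
  ts <- transcript_set(grl, expr = expr)
  expect_equal(tx_ids(filter_expression(ts, 0.3)), c("b", "c"))
  set.seed(34)
  expr2 <- matrix(runif(40, 0, 1), 20, 2, dimnames = list(sprintf("r%02d", 1:20), NULL))
  grl2 <- lapply(1:20, function(i)
    GenomicRanges::GRanges("chr1", IRanges::IRanges(i * 1000, i * 1000 + 300), strand = "+"))
  names(grl2) <- rownames(expr2)
  ts2 <- transcript_set(grl2, expr = expr2)
  expect_equal(length(filter_expression(ts2, 0.3)),
               sum(apply(expr2, 1, max) >= 0.3))
})

test_that("class-code and coding-potential filters honour their cutoffs", {
  ts <- mk_tx(list(c(1, 300)), list(c(1000, 1300)), list(c(2000, 2300)),
              class_code = c("u", "e", "x"))
  expect_equal(tx_ids(filter_class_code(ts)), c("t01", "t03"))
  expect_equal(length(filter_class_code(ts, keep_codes = c("u", "e", "x"))), 3L)

  ts2 <- mk_tx(list(c(1, 300)), list(c(1000, 1300)), list(c(2000, 2300)),
               list(c(3000, 3300)))
  ts2$cpc_score <- c(-1.5, -1.0, 2, NA)
  out <- filter_coding_potential(ts2)
  expect_equal(tx_ids(out), "t01")   # strict < -1; NA fails
})

test_that("coding proximity removes only close intergenic candidates", {
  gs <- gene_set(list(G1 = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10000, 12000), c(10500, 12500)), strand = "+")), "coding")
  # gaps to the gene span [10000,12500]: 999 / 1000 / intronic inside
  grl <- list(
    near = GenomicRanges::GRanges("chr1", IRanges::IRanges(13500, 13800), strand = "+"),
    far = GenomicRanges::GRanges("chr1", IRanges::IRanges(13501, 13800), strand = "+"),
    inside = GenomicRanges::GRanges("chr1", IRanges::IRanges(10600, 10900), strand = "+"))
  ts <- transcript_set(grl)
  res <- filter_coding_proximity(ts, c("intergenic", "intergenic", "intronic"), gs)
  expect_equal(tx_ids(res$ts), c("far", "inside"))
  expect_warning(filter_coding_proximity(ts, rep("intergenic", 3),
                                         gene_set(list(), character(0))),
                 "no coding genes")
})

test_that("the cascade audit telescopes, is idempotent and order-invariant", {
  fx <- cached_fixture()
  casc <- cached_cascade()
  a <- casc$audit
  expect_true(all(a$n_removed >= 0))
  expect_equal(a$n_in[-1], a$n_out[-nrow(a)])
  expect_equal(a$n_removed, a$n_in - a$n_out)

  # idempotence: survivors pass every stage untouched
  again <- run_filter_cascade(casc$lncrna$transcripts, fx$genes)
  expect_equal(sum(again$audit$n_removed), 0L)
  expect_setequal(again$lncrna$info$tx_id, casc$lncrna$info$tx_id)

  # permutation invariance of the surviving id set
  set.seed(35)
  perm <- sample(length(fx$candidates))
  shuffled <- run_filter_cascade(fx$candidates[perm], fx$genes)
  expect_setequal(shuffled$lncrna$info$tx_id, casc$lncrna$info$tx_id)
})

test_that("empty input produces an empty cascade with a zero audit", {
  empty <- transcript_set(GenomicRanges::GRangesList())
  casc <- run_filter_cascade(empty, cached_fixture()$genes)
  expect_equal(length(casc$lncrna), 0L)
  expect_true(all(casc$audit$n_in == 0L))
})

test_that("filter_config enforces its contract", {
  cfg <- filter_config()
  expect_equal(cfg$min_length, 200)
  expect_equal(cfg$expression_threshold, 0.3)
  expect_equal(cfg$cpc_max, -1)
  expect_equal(cfg$min_coding_distance, 1000)
  expect_setequal(cfg$keep_class_codes, c("u", "i", "j", "x"))
  expect_error(filter_config(expression_threshold = 0.3, mapping_rate = 0.84),
               "exactly one")
  expect_error(filter_config(expression_threshold = NULL, mapping_rate = NULL),
               "exactly one")
})

test_that("a mapping-rate-driven cascade derives its threshold from the data", {
  fx <- cached_fixture()
  cfg <- filter_config(expression_threshold = NULL, mapping_rate = 0.84)
  casc <- run_filter_cascade(fx$candidates, fx$genes, cfg)
  expect_equal(casc$expression_threshold,
               as.numeric(derive_noise_threshold(as.numeric(fx$candidates$expr), 0.84)))
})
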