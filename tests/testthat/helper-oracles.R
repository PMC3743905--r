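## Independent brute-force oracles and small builders shared by the suite.
## The oracles work base-by-base (or by exhaustive enumeration) and share no
## code with the interval-index implementations they check.

# quick transcript_set builder: exons as list of c(start, end) pairs
mk_tx <- function(..., chrom = "chr1", strand = "+", class_code = "u",
                  cpc = -2, expr = NULL, stages = list()) {
  chains <- list(...)
  grl <- lapply(chains, function(ch) {
    m <- matrix(unlist(ch), ncol = 2, byrow = TRUE)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(m[, 1], m[, 2]),
                           strand = strand)
  })
  names(grl) <- sprintf("t%02d", seq_along(grl))
  n <- length(grl)
  if (is.null(expr)) expr <- matrix(1, n, 1, dimnames = list(names(grl), "E14"))
  if (length(stages) == 0) stages <- rep(list(c("E14", "E15")), n)
  transcript_set(grl, class_code = rep_len(class_code, n),
                 cpc_score = rep_len(cpc, n), expr = expr, stages = stages)
}

# base set of a GRanges as "chrom:pos" strings
bf_bases <- function(gr) {
  if (length(gr) == 0) return(character(0))
  unique(unlist(lapply(seq_along(gr), function(i)
    paste(as.character(GenomicRanges::seqnames(gr))[i],
          seq(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i])))))
}

bf_overlap_length <- function(a, b) length(intersect(bf_bases(a), bf_bases(b)))

# per-base classifier: rule precedence intergenic > intronic > antisense >
# residual, evaluated on explicit base sets
bf_classify <- function(ts, gs) {
  gsp <- gene_spans(gs)
  gspan_bases <- bf_bases(gsp)
  coding <- gs[gs$biotype == "coding"]
  intr_grl <- gene_introns(coding)
  intr <- unlist(intr_grl, use.names = FALSE)
  intr_bases <- lapply(seq_along(intr), function(i) bf_bases(intr[i]))
  rex <- unlist(gs$exons, use.names = FALSE)
  rex_str <- as.character(GenomicRanges::strand(rex))
  rex_bases_plus <- bf_bases(rex[rex_str == "+"])
  rex_bases_minus <- bf_bases(rex[rex_str == "-"])
  sp <- tx_spans(ts)
  out <- character(length(ts))
  for (i in seq_along(ts)) {
    span_b <- bf_bases(sp[i])
    if (!any(span_b %in% gspan_bases)) { out[i] <- "intergenic"; next }
    inside <- any(vapply(intr_bases, function(b) all(span_b %in% b),
                         logical(1)))
    if (inside) { out[i] <- "intronic"; next }
    str <- as.character(GenomicRanges::strand(sp))[i]
    ex_b <- bf_bases(ts$exons[[i]])
    anti <- (str == "+" && any(ex_b %in% rex_bases_minus)) ||
      (str == "-" && any(ex_b %in% rex_bases_plus))
    out[i] <- if (anti) "cis_antisense" else "alt_spliced"
  }
  out
}

# exhaustive Mann-Whitney two-sided p by enumerating all rank splits
bf_rank_sum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  obs <- u_of(x, y)
  idx <- utils::combn(m + n, m)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  mu <- m * n / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# exhaustive hypergeometric upper tail
bf_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# memoized default fixture + cascade (generation is deterministic)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function() {
  if (is.null(.fixture_cache$fx))
    .fixture_cache$fx <- generate_fixture(seed = 1)
  .fixture_cache$fx
}
cached_cascade <- function() {
  if (is.null(.fixture_cache$casc))
    .fixture_cache$casc <- run_filter_cascade(cached_fixture()$candidates,
                                              cached_fixture()$genes)
  .fixture_cache$casc
}
fixture_exclusions <- function() {
  fx <- cached_fixture()
  c(unname(fx$tracks$repeats$intervals), unname(gene_spans(fx$genes)))
}

# random annotation GRanges on a small coordinate space
rand_gr <- function(n, max_pos = 5000, max_w = 300, chrom = "chr1") {
  s <- sample.int(max_pos, n, replace = TRUE)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + sample.int(max_w, n, replace = TRUE) - 1L))
}
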