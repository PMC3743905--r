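## Exclusion-aware shuffling of candidate loci and empirical-p machinery.
## Placement is exact: the set of valid start positions for each span length
## is enumerated from the complement of the exclusion set (or from introns),
## and a start is drawn uniformly from it, so every draw preserves the span
## length and overlaps zero excluded bases by construction.

# place each length n_perm times, uniformly over valid starts within runs;
# returns data.frame(perm, idx, chrom, start, end)
.place_spans <- function(lengths, run_chrom, run_start, run_end, n_perm,
                         labels = NULL) {
  run_w <- run_end - run_start + 1
  n <- length(lengths)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  out_chrom <- character(n * n_perm)
  out_start <- integer(n * n_perm)
  for (i in seq_len(n)) {
    L <- lengths[i]
    counts <- pmax(0, run_w - L + 1)
    tot <- sum(counts)
    if (tot < 1)
      stop("no valid placement for span '", labels[i],
           "' of length ", L)
    cum <- cumsum(counts)
    r <- floor(stats::runif(n_perm) * tot)        # in [0, tot - 1]
    r[r >= tot] <- tot - 1                         # guard fp edge
    ri <- findInterval(r, cum) + 1L                # which run
    off <- r - c(0, cum)[ri]
    pos <- (i - 1L) * n_perm + seq_len(n_perm)
    out_chrom[pos] <- run_chrom[ri]
    out_start[pos] <- as.integer(run_start[ri] + off)
  }
  data.frame(perm = rep(seq_len(n_perm), n),
             idx = rep(seq_len(n), each = n_perm),
             chrom = out_chrom, start = out_start,
             end = out_start + rep(as.integer(lengths), each = n_perm) - 1L,
             stringsAsFactors = FALSE)
}

.spans_of <- function(x) {
  if (inherits(x, "lncrna_set")) x <- x$transcripts
  if (inherits(x, "transcript_set")) tx_spans(x) else as_track_granges(x)
}

.runs_from_exclusions <- function(chrom_sizes, exclusions) {
  excl_tbl <- if (is.null(exclusions) || length(as_track_granges(exclusions)) == 0L)
    list() else .chrom_table(exclusions)
  runs <- .allowed_runs(chrom_sizes, excl_tbl)
  list(chrom = rep(names(runs), vapply(runs, function(r) length(r$start), integer(1))),
       start = unlist(lapply(runs, `[[`, "start"), use.names = FALSE),
       end = unlist(lapply(runs, `[[`, "end"), use.names = FALSE))
}

#' Shuffle loci over the genome, avoiding exclusion regions
#'
#' Places each input span at a position drawn uniformly from all genomic
#' start positions at which a span of the same length fits entirely inside
#' a chromosome and overlaps zero excluded bases (the bedtools-shuffle-style
#' null used for intergenic candidates, with repeat-masked and annotated
#' gene regions excluded).
#'
#' @param x spans to shuffle: \code{GRanges}, \code{transcript_set} or
#'   \code{lncrna_set} (whole spans are shuffled; exon structure is not
#'   preserved).
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param exclusions \code{GRanges}/\code{annotation_track} of regions that
#'   permuted loci must not touch (may be \code{NULL}).
#' @param n_perm number of independent permutations (default 1).
#' @param seed optional integer seed.
#' @return \code{GRanges} of permuted loci with a \code{perm} metadata
#'   column (replicate index) and \code{idx} (input span index).
#' @export
shuffle_intergenic <- function(x, chrom_sizes, exclusions = NULL,
                               n_perm = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- .spans_of(x)
  runs <- .runs_from_exclusions(chrom_sizes, exclusions)
  pl <- .place_spans(GenomicRanges::width(sp), runs$chrom, runs$start,
                     runs$end, n_perm, labels = names(sp))
  GenomicRanges::GRanges(pl$chrom, IRanges::IRanges(pl$start, pl$end),
                         perm = pl$perm, idx = pl$idx)
}

#' Shuffle loci into introns
#'
#' Places each span uniformly over all start positions inside the supplied
#' introns at which it fits entirely; an intron is therefore chosen with
#' probability proportional to (intron length - span length + 1), the null
#' used for intronic candidates.
#'
#' @param x spans to shuffle (as in \code{\link{shuffle_intergenic}}).
#' @param introns \code{GRanges} or \code{GRangesList} of introns (e.g.
#'   \code{\link{gene_introns}} output).
#' @param n_perm number of permutations (default 1).
#' @param seed optional integer seed.
#' @return \code{GRanges} with \code{perm} and \code{idx} metadata columns.
#' @export
shuffle_intronic <- function(x, introns, n_perm = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- .spans_of(x)
  if (inherits(introns, "GRangesList") || (is.list(introns) && !inherits(introns, "GRanges")))
    introns <- unlist(GenomicRanges::GRangesList(introns), use.names = FALSE)
  if (length(introns) == 0L) stop("no introns supplied")
  pl <- .place_spans(GenomicRanges::width(sp),
                     as.character(GenomicRanges::seqnames(introns)),
                     GenomicRanges::start(introns),
                     GenomicRanges::end(introns),
                     n_perm, labels = names(sp))
  GenomicRanges::GRanges(pl$chrom, IRanges::IRanges(pl$start, pl$end),
                         perm = pl$perm, idx = pl$idx)
}

#' Empirical p-value from a permutation null
#'
#' The plain exceedance fraction \code{#\{permuted >= observed\} / n_perm}
#' (or \code{<=} for depletion). A value of 0 means "smaller than
#' 1/n_perm"; \code{format_empirical_p} renders it that way.
#'
#' @param observed observed statistic.
#' @param permuted vector of permuted statistics.
#' @param direction \code{"ge"} (enrichment, default) or \code{"le"}.
#' @return empirical p in [0, 1].
#' @export
empirical_p <- function(observed, permuted, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  if (length(permuted) == 0L) stop("permuted must be non-empty")
  if (direction == "ge") mean(permuted >= observed)
  else mean(permuted <= observed)
}

#' @rdname empirical_p
#' @param p an empirical p-value.
#' @param n_perm the number of permutations behind it.
#' @export
format_empirical_p <- function(p, n_perm) {
  if (p == 0) sprintf("< %g", 1 / n_perm) else sprintf("%g", p)
}

new_perm_result <- function(statistic, observed, permuted, seed, shuffler,
                            direction = "ge") {
  structure(list(statistic = statistic,
                 observed = observed,
                 permuted = permuted,
                 empirical_p = empirical_p(observed, permuted, direction),
                 n_perm = length(permuted),
                 seed = seed,
                 shuffler = shuffler,
                 direction = direction),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat("Permutation test: ", x$statistic, "\n",
      "  observed:  ", format(x$observed, digits = 4), "\n",
      "  null mean: ", format(mean(x$permuted), digits = 4),
      "  (n_perm = ", x$n_perm, ", shuffler = ", x$shuffler, ")\n",
      "  empirical p ", if (x$direction == "ge") "(enrichment)" else "(depletion)",
      ": ", format_empirical_p(x$empirical_p, x$n_perm), "\n", sep = "")
  invisible(x)
}

#' @export
plot.perm_result <- function(x, ...) {
  graphics::hist(x$permuted, breaks = 30, col = "grey80", border = "white",
                 main = x$statistic, xlab = "permuted statistic",
                 xlim = range(c(x$permuted, x$observed)), ...)
  graphics::abline(v = x$observed, col = "red3", lwd = 2)
  invisible(x)
}

# fraction of spans lying within max_dist of any target interval, computed
# on plain vectors (hot path shared by observed and permuted statistics)
.near_fraction <- function(chrom, start, end, target_tbl) {
  mean(.overlaps_any(chrom, start, end, target_tbl))
}

.perm_fraction_test <- function(statistic, sp, target_tbl, pad, shuffle_fun,
                                n_perm, seed, shuffler) {
  if (!is.null(seed)) set.seed(seed)
  obs <- .near_fraction(as.character(GenomicRanges::seqnames(sp)),
                        GenomicRanges::start(sp), GenomicRanges::end(sp),
                        target_tbl)
  perm <- shuffle_fun(n_perm)
  hit <- .overlaps_any(perm$chrom, perm$start, perm$end, target_tbl)
  permuted <- as.numeric(rowsum(as.numeric(hit), perm$perm)) /
    (length(sp))
  new_perm_result(statistic, obs, permuted, seed, shuffler)
}

#' Imprinted-cluster proximity test
#'
#' Tests whether candidate lncRNAs lie within \code{max_dist} (default
#' 100 kb) of known imprinted loci more often than expected under random
#' placement. The statistic is the fraction of candidate spans within
#' \code{max_dist} of any (position-deduplicated) imprinted locus; the null
#' re-places the candidates \code{n_perm} times with the exclusion-aware
#' genomic shuffler (or the intron shuffler when \code{introns} is given),
#' and enrichment is scored by the plain empirical exceedance fraction.
#'
#' @param x candidates: \code{GRanges}, \code{transcript_set} or
#'   \code{lncrna_set}.
#' @param imprinted \code{GRanges}/\code{annotation_track} of imprinted loci.
#' @param chrom_sizes named numeric vector of chromosome lengths.
#' @param exclusions regions the shuffler must avoid (repeats, gene spans).
#' @param max_dist proximity window in bp, default 100000.
#' @param n_perm number of permutations, default 10000.
#' @param seed optional integer seed (stored in the result).
#' @param introns optional \code{GRanges}/\code{GRangesList}; when supplied
#'   the intron shuffler builds the null instead.
#' @return a \code{perm_result}.
#' @export
imprinted_proximity_test <- function(x, imprinted, chrom_sizes,
                                     exclusions = NULL, max_dist = 100000,
                                     n_perm = 10000, seed = NULL,
                                     introns = NULL) {
  imp <- unique(as_track_granges(imprinted))   # identical-span dedup
  if (length(imp) == 0L) stop("imprinted locus list is empty")
  sp <- .spans_of(x)
  tbl <- .chrom_table(imp, pad = as.integer(max_dist))
  if (is.null(introns)) {
    runs <- .runs_from_exclusions(chrom_sizes, exclusions)
    shuffle_fun <- function(np) .place_spans(GenomicRanges::width(sp),
                                             runs$chrom, runs$start,
                                             runs$end, np, names(sp))
    shuffler <- "intergenic"
  } else {
    if (inherits(introns, "GRangesList"))
      introns <- unlist(introns, use.names = FALSE)
    shuffle_fun <- function(np) .place_spans(GenomicRanges::width(sp),
                                             as.character(GenomicRanges::seqnames(introns)),
                                             GenomicRanges::start(introns),
                                             GenomicRanges::end(introns),
                                             np, names(sp))
    shuffler <- "intronic"
  }
  .perm_fraction_test("imprinted_proximity_fraction", sp, tbl, max_dist,
                      shuffle_fun, n_perm, seed, shuffler)
}

#' Unspliced-EST overlap test
#'
#' Tests whether candidate spans overlap unspliced ESTs (>= 1 bp) more
#' often than random placements do; same null machinery as
#' \code{\link{imprinted_proximity_test}}.
#'
#' @inheritParams imprinted_proximity_test
#' @param ests \code{GRanges}/\code{annotation_track} of unspliced ESTs.
#' @return a \code{perm_result}.
#' @export
unspliced_est_overlap_test <- function(x, ests, chrom_sizes,
                                       exclusions = NULL, n_perm = 10000,
                                       seed = NULL) {
  est <- as_track_granges(ests)
  sp <- .spans_of(x)
  if (length(est) == 0L) {
    res <- new_perm_result("unspliced_est_overlap_fraction", 0,
                           rep(0, n_perm), seed, "intergenic")
    res$empirical_p <- 1
    return(res)
  }
  tbl <- .chrom_table(est)
  runs <- .runs_from_exclusions(chrom_sizes, exclusions)
  shuffle_fun <- function(np) .place_spans(GenomicRanges::width(sp),
                                           runs$chrom, runs$start, runs$end,
                                           np, names(sp))
  res <- .perm_fraction_test("unspliced_est_overlap_fraction", sp, tbl, 0,
                             shuffle_fun, n_perm, seed, "intergenic")
  if (res$observed == 1 && all(res$permuted == 1))
    message("statistic saturated at 1 in observed and null; ",
            "interpret two-sidedly with caution")
  res
}

#' Rank-sum comparison of two samples
#'
#' Mann-Whitney U comparison used for e.g. observed vs permuted CAGE-TSS
#' distance distributions: exact enumeration when the smaller sample has at
#' most 8 values and there are no ties, the tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with the U statistic (number of (x, y) pairs with x > y)
#'   and the two-sided p-value.
#' @export
rank_sum_compare <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  exact <- min(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' CAGE-distance comparison against one permuted replicate
#'
#' Computes the shortest TSS-to-CAGE-cluster distances of the observed
#' candidates and of a single permuted replicate set (placed by the
#' exclusion-aware shuffler; the permuted "TSS" is the span start, since
#' shuffled loci are unstranded), and compares the two distance
#' distributions with \code{\link{rank_sum_compare}}.
#'
#' @inheritParams imprinted_proximity_test
#' @param cage \code{GRanges}/\code{annotation_track} of CAGE clusters.
#' @return list with \code{observed} and \code{permuted} distance vectors
#'   and the \code{U}/\code{p} of the comparison.
#' @export
cage_distance_test <- function(x, cage, chrom_sizes, exclusions = NULL,
                               seed = NULL) {
  ts <- if (inherits(x, "lncrna_set")) x$transcripts else x
  obs <- cage_min_distances(ts, cage)
  perm <- shuffle_intergenic(ts, chrom_sizes, exclusions, n_perm = 1,
                             seed = seed)
  tss <- GenomicRanges::resize(perm, 1L, fix = "start")
  pd <- min_distance_to_set(tss, as_track_granges(cage))
  ok <- is.finite(obs) & is.finite(pd)
  cmp <- rank_sum_compare(obs[is.finite(obs)], pd[is.finite(pd)])
  list(observed = obs, permuted = pd, U = cmp$U, p = cmp$p)
}

#' Null-calibration experiment for the proximity test
#'
#' Builds a fixed synthetic world with no planted signal — three 10 Mb
#' chromosomes, random exclusion blocks (~6% of the genome) and a regular
#' grid of imprinted-like clusters whose 100 kb proximity zones cover about
#' half of the placeable genome — then repeatedly (i) draws an "observed"
#' candidate set with the same exclusion-aware shuffler the null uses and
#' (ii) runs \code{\link{imprinted_proximity_test}} on it. Because observed
#' and permuted sets are exchangeable by construction, the empirical
#' p-values must be uniform; the large candidate count keeps ties in the
#' discrete overlap-count statistic rare enough not to distort the
#' uniformity checks.
#'
#' @param n_rep number of replicate tests.
#' @param n_perm permutations per test.
#' @param n_spans candidate spans per replicate.
#' @param seed integer seed for the whole experiment.
#' @return numeric vector of \code{n_rep} empirical p-values.
#' @export
null_calibration_pvalues <- function(n_rep = 200, n_perm = 500,
                                     n_spans = 1000, seed = 1) {
  set.seed(seed)
  chrom_sizes <- setNames(rep(10e6, 3), paste0("chr", 1:3))
  excl <- GenomicRanges::GRanges(
    rep(names(chrom_sizes), each = 30),
    IRanges::IRanges(
      start = unlist(lapply(1:3, function(i)
        sort(sample.int(10e6 - 20000, 30)))),
      width = sample(5000:20000, 90, replace = TRUE)))
  imp_pos <- seq(300000, 9.7e6, by = 420000)
  imp <- GenomicRanges::GRanges(
    rep(names(chrom_sizes), each = length(imp_pos)),
    IRanges::IRanges(rep(imp_pos, 3), width = 5000))
  lens <- sample(1000:3000, n_spans, replace = TRUE)
  carrier <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, lens))
  vapply(seq_len(n_rep), function(r) {
    obs <- shuffle_intergenic(carrier, chrom_sizes, excl, n_perm = 1)
    imprinted_proximity_test(obs, imp, chrom_sizes, excl,
                             n_perm = n_perm)$empirical_p
  }, numeric(1))
}
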