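#' Total overlap between two interval sets
#'
#' Number of bases in the intersection of the base set of \code{a} with the
#' union of \code{b}. Strand is ignored; the result is symmetric in base-set
#' terms.
#'
#' @param a \code{GRanges} (e.g. the exon chain of one transcript) or
#'   \code{annotation_track}.
#' @param b \code{GRanges} or \code{annotation_track}.
#' @return integer, total overlapping bases.
#' @export
overlap_length <- function(a, b) {
  a <- GenomicRanges::reduce(as_track_granges(a), ignore.strand = TRUE)
  b <- GenomicRanges::reduce(as_track_granges(b), ignore.strand = TRUE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE))
  if (length(hits) == 0L) return(0L)
  qs <- GenomicRanges::start(a)[S4Vectors::queryHits(hits)]
  qe <- GenomicRanges::end(a)[S4Vectors::queryHits(hits)]
  ss <- GenomicRanges::start(b)[S4Vectors::subjectHits(hits)]
  se <- GenomicRanges::end(b)[S4Vectors::subjectHits(hits)]
  sum(pmin(qe, se) - pmax(qs, ss) + 1L)
}

#' Per-transcript exonic overlap with a track
#'
#' Vectorized overlap: for each element of \code{exons}, the number of exonic
#' bases intersecting the union of the track intervals.
#'
#' @param exons \code{GRangesList} of exon chains (e.g. \code{ts$exons}).
#' @param track \code{GRanges} or \code{annotation_track}.
#' @return named numeric vector of overlapping bases per transcript.
#' @export
exonic_overlap_bp <- function(exons, track) {
  track <- GenomicRanges::reduce(as_track_granges(track), ignore.strand = TRUE)
  out <- setNames(numeric(length(exons)), names(exons))
  if (length(exons) == 0L || length(track) == 0L) return(out)
  u <- unlist(exons, use.names = FALSE)
  grp <- rep(seq_along(exons), lengths(exons))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(u, track, ignore.strand = TRUE))
  if (length(hits) == 0L) return(out)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  w <- pmin(GenomicRanges::end(u)[qh], GenomicRanges::end(track)[sh]) -
    pmax(GenomicRanges::start(u)[qh], GenomicRanges::start(track)[sh]) + 1L
  agg <- tapply(w, grp[qh], sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Gap distance between intervals
#'
#' Distance between spans: 0 for overlapping, contained, or book-ended
#' (adjacent) intervals, the inter-span gap otherwise, and \code{Inf} across
#' chromosomes. Symmetric; strand is ignored.
#'
#' @param a,b parallel \code{GRanges} (recycled to common length).
#' @return numeric vector of distances in bp.
#' @export
interval_distance <- function(a, b) {
  d <- suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
  d <- as.numeric(d)
  d[is.na(d)] <- Inf
  d
}

#' Minimum distance from each query to an interval set
#'
#' @param query \code{GRanges}.
#' @param subject \code{GRanges} or \code{annotation_track}.
#' @return numeric vector: per query, the minimal gap distance to any subject
#'   interval (0 if overlapping/adjacent), \code{Inf} when no subject interval
#'   shares the chromosome.
#' @export
min_distance_to_set <- function(query, subject) {
  subject <- as_track_granges(subject)
  out <- rep(Inf, length(query))
  if (length(query) == 0L || length(subject) == 0L) return(out)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(query, subject, ignore.strand = TRUE))
  out[S4Vectors::queryHits(hits)] <- as.numeric(S4Vectors::mcols(hits)$distance)
  out
}

## ---- plain-vector interval machinery ----------------------------------
## The permutation null loops place and query hundreds of thousands of
## spans; these helpers work on per-chromosome sorted merged integer
## vectors to keep that cheap. Coordinates are 1-based closed throughout.

# merged per-chromosome interval table: list(chrom -> list(start, end))
.chrom_table <- function(gr, pad = 0L) {
  gr <- GenomicRanges::reduce(
    GenomicRanges::resize(as_track_granges(gr),
                          GenomicRanges::width(as_track_granges(gr)) + 2L * pad,
                          fix = "center"),
    ignore.strand = TRUE)
  sp <- split(gr, as.character(GenomicRanges::seqnames(gr)), drop = TRUE)
  lapply(sp, function(g) {
    o <- order(GenomicRanges::start(g))
    list(start = GenomicRanges::start(g)[o], end = GenomicRanges::end(g)[o])
  })
}

# does [start, end] on chrom overlap any merged interval in tbl?
.overlaps_any <- function(chrom, start, end, tbl) {
  out <- logical(length(chrom))
  for (ch in unique(chrom)) {
    t <- tbl[[ch]]
    sel <- chrom == ch
    if (is.null(t)) next
    idx <- findInterval(end[sel], t$start)   # last interval starting <= end
    hit <- idx >= 1L & t$end[pmax(idx, 1L)] >= start[sel]
    out[sel] <- hit
  }
  out
}

# allowed runs (complement of exclusions) per chromosome
.allowed_runs <- function(chrom_sizes, excl_tbl) {
  out <- list()
  for (ch in names(chrom_sizes)) {
    size <- chrom_sizes[[ch]]
    t <- excl_tbl[[ch]]
    if (is.null(t) || length(t$start) == 0L) {
      out[[ch]] <- list(start = 1L, end = as.integer(size))
      next
    }
    s <- pmax(t$start, 1L); e <- pmin(t$end, as.integer(size))
    keep <- s <= e
    s <- s[keep]; e <- e[keep]
    gs <- c(1L, e + 1L)
    ge <- c(s - 1L, as.integer(size))
    keep <- gs <= ge
    out[[ch]] <- list(start = gs[keep], end = ge[keep])
  }
  out
}
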