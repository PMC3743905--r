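#' Annotation stacking by priority
#'
#' Assigns each transcript the label of the highest-priority annotation
#' track whose intervals cover at least \code{min_frac} of its exonic
#' length; transcripts missing the threshold everywhere are labelled
#' \code{"Unannotated"}. The canonical stack is ESTs > mRNAs > NONCODE >
#' TransMap.
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param tracks list of \code{annotation_track}s; order of decreasing
#'   priority unless \code{priority} ranks are set on the tracks.
#' @param min_frac minimum overlap fraction of exonic length, in (0, 1];
#'   default 0.10.
#' @param denominator overlap fraction is measured over the transcript's
#'   exonic length (default) or, alternatively, over the annotation length.
#' @return named character vector of labels.
#' @export
annotate_by_priority <- function(ts, tracks, min_frac = 0.10,
                                 denominator = c("transcript", "annotation")) {
  denominator <- match.arg(denominator)
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("min_frac must lie in (0, 1]")
  ts <- as_transcript_set(ts)
  pr <- vapply(tracks, function(t) t$priority, integer(1))
  if (!anyNA(pr)) tracks <- tracks[order(pr)]
  lab <- setNames(rep("Unannotated", length(ts)), tx_ids(ts))
  exlen <- exonic_length(ts)
  undecided <- rep(TRUE, length(ts))
  for (tr in tracks) {
    if (!any(undecided)) break
    sub <- ts$exons[undecided]
    if (denominator == "transcript") {
      hit <- exonic_overlap_bp(sub, tr$intervals) / exlen[undecided] >= min_frac
    } else {
      # fraction measured over the annotation interval instead: a transcript
      # hits when it covers >= min_frac of some single annotation interval
      hit <- rep(FALSE, length(sub))
      iv <- as_track_granges(tr$intervals)
      u <- unlist(sub, use.names = FALSE)
      grp <- rep(seq_along(sub), lengths(sub))
      h <- GenomicRanges::findOverlaps(u, iv, ignore.strand = TRUE)
      if (length(h)) {
        qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
        w <- pmin(GenomicRanges::end(u)[qh], GenomicRanges::end(iv)[sh]) -
          pmax(GenomicRanges::start(u)[qh], GenomicRanges::start(iv)[sh]) + 1L
        key <- paste(grp[qh], sh)
        agg <- tapply(w, key, sum)
        ks <- strsplit(names(agg), " ", fixed = TRUE)
        txi <- as.integer(vapply(ks, `[`, character(1), 1L))
        ivi <- as.integer(vapply(ks, `[`, character(1), 2L))
        ok <- as.numeric(agg) / GenomicRanges::width(iv)[ivi] >= min_frac
        hit[unique(txi[ok])] <- TRUE
      }
    }
    lab[which(undecided)[hit]] <- tr$name
    undecided[which(undecided)[hit]] <- FALSE
  }
  lab
}

#' EST support flags
#'
#' A transcript is EST-supported when at least one nucleotide of its exons
#' overlaps the track (the classic "at least one nucleotide overlap"
#' criterion).
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param spliced_ests,unspliced_ests \code{GRanges} or
#'   \code{annotation_track}.
#' @return list with logical vectors \code{spliced}, \code{unspliced} and
#'   the two support rates.
#' @export
est_support <- function(ts, spliced_ests, unspliced_ests = NULL) {
  ts <- as_transcript_set(ts)
  spl <- exonic_overlap_bp(ts$exons, spliced_ests) >= 1
  out <- list(spliced = spl, spliced_rate = mean(spl))
  if (!is.null(unspliced_ests)) {
    uns <- exonic_overlap_bp(ts$exons, unspliced_ests) >= 1
    out$unspliced <- uns
    out$unspliced_rate <- mean(uns)
  }
  out
}

#' Repeat-element overlap flags
#'
#' Flags transcripts whose exonic overlap with repeat elements is strictly
#' greater than \code{min_frac} of their exonic length (default > 5\%).
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param repeats \code{GRanges} or \code{annotation_track}.
#' @param min_frac default 0.05 (strict).
#' @return list with logical \code{flag} and the flagged \code{rate}.
#' @export
repeat_overlap_flags <- function(ts, repeats, min_frac = 0.05) {
  ts <- as_transcript_set(ts)
  frac <- exonic_overlap_bp(ts$exons, repeats) / exonic_length(ts)
  flag <- frac > min_frac
  list(flag = flag, rate = mean(flag))
}

#' Ribosome-footprint association
#'
#' Flags transcripts with >= 1 bp exonic overlap with ribosome-protected
#' fragments, a proxy for engagement with the translation machinery.
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param footprints \code{GRanges} or \code{annotation_track}.
#' @return list with logical \code{flag} and the associated \code{rate}.
#' @export
ribosome_association <- function(ts, footprints) {
  ts <- as_transcript_set(ts)
  flag <- exonic_overlap_bp(ts$exons, footprints) >= 1
  list(flag = flag, rate = mean(flag))
}

#' Shortest CAGE-cluster distance per TSS
#'
#' For each transcript, the absolute base-coordinate difference between its
#' putative TSS and the nearest CAGE tag cluster base (0 when the TSS lies
#' inside a cluster, \code{Inf} when no cluster shares the chromosome).
#' Matching is strand-agnostic by default, appropriate for unstranded
#' single-end assemblies.
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param cage \code{GRanges} or \code{annotation_track} of CAGE clusters.
#' @param stranded if \code{TRUE}, only clusters on the transcript strand
#'   are considered.
#' @return named numeric vector of distances in bp.
#' @export
cage_min_distances <- function(ts, cage, stranded = FALSE) {
  ts <- as_transcript_set(ts)
  cage <- as_track_granges(cage)
  sp <- tx_spans(ts)
  tss <- suppressWarnings(tx_tss(ts))
  tss_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(sp),
                                   IRanges::IRanges(tss, width = 1L),
                                   strand = GenomicRanges::strand(sp))
  point_dist <- function(q, subj) {
    ## |TSS - nearest covered base|: interval gap + 1 unless overlapping
    d <- min_distance_to_set(q, subj)
    inside <- suppressWarnings(
      GenomicRanges::countOverlaps(q, subj, ignore.strand = TRUE)) > 0L
    ifelse(inside, 0, d + 1)
  }
  if (!stranded)
    return(setNames(point_dist(tss_gr, cage), tx_ids(ts)))
  out <- rep(Inf, length(ts))
  for (s in c("+", "-", "*")) {
    sel <- as.character(GenomicRanges::strand(tss_gr)) == s
    sub <- if (s == "*") cage else cage[as.character(GenomicRanges::strand(cage)) %in% c(s, "*")]
    if (any(sel)) out[sel] <- point_dist(tss_gr[sel], sub)
  }
  setNames(out, tx_ids(ts))
}

weighted_median <- function(values, weights) {
  o <- order(values)
  v <- values[o]; w <- weights[o]
  cw <- cumsum(w) / sum(w)
  lo <- v[which(cw >= 0.5)[1L]]
  hi <- v[which(cw > 0.5)[1L]]
  if (is.na(hi)) hi <- lo
  (lo + hi) / 2
}

#' Conservation score over concatenated exons
#'
#' Scores the concatenated exonic region of each transcript against scored
#' conservation elements (e.g. PhastCons elements with probabilities in
#' [0, 1]): each exonic base takes the score of the element covering it and
#' 0 where uncovered. \code{stat = "mean"} returns the average per-base
#' score; \code{stat = "median"} the per-base median. Elements are assumed
#' non-overlapping (as in the UCSC conservation-element tracks).
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param elements \code{GRanges} with a numeric \code{score} metadata
#'   column in [0, 1], or an \code{annotation_track}.
#' @param stat \code{"mean"} (default) or \code{"median"}.
#' @return named numeric vector of scores in [0, 1].
#' @export
conservation_score <- function(ts, elements, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  ts <- as_transcript_set(ts)
  el <- as_track_granges(elements)
  sc <- S4Vectors::mcols(el)$score
  if (is.null(sc)) stop("conservation elements need a 'score' column")
  if (length(sc) && (min(sc) < 0 || max(sc) > 1))
    stop("element scores must lie in [0, 1]")
  exlen <- exonic_length(ts)
  out <- setNames(numeric(length(ts)), tx_ids(ts))
  if (length(ts) == 0L || length(el) == 0L)
    return(out)
  u <- unlist(ts$exons, use.names = FALSE)
  grp <- rep(seq_along(ts$exons), lengths(ts$exons))
  h <- GenomicRanges::findOverlaps(u, el, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  w <- pmin(GenomicRanges::end(u)[qh], GenomicRanges::end(el)[sh]) -
    pmax(GenomicRanges::start(u)[qh], GenomicRanges::start(el)[sh]) + 1L
  tx <- grp[qh]
  if (stat == "mean") {
    agg <- tapply(w * sc[sh], tx, sum)
    out[as.integer(names(agg))] <- as.numeric(agg) / exlen[as.integer(names(agg))]
  } else {
    for (i in unique(tx)) {
      sel <- tx == i
      cov_bp <- sum(w[sel])
      vals <- c(sc[sh[sel]], 0)
      wts <- c(w[sel], exlen[i] - cov_bp)
      if (wts[length(wts)] == 0) { vals <- vals[-length(vals)]; wts <- wts[-length(wts)] }
      out[i] <- weighted_median(vals, wts)
    }
  }
  out
}

#' Chromatin-mark association rates
#'
#' For each mark, flags transcripts with any peak in the TSS-proximal
#' window (default: 5 kb upstream and 5 kb downstream of the TSS, i.e. the
#' half-open window [TSS - w, TSS + w)). The alternative criterion flags
#' transcripts whose exonic length is covered by peak bases to at least
#' \code{body_min_frac} (default 50\%).
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param peaks named list of \code{GRanges}/\code{annotation_track}, one
#'   per mark.
#' @param window bp on each side of the TSS (default 5000; must be > 0).
#' @param criterion \code{"tss_window"} (default) or \code{"body_fraction"}.
#' @param body_min_frac default 0.5.
#' @return list with a logical flag matrix (transcripts x marks) and the
#'   per-mark rates.
#' @export
chromatin_mark_rate <- function(ts, peaks, window = 5000,
                                criterion = c("tss_window", "body_fraction"),
                                body_min_frac = 0.5) {
  criterion <- match.arg(criterion)
  if (window <= 0) stop("window must be positive")
  ts <- as_transcript_set(ts)
  if (is.null(names(peaks))) stop("peaks must be a named list (one per mark)")
  flags <- matrix(FALSE, nrow = length(ts), ncol = length(peaks),
                  dimnames = list(tx_ids(ts), names(peaks)))
  if (criterion == "tss_window") {
    sp <- tx_spans(ts)
    tss <- suppressWarnings(tx_tss(ts))
    win <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(sp),
      IRanges::IRanges(pmax(1L, tss - as.integer(window)),
                       tss + as.integer(window) - 1L))
    for (m in names(peaks))
      flags[, m] <- GenomicRanges::countOverlaps(
        win, as_track_granges(peaks[[m]]), ignore.strand = TRUE) > 0L
  } else {
    exlen <- exonic_length(ts)
    for (m in names(peaks))
      flags[, m] <- exonic_overlap_bp(ts$exons, peaks[[m]]) / exlen >=
        body_min_frac
  }
  list(flags = flags, rates = colMeans(flags))
}

#' Nearest coding gene per transcript
#'
#' Minimal span-to-span distance; ties are broken by the smaller gene start
#' coordinate, then lexicographic gene id, so the winner is deterministic.
#'
#' @param ts a \code{transcript_set} (or \code{lncrna_set}).
#' @param genes a \code{gene_set} (only coding genes are considered).
#' @return data.frame with \code{tx_id}, \code{gene_id}, \code{distance}
#'   (bp; \code{Inf} and \code{NA} gene when no coding gene shares the
#'   chromosome).
#' @export
nearest_coding_gene <- function(ts, genes) {
  ts <- as_transcript_set(ts)
  coding <- genes[genes$biotype == "coding"]
  if (length(coding) == 0L) stop("no coding genes supplied")
  gsp <- gene_spans(coding)
  sp <- tx_spans(ts)
  out <- data.frame(tx_id = tx_ids(ts), gene_id = NA_character_,
                    distance = Inf, stringsAsFactors = FALSE)
  if (length(ts) == 0L) return(out)
  h <- GenomicRanges::distanceToNearest(sp, gsp, ignore.strand = TRUE)
  if (length(h) == 0L) return(out)
  qh0 <- S4Vectors::queryHits(h)
  d <- as.numeric(S4Vectors::mcols(h)$distance)
  ## distanceToNearest picks one arbitrary winner; re-collect every gene at
  ## the minimal distance so ties break on (start, id) deterministically
  widen <- GenomicRanges::resize(sp[qh0],
                                 GenomicRanges::width(sp[qh0]) + 2 * (d + 1),
                                 fix = "center")
  cand <- GenomicRanges::findOverlaps(widen, gsp, ignore.strand = TRUE)
  qh <- qh0[S4Vectors::queryHits(cand)]
  sh <- S4Vectors::subjectHits(cand)
  dd <- suppressWarnings(GenomicRanges::distance(sp[qh], gsp[sh],
                                                 ignore.strand = TRUE))
  keep <- !is.na(dd) & dd == d[match(qh, qh0)]
  qh <- qh[keep]; sh <- sh[keep]
  ord <- order(qh, GenomicRanges::start(gsp)[sh], names(gsp)[sh])
  first <- ord[!duplicated(qh[ord])]
  out$gene_id[qh[first]] <- names(gsp)[sh[first]]
  out$distance[qh[first]] <- d[match(qh[first], qh0)]
  out
}

#' Expression-matched sampling with replacement
#'
#' Draws a sample from \code{pool} whose log-expression distribution
#' matches a reference set: the reference log10(RPKM + eps) values are cut
#' into \code{n_bins} quantile bins, and pool members are sampled with
#' replacement bin-by-bin in proportion to the reference bin masses. An
#' empty pool bin falls back to the nearest non-empty bin (reported via a
#' message).
#'
#' @param pool numeric RPKM values of the candidates to sample from.
#' @param reference numeric RPKM values defining the target distribution.
#' @param n sample size.
#' @param n_bins number of quantile bins, default 10.
#' @param seed optional integer seed for reproducibility.
#' @param eps pseudo-count added before the log transform (default 1e-3
#'   RPKM, admits zeros).
#' @return integer vector of indices into \code{pool} (length \code{n}).
#' @export
expression_matched_sample <- function(pool, reference, n, n_bins = 10,
                                      seed = NULL, eps = 1e-3) {
  stopifnot(length(pool) >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  lp <- log10(pool + eps)
  lr <- log10(reference + eps)
  br <- unique(stats::quantile(lr, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) br <- c(br, br + 1e-9)
  ref_bin <- findInterval(lr, br, all.inside = TRUE)
  pool_bin <- findInterval(lp, br, all.inside = TRUE)
  nb <- length(br) - 1L
  mass <- tabulate(ref_bin, nbins = nb) / length(ref_bin)
  pick_bin <- sample.int(nb, n, replace = TRUE, prob = mass)
  by_bin <- split(seq_along(pool), factor(pool_bin, levels = seq_len(nb)))
  nonempty <- which(lengths(by_bin) > 0L)
  idx <- integer(n)
  fallback <- FALSE
  for (b in unique(pick_bin)) {
    sel <- pick_bin == b
    src <- b
    if (lengths(by_bin)[b] == 0L) {
      src <- nonempty[which.min(abs(nonempty - b))]
      fallback <- TRUE
    }
    cand <- by_bin[[src]]
    idx[sel] <- cand[sample.int(length(cand), sum(sel), replace = TRUE)]
  }
  if (fallback)
    message("empty pool bin(s): fell back to nearest non-empty bin")
  idx
}

as_transcript_set <- function(x) {
  if (inherits(x, "lncrna_set")) x$transcripts
  else if (inherits(x, "transcript_set")) x
  else stop("expected a transcript_set or lncrna_set")
}
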