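#' Knockdown microarray experiment container
#'
#' Bundles probe coordinates, the control expression matrix, the knockdown
#' (KD) profile matrix and the target roster of an RNAi screen. The screen
#' this emulates profiled 40 protein and 226 lncRNA targets with two
#' replicates each against 55 non-experiment control profiles.
#'
#' @param probes named \code{GRanges} of probe coordinates (names are probe
#'   ids).
#' @param controls numeric matrix, probes x control profiles (rownames are
#'   probe ids).
#' @param kd numeric matrix, probes x KD profiles; column names are
#'   \code{"<target>|<replicate>"}.
#' @param targets data.frame with columns \code{target} and \code{type}
#'   (\code{"protein"} or \code{"lncRNA"}).
#' @return an object of class \code{kd_experiment}.
#' @export
kd_experiment <- function(probes, controls, kd, targets) {
  stopifnot(inherits(probes, "GRanges"), !is.null(names(probes)),
            identical(rownames(controls), names(probes)),
            identical(rownames(kd), names(probes)),
            all(c("target", "type") %in% names(targets)))
  if (!all(is.finite(controls)) || !all(is.finite(kd)))
    stop("expression matrices must be finite")
  ct <- sub("\\|.*$", "", colnames(kd))
  if (!setequal(unique(ct), targets$target))
    stop("kd profile columns do not match the target roster")
  structure(list(probes = probes, controls = controls, kd = kd,
                 targets = targets),
            class = "kd_experiment")
}

#' @export
print.kd_experiment <- function(x, ...) {
  cat("<kd_experiment> ", length(x$probes), " probes, ",
      ncol(x$controls), " controls, ", nrow(x$targets), " targets (",
      sum(x$targets$type == "protein"), " protein / ",
      sum(x$targets$type == "lncRNA"), " lncRNA)\n", sep = "")
  invisible(x)
}

#' Map microarray probes onto lncRNA exons
#'
#' A probe represents a lncRNA when the probe bases covered by the
#' transcript's exon chain exceed \code{min_frac} of the probe length
#' (strictly; the classic "> 99\% overlap" rule). A probe passing the
#' threshold for several lncRNAs maps to all of them and is flagged
#' ambiguous.
#'
#' @param probes named \code{GRanges} of probe coordinates.
#' @param ts a \code{transcript_set} or \code{lncrna_set}.
#' @param min_frac default 0.99 (strict).
#' @return data.frame with columns \code{probe}, \code{tx_id},
#'   \code{ambiguous}.
#' @export
map_probes_to_lncrnas <- function(probes, ts, min_frac = 0.99) {
  ts <- as_transcript_set(ts)
  empty <- data.frame(probe = character(0), tx_id = character(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  if (length(probes) == 0L || length(ts) == 0L) return(empty)
  u <- unlist(ts$exons, use.names = FALSE)
  grp <- rep(seq_along(ts$exons), lengths(ts$exons))
  h <- GenomicRanges::findOverlaps(probes, u, ignore.strand = TRUE)
  if (length(h) == 0L) return(empty)
  qh <- S4Vectors::queryHits(h); sh <- S4Vectors::subjectHits(h)
  w <- pmin(GenomicRanges::end(probes)[qh], GenomicRanges::end(u)[sh]) -
    pmax(GenomicRanges::start(probes)[qh], GenomicRanges::start(u)[sh]) + 1L
  key <- paste(qh, grp[sh])
  agg <- tapply(w, key, sum)
  ks <- strsplit(names(agg), " ", fixed = TRUE)
  pi <- as.integer(vapply(ks, `[`, character(1), 1L))
  ti <- as.integer(vapply(ks, `[`, character(1), 2L))
  ok <- as.numeric(agg) > min_frac * GenomicRanges::width(probes)[pi]
  map <- data.frame(probe = names(probes)[pi[ok]],
                    tx_id = tx_ids(ts)[ti[ok]],
                    stringsAsFactors = FALSE)
  map <- map[order(map$probe, map$tx_id), , drop = FALSE]
  map$ambiguous <- map$probe %in% map$probe[duplicated(map$probe)]
  rownames(map) <- NULL
  map
}

#' Per-probe control percentile thresholds
#'
#' Nearest-rank 5th and 95th percentiles of each probe's values across the
#' control profiles; values above the high threshold call up-regulation,
#' below the low threshold down-regulation. Probes whose two thresholds
#' coincide (constant controls) are uncallable and reported.
#'
#' @param controls numeric matrix, probes x control profiles (>= 2 columns).
#' @param lo,hi percentiles, defaults 5 and 95.
#' @return data.frame with \code{probe}, \code{lo_value}, \code{hi_value},
#'   \code{callable}.
#' @export
control_percentile_thresholds <- function(controls, lo = 5, hi = 95) {
  stopifnot(ncol(controls) >= 2L, lo <= hi)
  lo_v <- apply(controls, 1, nearest_rank, percentile = lo)
  hi_v <- apply(controls, 1, nearest_rank, percentile = hi)
  callable <- lo_v < hi_v
  if (any(!callable))
    message(sum(!callable), " constant probe(s) excluded from calling")
  data.frame(probe = rownames(controls), lo_value = lo_v, hi_value = hi_v,
             callable = callable, stringsAsFactors = FALSE,
             row.names = NULL)
}

# per-probe up/down status for one target's replicate matrix
.probe_status <- function(reps, thr, rule) {
  if (rule == "both") {
    up <- rowSums(reps > thr$hi_value) == ncol(reps)
    dn <- rowSums(reps < thr$lo_value) == ncol(reps)
  } else {
    m <- rowMeans(reps)
    up <- m > thr$hi_value
    dn <- m < thr$lo_value
  }
  up <- up & thr$callable
  dn <- dn & thr$callable
  list(up = up, down = dn)
}

# collapse per-probe status to per-lncRNA calls through the probe map
.lnc_calls <- function(status, probe_ids, map) {
  up_l <- unique(map$tx_id[map$probe %in% probe_ids[status$up]])
  dn_l <- unique(map$tx_id[map$probe %in% probe_ids[status$down]])
  conflict <- intersect(up_l, dn_l)
  list(up = setdiff(up_l, conflict), down = setdiff(dn_l, conflict),
       n_conflict = length(conflict))
}

#' Call up-/down-regulated lncRNAs per knockdown target
#'
#' A probe calls up-regulation when its KD value exceeds the probe's 95th
#' control percentile and down-regulation when below the 5th percentile;
#' under the default \code{"both"} replicate rule every replicate must
#' agree (under \code{"mean"} the replicate mean is compared). A lncRNA is
#' called through any of its mapped probes; lncRNAs with conflicting
#' up/down probes are called neither and counted.
#'
#' @param kd KD profile matrix (probes x profiles, columns
#'   \code{"<target>|<rep>"}) or a \code{kd_experiment}.
#' @param thresholds output of \code{\link{control_percentile_thresholds}}.
#' @param probe_map output of \code{\link{map_probes_to_lncrnas}}.
#' @param replicate_rule \code{"both"} (default) or \code{"mean"}.
#' @return an object of class \code{regulation_calls}: per-target lists of
#'   up- and down-regulated lncRNA ids.
#' @export
call_regulation <- function(kd, thresholds, probe_map,
                            replicate_rule = c("both", "mean")) {
  replicate_rule <- match.arg(replicate_rule)
  if (inherits(kd, "kd_experiment")) kd <- kd$kd
  stopifnot(identical(rownames(kd), thresholds$probe))
  tgt <- sub("\\|.*$", "", colnames(kd))
  calls <- list()
  n_conflict <- 0L
  for (t in unique(tgt)) {
    reps <- kd[, tgt == t, drop = FALSE]
    if (ncol(reps) == 0L) stop("missing replicate profiles for ", t)
    st <- .probe_status(reps, thresholds, replicate_rule)
    cl <- .lnc_calls(st, thresholds$probe, probe_map)
    n_conflict <- n_conflict + cl$n_conflict
    calls[[t]] <- cl[c("up", "down")]
  }
  if (n_conflict > 0L)
    message(n_conflict, " lncRNA call(s) dropped due to up/down conflicts")
  structure(list(calls = calls, replicate_rule = replicate_rule),
            class = "regulation_calls")
}

#' @export
print.regulation_calls <- function(x, ...) {
  aff <- vapply(x$calls, function(cl) length(cl$up) + length(cl$down),
                integer(1))
  cat("<regulation_calls> ", length(x$calls), " targets, mean affected ",
      format(mean(aff), digits = 3), " (rule: ", x$replicate_rule, ")\n",
      sep = "")
  invisible(x)
}

#' Per-target affected counts
#' @param calls a \code{regulation_calls} object.
#' @return data.frame with \code{target}, \code{n_up}, \code{n_down},
#'   \code{affected}.
#' @export
affected_counts <- function(calls) {
  data.frame(target = names(calls$calls),
             n_up = vapply(calls$calls, function(cl) length(cl$up), integer(1)),
             n_down = vapply(calls$calls, function(cl) length(cl$down), integer(1)),
             affected = vapply(calls$calls, function(cl)
               length(cl$up) + length(cl$down), integer(1)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regulator summary with probe-label permutation null
#'
#' Ranks knockdown targets by the number of lncRNAs they affect, summarizes
#' protein vs lncRNA target groups (lncRNA knockdowns act as negative
#' controls), and builds a per-target null by permuting the probe-to-lncRNA
#' label assignment \code{n_perm} times and re-counting.
#'
#' @param kd KD matrix or \code{kd_experiment}.
#' @param thresholds per-probe thresholds.
#' @param probe_map probe-to-lncRNA map.
#' @param targets data.frame with \code{target} and \code{type}.
#' @param replicate_rule passed to \code{\link{call_regulation}}.
#' @param n_perm number of label permutations, default 1000.
#' @param seed optional integer seed.
#' @return an object of class \code{kd_summary}: ranked per-target table
#'   (with empirical p against the label-permutation null), group means,
#'   and the null band (2.5/50/97.5 percentiles of permuted counts).
#' @export
regulator_summary <- function(kd, thresholds, probe_map, targets,
                              replicate_rule = c("both", "mean"),
                              n_perm = 1000, seed = NULL) {
  replicate_rule <- match.arg(replicate_rule)
  if (!is.null(seed)) set.seed(seed)
  if (inherits(kd, "kd_experiment")) {
    if (missing(targets) || is.null(targets)) targets <- kd$targets
    kd <- kd$kd
  }
  obs_calls <- call_regulation(kd, thresholds, probe_map, replicate_rule)
  tab <- affected_counts(obs_calls)
  tab$type <- targets$type[match(tab$target, targets$target)]

  tgt <- sub("\\|.*$", "", colnames(kd))
  status <- lapply(unique(tgt), function(t)
    .probe_status(kd[, tgt == t, drop = FALSE], thresholds, replicate_rule))
  names(status) <- unique(tgt)

  nmap <- nrow(probe_map)
  perm_counts <- matrix(0L, nrow = nrow(tab), ncol = n_perm,
                        dimnames = list(tab$target, NULL))
  for (p in seq_len(n_perm)) {
    pm <- probe_map
    pm$tx_id <- pm$tx_id[sample.int(nmap)]
    for (t in tab$target) {
      cl <- suppressMessages(.lnc_calls(status[[t]], thresholds$probe, pm))
      perm_counts[t, p] <- length(cl$up) + length(cl$down)
    }
  }
  tab$p_perm <- vapply(seq_len(nrow(tab)), function(i)
    empirical_p(tab$affected[i], perm_counts[i, ], "ge"), numeric(1))
  tab <- tab[order(-tab$affected, tab$target), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 group_means = tapply(tab$affected, tab$type, mean),
                 null_band = stats::quantile(perm_counts,
                                             c(0.025, 0.5, 0.975)),
                 calls = obs_calls,
                 n_perm = n_perm, seed = seed),
            class = "kd_summary")
}

#' @export
print.kd_summary <- function(x, ...) {
  cat("Knockdown screen summary (", nrow(x$table), " targets)\n", sep = "")
  cat("  group mean affected: ",
      paste(sprintf("%s = %.1f", names(x$group_means), x$group_means),
            collapse = ", "), "\n", sep = "")
  cat("  top regulators:\n")
  print(utils::head(x$table, 5), row.names = FALSE)
  invisible(x)
}
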