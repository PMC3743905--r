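#' Filter cascade configuration
#'
#' Holds the cutoffs of the candidate-selection cascade. Defaults are the
#' standard stringent settings: minimum exonic length 200 nt (strictly
#' greater required), single-exon models kept only with assembly support
#' from at least two developmental stages, expression noise cutoff of
#' RPKM 0.3 (transcripts below it in every stage are removed), assembler
#' class codes u/i/j/x retained, coding-potential score strictly below -1,
#' and intergenic candidates closer than 1000 bp to a coding gene removed.
#'
#' Exactly one of \code{expression_threshold} and \code{mapping_rate} drives
#' the expression filter: when \code{mapping_rate} is given, the RPKM cutoff
#' is derived from the pooled expression values at the noise percentile
#' \code{100 * (1 - mapping_rate)} (see \code{\link{derive_noise_threshold}}).
#'
#' @param min_length minimum exonic length in bp (kept if strictly greater).
#' @param min_stage_support_single_exon minimum number of supporting stages
#'   for single-exon models.
#' @param expression_threshold RPKM cutoff (kept if max over stages >= it),
#'   or \code{NULL} to derive it from \code{mapping_rate}.
#' @param mapping_rate average read mapping rate in (0, 1], or \code{NULL}.
#' @param keep_class_codes class codes to retain.
#' @param cpc_max coding-potential cutoff (kept if strictly below).
#' @param min_coding_distance minimum distance of intergenic candidates to
#'   the nearest coding gene in bp (kept if >= it).
#' @return an object of class \code{filter_config}.
#' @export
filter_config <- function(min_length = 200,
                          min_stage_support_single_exon = 2,
                          expression_threshold = 0.3,
                          mapping_rate = NULL,
                          keep_class_codes = c("u", "i", "j", "x"),
                          cpc_max = -1,
                          min_coding_distance = 1000) {
  if (is.null(expression_threshold) == is.null(mapping_rate))
    stop("exactly one of expression_threshold and mapping_rate must be set")
  if (!is.null(mapping_rate) && (mapping_rate <= 0 || mapping_rate > 1))
    stop("mapping_rate must lie in (0, 1]")
  stopifnot(is.finite(min_length), min_length >= 1,
            is.finite(cpc_max), is.finite(min_coding_distance))
  structure(list(min_length = min_length,
                 min_stage_support_single_exon = min_stage_support_single_exon,
                 expression_threshold = expression_threshold,
                 mapping_rate = mapping_rate,
                 keep_class_codes = keep_class_codes,
                 cpc_max = cpc_max,
                 min_coding_distance = min_coding_distance),
            class = "filter_config")
}

# nearest-rank percentile: value at rank ceiling(p/100 * n) of the sorted
# sample (rank 0 maps to the minimum); the epsilon keeps a nominally
# integer rank from being pushed up by floating-point error
nearest_rank <- function(values, percentile) {
  s <- sort(values)
  r <- max(1L, ceiling(percentile / 100 * length(s) - 1e-9))
  s[r]
}

#' Derive the expression noise threshold from the mapping rate
#'
#' The fraction of reads that fail to map bounds the fraction of expression
#' signal treated as noise: with an average mapping rate m, the bottom
#' \code{100 * (1 - m)} percent of the pooled expression values are
#' considered noise, and the nearest-rank percentile of the pooled values at
#' that level is returned as the RPKM cutoff. With m = 0.84 the cutoff is
#' the 16th percentile.
#'
#' @param expression_values non-empty vector of non-negative RPKM values
#'   (all transcripts, all stages pooled).
#' @param mapping_rate fraction in (0, 1].
#' @return the RPKM threshold, with the percentile used stored in the
#'   \code{"percentile"} attribute.
#' @export
derive_noise_threshold <- function(expression_values, mapping_rate) {
  if (length(expression_values) == 0L)
    stop("expression_values must be non-empty")
  if (mapping_rate <= 0 || mapping_rate > 1)
    stop("mapping_rate must lie in (0, 1]")
  pct <- 100 * (1 - mapping_rate)
  structure(nearest_rank(expression_values, pct), percentile = pct)
}

#' Merge redundant transcript models
#'
#' Transcripts with identical exon chains (chromosome, strand and exact exon
#' coordinates) are collapsed to a single representative: the
#' lexicographically smallest id, with per-stage expression max-merged and
#' stage support unioned.
#'
#' @param ts a \code{transcript_set}.
#' @return a deduplicated \code{transcript_set} (input order of first
#'   occurrences preserved).
#' @export
merge_redundant <- function(ts) {
  if (length(ts) == 0L) return(ts)
  sp <- tx_spans(ts)
  chrom <- as.character(GenomicRanges::seqnames(sp))
  str <- as.character(GenomicRanges::strand(sp))
  st <- GenomicRanges::start(ts$exons)
  en <- GenomicRanges::end(ts$exons)
  key <- vapply(seq_along(ts$exons), function(i)
    paste(chrom[i], str[i],
          paste(st[[i]], en[[i]], sep = "-", collapse = ","), sep = "|"),
    character(1))
  grp <- split(seq_along(key), key)
  if (all(lengths(grp) == 1L)) return(ts)
  reps <- integer(0)
  for (g in grp) {
    if (length(g) > 1L) {
      keep <- g[order(tx_ids(ts)[g])][1L]
      ts$expr[keep, ] <- apply(ts$expr[g, , drop = FALSE], 2, max)
      ts$stages[[keep]] <- sort(unique(unlist(ts$stages[g])))
    } else keep <- g
    reps <- c(reps, keep)
  }
  ts[sort(reps)]
}

#' Length filter
#'
#' Keeps transcripts whose total exonic length is strictly greater than
#' \code{min_length} (the classic "> 200 nt" small-RNA exclusion).
#'
#' @param ts a \code{transcript_set}.
#' @param min_length bp, default 200.
#' @export
filter_min_length <- function(ts, min_length = 200) {
  stopifnot(min_length >= 1)
  ts[exonic_length(ts) > min_length]
}

#' Single-exon support filter
#'
#' Multi-exon transcripts always pass; single-exon models pass only when
#' assembled in at least \code{min_stage_support} developmental stages.
#'
#' @param ts a \code{transcript_set}.
#' @param min_stage_support default 2.
#' @export
filter_single_exon <- function(ts, min_stage_support = 2) {
  ts[lengths(ts$exons) > 1L | lengths(ts$stages) >= min_stage_support]
}

#' Expression filter
#'
#' Keeps transcripts whose maximum RPKM over stages is at least the
#' threshold; transcripts strictly below it in every stage are treated as
#' transcriptional noise.
#'
#' @param ts a \code{transcript_set}.
#' @param threshold RPKM cutoff, default 0.3.
#' @export
filter_expression <- function(ts, threshold = 0.3) {
  stopifnot(threshold >= 0)
  if (ncol(ts$expr) == 0L) return(ts)
  mx <- apply(ts$expr, 1, max)
  ts[mx >= threshold]
}

#' Class-code filter
#'
#' Retains transcripts whose assembler class code is in \code{keep_codes}
#' (u = novel intergenic, i = intronic, j = alternatively spliced isoform,
#' x = exonic antisense); other codes mark likely assembly artifacts or
#' run-on fragments. Missing codes are reported and removed.
#'
#' @param ts a \code{transcript_set}.
#' @param keep_codes default \code{c("u","i","j","x")}.
#' @export
filter_class_code <- function(ts, keep_codes = c("u", "i", "j", "x")) {
  if (anyNA(ts$class_code))
    message(sum(is.na(ts$class_code)),
            " transcript(s) without a class code removed")
  keep <- !is.na(ts$class_code) & ts$class_code %in% keep_codes
  ts[keep]
}

#' Coding-potential filter
#'
#' Keeps transcripts whose coding-potential score is strictly below
#' \code{cpc_max}; a missing score is treated as failing (conservative).
#'
#' @param ts a \code{transcript_set}.
#' @param cpc_max default -1.
#' @export
filter_coding_potential <- function(ts, cpc_max = -1) {
  ts[!is.na(ts$cpc_score) & ts$cpc_score < cpc_max]
}

#' Coding-proximity filter for intergenic candidates
#'
#' Removes intergenic candidates whose span lies closer than
#' \code{min_coding_distance} to the nearest coding-gene span (guards
#' against unannotated UTR extensions and promoter-proximal divergent
#' transcripts). Non-intergenic transcripts pass unchanged.
#'
#' @param ts a \code{transcript_set}.
#' @param category factor/character of categories parallel to \code{ts}
#'   (from \code{\link{classify_all}}).
#' @param coding_genes a \code{gene_set} (only its coding genes are used).
#' @param min_coding_distance bp, default 1000.
#' @return list with the filtered \code{transcript_set} and the surviving
#'   categories.
#' @export
filter_coding_proximity <- function(ts, category, coding_genes,
                                    min_coding_distance = 1000) {
  coding <- coding_genes[coding_genes$biotype == "coding"]
  if (length(coding) == 0L) {
    warning("no coding genes supplied; all intergenic candidates kept")
    return(list(ts = ts, category = category))
  }
  keep <- rep(TRUE, length(ts))
  ig <- which(category == "intergenic")
  if (length(ig)) {
    d <- min_distance_to_set(tx_spans(ts)[ig], gene_spans(coding))
    keep[ig] <- d >= min_coding_distance
  }
  list(ts = ts[keep], category = category[keep])
}

new_audit <- function(stage, n_in, n_out) {
  structure(data.frame(stage = stage, n_in = n_in, n_out = n_out,
                       n_removed = n_in - n_out, stringsAsFactors = FALSE),
            class = c("filter_audit", "data.frame"))
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("Filter cascade audit:\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Run the full candidate-selection cascade
#'
#' Applies, in order: redundancy merge, length filter, single-exon support,
#' expression noise threshold, class-code filter, coding-potential filter,
#' genomic classification, and the coding-proximity filter on intergenic
#' candidates. Every removed transcript is attributed to exactly one stage.
#'
#' @param ts a \code{transcript_set} of assembled candidates.
#' @param genes a \code{gene_set} of reference gene models (coding and
#'   noncoding).
#' @param config a \code{\link{filter_config}}.
#' @return list with elements \code{lncrna} (an \code{\link{lncrna_set}} of
#'   surviving candidates with categories), \code{audit} (per-stage
#'   \code{filter_audit}), and \code{expression_threshold} (the RPKM cutoff
#'   actually applied).
#' @export
run_filter_cascade <- function(ts, genes, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  stages <- character(0); n_in <- integer(0); n_out <- integer(0)
  step <- function(name, before, after) {
    stages <<- c(stages, name)
    n_in <<- c(n_in, length(before))
    n_out <<- c(n_out, length(after))
    after
  }
  thr <- config$expression_threshold
  if (is.null(thr))
    thr <- derive_noise_threshold(as.numeric(ts$expr), config$mapping_rate)

  s1 <- step("merge", ts, merge_redundant(ts))
  s2 <- step("min_length", s1, filter_min_length(s1, config$min_length))
  s3 <- step("single_exon", s2,
             filter_single_exon(s2, config$min_stage_support_single_exon))
  s4 <- step("expression", s3, filter_expression(s3, thr))
  s5 <- step("class_code", s4,
             filter_class_code(s4, config$keep_class_codes))
  s6 <- step("coding_potential", s5,
             filter_coding_potential(s5, config$cpc_max))
  cls <- classify_all(s6, genes)
  s7 <- step("classify", s6, s6)
  px <- filter_coding_proximity(s6, cls$info$category, genes,
                                config$min_coding_distance)
  s8 <- step("coding_proximity", s7, px$ts)

  out <- lncrna_set(px$ts, cls$info[match(tx_ids(px$ts), cls$info$tx_id), ,
                                    drop = FALSE])
  list(lncrna = out, audit = new_audit(stages, n_in, n_out),
       expression_threshold = as.numeric(thr))
}
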