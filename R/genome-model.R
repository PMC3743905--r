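#' lncforge: post-assembly identification and characterization of lncRNAs
#'
#' Core containers are thin S3 wrappers around Bioconductor ranges:
#' transcripts are a named \code{GRangesList} of exons plus a per-transcript
#' metadata table, reference genes are exon lists with a biotype, and
#' annotation tracks are named \code{GRanges} with an optional priority rank.
#' All internal coordinates follow the GenomicRanges convention (1-based,
#' closed); BED and GTF conventions are converted on I/O by rtracklayer.
#'
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end
#'   width reduce findOverlaps distance distanceToNearest resize
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols `mcols<-`
#' @importFrom stats median quantile rnorm runif rlnorm setNames wilcox.test
#'   phyper p.adjust rbinom
#' @importFrom utils read.delim write.table head
#' @keywords internal
"_PACKAGE"

#' Build a transcript set
#'
#' A transcript set bundles assembled transcript models: an exon chain per
#' transcript together with the assembler class code, a coding-potential
#' (CPC-style) score, per-stage expression (RPKM) and the set of
#' developmental stages in which the model was assembled.
#'
#' @param exons named \code{GRangesList} (or list of \code{GRanges}), one
#'   element per transcript; exons must be on a single chromosome and strand,
#'   sorted and non-overlapping.
#' @param class_code character vector of assembler class codes
#'   (\code{"u"}, \code{"i"}, \code{"j"}, \code{"x"}, or other codes).
#' @param cpc_score numeric coding-potential scores; negative values indicate
#'   non-coding. \code{NA} allowed (treated as failing the coding-potential
#'   filter).
#' @param expr numeric matrix of RPKM values, rows = transcripts, columns =
#'   stages (column names are stage names).
#' @param stages list of character vectors: per-transcript assembly support
#'   (which stages the model was assembled in).
#' @return An object of class \code{transcript_set}.
#' @export
transcript_set <- function(exons, class_code = NULL, cpc_score = NULL,
                           expr = NULL, stages = NULL) {
  if (is.list(exons) && !inherits(exons, "GRangesList"))
    exons <- GenomicRanges::GRangesList(exons)
  n <- length(exons)
  ids <- names(exons)
  if (n > 0L && (is.null(ids) || anyDuplicated(ids)))
    stop("transcript exon list must have unique names (transcript ids)")
  if (is.null(class_code)) class_code <- rep(NA_character_, n)
  if (is.null(cpc_score)) cpc_score <- rep(NA_real_, n)
  if (is.null(expr)) expr <- matrix(numeric(0), nrow = n, ncol = 0,
                                    dimnames = list(ids, NULL))
  if (is.null(rownames(expr))) rownames(expr) <- ids
  if (is.null(stages)) stages <- rep(list(character(0)), n)
  stopifnot(length(class_code) == n, length(cpc_score) == n,
            nrow(expr) == n, length(stages) == n)
  obj <- structure(list(exons = exons,
                        class_code = as.character(class_code),
                        cpc_score = as.numeric(cpc_score),
                        expr = expr,
                        stages = stages),
                   class = "transcript_set")
  validate_transcript_set(obj)
  obj
}

validate_transcript_set <- function(ts) {
  ex <- ts$exons
  if (length(ex) == 0L) return(invisible(ts))
  nchrom <- lengths(unique(GenomicRanges::seqnames(ex)))
  nstr <- lengths(unique(GenomicRanges::strand(ex)))
  if (any(nchrom != 1L) || any(nstr != 1L))
    stop("each transcript must lie on a single chromosome and strand: ",
         paste(names(ex)[nchrom != 1L | nstr != 1L], collapse = ", "))
  st <- GenomicRanges::start(ex)
  en <- GenomicRanges::end(ex)
  bad <- vapply(seq_along(ex), function(i) {
    s <- st[[i]]; e <- en[[i]]
    is.unsorted(s) || (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
  }, logical(1))
  if (any(bad))
    stop("exons must be sorted and non-overlapping within a transcript: ",
         paste(names(ex)[bad], collapse = ", "))
  invisible(ts)
}

#' @export
length.transcript_set <- function(x) length(x$exons)

#' Transcript identifiers
#' @param ts a \code{transcript_set}
#' @return character vector of transcript ids.
#' @export
tx_ids <- function(ts) {
  ids <- names(ts$exons)
  if (is.null(ids)) character(0) else ids
}

#' Subset a transcript set
#' @param x a \code{transcript_set}
#' @param i index vector (integer, logical, or transcript ids)
#' @param ... ignored
#' @export
`[.transcript_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, tx_ids(x))
  structure(list(exons = x$exons[i],
                 class_code = x$class_code[i],
                 cpc_score = x$cpc_score[i],
                 expr = x$expr[i, , drop = FALSE],
                 stages = x$stages[i]),
            class = "transcript_set")
}

#' Total exonic length of each transcript
#' @param ts a \code{transcript_set}
#' @return named integer vector of summed exon widths (bp).
#' @export
exonic_length <- function(ts) {
  setNames(vapply(GenomicRanges::width(ts$exons), sum, numeric(1)),
           tx_ids(ts))
}

#' Genomic spans of transcripts
#'
#' The span runs from the first exon start to the last exon end.
#'
#' @param ts a \code{transcript_set}
#' @return \code{GRanges}, one range per transcript, named by id.
#' @export
tx_spans <- function(ts) {
  if (length(ts) == 0L)
    return(GenomicRanges::GRanges())
  sp <- unlist(range(ts$exons), use.names = TRUE)
  sp
}

#' Transcription start sites
#'
#' TSS is the 5' end of the span: the span start on '+' and the span end on
#' '-'. For unstranded transcripts the span start is used and a warning is
#' issued (single-end libraries carry no strand information).
#'
#' @param ts a \code{transcript_set}
#' @return named integer vector of TSS positions (1-based).
#' @export
tx_tss <- function(ts) {
  sp <- tx_spans(ts)
  str <- as.character(GenomicRanges::strand(sp))
  if (any(str == "*"))
    warning("unstranded transcript(s): TSS defaults to span start")
  pos <- ifelse(str == "-", GenomicRanges::end(sp), GenomicRanges::start(sp))
  setNames(as.integer(pos), names(sp))
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> ", length(x), " transcripts\n", sep = "")
  if (length(x)) {
    cc <- table(x$class_code, useNA = "ifany")
    cat("  class codes: ",
        paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n", sep = "")
    cat("  stages: ", paste(colnames(x$expr), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Build a reference gene set
#'
#' @param exons named \code{GRangesList} of exons per gene. Exons of multiple
#'   isoforms may overlap; the union-exon model is used for introns.
#' @param biotype character vector, \code{"coding"} or \code{"noncoding"},
#'   one per gene (coding emulates NM_ accessions, noncoding NR_).
#' @return An object of class \code{gene_set}.
#' @export
gene_set <- function(exons, biotype) {
  if (is.list(exons) && !inherits(exons, "GRangesList"))
    exons <- GenomicRanges::GRangesList(exons)
  ids <- names(exons)
  if (length(exons) && (is.null(ids) || anyDuplicated(ids)))
    stop("gene exon list must have unique names (gene ids)")
  if (length(exons)) {
    biotype <- match.arg(biotype, c("coding", "noncoding"), several.ok = TRUE)
    biotype <- rep_len(biotype, length(exons))
  } else biotype <- character(0)
  structure(list(exons = GenomicRanges::reduce(exons),
                 biotype = biotype),
            class = "gene_set")
}

#' @export
length.gene_set <- function(x) length(x$exons)

#' Gene identifiers
#' @param gs a \code{gene_set}
#' @export
gene_ids <- function(gs) names(gs$exons)

#' Gene locus spans
#' @param gs a \code{gene_set}
#' @return named \code{GRanges} of locus spans.
#' @export
gene_spans <- function(gs) {
  if (length(gs) == 0L) return(GenomicRanges::GRanges())
  unlist(range(gs$exons), use.names = TRUE)
}

#' Introns of the union-exon gene models
#'
#' Gaps between the union of exon intervals of each gene; isoform-dependent
#' ambiguity is avoided by working on the reduced exon set.
#'
#' @param gs a \code{gene_set}
#' @return named \code{GRangesList} of introns (possibly empty per gene).
#' @export
gene_introns <- function(gs) {
  if (length(gs) == 0L) return(GenomicRanges::GRangesList())
  GenomicRanges::psetdiff(gene_spans(gs), gs$exons)
}

#' Subset a gene set
#' @param x a \code{gene_set}
#' @param i index vector (integer, logical, or gene ids)
#' @param ... ignored
#' @export
`[.gene_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, gene_ids(x))
  structure(list(exons = x$exons[i], biotype = x$biotype[i]),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", length(x), " genes (",
      sum(x$biotype == "coding"), " coding, ",
      sum(x$biotype == "noncoding"), " noncoding)\n", sep = "")
  invisible(x)
}

#' Build an annotation track
#'
#' A named interval set (ESTs, repeats, CAGE clusters, footprints, peaks,
#' imprinted loci, scored conservation elements) with an optional priority
#' rank used for annotation stacking.
#'
#' @param name track label (unique within a bundle)
#' @param intervals \code{GRanges}; an optional \code{score} metadata column
#'   carries per-interval scores (e.g. conservation probabilities).
#' @param priority optional integer rank (lower = higher priority).
#' @return An object of class \code{annotation_track}.
#' @export
annotation_track <- function(name, intervals, priority = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(intervals, "GRanges"))
  structure(list(name = name, intervals = intervals,
                 priority = as.integer(priority)),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat("<annotation_track> '", x$name, "': ", length(x$intervals),
      " intervals", if (!is.na(x$priority)) paste0(" (priority ", x$priority, ")"),
      "\n", sep = "")
  invisible(x)
}

as_track_granges <- function(x) {
  if (inherits(x, "annotation_track")) x$intervals
  else if (inherits(x, "GRanges")) x
  else stop("expected a GRanges or annotation_track")
}
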