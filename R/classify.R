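#' Categorized lncRNA candidate set
#'
#' Pairs surviving candidate transcripts with their genomic category and the
#' reference-gene relations recorded during classification (host gene and
#' host-intron width for intronic candidates, opposite-strand partner genes
#' for cis-antisense candidates).
#'
#' @param ts a \code{transcript_set}.
#' @param info data.frame with columns \code{tx_id}, \code{category},
#'   \code{host_gene}, \code{host_intron_width}, \code{partners} (comma
#'   separated gene ids), parallel to \code{ts}.
#' @return an object of class \code{lncrna_set}.
#' @export
lncrna_set <- function(ts, info) {
  stopifnot(inherits(ts, "transcript_set"),
            identical(tx_ids(ts), info$tx_id))
  info$category <- factor(info$category, levels = lnc_categories())
  structure(list(transcripts = ts, info = info), class = "lncrna_set")
}

#' Category labels used by the classifier
#' @return character vector of the four category names.
#' @export
lnc_categories <- function()
  c("intergenic", "intronic", "cis_antisense", "alt_spliced")

#' @export
length.lncrna_set <- function(x) length(x$transcripts)

#' @export
print.lncrna_set <- function(x, ...) {
  cat("<lncrna_set> ", length(x), " candidates\n", sep = "")
  print(table(x$info$category))
  invisible(x)
}

#' @export
summary.lncrna_set <- function(object, ...) {
  tab <- table(object$info$category)
  data.frame(category = names(tab), n = as.integer(tab))
}

#' Classify candidate transcripts against reference gene models
#'
#' Each candidate is assigned exactly one category, with rule precedence:
#' \enumerate{
#'   \item \emph{intergenic}: the candidate span overlaps no reference gene
#'     span (coding or noncoding);
#'   \item \emph{intronic}: the span is entirely contained within a single
#'     intron of a protein-coding gene (union-exon model), in either
#'     orientation;
#'   \item \emph{cis-antisense}: at least one candidate exon overlaps a
#'     reference exon on the opposite strand by >= 1 bp (unstranded
#'     candidates can never be cis-antisense);
#'   \item \emph{alt_spliced}: the residual (exonic overlap with reference
#'     genes in the sense orientation, novel isoform-like).
#' }
#'
#' @param ts a \code{transcript_set}.
#' @param genes a \code{gene_set} with coding and noncoding reference genes.
#' @param intergenic_includes_noncoding should rule 1 consider noncoding
#'   reference genes as well (default \code{TRUE}: intergenic means clear of
#'   all annotation)?
#' @return an \code{\link{lncrna_set}}.
#' @export
classify_all <- function(ts, genes, intergenic_includes_noncoding = TRUE) {
  n <- length(ts)
  info <- data.frame(tx_id = as.character(tx_ids(ts)),
                     category = rep("alt_spliced", n),
                     host_gene = rep(NA_character_, n),
                     host_intron_width = rep(NA_integer_, n),
                     partners = rep(NA_character_, n),
                     stringsAsFactors = FALSE)
  if (n == 0L) return(lncrna_set(ts, info))
  sp <- tx_spans(ts)

  # rule 1: no overlap with any reference gene span
  rule1_genes <- if (intergenic_includes_noncoding) genes
                 else genes[genes$biotype == "coding"]
  gsp <- gene_spans(rule1_genes)
  hit_gene <- GenomicRanges::countOverlaps(sp, gsp, ignore.strand = TRUE) > 0L
  info$category[!hit_gene] <- "intergenic"

  # rule 2: fully contained in one intron of a coding gene (either strand)
  coding <- genes[genes$biotype == "coding"]
  introns <- gene_introns(coding)
  intr <- unlist(introns, use.names = FALSE)
  intr_gene <- rep(gene_ids(coding), lengths(introns))
  cand <- which(hit_gene)
  if (length(cand) && length(intr)) {
    h <- GenomicRanges::findOverlaps(sp[cand], intr, type = "within",
                                     ignore.strand = TRUE)
    if (length(h)) {
      first <- !duplicated(S4Vectors::queryHits(h))
      qi <- cand[S4Vectors::queryHits(h)[first]]
      si <- S4Vectors::subjectHits(h)[first]
      info$category[qi] <- "intronic"
      info$host_gene[qi] <- intr_gene[si]
      info$host_intron_width[qi] <- GenomicRanges::width(intr)[si]
    }
  }

  # rule 3: exon-exon overlap on the opposite strand
  cand <- which(info$category == "alt_spliced")
  if (length(cand)) {
    rex <- unlist(genes$exons, use.names = FALSE)
    rex_gene <- rep(gene_ids(genes), lengths(genes$exons))
    cex <- unlist(ts$exons[cand], use.names = FALSE)
    cex_tx <- rep(cand, lengths(ts$exons[cand]))
    h <- GenomicRanges::findOverlaps(cex, rex, ignore.strand = TRUE)
    if (length(h)) {
      cs <- as.character(GenomicRanges::strand(cex))[S4Vectors::queryHits(h)]
      rs <- as.character(GenomicRanges::strand(rex))[S4Vectors::subjectHits(h)]
      anti <- (cs == "+" & rs == "-") | (cs == "-" & rs == "+")
      if (any(cs == "*"))
        message("unstranded candidate(s) cannot be cis-antisense")
      if (any(anti)) {
        qi <- cex_tx[S4Vectors::queryHits(h)[anti]]
        gid <- rex_gene[S4Vectors::subjectHits(h)[anti]]
        partners <- vapply(split(gid, qi), function(g)
          paste(sort(unique(g)), collapse = ","), character(1))
        idx <- as.integer(names(partners))
        info$category[idx] <- "cis_antisense"
        info$partners[idx] <- partners
      }
    }
  }
  lncrna_set(ts, info)
}

#' Classify a single transcript
#'
#' Convenience wrapper around \code{\link{classify_all}} for one transcript.
#'
#' @param ts a \code{transcript_set} (the transcript of interest may be a
#'   one-element set).
#' @param i index or id of the transcript to classify.
#' @param genes a \code{gene_set}.
#' @param ... passed to \code{\link{classify_all}}.
#' @return the category label (character scalar).
#' @export
classify_transcript <- function(ts, i, genes, ...) {
  as.character(classify_all(ts[i], genes, ...)$info$category[1L])
}
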