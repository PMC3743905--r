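## GTF / BED readers and writers. rtracklayer does the coordinate-convention
## work (GTF 1-based closed, BED 0-based half-open); everything internal is
## GenomicRanges 1-based closed.

.check_gtf_lines <- function(path) {
  ln <- readLines(path)
  keep <- !grepl("^#", ln) & nzchar(ln)
  nf <- lengths(strsplit(ln[keep], "\t", fixed = TRUE))
  bad <- which(keep)[nf < 9L]
  if (length(bad))
    stop("malformed GTF line ", bad[1L], " in '", path,
         "': expected >= 9 tab-separated fields")
  invisible(TRUE)
}

.gtf_exons_by <- function(path, by) {
  .check_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ids <- S4Vectors::mcols(gr)[[by]]
  if (is.null(ids) || anyNA(ids))
    stop("GTF exon records in '", path, "' lack a ", by, " attribute")
  grl <- GenomicRanges::split(gr[, character(0)], factor(ids, unique(ids)))
  grl <- GenomicRanges::sort(grl)
  grl
}

#' Read assembled transcripts from GTF (+ optional side table)
#'
#' @param gtf path to a GTF file with exon features carrying
#'   \code{transcript_id} attributes (Ensembl dialect).
#' @param table optional path to the tab-delimited transcript side table with
#'   columns \code{transcript_id}, \code{class_code}, \code{cpc_score},
#'   \code{stage_presence} (comma-separated stage names) and one
#'   \code{rpkm_<stage>} column per stage.
#' @return a \code{\link{transcript_set}}.
#' @export
read_transcripts_gtf <- function(gtf, table = NULL) {
  grl <- .gtf_exons_by(gtf, "transcript_id")
  ts <- transcript_set(grl)
  if (!is.null(table)) {
    tab <- utils::read.delim(table, stringsAsFactors = FALSE)
    m <- match(tx_ids(ts), tab$transcript_id)
    if (anyNA(m))
      stop("transcripts missing from side table: ",
           paste(utils::head(tx_ids(ts)[is.na(m)]), collapse = ", "))
    tab <- tab[m, , drop = FALSE]
    rpkm_cols <- grep("^rpkm_", names(tab), value = TRUE)
    expr <- as.matrix(tab[, rpkm_cols, drop = FALSE])
    colnames(expr) <- sub("^rpkm_", "", rpkm_cols)
    rownames(expr) <- tx_ids(ts)
    stages <- strsplit(ifelse(is.na(tab$stage_presence), "",
                              tab$stage_presence), ",", fixed = TRUE)
    ts <- transcript_set(grl, class_code = tab$class_code,
                         cpc_score = tab$cpc_score, expr = expr,
                         stages = stages)
  }
  ts
}

#' Write a transcript set to GTF (+ side table)
#'
#' Inverse of \code{\link{read_transcripts_gtf}}; a write/read round trip
#' preserves coordinates, strand, class codes, scores, expression and stage
#' support.
#'
#' @param ts a \code{transcript_set}.
#' @param gtf output GTF path.
#' @param table optional output path for the side table.
#' @export
write_transcripts_gtf <- function(ts, gtf, table = NULL) {
  ex <- unlist(ts$exons, use.names = FALSE)
  ids <- rep(tx_ids(ts), lengths(ts$exons))
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = "lncforge", type = "exon",
    gene_id = ids, transcript_id = ids)
  rtracklayer::export(ex, gtf, format = "gtf")
  if (!is.null(table)) {
    tab <- data.frame(transcript_id = tx_ids(ts),
                      class_code = ts$class_code,
                      cpc_score = ts$cpc_score,
                      stage_presence = vapply(ts$stages, paste,
                                              character(1), collapse = ","),
                      stringsAsFactors = FALSE)
    if (ncol(ts$expr)) {
      ecols <- as.data.frame(ts$expr)
      names(ecols) <- paste0("rpkm_", colnames(ts$expr))
      tab <- cbind(tab, ecols)
    }
    utils::write.table(tab, table, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(gtf)
}

#' Read reference gene models from GTF
#'
#' Exons are grouped by \code{gene_id}; the \code{gene_biotype} attribute
#' (\code{"protein_coding"} maps to coding, anything else to noncoding)
#' assigns the biotype.
#'
#' @param gtf path to a GTF file.
#' @return a \code{\link{gene_set}}.
#' @export
read_genes_gtf <- function(gtf) {
  .check_gtf_lines(gtf)
  gr <- rtracklayer::import(gtf, format = "gtf")
  gr <- gr[gr$type == "exon"]
  ids <- S4Vectors::mcols(gr)$gene_id
  bio <- S4Vectors::mcols(gr)$gene_biotype
  if (is.null(bio)) bio <- rep("protein_coding", length(gr))
  grl <- GenomicRanges::split(gr[, character(0)], factor(ids, unique(ids)))
  grl <- GenomicRanges::sort(grl)
  bio1 <- vapply(split(as.character(bio), factor(ids, unique(ids))),
                 function(b) b[[1L]], character(1))
  gene_set(grl, ifelse(bio1 == "protein_coding", "coding", "noncoding"))
}

#' Write reference gene models to GTF
#' @param gs a \code{gene_set}.
#' @param gtf output path.
#' @export
write_genes_gtf <- function(gs, gtf) {
  ex <- unlist(gs$exons, use.names = FALSE)
  ids <- rep(gene_ids(gs), lengths(gs$exons))
  bio <- rep(ifelse(gs$biotype == "coding", "protein_coding", "noncoding"),
             lengths(gs$exons))
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = "lncforge", type = "exon",
    gene_id = ids, transcript_id = ids, gene_biotype = bio)
  rtracklayer::export(ex, gtf, format = "gtf")
  invisible(gtf)
}

#' Read a BED3/BED6 annotation track
#'
#' BED's native 0-based half-open coordinates are converted to the internal
#' 1-based closed convention; strand \code{"."} becomes unstranded and the
#' BED score column is kept as per-interval score.
#'
#' @param path BED file path.
#' @param name track label (defaults to the file name).
#' @param priority optional integer rank for annotation stacking.
#' @return an \code{\link{annotation_track}}.
#' @export
read_bed <- function(path, name = basename(path), priority = NA_integer_) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e)
                   stop("invalid BED interval in '", path, "': ",
                        conditionMessage(e)))
  if (length(gr) && any(GenomicRanges::width(gr) < 1L))
    stop("invalid BED interval in '", path, "': start >= end")
  annotation_track(name, gr, priority)
}

#' Write an annotation track to BED
#' @param track an \code{annotation_track} or \code{GRanges}.
#' @param path output path.
#' @export
write_bed <- function(track, path) {
  gr <- as_track_granges(track)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
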