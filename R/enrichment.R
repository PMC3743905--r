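#' Closest-gene list for intergenic candidates
#'
#' Unique ids of the nearest coding gene of each intergenic candidate at a
#' span-to-span distance strictly below \code{max_dist} (default 500 kb;
#' more distant genes are considered irrelevant). This is the gene list
#' submitted to functional-term enrichment for the intergenic category.
#'
#' @param lnc an \code{lncrna_set}.
#' @param genes a \code{gene_set}.
#' @param max_dist bp, default 500000 (strict).
#' @return character vector of deduplicated gene ids.
#' @export
closest_gene_list <- function(lnc, genes, max_dist = 500000) {
  ig <- lnc$info$category == "intergenic"
  if (!any(ig)) return(character(0))
  nn <- nearest_coding_gene(lnc$transcripts[which(ig)], genes)
  unique(nn$gene_id[!is.na(nn$gene_id) & nn$distance < max_dist])
}

#' Host-gene list for intronic candidates
#'
#' Ids of the genes hosting intronic candidates, excluding hosts whose
#' containing intron is longer than \code{max_intron} (default 100 kb;
#' large introns bias the list).
#'
#' @param lnc an \code{lncrna_set} (host gene and intron width recorded at
#'   classification time).
#' @param max_intron bp, default 100000 (hosts with strictly longer introns
#'   are discarded).
#' @return character vector of deduplicated gene ids.
#' @export
host_gene_list <- function(lnc, max_intron = 100000) {
  ii <- lnc$info$category == "intronic"
  if (!any(ii)) return(character(0))
  host <- lnc$info$host_gene[ii]
  iw <- lnc$info$host_intron_width[ii]
  if (anyNA(host))
    stop("intronic candidate(s) without a recorded host intron: ",
         paste(utils::head(lnc$info$tx_id[ii][is.na(host)]), collapse = ", "))
  unique(host[iw <= max_intron])
}

#' Overlapping-gene list for cis-antisense candidates
#'
#' Deduplicated opposite-strand partner gene ids recorded at
#' classification time.
#'
#' @param lnc an \code{lncrna_set}.
#' @return character vector of gene ids.
#' @export
overlapping_gene_list <- function(lnc) {
  ca <- lnc$info$category == "cis_antisense"
  if (!any(ca)) return(character(0))
  unique(unlist(strsplit(lnc$info$partners[ca], ",", fixed = TRUE),
                use.names = FALSE))
}

#' Hypergeometric term enrichment
#'
#' Generic over-representation test for a gene list against a background:
#' for each term with K members among the N background genes, the
#' upper-tail hypergeometric probability of observing at least k members in
#' the n-gene list, with Benjamini-Hochberg adjustment across the tested
#' terms (the conventional "adjusted p < 0.05" readout).
#'
#' @param gene_list character vector of gene ids (must be a subset of
#'   \code{background}).
#' @param background character vector of background gene ids.
#' @param term_map data.frame with columns \code{term} and \code{gene}
#'   (two-column term-membership table).
#' @return data.frame sorted by adjusted p with columns \code{term},
#'   \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{p_adj}.
#' @export
term_enrichment <- function(gene_list, background, term_map) {
  stopifnot(all(c("term", "gene") %in% names(term_map)),
            nrow(term_map) > 0)
  background <- unique(background)
  gene_list <- unique(gene_list)
  extra <- setdiff(gene_list, background)
  if (length(extra))
    stop("gene list members missing from background: ",
         paste(utils::head(extra), collapse = ", "))
  N <- length(background); n <- length(gene_list)
  tm <- unique(term_map[term_map$gene %in% background,
                        c("term", "gene"), drop = FALSE])
  terms <- split(tm$gene, tm$term)
  K <- lengths(terms)
  keep <- K > 0L
  terms <- terms[keep]; K <- K[keep]
  k <- vapply(terms, function(g) length(intersect(g, gene_list)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(terms), k = k, K = as.integer(K),
                    n = n, N = N, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_adj, out$p, out$term), , drop = FALSE]
}
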