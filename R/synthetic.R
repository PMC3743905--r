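## Synthetic fixture generator. Every property the downstream analysis is
## supposed to recover is planted by construction (not sampled and then
## re-measured), so the generated manifest is an exact oracle: transcripts
## destined to fail a filter stage violate exactly that stage's criterion,
## categories follow from planted geometry, and annotation flags correspond
## one-to-one to planted track intervals.

#' Fixture configuration
#'
#' Defaults describe the emulated study conditions: four developmental
#' stages, log-normal expression with lncRNAs at about one tenth of the
#' coding-gene median, coding-potential scores separated around the -1
#' cutoff, spliced-EST support 82\%, repeat association 40\%, ribosome
#' association 5\%, H3K4me3 at half of the candidate TSSs, and an imprinted
#' zone harbouring a quarter of the intergenic survivors within 100 kb of a
#' cluster. Candidate destinies partition the 2,000 generated models across
#' the filter stages and the four genomic categories.
#'
#' @param n_chrom number of chromosomes (the last one is the imprinted
#'   zone).
#' @param chrom_len chromosome length in bp.
#' @param stages stage names.
#' @param n_coding,n_noncoding reference gene counts.
#' @param coding_meanlog,lnc_meanlog,sdlog log-normal expression parameters
#'   (RPKM scale).
#' @param destinies named integer vector: candidates per filter-stage
#'   failure (\code{duplicate}, \code{min_length}, \code{single_exon},
#'   \code{expression}, \code{class_code}, \code{coding_potential},
#'   \code{coding_proximity}) and per surviving category
#'   (\code{intergenic}, \code{intronic}, \code{cis_antisense},
#'   \code{alt_spliced}).
#' @param rate_est_spliced,rate_est_unspliced,rate_repeat,rate_ribosome,rate_cage
#'   planted coverage rates on survivors.
#' @param mark_rates named vector of planted chromatin-mark rates at
#'   survivor TSSs.
#' @param n_imprinted imprinted cluster count.
#' @param imprinted_near_frac fraction of intergenic survivors planted
#'   within 100 kb of a cluster.
#' @param unspliced_null_rate target chance for a random placement to hit a
#'   background unspliced EST (sets the background density so planted
#'   support is about a three-fold enrichment over it).
#' @param expr_threshold RPKM noise cutoff the expression destinies are
#'   built against.
#' @return an object of class \code{fixture_config}.
#' @export
fixture_config <- function(n_chrom = 4,
                           chrom_len = 12e6,
                           stages = c("E14", "E15", "E17", "ES"),
                           n_coding = 700,
                           n_noncoding = 100,
                           coding_meanlog = log(30),
                           lnc_meanlog = log(3),
                           sdlog = 1,
                           destinies = c(duplicate = 100, min_length = 150,
                                         single_exon = 150, expression = 250,
                                         class_code = 150,
                                         coding_potential = 200,
                                         coding_proximity = 100,
                                         intergenic = 200, intronic = 300,
                                         cis_antisense = 100,
                                         alt_spliced = 300),
                           rate_est_spliced = 0.82,
                           rate_est_unspliced = 0.30,
                           rate_repeat = 0.40,
                           rate_ribosome = 0.05,
                           rate_cage = 0.60,
                           mark_rates = c(H3K4me3 = 0.50, CTCF = 0.40,
                                          PolII = 0.45, H3K27ac = 0.30,
                                          H3K4me1 = 0.20),
                           n_imprinted = 10,
                           imprinted_near_frac = 0.25,
                           unspliced_null_rate = 0.10,
                           expr_threshold = 0.3) {
  cfg <- as.list(environment())
  stopifnot(n_chrom >= 2, chrom_len > 1e6,
            all(destinies >= 0),
            all(c(rate_est_spliced, rate_est_unspliced, rate_repeat,
                  rate_ribosome, rate_cage, mark_rates,
                  imprinted_near_frac) >= 0),
            all(c(rate_est_spliced, rate_est_unspliced, rate_repeat,
                  rate_ribosome, rate_cage, mark_rates,
                  imprinted_near_frac) <= 1))
  needed_hosts <- destinies[["intronic"]] + destinies[["cis_antisense"]] +
    destinies[["alt_spliced"]]
  if (n_coding < needed_hosts)
    stop("n_coding must be at least the number of gene-attached candidates (",
         needed_hosts, ")")
  structure(cfg, class = "fixture_config")
}

# sub-intervals covering `nbp` bases walking the exon chain from its start
.plant_in_exons <- function(ex_start, ex_end, nbp, offset = 0L) {
  out_s <- integer(0); out_e <- integer(0)
  left <- nbp
  for (i in seq_along(ex_start)) {
    s <- ex_start[i] + (if (i == 1L) offset else 0L)
    avail <- ex_end[i] - s + 1L
    if (avail <= 0L) next
    take <- min(left, avail)
    out_s <- c(out_s, s); out_e <- c(out_e, s + take - 1L)
    left <- left - take
    if (left <= 0L) break
  }
  if (left > 0L) stop("exon chain shorter than requested planting length")
  list(start = out_s, end = out_e)
}

.rnorm_trunc <- function(n, mean, sd, upper = Inf, lower = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  for (it in 1:50) {
    bad <- x >= upper | x <= lower
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x[x >= upper] <- upper - abs(stats::rnorm(sum(x >= upper), 0, sd / 10)) - 1e-6
  x[x <= lower] <- lower + abs(stats::rnorm(sum(x <= lower), 0, sd / 10)) + 1e-6
  x
}

# random candidate structure: local exon coordinates (start at 0)
.cand_structure <- function(n_ex, total_len) {
  w <- pmax(80L, as.integer(stats::rmultinom(1, total_len - 80L * n_ex,
                                             rep(1, n_ex))) + 80L)
  gaps <- if (n_ex > 1L) sample(300:900, n_ex - 1L, replace = TRUE) else integer(0)
  st <- cumsum(c(0L, utils::head(w, -1L) + gaps))
  list(start = as.integer(st), end = as.integer(st + w - 1L))
}

#' Generate the synthetic fixture bundle
#'
#' Builds a complete deterministic fixture: reference gene models (coding
#' and noncoding), candidate transcript models with planted destinies and
#' categories, annotation tracks (spliced/unspliced ESTs, repeats, ribosome
#' footprints, CAGE clusters, scored conservation elements, per-mark ChIP
#' peaks, imprinted clusters), per-gene expression, and the ground-truth
#' manifest. Optionally writes the bundle as GTF/TSV/BED/JSON files.
#'
#' @param config a \code{\link{fixture_config}}.
#' @param seed integer seed; the bundle is a deterministic function of
#'   (config, seed).
#' @param out_dir optional directory to write the file bundle to.
#' @return list with \code{candidates} (\code{transcript_set}),
#'   \code{genes} (\code{gene_set}), \code{tracks} (named list;
#'   \code{marks} is a nested named list of peak tracks),
#'   \code{chrom_sizes}, \code{gene_expr} (coding/noncoding log-normal RPKM
#'   matrices), \code{manifest} (per-candidate truth data.frame), and
#'   \code{config}.
#' @export
generate_fixture <- function(config = fixture_config(), seed = 1,
                             out_dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  set.seed(seed)
  d <- config$destinies
  n_surv <- d[["intergenic"]] + d[["intronic"]] + d[["cis_antisense"]] +
    d[["alt_spliced"]]
  chroms <- paste0("chr", seq_len(config$n_chrom))
  main_chroms <- utils::head(chroms, -1L)
  imp_chrom <- chroms[length(chroms)]
  chrom_sizes <- setNames(rep(config$chrom_len, config$n_chrom), chroms)

  ## ---- reference gene structures (local coordinates) ----
  n_g <- config$n_coding
  host_ids <- seq_len(d[["intronic"]])
  anti_ids <- d[["intronic"]] + seq_len(d[["cis_antisense"]])
  alt_ids <- d[["intronic"]] + d[["cis_antisense"]] + seq_len(d[["alt_spliced"]])
  prox_ids <- seq_len(d[["coding_proximity"]])   # reuse early genes downstream

  genes <- vector("list", n_g)
  for (g in seq_len(n_g)) {
    n_ex <- sample(4:7, 1)
    ex_w <- sample(120:400, n_ex, replace = TRUE)
    intron_w <- c(sample(6000:9000, 1),
                  sample(1500:4000, n_ex - 2L, replace = TRUE))
    if (g %in% host_ids) intron_w[2L] <- sample(8000:15000, 1)
    st <- cumsum(c(0L, ex_w[-n_ex] + intron_w))
    genes[[g]] <- list(ex_start = as.integer(st),
                       ex_end = as.integer(st + ex_w - 1L),
                       strand = sample(c("+", "-"), 1),
                       width = st[n_ex] + ex_w[n_ex])
  }

  ## ---- candidates: destiny roster -------------------------------------
  mk_cand <- function(destiny, category, n_ex, total_len) {
    s <- .cand_structure(n_ex, total_len)
    list(destiny = destiny, category = category,
         ex_start = s$start, ex_end = s$end,
         strand = sample(c("+", "-"), 1),
         host = NA_character_, partner = NA_character_,
         host_intron = NA_integer_, near_imprinted = FALSE)
  }
  cands <- list()
  add <- function(x) { cands[[length(cands) + 1L]] <<- x; length(cands) }

  n_near <- round(config$imprinted_near_frac * d[["intergenic"]])
  for (i in seq_len(d[["intergenic"]]))
    add(within_list(mk_cand("survivor", "intergenic",
                            sample(2:4, 1), sample(800:2500, 1)),
                    near_imprinted = i <= n_near))
  for (i in seq_len(d[["min_length"]]))
    add(mk_cand("min_length", NA, 2L, sample(165:200, 1)))
  for (i in seq_len(d[["single_exon"]]))
    add(mk_cand("single_exon", NA, 1L, sample(250:800, 1)))
  for (i in seq_len(d[["expression"]]))
    add(mk_cand("expression", NA, sample(2:3, 1), sample(600:2000, 1)))
  for (i in seq_len(d[["class_code"]]))
    add(mk_cand("class_code", NA, sample(2:3, 1), sample(600:2000, 1)))
  for (i in seq_len(d[["coding_potential"]]))
    add(mk_cand("coding_potential", NA, sample(2:3, 1), sample(600:2000, 1)))
  standalone_idx <- seq_along(cands)

  ## gene-attached candidates
  attach <- list()  # cand index -> list(gene, kind)
  for (k in seq_along(host_ids)) {
    g <- host_ids[k]
    gn <- genes[[g]]
    intron_s <- gn$ex_end[2L] + 1L
    intron_e <- gn$ex_start[3L] - 1L
    iw <- intron_e - intron_s + 1L
    span <- sample(1200:min(2800, iw - 400L), 1)
    s <- .cand_structure(2L, span)
    while (max(s$end) > iw - 400L) s <- .cand_structure(2L, span - 200L)
    off <- intron_s + sample(100:200, 1)
    i <- add(list(destiny = "survivor", category = "intronic",
                  ex_start = s$start + off, ex_end = s$end + off,
                  strand = sample(c("+", "-"), 1),
                  host = sprintf("G%04d", g), partner = NA_character_,
                  host_intron = iw, near_imprinted = FALSE))
    attach[[as.character(i)]] <- g
  }
  mk_exonic_overlap <- function(g, antisense) {
    gn <- genes[[g]]
    e3 <- gn$ex_start[3L]
    st <- c(e3 - 300L, e3 + 400L)
    en <- c(e3 + 100L, e3 + 700L)
    list(destiny = "survivor",
         category = if (antisense) "cis_antisense" else "alt_spliced",
         ex_start = st, ex_end = en,
         strand = if (antisense) setdiff(c("+", "-"), gn$strand) else gn$strand,
         host = NA_character_,
         partner = if (antisense) sprintf("G%04d", g) else NA_character_,
         host_intron = NA_integer_, near_imprinted = FALSE)
  }
  for (g in anti_ids) attach[[as.character(add(mk_exonic_overlap(g, TRUE)))]] <- g
  for (g in alt_ids) attach[[as.character(add(mk_exonic_overlap(g, FALSE)))]] <- g
  for (k in seq_len(d[["coding_proximity"]])) {
    g <- prox_ids[k]
    gn <- genes[[g]]
    gap <- sample(100:900, 1)
    s <- .cand_structure(2L, sample(900:1500, 1))
    off <- gn$width + gap
    i <- add(list(destiny = "coding_proximity", category = "intergenic",
                  ex_start = s$start + off, ex_end = s$end + off,
                  strand = sample(c("+", "-"), 1),
                  host = NA_character_, partner = NA_character_,
                  host_intron = NA_integer_, near_imprinted = FALSE))
    attach[[as.character(i)]] <- g
  }

  ## ---- genome layout ---------------------------------------------------
  ## items: genes (with their attached candidates), noncoding genes, and
  ## standalone candidates, shuffled over the main chromosomes with a 6 kb
  ## separation so TSS-window tracks cannot leak between items.
  gene_attached <- split(as.integer(names(attach)), unlist(attach))
  item_gap <- 6000L
  near_idx <- which(vapply(cands, function(x) isTRUE(x$near_imprinted),
                           logical(1)))
  items <- c(lapply(seq_len(n_g), function(g) list(type = "gene", id = g)),
             lapply(seq_len(config$n_noncoding), function(g)
               list(type = "ncgene", id = g)),
             lapply(setdiff(standalone_idx, near_idx), function(i)
               list(type = "cand", id = i)))
  items <- items[sample.int(length(items))]

  nc_genes <- vector("list", config$n_noncoding)
  for (g in seq_len(config$n_noncoding)) {
    n_ex <- sample(3:5, 1)
    ex_w <- sample(150:400, n_ex, replace = TRUE)
    intron_w <- sample(1500:4000, n_ex - 1L, replace = TRUE)
    st <- cumsum(c(0L, ex_w[-n_ex] + intron_w))
    nc_genes[[g]] <- list(ex_start = as.integer(st),
                          ex_end = as.integer(st + ex_w - 1L),
                          strand = sample(c("+", "-"), 1),
                          width = st[n_ex] + ex_w[n_ex])
  }

  item_width <- vapply(items, function(it) {
    switch(it$type,
           gene = {
             w <- genes[[it$id]]$width
             for (ci in gene_attached[[as.character(it$id)]])
               w <- max(w, max(cands[[ci]]$ex_end) + 1L)
             w
           },
           ncgene = nc_genes[[it$id]]$width,
           cand = max(cands[[it$id]]$ex_end) + 1L)
  }, numeric(1))

  cursor <- setNames(rep(10000, length(main_chroms)), main_chroms)
  item_chrom <- character(length(items))
  item_off <- numeric(length(items))
  for (k in seq_along(items)) {
    ch <- names(which.min(cursor))
    if (cursor[ch] + item_width[k] + item_gap > chrom_sizes[[ch]] - 50000)
      stop("infeasible fixture config: chromosomes too small for the items")
    item_chrom[k] <- ch
    item_off[k] <- cursor[ch]
    cursor[ch] <- cursor[ch] + item_width[k] + item_gap
  }

  gene_chrom <- character(n_g); gene_off <- numeric(n_g)
  nc_chrom <- character(config$n_noncoding); nc_off <- numeric(config$n_noncoding)
  cand_chrom <- character(length(cands)); cand_off <- numeric(length(cands))
  for (k in seq_along(items)) {
    it <- items[[k]]
    if (it$type == "gene") {
      gene_chrom[it$id] <- item_chrom[k]; gene_off[it$id] <- item_off[k]
      for (ci in gene_attached[[as.character(it$id)]]) {
        cand_chrom[ci] <- item_chrom[k]; cand_off[ci] <- item_off[k]
      }
    } else if (it$type == "ncgene") {
      nc_chrom[it$id] <- item_chrom[k]; nc_off[it$id] <- item_off[k]
    } else {
      cand_chrom[it$id] <- item_chrom[k]; cand_off[it$id] <- item_off[k]
    }
  }

  ## imprinted zone: clusters on the last chromosome with near-planted
  ## intergenic survivors trailing each cluster within 100 kb
  imp_s <- integer(0); imp_e <- integer(0)
  pos <- 200000
  if (config$n_imprinted > 0 && n_near > 0) {
    per <- split(near_idx, rep(seq_len(config$n_imprinted),
                               length.out = length(near_idx)))
  } else per <- list()
  for (cl in seq_len(config$n_imprinted)) {
    w <- sample(2000:10000, 1)
    imp_s <- c(imp_s, pos); imp_e <- c(imp_e, pos + w - 1L)
    tail_pos <- pos + w
    for (ci in if (cl <= length(per)) per[[cl]] else integer(0)) {
      tail_pos <- tail_pos + sample(6000:9000, 1)
      cand_chrom[ci] <- imp_chrom
      cand_off[ci] <- tail_pos
      tail_pos <- tail_pos + max(cands[[ci]]$ex_end) + 1L
    }
    pos <- tail_pos + sample(250000:400000, 1)
    if (pos > chrom_sizes[[imp_chrom]] - 200000)
      stop("infeasible fixture config: imprinted chromosome too small")
  }

  ## ---- materialize GRanges (single vectorized construction) -----------
  g_nex <- vapply(genes, function(g) length(g$ex_start), integer(1))
  nc_nex <- vapply(nc_genes, function(g) length(g$ex_start), integer(1))
  gene_labels <- c(sprintf("G%04d", seq_len(n_g)),
                   sprintf("N%04d", seq_len(config$n_noncoding)))
  all_gex <- GenomicRanges::GRanges(
    c(rep(gene_chrom, g_nex), rep(nc_chrom, nc_nex)),
    IRanges::IRanges(
      c(rep(gene_off, g_nex) + unlist(lapply(genes, `[[`, "ex_start")),
        rep(nc_off, nc_nex) + unlist(lapply(nc_genes, `[[`, "ex_start"))),
      c(rep(gene_off, g_nex) + unlist(lapply(genes, `[[`, "ex_end")),
        rep(nc_off, nc_nex) + unlist(lapply(nc_genes, `[[`, "ex_end")))),
    strand = c(rep(vapply(genes, `[[`, character(1), "strand"), g_nex),
               rep(vapply(nc_genes, `[[`, character(1), "strand"), nc_nex)))
  gene_f <- factor(rep(gene_labels, c(g_nex, nc_nex)), levels = gene_labels)
  gs <- gene_set(GenomicRanges::split(all_gex, gene_f),
                 rep(c("coding", "noncoding"),
                     c(n_g, config$n_noncoding)))

  n_c <- length(cands)
  cand_ids <- sprintf("TX%04d", seq_len(n_c))

  ## duplicates: exact copies of survivors, ids sorting after the source
  surv_idx <- which(vapply(cands, function(x) x$destiny == "survivor",
                           logical(1)))
  dup_src <- sample(surv_idx, d[["duplicate"]], replace = FALSE)
  dup_ids <- paste0(cand_ids[dup_src], "_d1")
  all_ids <- c(cand_ids, dup_ids)
  n_all <- length(all_ids)

  src_idx <- c(seq_len(n_c), dup_src)
  c_nex <- vapply(cands, function(x) length(x$ex_start), integer(1))[src_idx]
  all_cex <- GenomicRanges::GRanges(
    rep(cand_chrom[src_idx], c_nex),
    IRanges::IRanges(
      rep(cand_off[src_idx], c_nex) +
        unlist(lapply(cands[src_idx], `[[`, "ex_start")),
      rep(cand_off[src_idx], c_nex) +
        unlist(lapply(cands[src_idx], `[[`, "ex_end"))),
    strand = rep(vapply(cands[src_idx], `[[`, character(1), "strand"),
                 c_nex))
  cand_grl <- GenomicRanges::split(all_cex,
                                   factor(rep(all_ids, c_nex),
                                          levels = all_ids))

  ## ---- attributes ------------------------------------------------------
  destiny <- c(vapply(cands, `[[`, character(1), "destiny"),
               rep("duplicate", d[["duplicate"]]))
  category <- c(vapply(cands, function(x)
    if (is.null(x$category) || is.na(x$category)) NA_character_ else x$category,
    character(1)), rep(NA_character_, d[["duplicate"]]))

  stage_names <- config$stages
  n_stage <- length(stage_names)
  expr <- matrix(stats::rlnorm(n_all * n_stage, config$lnc_meanlog,
                               config$sdlog),
                 nrow = n_all, dimnames = list(all_ids, stage_names))
  low <- destiny == "expression"
  expr[low, ] <- matrix(stats::runif(sum(low) * n_stage, 0,
                                     config$expr_threshold * 0.97),
                        ncol = n_stage)
  hi_guard <- which(!low)
  mx <- apply(expr[hi_guard, , drop = FALSE], 1, max)
  need <- mx < config$expr_threshold
  if (any(need)) {
    j <- sample.int(n_stage, sum(need), replace = TRUE)
    expr[cbind(hi_guard[need], j)] <- config$expr_threshold +
      stats::runif(sum(need), 0, 0.5)
  }

  stages <- lapply(seq_len(n_all), function(i)
    sort(sample(stage_names, sample(2:n_stage, 1))))
  se <- destiny == "single_exon"
  stages[se] <- lapply(seq_len(sum(se)), function(i) sample(stage_names, 1))
  isdup <- destiny == "duplicate"
  stages[isdup] <- lapply(seq_len(sum(isdup)), function(i)
    sample(stage_names, 1))

  class_code <- character(n_all)
  class_code[match(cand_ids, all_ids)] <- vapply(cands, function(x)
    switch(ifelse(is.na(x$category), "none", x$category),
           intergenic = "u", intronic = "i", cis_antisense = "x",
           alt_spliced = "j", none = "u"), character(1))
  class_code[destiny == "class_code"] <- sample(c("=", "c", "e", "o", "p"),
                                                d[["class_code"]],
                                                replace = TRUE)
  class_code[isdup] <- class_code[match(sub("_d1$", "", all_ids[isdup]),
                                        all_ids)]

  cpc <- .rnorm_trunc(n_all, -3, 1, upper = -1.02)
  cpc[destiny == "coding_potential"] <- .rnorm_trunc(d[["coding_potential"]],
                                                     3, 1, lower = -0.98)

  ts <- transcript_set(cand_grl,
                       class_code = class_code, cpc_score = cpc,
                       expr = expr, stages = stages)

  ## ---- planted annotation flags & tracks -------------------------------
  surv_ids <- cand_ids[surv_idx]
  pick <- function(rate) sample(surv_ids, round(rate * length(surv_ids)))
  flagged <- list(est_spliced = pick(config$rate_est_spliced),
                  est_unspliced = pick(config$rate_est_unspliced),
                  repeat_el = pick(config$rate_repeat),
                  ribosome = pick(config$rate_ribosome),
                  cage = pick(config$rate_cage))
  for (m in names(config$mark_rates))
    flagged[[paste0("mark_", m)]] <- pick(config$mark_rates[[m]])

  exon_tab <- function(id) {
    i <- match(id, cand_ids)
    list(start = cand_off[i] + cands[[i]]$ex_start,
         end = cand_off[i] + cands[[i]]$ex_end,
         chrom = cand_chrom[i])
  }
  plant_track <- function(ids, nbp_fun) {
    ch <- character(0); s <- integer(0); e <- integer(0)
    for (id in ids) {
      et <- exon_tab(id)
      p <- .plant_in_exons(et$start, et$end, nbp_fun(et),
                           offset = sample(0:20, 1))
      ch <- c(ch, rep(et$chrom, length(p$start)))
      s <- c(s, p$start); e <- c(e, p$end)
    }
    GenomicRanges::GRanges(ch, IRanges::IRanges(s, e))
  }
  exlen_of <- function(et) sum(et$end - et$start + 1L)
  spliced_est <- plant_track(flagged$est_spliced,
                             function(et) min(150L, et$end[1] - et$start[1] - 25L))
  unspliced_est <- plant_track(flagged$est_unspliced,
                               function(et) min(120L, et$end[1] - et$start[1] - 25L))
  repeats <- plant_track(flagged$repeat_el,
                         function(et) as.integer(ceiling(0.2 * exlen_of(et))))
  ribosome <- plant_track(flagged$ribosome, function(et) 30L)

  ## conservation elements: scored sub-intervals on a survivor subset
  cons_ids <- sample(surv_ids, round(0.3 * length(surv_ids)))
  cons <- plant_track(cons_ids,
                      function(et) as.integer(ceiling(0.4 * exlen_of(et))))
  S4Vectors::mcols(cons)$score <- round(stats::runif(length(cons), 0.3, 1), 3)

  ## TSS-anchored tracks (CAGE, chromatin peaks)
  tss_all <- suppressWarnings(tx_tss(ts))
  sp_all <- tx_spans(ts)
  tss_of <- function(ids) {
    i <- match(ids, names(tss_all))
    list(chrom = as.character(GenomicRanges::seqnames(sp_all))[i],
         pos = tss_all[i])
  }
  tp <- tss_of(flagged$cage)
  cage <- GenomicRanges::GRanges(tp$chrom,
                                 IRanges::IRanges(tp$pos - 25L, tp$pos + 25L))
  gene_tss <- vapply(seq_len(n_g), function(g) {
    gn <- genes[[g]]
    if (gn$strand == "+") gene_off[g] + gn$ex_start[1L]
    else gene_off[g] + gn$ex_end[length(gn$ex_end)]
  }, numeric(1))
  cage <- c(cage, GenomicRanges::GRanges(
    gene_chrom, IRanges::IRanges(as.integer(gene_tss) - 25L,
                                 as.integer(gene_tss) + 25L)))

  ## gene TSS peaks for promoter marks, skipping genes whose attached
  ## candidate TSS is close enough for the peak to leak into its window
  safe_gene <- vapply(seq_len(n_g), function(g) {
    cis <- gene_attached[[as.character(g)]]
    if (is.null(cis)) return(TRUE)
    all(abs(tss_all[cis] - gene_tss[g]) > 5500)
  }, logical(1))
  marks <- list()
  for (m in names(config$mark_rates)) {
    tp <- tss_of(flagged[[paste0("mark_", m)]])
    pk <- GenomicRanges::GRanges(tp$chrom,
                                 IRanges::IRanges(tp$pos - 150L, tp$pos + 150L))
    if (m %in% c("H3K4me3", "PolII")) {
      gsel <- which(safe_gene)
      pk <- c(pk, GenomicRanges::GRanges(
        gene_chrom[gsel],
        IRanges::IRanges(as.integer(gene_tss[gsel]) - 150L,
                         as.integer(gene_tss[gsel]) + 150L)))
    }
    marks[[m]] <- sort(pk)
  }

  imprinted <- GenomicRanges::GRanges(imp_chrom, IRanges::IRanges(imp_s, imp_e))

  ## background unspliced ESTs scattered outside all candidate exons, at a
  ## density giving roughly the configured null hit rate for a random span
  ## placed in the shuffleable (non-excluded) part of the genome
  est_w <- 600L
  ig_idx <- which(vapply(cands, function(x)
    x$destiny == "survivor" && identical(x$category, "intergenic"),
    logical(1)))
  mean_span <- mean(GenomicRanges::width(sp_all)[ig_idx])
  excl_len <- sum(GenomicRanges::width(GenomicRanges::reduce(
    c(unname(gene_spans(gs)), repeats), ignore.strand = TRUE)))
  valid_len <- sum(chrom_sizes) - excl_len
  n_bg <- round(log(1 / (1 - config$unspliced_null_rate)) *
                  valid_len / (mean_span + est_w))
  cand_zone <- GenomicRanges::reduce(c(
    GenomicRanges::GRanges(cand_chrom,
                           IRanges::IRanges(cand_off + 1,
                                            cand_off + vapply(cands, function(x)
                                              max(x$ex_end) + 1, numeric(1)))),
    GenomicRanges::GRanges(gene_chrom,
                           IRanges::IRanges(gene_off + 1,
                                            gene_off + vapply(genes, `[[`,
                                                              numeric(1), "width")))),
    ignore.strand = TRUE)
  bg_ch <- sample(chroms, 3 * n_bg, replace = TRUE,
                  prob = chrom_sizes / sum(chrom_sizes))
  bg_s <- as.integer(floor(stats::runif(3 * n_bg) *
                             (chrom_sizes[bg_ch] - est_w))) + 1L
  bg <- GenomicRanges::GRanges(bg_ch, IRanges::IRanges(bg_s, bg_s + est_w - 1L))
  bg <- bg[GenomicRanges::countOverlaps(bg, cand_zone,
                                        ignore.strand = TRUE) == 0L]
  bg <- utils::head(bg, n_bg)
  unspliced_est <- sort(c(unspliced_est, bg))

  ## background repeats in a sample of inter-item gap midpoints
  gap_mid <- item_off + item_width + item_gap / 2
  sel <- sample(seq_along(items), round(0.3 * length(items)))
  bg_rep <- GenomicRanges::GRanges(item_chrom[sel],
                                   IRanges::IRanges(as.integer(gap_mid[sel]) - 500L,
                                                    as.integer(gap_mid[sel]) + 499L))
  repeats <- sort(c(repeats, bg_rep))

  ## ---- gene expression --------------------------------------------------
  gene_expr <- list(
    coding = matrix(stats::rlnorm(n_g * n_stage, config$coding_meanlog,
                                  config$sdlog),
                    nrow = n_g,
                    dimnames = list(sprintf("G%04d", seq_len(n_g)),
                                    stage_names)),
    noncoding = matrix(stats::rlnorm(config$n_noncoding * n_stage,
                                     config$lnc_meanlog, config$sdlog),
                       nrow = config$n_noncoding,
                       dimnames = list(sprintf("N%04d",
                                               seq_len(config$n_noncoding)),
                                       stage_names)))

  ## ---- manifest ---------------------------------------------------------
  manifest <- data.frame(tx_id = all_ids, destiny = destiny,
                         category = category, stringsAsFactors = FALSE)
  for (f in names(flagged))
    manifest[[f]] <- manifest$tx_id %in% flagged[[f]]
  manifest$near_imprinted <- manifest$tx_id %in%
    cand_ids[vapply(cands, function(x) isTRUE(x$near_imprinted), logical(1))]
  manifest$host_gene <- c(vapply(cands, function(x)
    if (is.na(x$host)) NA_character_ else x$host, character(1)),
    rep(NA_character_, d[["duplicate"]]))
  manifest$host_intron_width <- c(vapply(cands, function(x)
    as.integer(x$host_intron), integer(1)), rep(NA_integer_, d[["duplicate"]]))
  manifest$partner_gene <- c(vapply(cands, function(x)
    if (is.na(x$partner)) NA_character_ else x$partner, character(1)),
    rep(NA_character_, d[["duplicate"]]))

  tracks <- list(
    spliced_est = annotation_track("spliced_est", sort(spliced_est), 1L),
    unspliced_est = annotation_track("unspliced_est", unspliced_est, NA_integer_),
    repeats = annotation_track("repeats", repeats),
    ribosome = annotation_track("ribosome", sort(ribosome)),
    cage = annotation_track("cage", sort(cage)),
    conservation = annotation_track("conservation", sort(cons)),
    imprinted = annotation_track("imprinted", imprinted),
    marks = lapply(marks, function(pk) annotation_track("mark", pk)))

  fx <- list(candidates = ts, genes = gs, tracks = tracks,
             chrom_sizes = chrom_sizes, gene_expr = gene_expr,
             manifest = manifest, config = config, seed = seed)
  class(fx) <- "lnc_fixture"
  if (!is.null(out_dir)) write_fixture(fx, out_dir)
  fx
}

within_list <- function(x, ...) {
  dots <- list(...)
  x[names(dots)] <- dots
  x
}

#' @export
print.lnc_fixture <- function(x, ...) {
  cat("<lnc_fixture> ", length(x$candidates), " candidates, ",
      length(x$genes), " reference genes, ",
      length(x$tracks) - 1L + length(x$tracks$marks), " tracks (seed ",
      x$seed, ")\n", sep = "")
  print(table(x$manifest$destiny))
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' GTF for candidates and reference genes, the transcript side table,
#' BED per annotation track, chromosome sizes, and the manifest as JSON.
#'
#' @param fx a fixture from \code{\link{generate_fixture}}.
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_fixture <- function(fx, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_transcripts_gtf(fx$candidates, p("candidates.gtf"),
                        p("candidates.tsv"))
  write_genes_gtf(fx$genes, p("genes.gtf"))
  for (nm in setdiff(names(fx$tracks), "marks"))
    write_bed(fx$tracks[[nm]], p(paste0(nm, ".bed")))
  for (m in names(fx$tracks$marks))
    write_bed(fx$tracks$marks[[m]], p(paste0("mark_", m, ".bed")))
  utils::write.table(data.frame(chrom = names(fx$chrom_sizes),
                                size = as.integer(fx$chrom_sizes)),
                     p("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(fx$manifest, p("manifest.json"), dataframe = "rows",
                       na = "null")
  invisible(out_dir)
}

#' Expected per-stage audit from a fixture manifest
#'
#' Tabulates the planted destinies in cascade order into the audit the
#' filter cascade must reproduce exactly.
#'
#' @param manifest the fixture manifest.
#' @return a \code{filter_audit} data.frame.
#' @export
manifest_expected_audit <- function(manifest) {
  order_ <- c("duplicate", "min_length", "single_exon", "expression",
              "class_code", "coding_potential", "classify",
              "coding_proximity")
  removed <- c(sum(manifest$destiny == "duplicate"),
               sum(manifest$destiny == "min_length"),
               sum(manifest$destiny == "single_exon"),
               sum(manifest$destiny == "expression"),
               sum(manifest$destiny == "class_code"),
               sum(manifest$destiny == "coding_potential"),
               0L,
               sum(manifest$destiny == "coding_proximity"))
  n_in <- nrow(manifest) - c(0L, cumsum(utils::head(removed, -1L)))
  stage <- c("merge", "min_length", "single_exon", "expression",
             "class_code", "coding_potential", "classify",
             "coding_proximity")
  new_audit(stage, as.integer(n_in), as.integer(n_in - removed))
}

#' Knockdown-screen fixture configuration
#'
#' Defaults emulate the screened array: 55 control profiles, 40 protein and
#' 226 lncRNA knockdown targets with two replicates each, 187 probes mapped
#' onto candidate lncRNA exons, and four planted protein regulators with
#' up/down effect sets of 81/2, 3/64, 62/2 and 0/47 lncRNAs shifted beyond
#' the 5th/95th control percentile band.
#'
#' @param n_controls number of control profiles.
#' @param n_protein,n_lncrna_targets target roster sizes (protein count
#'   includes the planted regulators).
#' @param n_replicates replicates per knockdown.
#' @param n_mapped_lnc number of lncRNAs carrying probes.
#' @param n_two_probe how many of those carry two probes (the rest one).
#' @param n_unmapped_probes probes mapping to no lncRNA.
#' @param regulators named list of planted effects,
#'   \code{list(name = c(up = ..., down = ...))}.
#' @param probe_width probe length in bp.
#' @param baseline_mean,baseline_sd per-probe baseline intensity
#'   distribution (log2 scale).
#' @param control_sd within-probe control variability.
#' @param margin shift beyond the percentile threshold for planted probes.
#' @param replicate_noise per-replicate noise sd on KD profiles (0 =
#'   noise-free).
#' @return an object of class \code{kd_config}.
#' @export
kd_config <- function(n_controls = 55, n_protein = 40,
                      n_lncrna_targets = 226, n_replicates = 2,
                      n_mapped_lnc = 180, n_two_probe = 7,
                      n_unmapped_probes = 13,
                      regulators = list(Sall4 = c(up = 81, down = 2),
                                        Suv39h2 = c(up = 3, down = 64),
                                        Iws1 = c(up = 62, down = 2),
                                        Ruvbl1 = c(up = 0, down = 47)),
                      probe_width = 60,
                      baseline_mean = 10, baseline_sd = 2,
                      control_sd = 0.5, margin = 1,
                      replicate_noise = 0.2) {
  stopifnot(n_controls >= 2, length(regulators) <= n_protein,
            all(vapply(regulators, sum, numeric(1)) <= n_mapped_lnc))
  structure(as.list(environment()), class = "kd_config")
}

#' Generate a knockdown microarray fixture
#'
#' Places probes inside exons of candidate lncRNAs, draws control profiles
#' per probe, and builds KD profiles that copy the per-probe control median
#' except for probes of planted effect lncRNAs, which are shifted beyond
#' the control percentile band by \code{margin}. With
#' \code{replicate_noise = 0} the planted calls are recovered exactly by
#' the percentile-threshold caller.
#'
#' @param lnc candidate lncRNAs (\code{lncrna_set} or
#'   \code{transcript_set}); probes are planted in their exons.
#' @param config a \code{\link{kd_config}}.
#' @param seed integer seed.
#' @return list with \code{experiment} (a \code{kd_experiment}),
#'   \code{manifest} (planted probe-lncRNA map and per-regulator up/down
#'   sets), and \code{config}.
#' @export
generate_kd_experiment <- function(lnc, config = kd_config(), seed = 1) {
  stopifnot(inherits(config, "kd_config"))
  set.seed(seed)
  ts <- as_transcript_set(lnc)
  w1 <- vapply(GenomicRanges::width(ts$exons), `[`, numeric(1), 1L)
  eligible <- which(w1 >= config$probe_width + 20L &
                      lengths(ts$exons) >= 2L)
  if (length(eligible) < config$n_mapped_lnc)
    stop("not enough candidate lncRNAs with probe-sized exons")
  mapped <- sort(sample(eligible, config$n_mapped_lnc))
  two <- sample(seq_along(mapped), config$n_two_probe)

  probe_ch <- character(0); probe_s <- integer(0); probe_lnc <- character(0)
  for (k in seq_along(mapped)) {
    i <- mapped[k]
    ex <- ts$exons[[i]]
    probe_ch <- c(probe_ch, as.character(GenomicRanges::seqnames(ex))[1L])
    probe_s <- c(probe_s, GenomicRanges::start(ex)[1L] + 5L)
    probe_lnc <- c(probe_lnc, tx_ids(ts)[i])
    if (k %in% two) {
      probe_ch <- c(probe_ch, as.character(GenomicRanges::seqnames(ex))[2L])
      probe_s <- c(probe_s, GenomicRanges::start(ex)[2L] + 5L)
      probe_lnc <- c(probe_lnc, tx_ids(ts)[i])
    }
  }
  ## background probes mapping to nothing (parked before the first feature)
  if (config$n_unmapped_probes > 0) {
    ch0 <- as.character(GenomicRanges::seqnames(tx_spans(ts)))[1L]
    probe_ch <- c(probe_ch,
                  rep(ch0, config$n_unmapped_probes))
    probe_s <- c(probe_s,
                 seq(1000L, by = config$probe_width + 40L,
                     length.out = config$n_unmapped_probes))
    probe_lnc <- c(probe_lnc, rep(NA_character_, config$n_unmapped_probes))
  }
  n_pr <- length(probe_ch)
  probe_ids <- sprintf("PR%04d", seq_len(n_pr))
  probes <- GenomicRanges::GRanges(
    probe_ch, IRanges::IRanges(probe_s,
                               probe_s + as.integer(config$probe_width) - 1L))
  names(probes) <- probe_ids

  baseline <- stats::rnorm(n_pr, config$baseline_mean, config$baseline_sd)
  controls <- matrix(baseline + stats::rnorm(n_pr * config$n_controls, 0,
                                             config$control_sd),
                     nrow = n_pr,
                     dimnames = list(probe_ids,
                                     sprintf("C%02d",
                                             seq_len(config$n_controls))))
  thr <- suppressMessages(control_percentile_thresholds(controls))
  ctrl_med <- apply(controls, 1, stats::median)

  n_extra <- length(config$regulators)
  prot <- c(names(config$regulators),
            sprintf("P%03d", seq_len(config$n_protein - n_extra)))
  lnct <- sprintf("L%03d", seq_len(config$n_lncrna_targets))
  targets <- data.frame(target = c(prot, lnct),
                        type = c(rep("protein", length(prot)),
                                 rep("lncRNA", length(lnct))),
                        stringsAsFactors = FALSE)

  mapped_lnc_ids <- unique(probe_lnc[!is.na(probe_lnc)])
  planted <- list()
  for (r in names(config$regulators)) {
    eff <- config$regulators[[r]]
    sel <- sample(mapped_lnc_ids, sum(eff))
    planted[[r]] <- list(up = sort(utils::head(sel, eff[["up"]])),
                         down = sort(utils::tail(sel, eff[["down"]])))
  }
  bad <- setdiff(unlist(lapply(planted, unlist)), mapped_lnc_ids)
  if (length(bad))
    stop("planted effects target unmapped lncRNAs: ",
         paste(bad, collapse = ", "))

  reps <- paste0("r", seq_len(config$n_replicates))
  cols <- as.vector(t(outer(targets$target, reps, paste, sep = "|")))
  kd <- matrix(rep(ctrl_med, length(cols)), nrow = n_pr,
               dimnames = list(probe_ids, cols))
  for (r in names(planted)) {
    up_pr <- probe_ids[probe_lnc %in% planted[[r]]$up]
    dn_pr <- probe_ids[probe_lnc %in% planted[[r]]$down]
    rc <- paste0(r, "|", reps)
    kd[up_pr, rc] <- thr$hi_value[match(up_pr, thr$probe)] + config$margin
    kd[dn_pr, rc] <- thr$lo_value[match(dn_pr, thr$probe)] - config$margin
  }
  if (config$replicate_noise > 0)
    kd <- kd + stats::rnorm(length(kd), 0, config$replicate_noise)

  exp_obj <- kd_experiment(probes, controls, kd, targets)
  truth_map <- data.frame(probe = probe_ids, tx_id = probe_lnc,
                          stringsAsFactors = FALSE)
  list(experiment = exp_obj,
       manifest = list(planted = planted,
                       probe_map = truth_map[!is.na(truth_map$tx_id), ]),
       config = config, seed = seed)
}
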