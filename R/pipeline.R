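#' Default pipeline configuration
#'
#' Returns the full configuration list understood by
#' \code{\link{run_pipeline}}: a \code{fixture} block (passed to
#' \code{\link{fixture_config}}), a \code{kd} block (passed to
#' \code{\link{kd_config}}), a \code{filter} block (passed to
#' \code{\link{filter_config}}) and top-level \code{seed} and \code{n_perm}.
#' Every threshold the pipeline applies is taken from here, so reports are
#' traceable to the configuration.
#'
#' @return nested configuration list.
#' @export
default_pipeline_config <- function() {
  list(seed = 1,
       n_perm = 1000,
       fixture = list(),
       kd = list(),
       filter = list())
}

.merge_config <- function(base, user, where = "config") {
  if (is.null(user)) return(base)
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown ", where, " key(s): ", paste(bad, collapse = ", "))
  base[names(user)] <- user
  base
}

#' Read a pipeline configuration file
#'
#' YAML with the structure of \code{\link{default_pipeline_config}};
#' unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- .merge_config(default_pipeline_config(), user)
  cfg
}

#' Run the full analysis pipeline on a simulated fixture
#'
#' Orchestrates simulate, filter, classify, characterize, permutation
#' tests, knockdown screen and enrichment-list construction, writing stage
#' artifacts under \code{out_dir}: the fixture bundle, the filter audit,
#' per-category candidate tables, the characterization report, permutation
#' results, knockdown calls and the run log. The candidate and track inputs
#' are re-read from the written bundle, so the run also exercises the
#' GTF/BED round trip.
#'
#' @param out_dir output directory.
#' @param config configuration list (see
#'   \code{\link{default_pipeline_config}}) or path to a YAML file.
#' @param seed overrides the configured seed when given.
#' @return list with the in-memory stage results (fixture, cascade,
#'   characterization, permutation results, kd summary, gene lists).
#' @export
run_pipeline <- function(out_dir, config = default_pipeline_config(),
                         seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- .merge_config(default_pipeline_config(), config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  ## simulate + write + read back
  fx_cfg <- do.call(fixture_config, config$fixture)
  fx <- generate_fixture(fx_cfg, seed = config$seed,
                         out_dir = p("fixtures"))
  cand <- read_transcripts_gtf(p("fixtures", "candidates.gtf"),
                               p("fixtures", "candidates.tsv"))
  genes <- read_genes_gtf(p("fixtures", "genes.gtf"))
  trk <- fx$tracks

  ## filter + classify
  fcfg <- do.call(filter_config, config$filter)
  casc <- run_filter_cascade(cand, genes, fcfg)
  utils::write.table(casc$audit, p("filter_audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lnc <- casc$lncrna
  utils::write.table(data.frame(tx_id = lnc$info$tx_id,
                                category = lnc$info$category),
                     p("categories.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## characterize
  ts <- lnc$transcripts
  stack <- annotate_by_priority(ts, list(trk$spliced_est,
                                         annotation_track("unspliced_est",
                                                          trk$unspliced_est$intervals,
                                                          2L)))
  est <- est_support(ts, trk$spliced_est, trk$unspliced_est)
  rep_fl <- repeat_overlap_flags(ts, trk$repeats)
  ribo <- ribosome_association(ts, trk$ribosome)
  cage_d <- cage_min_distances(ts, trk$cage)
  cons <- conservation_score(ts, trk$conservation)
  cmr <- chromatin_mark_rate(ts, lapply(trk$marks, `[[`, "intervals"))
  nn <- nearest_coding_gene(ts, genes)
  report <- data.frame(tx_id = tx_ids(ts),
                       category = lnc$info$category,
                       annotation = stack,
                       spliced_est = est$spliced,
                       unspliced_est = est$unspliced,
                       repeat_flag = rep_fl$flag,
                       ribosome_flag = ribo$flag,
                       cage_min_distance = cage_d,
                       conservation = cons,
                       nearest_gene = nn$gene_id,
                       nearest_gene_distance = nn$distance)
  report <- cbind(report, as.data.frame(cmr$flags))
  utils::write.table(report, p("characterization.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## permutation tests (intergenic candidates, exclusion-aware null)
  gsp <- unname(gene_spans(genes))
  exclusions <- c(unname(trk$repeats$intervals), gsp)
  ig <- lnc$transcripts[which(lnc$info$category == "intergenic")]
  imp_res <- imprinted_proximity_test(ig, trk$imprinted, fx$chrom_sizes,
                                      exclusions, n_perm = config$n_perm,
                                      seed = config$seed)
  est_res <- unspliced_est_overlap_test(ig, trk$unspliced_est,
                                        fx$chrom_sizes, exclusions,
                                        n_perm = config$n_perm,
                                        seed = config$seed + 1)
  cage_res <- cage_distance_test(ig, trk$cage, fx$chrom_sizes, exclusions,
                                 seed = config$seed + 2)
  perm_out <- list(
    imprinted = list(observed = imp_res$observed,
                     empirical_p = imp_res$empirical_p,
                     n_perm = imp_res$n_perm),
    unspliced_est = list(observed = est_res$observed,
                         empirical_p = est_res$empirical_p,
                         n_perm = est_res$n_perm),
    cage_rank_sum = list(U = cage_res$U, p = cage_res$p))
  jsonlite::write_json(perm_out, p("permutation_tests.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(data.frame(perm = seq_along(imp_res$permuted),
                                imprinted = imp_res$permuted,
                                unspliced_est = est_res$permuted),
                     p("permuted_statistics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## knockdown screen
  kd_cfg <- do.call(kd_config, config$kd)
  kd <- generate_kd_experiment(lnc, kd_cfg, seed = config$seed)
  pm <- map_probes_to_lncrnas(kd$experiment$probes, lnc)
  thr <- control_percentile_thresholds(kd$experiment$controls)
  kd_sum <- regulator_summary(kd$experiment, thr, pm,
                              kd$experiment$targets,
                              n_perm = min(200, config$n_perm),
                              seed = config$seed)
  utils::write.table(kd_sum$table, p("kd_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## enrichment gene lists
  lists <- list(closest = closest_gene_list(lnc, genes),
                host = host_gene_list(lnc),
                overlapping = overlapping_gene_list(lnc))
  jsonlite::write_json(lists, p("gene_lists.json"))

  ## run log: every applied threshold, traceable to the config
  log <- list(seed = config$seed, n_perm = config$n_perm,
              package_version = as.character(utils::packageVersion("lncforge")),
              filter = unclass(fcfg),
              expression_threshold_applied = casc$expression_threshold)
  yaml::write_yaml(log, p("run_log.yaml"))

  invisible(list(fixture = fx, cascade = casc, report = report,
                 imprinted_test = imp_res, unspliced_est_test = est_res,
                 cage_test = cage_res, kd = kd, kd_summary = kd_sum,
                 gene_lists = lists, config = config))
}
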