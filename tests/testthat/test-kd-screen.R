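# shared small KD world: probes mapped 1-1 onto synthetic lncRNA exons
kd_world <- function(seed = 71, n_probes = 200, n_controls = 55) {
  set.seed(seed)
  chains <- lapply(seq_len(n_probes), function(i) GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(i * 1000, i * 1000 + 200), strand = "+"))
  names(chains) <- sprintf("lnc%03d", seq_len(n_probes))
  ts <- transcript_set(chains)
  probes <- GenomicRanges::GRanges("chr1",
                                   IRanges::IRanges(seq_len(n_probes) * 1000 + 10,
                                                    width = 60))
  names(probes) <- sprintf("PR%03d", seq_len(n_probes))
  controls <- matrix(rnorm(n_probes * n_controls), n_probes,
                     dimnames = list(names(probes),
                                     sprintf("C%02d", seq_len(n_controls))))
  list(ts = ts, probes = probes, controls = controls)
}

test_that("probe mapping is strict at >99% exonic overlap", {
  ts <- mk_tx(list(c(1000, 1500)), list(c(3000, 3100), c(3101, 3300)))
  probes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(1100, 1441, 3071), width = 60))
  names(probes) <- c("in", "edge", "junction")
  pm <- map_probes_to_lncrnas(probes, ts)
  # "in": 60/60 inside an exon -> mapped
  expect_true("in" %in% pm$probe)
  # "edge": 1441..1500 fully inside -> mapped; shift by one exits
  probes2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1442, width = 60))
  names(probes2) <- "p59"
  expect_equal(nrow(map_probes_to_lncrnas(probes2, ts)), 0L)  # 59/60 = 0.983
  # book-ended exons: 100% exonic coverage across the junction -> mapped
  expect_true("junction" %in% pm$probe)
  expect_false(any(pm$ambiguous))
})

test_that("control thresholds are nearest-rank percentiles per probe", {
  controls <- matrix(1:55, 1, 55, dimnames = list("p1", NULL))
  thr <- control_percentile_thresholds(controls)
  expect_equal(thr$lo_value, 3)    # rank ceiling(0.05 * 55) = 3
  expect_equal(thr$hi_value, 53)   # rank ceiling(0.95 * 55) = 53
  expect_true(thr$callable)
  # sort-based oracle across random matrices
  w <- kd_world()
  thr2 <- control_percentile_thresholds(w$controls)
  for (i in sample(nrow(w$controls), 20)) {
    s <- sort(w$controls[i, ])
    expect_equal(thr2$lo_value[i], unname(s[ceiling(0.05 * 55)]))
    expect_equal(thr2$hi_value[i], unname(s[ceiling(0.95 * 55)]))
  }
  # constant probe is uncallable
  cc <- rbind(p1 = rep(1, 10), p2 = rnorm(10))
  expect_message(thr3 <- control_percentile_thresholds(cc), "constant")
  expect_false(thr3$callable[1])
  expect_true(thr3$callable[2])
})

test_that("replicate agreement rules drive the calls", {
  w <- kd_world()
  thr <- control_percentile_thresholds(w$controls)
  pm <- map_probes_to_lncrnas(w$probes, w$ts)
  hi1 <- thr$hi_value[1]
  kd <- matrix(rep(apply(w$controls, 1, median), 4), nrow(w$controls),
               dimnames = list(rownames(w$controls),
                               c("T1|r1", "T1|r2", "T2|r1", "T2|r2")))
  kd[1, c("T1|r1", "T1|r2")] <- hi1 + 1          # both above
  kd[1, c("T2|r1", "T2|r2")] <- c(hi1 + 1, hi1 - 1)  # inconsistent
  calls <- call_regulation(kd, thr, pm)
  expect_equal(calls$calls$T1$up, pm$tx_id[pm$probe == rownames(kd)[1]])
  expect_equal(length(calls$calls$T2$up), 0L)
  # mean rule accepts the inconsistent pair when the mean clears the bar
  kd[1, c("T2|r1", "T2|r2")] <- c(hi1 + 3, hi1 - 0.5)
  calls_m <- call_regulation(kd, thr, pm, replicate_rule = "mean")
  expect_equal(length(calls_m$calls$T2$up), 1L)
})

test_that("fresh control-like profiles call at about lo% + (100-hi)%", {
  w <- kd_world(seed = 72)
  thr <- control_percentile_thresholds(w$controls)
  pm <- map_probes_to_lncrnas(w$probes, w$ts)
  set.seed(73)
  pseudo <- matrix(rnorm(nrow(w$controls) * 20), nrow(w$controls),
                   dimnames = list(rownames(w$controls),
                                   paste0("S", 1:20, "|r1")))
  calls <- call_regulation(pseudo, thr, pm, replicate_rule = "mean")
  n_calls <- sum(affected_counts(calls)$affected)
  n_tests <- nrow(w$controls) * 20
  # expected rate for a fresh draw vs order statistics of 55: 6/56
  p_exp <- 6 / 56
  expect_gt(n_calls, qbinom(0.0005, n_tests, p_exp))
  expect_lt(n_calls, qbinom(0.9995, n_tests, p_exp))
})

test_that("the planted KD fixture is recovered exactly without noise", {
  fx <- cached_fixture()
  lnc <- cached_cascade()$lncrna
  kd <- generate_kd_experiment(lnc, kd_config(replicate_noise = 0), seed = 2)
  pm <- map_probes_to_lncrnas(kd$experiment$probes, lnc)
  # probe map equals the planted truth
  truth <- kd$manifest$probe_map
  expect_equal(pm[order(pm$probe), c("probe", "tx_id")],
               truth[order(truth$probe), ], ignore_attr = TRUE)
  thr <- control_percentile_thresholds(kd$experiment$controls)
  calls <- call_regulation(kd$experiment, thr, pm)
  for (r in names(kd$manifest$planted)) {
    expect_setequal(calls$calls[[r]]$up, kd$manifest$planted[[r]]$up)
    expect_setequal(calls$calls[[r]]$down, kd$manifest$planted[[r]]$down)
  }
  ac <- affected_counts(calls)
  others <- setdiff(ac$target, names(kd$manifest$planted))
  expect_equal(sum(ac$affected[match(others, ac$target)]), 0L)
})

test_that("planted counts survive the configured replicate noise within 10%", {
  fx <- cached_fixture()
  lnc <- cached_cascade()$lncrna
  kd <- generate_kd_experiment(lnc, kd_config(), seed = 2)  # default noise
  pm <- map_probes_to_lncrnas(kd$experiment$probes, lnc)
  thr <- control_percentile_thresholds(kd$experiment$controls)
  calls <- call_regulation(kd$experiment, thr, pm)
  for (r in names(kd$manifest$planted)) {
    want <- length(kd$manifest$planted[[r]]$up) +
      length(kd$manifest$planted[[r]]$down)
    got <- length(calls$calls[[r]]$up) + length(calls$calls[[r]]$down)
    expect_lte(abs(got - want), max(1, ceiling(0.1 * want)))
  }
})

test_that("regulator summary ranks planted regulators and is seed-stable", {
  lnc <- cached_cascade()$lncrna
  kd <- generate_kd_experiment(lnc, kd_config(replicate_noise = 0), seed = 2)
  pm <- map_probes_to_lncrnas(kd$experiment$probes, lnc)
  thr <- control_percentile_thresholds(kd$experiment$controls)
  s1 <- regulator_summary(kd$experiment, thr, pm, kd$experiment$targets,
                          n_perm = 50, seed = 4)
  expect_equal(s1$table$target[1], "Sall4")
  expect_equal(s1$table$affected[1], 83L)
  expect_equal(unname(s1$group_means["lncRNA"]), 0)
  s2 <- regulator_summary(kd$experiment, thr, pm, kd$experiment$targets,
                          n_perm = 50, seed = 4)
  expect_identical(s1$table, s2$table)
})
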