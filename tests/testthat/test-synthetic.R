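# synthetic-data generators: exact ground truth, seeded determinism,
# quantile-matched cohorts

test_that("synthetic AP trace is seeded-deterministic and annotated exactly", {
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6, noise_sd = 0.3,
                              seed = 42)
  t1 <- synth_ap_trace(spec, dt = 0.02)
  t2 <- synth_ap_trace(spec, dt = 0.02)
  expect_identical(t1$v_soma, t2$v_soma)
  # different seed, different trace
  t3 <- synth_ap_trace(synthetic_cell_spec(threshold = -38.9, peak = 15.6,
                                           noise_sd = 0.3, seed = 43), dt = 0.02)
  expect_false(identical(t1$v_soma, t3$v_soma))
  # the generator does not disturb the global RNG stream
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(synth_ap_trace(spec, dt = 0.05)); after <- runif(1)
  expect_identical(before, after)
  # ground truth annotations carry the programmed values
  gt <- t1$meta$ground_truth[[1]]
  expect_equal(gt$v, -38.9, tolerance = 1e-6)
  expect_equal(gt$v_peak, 15.6, tolerance = 0.2)
})

test_that("trace with no AP segment yields empty detection", {
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6)
  tr <- synth_ap_trace(spec, dt = 0.02, n_aps = 0, total_ms = 80)
  expect_equal(nrow(detect_aps(tr)), 0)
})

test_that("dt coarser than the upstroke is rejected", {
  # a threshold very close to the plateau forces a narrow upstroke foot
  spec <- synthetic_cell_spec(threshold = -38.9, peak = 15.6,
                              plateau_dv = 30.2)
  expect_error(synth_ap_trace(spec, dt = 0.1), "dt too coarse")
})

test_that("passive generator round-trips Rin and tau through the measurers", {
  tr <- synth_passive_trace(rin = 187.9, tau = 6.65, step_pA = 40)
  expect_equal(as.numeric(measure_rin(tr)), 187.9, tolerance = 0.01)
  expect_equal(as.numeric(measure_tau(tr)), 6.65, tolerance = 0.01)
  # zero step: flat trace
  flat <- synth_passive_trace(rin = 100, tau = 5, step_pA = 0)
  expect_true(all(flat$v_soma == -70))
  # Monte-Carlo: noisy tau recovery is nearly unbiased
  taus <- vapply(1:50, function(s)
    as.numeric(measure_tau(synth_passive_trace(187.9, 6.65, 50,
                                               noise_sd = 0.2, seed = s))),
    numeric(1))
  expect_lt(abs(mean(taus) - 6.65) / 6.65, 0.02)
})

test_that("cohort generator matches requested median and quartiles", {
  tg <- cohort_targets("human")
  coh <- synth_cohort(10000, tg, seed = 1)
  expect_equal(nrow(coh), 10000)
  thr <- coh$threshold
  expect_lt(abs(median(thr) - (-38.9)), 0.2)
  q <- unname(quantile(thr, c(0.25, 0.75)))
  expect_lt(abs(q[1] - (-42.8)), 0.4)
  expect_lt(abs(q[2] - (-34.2)), 0.4)
  # every feature matches its own quantile triple within sampling error
  for (i in seq_len(nrow(tg))) {
    x <- coh[[tg$feature[i]]]
    iqr <- tg$q3[i] - tg$q1[i]
    expect_lt(abs(median(x) - tg$median[i]) / iqr, 0.05)
    expect_lt(abs(quantile(x, 0.25) - tg$q1[i]) / iqr, 0.08)
    expect_lt(abs(quantile(x, 0.75) - tg$q3[i]) / iqr, 0.08)
  }
  # two seeds: different draws, same target quantiles
  coh2 <- synth_cohort(10000, tg, seed = 2)
  expect_false(identical(coh$threshold, coh2$threshold))
  expect_lt(abs(median(coh2$threshold) - (-38.9)), 0.3)
  # n = 1: single row
  expect_equal(nrow(synth_cohort(1, tg, seed = 3)), 1)
  # unordered quantiles rejected
  bad <- tg; bad$q1[1] <- bad$q3[1]
  expect_error(synth_cohort(10, bad, seed = 1), "unordered|ordered")
})

test_that("end-to-end: features recover generator ground truth on random specs", {
  set.seed(99)
  n_ok <- 0
  for (i in 1:100) {
    thr <- runif(1, -45, -33)
    pk <- runif(1, 5, 30)
    spec <- synthetic_cell_spec(threshold = thr, peak = pk,
                                ahp_depth = runif(1, 12, 24),
                                rise_w = runif(1, 0.08, 0.2),
                                noise_sd = 0, seed = i)
    tr <- synth_ap_trace(spec, dt = 0.02)
    fx <- trace_features(tr)
    expect_equal(fx$threshold, thr, tolerance = 0.25)
    expect_equal(fx$peak, pk, tolerance = 0.2)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})
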