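test_that("generators are bit-identical for a fixed seed", {
  a <- simulate_creep(ref_params(), noise = noise_spec(scale = 0.02, seed = 5))
  b <- simulate_creep(ref_params(), noise = noise_spec(scale = 0.02, seed = 5))
  expect_identical(a$lengths, b$lengths)
  ca <- simulate_indentation(1721, noise = noise_spec(scale = 0.02, seed = 5))
  cb <- simulate_indentation(1721, noise = noise_spec(scale = 0.02, seed = 5))
  expect_identical(ca$load, cb$load)
  ta <- simulate_trajectories(3, walk_spec(seed = 5))
  tb <- simulate_trajectories(3, walk_spec(seed = 5))
  expect_identical(ta[[2]]$xs, tb[[2]]$xs)
})

test_that("zero-noise generators reproduce the forward models exactly", {
  rec <- ref_creep()
  expect_equal(rec$lengths,
               sls_forward(ref_params(), rec$delta_p, rec$rp, rec$times),
               tolerance = 1e-15)
  cur <- simulate_indentation(1721, noise = noise_spec(scale = 0))
  gt <- attr(cur, "ground_truth")
  delta <- pmax(cur$depth - gt$contact_offset, 0)
  expect_equal(cur$load, hertz_force(1721, cur$instrument$tip_radius, delta),
               tolerance = 1e-15)
})

test_that("generators carry ground truth for recovery assertions", {
  rec <- ref_creep()
  expect_equal(attr(rec, "ground_truth")$params$k1, 200)
  cur <- simulate_indentation(1113, noise = noise_spec(scale = 0))
  expect_equal(attr(cur, "ground_truth")$e_reduced, 1113)
  expect_equal(attr(cur, "ground_truth")$contact_index, 51L)
  tr <- simulate_trajectories(1, walk_spec(drift_fraction = 0.7, seed = 2))[[1]]
  expect_equal(attr(tr, "ground_truth")$drift_fraction, 0.7)
})

test_that("injected noise RMS matches its specification", {
  # 2% of the signal ceiling, 200 samples: the sample RMS of the injected
  # noise is chi-distributed around 2%, well inside [1.6%, 2.4%]
  rec <- simulate_creep(ref_params(), ref_dp, ref_rp, n_points = 200, t_max = 45,
                        noise = noise_spec("additive_gaussian", 0.02, seed = 13))
  clean <- sls_forward(ref_params(), ref_dp, ref_rp, rec$times)
  rms <- sqrt(mean((rec$lengths - clean)^2)) / max(clean)
  expect_gt(rms, 0.016)
  expect_lt(rms, 0.024)
})

test_that("creep generator warns on short windows and rejects tiny records", {
  expect_warning(simulate_creep(ref_params(), t_max = 2 * ref_tau,
                                noise = noiseless()),
                 "time constants")
  expect_error(simulate_creep(ref_params(), n_points = 3),
               class = "cellmech_insufficient_samples")
})

test_that("indentation generator validates its geometry", {
  expect_error(simulate_indentation(1721, baseline_points = 50, contact_offset = 0),
               class = "cellmech_degenerate_curve")
  cur <- simulate_indentation(1721, baseline_points = 0, contact_offset = 0,
                              noise = noise_spec(scale = 0))
  expect_equal(attr(cur, "ground_truth")$contact_index, 1L)
})

test_that("pure drift gives perfect directionality; no drift averages to zero", {
  drifty <- simulate_trajectories(5, walk_spec(drift_fraction = 1, seed = 3))
  for (tr in drifty) expect_equal(track_metrics(tr)$directionality, 1, tolerance = 1e-12)
  free <- simulate_trajectories(200, walk_spec(drift_fraction = 0, seed = 4))
  mean_dir <- mean(vapply(free, function(tr) track_metrics(tr)$directionality,
                          numeric(1)))
  expect_lt(abs(mean_dir), 0.05)
})

test_that("persistence increases net displacement at matched speed", {
  pers <- simulate_trajectories(100, walk_spec(drift_fraction = 0,
                                               persistence = 0.8, seed = 6))
  brown <- simulate_trajectories(100, walk_spec(drift_fraction = 0,
                                                persistence = 0, seed = 6))
  net <- function(trs) mean(vapply(trs, function(tr) track_metrics(tr)$net_displacement,
                                   numeric(1)))
  expect_gt(net(pers), net(brown))
})

test_that("mechanics cohorts honor their group structure", {
  # cv = 0: all cells identical to the group mean
  coh <- simulate_cohort_mechanics(list(ctrl = list(mean = 1721, cv = 0, n = 4)),
                                   seed = 1, noise_scale = 0)
  truths <- attr(coh$ctrl, "group_truth")
  expect_equal(truths, rep(1721, 4))
  es <- vapply(coh$ctrl, function(cur) fit_hertz(cur)$e_reduced, numeric(1))
  expect_equal(es, rep(es[1], 4), tolerance = 1e-9)
  # log-normal draws average to the group mean (law of large numbers check)
  coh2 <- simulate_cohort_mechanics(list(g = list(mean = 1721, cv = 0.3, n = 400)),
                                    seed = 2, noise_scale = 0)
  expect_lt(rel_err(mean(attr(coh2$g, "group_truth")), 1721), 0.05)
})

test_that("well-separated cohorts always order correctly after fitting", {
  for (seed in 1:10) {
    coh <- simulate_cohort_mechanics(
      list(ctrl = list(mean = 1721, cv = 0.3, n = 8),
           lps = list(mean = 4838, cv = 0.3, n = 8)),
      seed = seed, noise_scale = 0.02)
    fits <- lapply(coh, function(g) vapply(g, function(cur) fit_hertz(cur)$e_reduced,
                                           numeric(1)))
    expect_gt(mean(fits$lps), mean(fits$ctrl))
  }
})

test_that("equal-spec cohorts are statistically indistinguishable", {
  # null calibration: two groups drawn from the same spec should fail a
  # t-test at alpha = 0.05 in about 95% of seeds (here >= 43/50)
  n_null <- 0L
  for (seed in 1:50) {
    coh <- simulate_cohort_mechanics(
      list(a = list(mean = 1721, cv = 0.2, n = 10),
           b = list(mean = 1721, cv = 0.2, n = 10)),
      seed = 100 + seed, noise_scale = 0.02)
    fits <- lapply(coh, function(g) vapply(g, function(cur) fit_hertz(cur)$e_reduced,
                                           numeric(1)))
    if (stats::t.test(fits$a, fits$b)$p.value > 0.05) n_null <- n_null + 1L
  }
  expect_gte(n_null, 43L)
})
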