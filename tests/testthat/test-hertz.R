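test_that("Hertz force law matches scalar evaluation and scaling laws", {
  # (4/3) * 1000 * sqrt(4.5e-6) * (2e-6)^1.5 = 8.0 nN exactly
  expect_equal(hertz_force(1000, 4.5e-6, 2e-6), 8e-9, tolerance = 1e-12)
  expect_equal(hertz_force(1000, 4.5e-6, 0), 0)
  d <- c(0.5, 1, 2, 4) * 1e-6
  expect_equal(hertz_force(1000, 9e-6, 2 * d) / hertz_force(1000, 9e-6, d),
               rep(2^1.5, 4), tolerance = 1e-12)
  expect_error(hertz_force(1000, 9e-6, -1e-6), class = "cellmech_domain_error")
})

test_that("raw-curve reduction applies cantilever mechanics and is idempotent", {
  # deflection 100 nm at 0.048 N/m is 4.8 nN
  inst <- instrument_config()
  z <- seq(0, 6e-6, length.out = 50)
  d <- rep(100e-9, 50)
  cur <- indentation_curve(z = z, d = d, mode = "raw", instrument = inst)
  red <- reduce_raw(cur)
  expect_equal(red$load, rep(4.8e-9, 50), tolerance = 1e-15)
  expect_equal(red$depth, z - d, tolerance = 1e-15)
  expect_message(again <- reduce_raw(red), "already in reduced mode")
  expect_identical(again$load, red$load)
  # zero deflection: no contact, zero load, depth equals piezo position
  cur0 <- indentation_curve(z = z, d = rep(0, 50), mode = "raw", instrument = inst)
  red0 <- reduce_raw(cur0)
  expect_equal(red0$load, rep(0, 50))
  expect_equal(red0$depth, z)
})

test_that("simulated raw curves round-trip through reduction exactly", {
  cur_red <- simulate_indentation(1721, noise = noise_spec(scale = 0))
  cur_raw <- simulate_indentation(1721, noise = noise_spec(scale = 0), mode = "raw")
  back <- reduce_raw(cur_raw)
  expect_equal(back$depth, cur_red$depth, tolerance = 1e-12)
  expect_equal(back$load, cur_red$load, tolerance = 1e-12)
})

test_that("contact detection finds the exact sample on noiseless curves", {
  cur <- simulate_indentation(1721, noise = noise_spec(scale = 0),
                              baseline_points = 50, contact_offset = 0.5e-6)
  cp <- detect_contact_point(cur)
  expect_identical(cp$contact_index, attr(cur, "ground_truth")$contact_index)
  expect_lt(abs(cp$baseline_force), 1e-15)
  # contact at the first sample when there is no pre-contact travel
  cur0 <- simulate_indentation(1721, noise = noise_spec(scale = 0),
                               baseline_points = 0, contact_offset = 0)
  cp0 <- detect_contact_point(cur0)
  expect_lte(cp0$contact_index, 2L)
})

test_that("a contact-free noise trace raises a no-contact error", {
  set.seed(5)
  inst <- instrument_config()
  cur <- indentation_curve(depth = seq(0, 5e-6, length.out = 100),
                           load = rnorm(100, 0, 1e-9), instrument = inst)
  expect_error(detect_contact_point(cur), class = "cellmech_no_contact")
})

test_that("contact detection under noise stays within the calibrated window", {
  # Calibrated at 2% additive load noise (100 seeded replicates): the
  # force signal within a couple of samples of contact is ~1e-3 of the
  # noise sd, so sample-exact localization is impossible; the detector
  # stays within +-5 samples in >=90% of replicates and the downstream
  # modulus error stays below 5%.
  n_win <- 0L; n_rep <- 50L; e_err <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    cur <- simulate_indentation(1721,
                                noise = noise_spec("additive_gaussian", 0.02, seed = 2000 + i))
    cp <- detect_contact_point(cur)
    if (abs(cp$contact_index - 51L) <= 5) n_win <- n_win + 1L
    e_err[i] <- rel_err(fit_hertz(cur, contact = cp)$e_reduced, 1721)
  }
  expect_gte(n_win, 0.9 * n_rep)
  expect_lt(max(e_err), 0.05)
})

test_that("Hertz fit recovers the generating modulus and obeys scaling", {
  cur <- simulate_indentation(1721, noise = noise_spec(scale = 0))
  f <- fit_hertz(cur)
  expect_true(f$converged)
  expect_lt(rel_err(f$e_reduced, 1721), 1e-3)
  # linearity in load
  cur2 <- cur; cur2$load <- 2 * cur$load
  expect_equal(fit_hertz(cur2)$e_reduced, 2 * f$e_reduced, tolerance = 1e-6)
  # depth rescaling at fixed loads: E scales by 2^(-3/2)
  cur3 <- cur; cur3$depth <- 2 * cur$depth
  expect_equal(fit_hertz(cur3)$e_reduced, f$e_reduced * 2^-1.5, tolerance = 1e-3)
})

test_that("linearized Hertz fit equals brute-force nonlinear minimization", {
  set.seed(31)
  es <- rlnorm(20, log(1721), 0.5)
  for (e in es) {
    cur <- simulate_indentation(e, noise = noise_spec(scale = 0))
    cp <- detect_contact_point(cur)
    f <- fit_hertz(cur, contact = cp)
    # independent route: golden-section/parabolic search on the sum of
    # squares of the nonlinear model over the same post-contact samples
    delta <- cur$depth - cp$contact_position
    use <- delta > 0
    ss <- function(E) sum((cur$load[use] - cp$baseline_force -
                             hertz_force(E, cur$instrument$tip_radius, delta[use]))^2)
    brute <- stats::optimize(ss, interval = c(e / 10, e * 10), tol = 1e-10 * e)
    expect_lt(rel_err(f$e_reduced, brute$minimum), 1e-9)
  }
})

test_that("forcing a late contact point biases the modulus monotonically", {
  cur <- simulate_indentation(1721, noise = noise_spec(scale = 0))
  cp <- detect_contact_point(cur)
  biased <- sapply(c(0L, 5L, 10L, 20L), function(s) {
    shifted <- list(contact_index = cp$contact_index + s,
                    contact_position = cur$depth[cp$contact_index + s],
                    baseline_force = 0)
    fit_hertz(cur, contact = shifted)$e_reduced
  })
  expect_true(all(diff(biased) > 0))  # late contact inflates E*
})

test_that("restricting the depth range still identifies the modulus", {
  cur <- simulate_indentation(1721, noise = noise_spec(scale = 0))
  f_half <- fit_hertz(cur, depth_fraction = 0.5)
  expect_lt(rel_err(f_half$e_reduced, 1721), 1e-3)
  expect_lte(f_half$fit_depth_range[2], 0.5 * 5e-6 + 1e-12)
  expect_error(fit_hertz(cur, depth_fraction = 0),
               class = "cellmech_invalid_parameter")
})

test_that("too few post-contact samples raise an insufficient-data error", {
  inst <- instrument_config()
  pos <- seq(0, 5e-6, length.out = 40)
  load <- c(rep(0, 36), hertz_force(1721, inst$tip_radius,
                                    pos[37:40] - pos[36]))
  cur <- indentation_curve(depth = pos, load = load, instrument = inst)
  cp <- list(contact_index = 36L, contact_position = pos[36], baseline_force = 0)
  expect_error(fit_hertz(cur, contact = cp, depth_fraction = 0.5),
               class = "cellmech_insufficient_data")
})

test_that("full pipeline recovers the modulus within 5% at 3% load noise", {
  errs <- sapply(1:100, function(i) {
    cur <- simulate_indentation(1721,
                                noise = noise_spec("additive_gaussian", 0.03, seed = 3000 + i))
    rel_err(fit_hertz(cur)$e_reduced, 1721)
  })
  expect_lt(median(errs), 0.05)
})

test_that("reduced-to-Young conversion is explicit about Poisson ratio", {
  expect_equal(young_from_reduced(1000, nu = 0.5), 750)
  expect_equal(young_from_reduced(1000, nu = 0), 1000)
  expect_error(young_from_reduced(1000, nu = 1), class = "cellmech_invalid_parameter")
})

test_that("modulus aggregation mirrors per-group mean +- SEM reporting", {
  set.seed(1)
  vals <- rnorm(25, 1721, 0.1 * 1721)
  fits <- lapply(vals, function(v) structure(list(e_reduced = v, converged = TRUE),
                                             class = "hertz_fit"))
  tab <- aggregate_moduli(fits, rep("ctrl", 25))
  expect_equal(tab$n, 25)
  expect_lt(abs(tab$mean_pa - 1721), 2 * tab$sem_pa)
  # a single fit has an undefined SEM, not an error
  tab1 <- aggregate_moduli(fits[1], "solo")
  expect_equal(tab1$mean_pa, vals[1])
  expect_true(is.na(tab1$sem_pa))
  # identical groups produce identical rows; non-converged fits are counted
  fits2 <- c(fits, fits)
  tab2 <- aggregate_moduli(fits2, rep(c("a", "b"), each = 25))
  expect_equal(tab2$mean_pa[1], tab2$mean_pa[2])
  expect_equal(tab2$sem_pa[1], tab2$sem_pa[2])
  fits3 <- c(fits, list(structure(list(e_reduced = NA_real_, converged = FALSE),
                                  class = "hertz_fit")))
  tab3 <- aggregate_moduli(fits3, rep("ctrl", 26))
  expect_equal(tab3$n, 25)
  expect_equal(tab3$n_excluded, 1)
})
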