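lam1 <- model_spec("model1", rates = lambda_rates())

test_that("ratiometric FRET efficiency with crosstalk correction", {
  expect_equal(compute_fret(300, 300), 0.5)
  expect_equal(compute_fret(500, 0), 0)
  expect_equal(compute_fret(0, 500), 1)
  expect_equal(compute_fret(300, 300, crosstalk = 0.1), 270 / 570)
  # over-corrected acceptor clips at zero rather than going negative
  expect_equal(compute_fret(1000, 50, crosstalk = 0.2), 0)
  expect_true(is.na(compute_fret(0, 0)))
  expect_equal(compute_fret(c(300, 0), c(300, 0)), c(0.5, NA))
  expect_error(compute_fret(-1, 5), "non-negative")
})

test_that("velocity readout: exact fixture, degenerate trace, noisy recovery", {
  # noise-free ramp covering 20 nt in exactly 2 s, thresholds 0/1
  t <- seq(0.05, 6, by = 0.1)
  fret <- approx(c(0, 1, 3, 6), c(0.26, 0.26, 0.53, 0.53), xout = t)$y
  tr <- structure(data.frame(time_s = t, fret = fret),
                  class = c("fret_trace", "data.frame"))
  v <- measure_velocity_from_trace(tr, low_frac = 0, high_frac = 1,
                                   E_min = 0.26, E_max = 0.53, n_sites = 20,
                                   smooth = 1)
  expect_equal(v, 10, tolerance = 0.06)  # frame-centre discretization
  # a trace stuck at baseline yields the no-event marker
  stuck <- structure(data.frame(time_s = t, fret = rep(0.26, length(t))),
                     class = c("fret_trace", "data.frame"))
  expect_true(is.na(measure_velocity_from_trace(stuck, E_min = 0.26,
                                                E_max = 0.53, n_sites = 20)))
  # noisy synthetic traces at 3 mM: mean estimate within 10% of E[N/tau]
  v_hat <- withr::with_seed(21, vapply(1:500, function(i) {
    measure_velocity_from_trace(trajectory_to_fret(
      simulate_trajectory(lam1, 3)))
  }, numeric(1)))
  expect_lt(sum(is.na(v_hat)) / 500, 0.02)
  expect_lt(abs(mean(v_hat, na.rm = TRUE) * tau1(lam1, 3) - 1), 0.10)
})

test_that("velocity-curve fits: round trips, nested limit, scale consistency", {
  grid <- mg_concentrations()
  v <- vapply(grid, function(c0) mean_velocity(lam1, c0), numeric(1))
  d <- data.frame(mg_mM = grid, mean = v)
  f1 <- fit_velocity_curve(d, "model1")
  expect_true(f1$converged)
  expect_equal(f1$par[["kB_off"]], 18, tolerance = 1e-3)
  expect_equal(f1$par[["K_B"]], 0.71, tolerance = 1e-3)
  expect_equal(f1$par[["K_A"]], 0.30, tolerance = 1e-3)
  # Hill fit to a two-site curve shows intermediate cooperativity
  fh <- fit_velocity_curve(d, "hill")
  expect_gt(fh$par[["n"]], 1)
  expect_lt(fh$par[["n"]], 2)
  # K_A -> 0: the mechanistic fit degenerates to Michaelis-Menten
  r0 <- rate_constants(18, 25.35, 1e-10, 0.333)
  v0 <- vapply(grid, function(c0)
    mean_velocity(model_spec("model1", rates = r0), c0), numeric(1))
  d0 <- data.frame(mg_mM = grid, mean = v0)
  fmm <- fit_velocity_curve(d0, "mm")
  f10 <- fit_velocity_curve(d0, "model1")
  expect_lt(abs(f10$rss - fmm$rss), 1e-8 + 0.01 * max(fmm$rss, 1e-12))
  # scale consistency: velocities x a rescale only the plateau parameter
  d3 <- data.frame(mg_mM = grid, mean = 3.7 * v)
  f3 <- fit_velocity_curve(d3, "model1")
  expect_equal(f3$par[["kB_off"]], 3.7 * f1$par[["kB_off"]], tolerance = 1e-4)
  expect_equal(f3$par[["K_B"]], f1$par[["K_B"]], tolerance = 1e-4)
  expect_equal(f3$par[["K_A"]], f1$par[["K_A"]], tolerance = 1e-4)
  fh3 <- fit_velocity_curve(d3, "hill")
  expect_equal(fh3$par[["n"]], fh$par[["n"]], tolerance = 1e-4)
  expect_error(fit_velocity_curve(d[1:2, ], "model1"), "distinct")
})

test_that("model-1 refits of noisy datasets recover parameters at scale", {
  grid <- mg_concentrations()
  v <- vapply(grid, function(c0) mean_velocity(lam1, c0), numeric(1))
  est <- withr::with_seed(31, t(vapply(1:30, function(i) {
    noisy <- v * (1 + rnorm(length(v), 0, 0.03))  # SEM-level noise
    f <- fit_velocity_curve(data.frame(mg_mM = grid, mean = noisy), "model1")
    f$par
  }, numeric(3))))
  bias <- apply(est, 2, stats::median) / c(18, 0.71, 0.30) - 1
  expect_true(all(abs(bias) < 0.05))
})

test_that("disorder-width estimation recovers a lognormal spread", {
  zsd <- 0.5 * log10(exp(1))
  v <- withr::with_seed(41, 10^rnorm(5000, log10(5), zsd))
  s <- estimate_sigma(v)
  expect_equal(s$sigma_kBT, 0.5, tolerance = 0.05)
  expect_equal(s$sigma_zeta, zsd, tolerance = 0.05)
  # intrinsic-width correction in quadrature
  s2 <- estimate_sigma(v, intrinsic_sd_zeta = zsd / 2)
  expect_equal(s2$sigma_zeta_corrected, sqrt(s$sigma_zeta^2 - zsd^2 / 4),
               tolerance = 1e-10)
  expect_warning(sdeg <- estimate_sigma(rep(2, 30)), "identical")
  expect_equal(sdeg$sigma_kBT, 0)
  expect_error(estimate_sigma(1:10), "at least 20")
  # disorder-free simulation still shows intrinsic stochastic width
  v0 <- withr::with_seed(42, vapply(1:100, function(i)
    20 / simulate_trajectory(lam1, 0.3)$tau, numeric(1)))
  expect_gt(estimate_sigma(v0)$sigma_kBT, 0.05)
})

test_that("log-velocity histograms: normalization and CME prediction", {
  edges <- seq(-3, 2, by = 0.1)
  h <- logv_histogram(c(0.5, 1, 2, 4, 8), edges)
  expect_equal(sum(h$prob), 1)
  expect_equal(h$n, 5L)
  expect_warning(logv_histogram(c(1, 1e5), edges), "outside")
  # sharp distribution falls into a single bin
  hs <- logv_histogram(rep(3.2, 50), edges)
  expect_equal(max(hs$prob), 1)
  # predicted bin masses sum to the captured density mass
  dis <- disorder_spec(sigma = 0.3, n_draws = 400)
  ph <- predict_logV_histogram(lam1, 0.3, dis, edges)
  zp <- logV_transform(disorder_average_pdf(lam1, 0.3, dis))
  expect_equal(sum(ph$prob), trapz_o(zp$x, zp$density), tolerance = 1e-6)
  # and track the empirical histogram of simulated velocities
  ds <- synth_velocity_dataset(lam1, 0.3, n_traces = 800,
                               disorder = disorder_spec(sigma = 0.3),
                               seed = 55)
  he <- logv_histogram(ds$velocity_nt_s, edges)
  se_bin <- sqrt(ph$prob * (1 - ph$prob) / 800)
  expect_lt(max(abs(he$prob - ph$prob) - 3 * se_bin - 0.01), 0)
})

test_that("kA_off grid search is deterministic and order-invariant", {
  edges <- seq(-3, 2, by = 0.1)
  dis <- disorder_spec(sigma = 0.4, n_draws = 300)
  obs <- lapply(stats::setNames(nm = c("0.1", "1")), function(m)
    predict_logV_histogram(lam1, as.numeric(m), dis, edges))
  e1 <- estimate_kAoff(c(0.01, 0.1, 1), obs, lambda_rates(), dis)
  e2 <- estimate_kAoff(c(1, 0.01, 0.1), obs, lambda_rates(), dis)
  expect_identical(e1$mse, e2$mse)
  expect_identical(e1$best, e2$best)
  expect_equal(e1$best, 0.1)      # self-consistency: generating value wins
  expect_lt(e1$mse[["0.1"]], 1e-6)
  expect_error(estimate_kAoff(c(0.1, 1), unname(obs), lambda_rates(), dis),
               "named")
})

test_that("pause statistics: empty input, thresholding, trace fractions", {
  expect_equal(pause_statistics(NULL)$n_pauses, 0L)
  none <- data.frame(start = 1, duration = 4, position = 2L, frac_E = 1,
                     frac_EM = 0, frac_EMM = 0, majority_state = "E")
  expect_equal(pause_statistics(none)$n_pauses, 0L)  # below 10 s threshold
  two <- data.frame(start = c(1, 50), duration = c(12, 30),
                    position = c(2L, 9L), frac_E = c(0.9, 0.2),
                    frac_EM = c(0.1, 0.7), frac_EMM = c(0, 0.1),
                    majority_state = c("E", "EM"),
                    trace_id = c(1L, 1L))
  s <- pause_statistics(two, n_traces = 4)
  expect_equal(s$n_pauses, 2L)
  expect_equal(s$mean_duration, 21)
  expect_equal(s$state_fractions, c(E = 0.5, EM = 0.5, EMM = 0))
  expect_equal(s$frac_traces_with_pause, 0.25)
})

test_that("arithmetic-mean and log-mean velocities disagree on skewed data", {
  ds <- synth_velocity_dataset(lam1, 0.1, n_traces = 400,
                               disorder = disorder_spec(sigma = 0),
                               seed = 60)
  v <- ds$velocity_nt_s
  expect_gt(abs(mean(log10(v)) - log10(mean(v))), 0.05)
})
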