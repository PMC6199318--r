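test_that("rate constants validate, derive K's and on-rates", {
  r <- rate_constants(18, 25, 0.1, 0.34)
  K <- eq_constants(r)
  expect_equal(K[["K_B"]], 18 / 25)
  expect_equal(K[["K_A"]], 0.1 / 0.34)
  expect_equal(on_rates(r, 3), c(kA_on = 0.34 * 3, kB_on = 25 * 3))
  expect_error(rate_constants(18, 25, 0, 0.34), "strictly positive")
  expect_error(rate_constants(-1, 25, 0.1, 0.34), "strictly positive")
  expect_error(rate_constants(18, Inf, 0.1, 0.34), "strictly positive")
  # scaling all rates preserves the equilibrium constants (disorder
  # invariance of K_A, K_B)
  expect_equal(eq_constants(scale_rates(r, 0.123)), K)
})

test_that("sequential-scheme velocity: saturation, examples, degenerate input", {
  spec <- model_spec("model1", rates = lambda_rates())
  # printed saturated rate at 9 mM rounds to ~17 nt/s
  expect_equal(round(mean_velocity(spec, 9)), 17)
  # saturation limit -> kB_off
  expect_equal(mean_velocity(spec, 1e9), 18, tolerance = 1e-6)
  # c = 0 only via the explicit limit flag
  expect_error(mean_velocity(spec, 0), "positive")
  expect_identical(mean_velocity(spec, 0, zero_limit = TRUE), 0)
  expect_error(mean_velocity(spec, -1))
  # velocity equals n_sites / MFPT from the master-equation linear solve
  spec2 <- model_spec("model1", rates = rate_constants(18, 25.35, 0.1, 0.333))
  v <- mean_velocity(spec2, 0.3)
  expect_equal(v, spec2$n_sites / mean_first_passage_time(spec2, 0.3),
               tolerance = 1e-8)
  expect_equal(v, 3.14, tolerance = 1e-3)
})

test_that("tau1 is the exact reciprocal and decomposes into cycle terms", {
  set.seed(101)
  for (i in 1:1000) {
    r <- rate_constants(runif(1, 0.5, 60), runif(1, 0.5, 60),
                        runif(1, 0.005, 10), runif(1, 0.01, 10))
    v <- sample(c("model1", "model2"), 1)
    spec <- model_spec(v, sample(1:30, 1), r)
    c0 <- runif(1, 0.01, 12)
    expect_lt(abs(mean_velocity(spec, c0) * tau1(spec, c0) - 1), 1e-12)
  }
  # decomposition 1/kB_off + tau_d + 1/kB_on for the sequential scheme
  r <- rate_constants(18, 25.35, 0.1, 0.333)
  spec <- model_spec("model1", rates = r)
  on <- on_rates(r, 3)
  expect_equal(tau1(spec, 3),
               1 / 18 + tau_d(r, 3) + 1 / on[["kB_on"]])
  expect_equal(tau1(spec, 3), mfpt1_oracle(18, 25.35, 0.1, 0.333, 3),
               tolerance = 1e-12)
  # vanishing A-ion dissociation removes the excursion term
  r0 <- rate_constants(18, 25.35, 1e-14, 0.333)
  expect_equal(tau1(model_spec("model1", rates = r0), 3),
               1 / 18 + 1 / on[["kB_on"]], tolerance = 1e-9)
})

test_that("tau_d: closed form equals the excursion series and its MC oracle", {
  r <- rate_constants(18, 25.35, 0.1, 0.333)
  on <- on_rates(r, 3)
  # geometric series truncated at 50 terms
  q <- r$kA_off / (r$kA_off + on[["kB_on"]])
  series <- sum(q^(1:50)) / on[["kA_on"]]
  expect_lt(abs(series / tau_d(r, 3) - 1), 1e-12)
  # Monte-Carlo oracle over 1e6 simulated cycles
  mc <- tau_d_mc_oracle(18, 25.35, 0.1, 0.333, 3, n = 1e6, seed = 7)
  expect_lt(abs(tau_d(r, 3) - mc$mean), 3 * mc$se)
  expect_equal(tau_d(r, 3), 1.31e-3, tolerance = 5e-3)
  # kA_off -> 0 kills the excursions
  expect_lt(tau_d(rate_constants(18, 25.35, 1e-14, 0.333), 3), 1e-12)
})

test_that("Hill and Michaelis-Menten reference curves", {
  p1 <- hill_params(17.2, 0.885, n = 1)
  for (c0 in c(0.05, 0.3, 2, 9)) {
    expect_equal(hill_velocity(p1, c0), mm_velocity(17.2, 0.885, c0))
  }
  p <- hill_params(10, 0.5, n = 1.6)
  expect_equal(hill_velocity(p, 0.5), 5)  # half-saturation at c = K
  expect_error(hill_params(10, -1, 1.6), "positive")
})

test_that("kinetic-barrier difference", {
  expect_equal(barrier_difference(rate_constants(18, 25, 0.1, 0.34)),
               log(180))
  expect_equal(round(barrier_difference(rate_constants(18, 25, 0.1, 0.34)), 1),
               5.2)
  expect_equal(barrier_difference(rate_constants(3, 1, 3, 1)), 0)
  expect_equal(barrier_difference(rate_constants(2, 1, 1, 1)), log(2))
})

test_that("monotonicity and MM limit of the sequential velocity", {
  spec <- model_spec("model1", rates = lambda_rates())
  grid <- exp(seq(log(1e-3), log(100), length.out = 300))
  v <- vapply(grid, function(c0) mean_velocity(spec, c0), numeric(1))
  expect_true(all(diff(v) > 0))
  # K_A -> 0 collapses onto Michaelis-Menten with V_max = kB_off, K_m = K_B
  r0 <- rate_constants(18, 25.35, 1e-12 * 0.333, 0.333)
  s0 <- model_spec("model1", rates = r0)
  for (c0 in c(0.01, 0.1, 1, 10)) {
    expect_equal(mean_velocity(s0, c0), mm_velocity(18, 18 / 25.35, c0),
                 tolerance = 1e-10)
  }
})

test_that("coincident-scheme binding rates: roots, bound, round trips", {
  # frozen oracle values (polyroot evaluation of the quadratic)
  or <- model2_roots_oracle(0.30, 0.71, 18, 40)
  br <- model2_binding_rates(0.30, 0.71, 18, 40)
  expect_equal(unname(br), unname(or), tolerance = 1e-10)
  expect_equal(br[["kA_b"]], 19.91222, tolerance = 1e-6)
  expect_equal(br[["kB_b"]], 169.7591, tolerance = 1e-6)
  expect_lte(br[["kA_b"]], br[["kB_b"]])

  # double root exactly at the feasibility bound
  kb <- model2_kAoff_lower_bound(0.2, 0.9, 12)
  dr <- model2_binding_rates(0.2, 0.9, 12, kb)
  expect_equal(dr[["kA_b"]], dr[["kB_b"]], tolerance = 1e-9)
  expect_equal(dr[["kA_b"]], kb * (0.2 + 0.9) / (2 * 0.2 * 0.9),
               tolerance = 1e-9)

  # AM-GM equality case and printed-constants value
  expect_equal(model2_kAoff_lower_bound(0.4, 0.4, 18), 18)
  expect_equal(model2_kAoff_lower_bound(0.30, 0.71, 18), 15.03,
               tolerance = 1e-3)

  # infeasible below the bound, feasible at/above it
  expect_error(model2_binding_rates(0.30, 0.71, 18, 15.0), "infeasible")
  expect_silent(model2_binding_rates(0.30, 0.71, 18, 15.04))

  # round trip: the effective constants of the returned rate set reproduce
  # the inputs, and the titration-form velocity matches the exact mean
  set.seed(42)
  for (i in 1:25) {
    K_A <- runif(1, 0.05, 1); K_B <- runif(1, 0.05, 1)
    kB_off <- runif(1, 5, 40)
    kA_off <- model2_kAoff_lower_bound(K_A, K_B, kB_off) * runif(1, 1, 8)
    b <- model2_binding_rates(K_A, K_B, kB_off, kA_off)
    r2 <- rate_constants(kB_off, b[["kB_b"]], kA_off, b[["kA_b"]])
    eff <- model2_effective_constants(r2)
    expect_equal(eff$K_sum, K_A + K_B, tolerance = 1e-10)
    expect_equal(eff$K_prod, K_A * K_B, tolerance = 1e-10)
    expect_equal(eff$K_pair, sort(c(K_A, K_B)), tolerance = 1e-8)
    s2 <- model_spec("model2", rates = r2)
    for (c0 in c(0.1, 1, 3)) {
      expect_equal(mean_velocity(s2, c0),
                   kB_off / (1 + (K_A + K_B) / c0 + K_A * K_B / c0^2),
                   tolerance = 1e-12)
    }
  }
})

test_that("the two schemes coincide when effective coefficients match", {
  # model-1 with (K_B, K_A*K_B) = (S, P) of a model-2 parameter set gives
  # identical mean velocities at every concentration
  K_A1 <- 0.1; K_B1 <- 0.8; kB_off <- 20
  r1 <- rate_constants(kB_off, kB_off / K_B1, 1, 1 / K_A1)
  s1 <- model_spec("model1", rates = r1)
  pair <- sort(Re(polyroot(c(K_A1 * K_B1, -K_B1, 1))))
  b <- model2_binding_rates(pair[1], pair[2], kB_off,
                            model2_kAoff_lower_bound(pair[1], pair[2],
                                                     kB_off) * 2)
  s2 <- model_spec("model2",
                   rates = rate_constants(kB_off, b[["kB_b"]],
                                          model2_kAoff_lower_bound(
                                            pair[1], pair[2], kB_off) * 2,
                                          b[["kA_b"]]))
  for (c0 in c(0.05, 0.3, 1, 5)) {
    expect_equal(mean_velocity(s1, c0), mean_velocity(s2, c0),
                 tolerance = 1e-10)
  }
})
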