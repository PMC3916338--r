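test_that("the fixed point is invariant under integration", {
  circ <- default_circuit()
  ss <- steady_state(circ)
  sim <- integrate_circuit(circ, horizon = 100, dt = 0.01,
                           init = "fixed_point", record_every = 100L)
  rates <- as.matrix(sim[, paste0("f_", names(ss$rates), "_Hz")])
  expect_lt(max(abs(sweep(rates, 2, ss$rates))), 1e-6)
})

test_that("integration from zero currents converges to the analytic fixed point", {
  circ <- default_circuit()
  ss <- steady_state(circ)
  sim <- integrate_circuit(circ, horizon = 600, dt = 0.01, init = "zero",
                           record_every = 1000L)
  expect_equal(unname(last_rates(sim)), unname(ss$rates), tolerance = 0.03)
  # fully relaxed after several multiples of the slowest time constant
  sim2 <- integrate_circuit(circ, horizon = 2000, dt = 0.01, init = "zero",
                            record_every = 1000L)
  expect_equal(unname(last_rates(sim2)), unname(ss$rates), tolerance = 1e-5)
})

test_that("halving the time step does not change terminal rates materially", {
  circ <- default_circuit()
  a <- last_rates(integrate_circuit(circ, 600, dt = 0.01, init = "zero",
                                    record_every = 60000L))
  b <- last_rates(integrate_circuit(circ, 600, dt = 0.005, init = "zero",
                                    record_every = 120000L))
  expect_lt(max(abs(a - b)), 1e-3)
})

test_that("the integrator converges at second order in dt", {
  circ <- default_circuit()
  ref <- last_rates(integrate_circuit(circ, 100, dt = 0.001, init = "zero",
                                      record_every = 100000L))
  errs <- vapply(c(0.08, 0.04, 0.02), function(h) {
    max(abs(last_rates(integrate_circuit(circ, 100, dt = h, init = "zero",
                                         record_every = 10000L)) - ref))
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  # error drops ~4x per halving for an order-2 method
  expect_true(all(ratios > 3 & ratios < 6))
})

test_that("trajectories agree with a stiff ODE solver on the same vector field", {
  circ <- default_circuit()
  rhs <- function(t, y, p) {
    names(y) <- names(circ$tau)
    r <- instantaneous_rates(circ, y)
    list(unname(slow_current_derivs(circ, y, r$rates)))
  }
  out <- deSolve::ode(rep(0, 8), seq(0, 100, by = 10), rhs, NULL,
                      rtol = 1e-10, atol = 1e-10)
  yT <- stats::setNames(out[nrow(out), -1], names(circ$tau))
  oracle <- instantaneous_rates(circ, yT)$rates
  mine <- last_rates(integrate_circuit(circ, 100, dt = 0.001, init = "zero",
                                       record_every = 100000L))
  expect_equal(unname(mine), unname(oracle), tolerance = 1e-6)
})

test_that("rates stay nonnegative from arbitrary nonnegative starts", {
  circ <- default_circuit()
  set.seed(7)
  for (k in 1:10) {
    init <- stats::setNames(runif(8, 0, 400), names(circ$tau))
    prot <- stimulus_protocol(sample(c("5HT", "Ox"), 1),
                              amplitude = sample(c(-150, 150), 1),
                              onset = 1, duration = 0.5)
    sim <- integrate_circuit(circ, horizon = 30, dt = 0.01, init = init,
                             protocol = prot, record_every = 10L)
    expect_true(all(as.matrix(
      sim[, paste0("f_", c("5HT", "GABA_DRN", "Ox", "GABA_LHA"), "_Hz")]) >=
        0))
  }
})

test_that("integration inputs are validated", {
  circ <- default_circuit()
  expect_error(integrate_circuit(circ, horizon = -1), "horizon")
  expect_error(integrate_circuit(circ, horizon = 10, dt = 0.2), "coarse")
  bad <- stats::setNames(c(-1, rep(0, 7)), names(circ$tau))
  expect_error(integrate_circuit(circ, horizon = 10, init = bad),
               "nonnegative")
  expect_error(integrate_circuit(circ, horizon = 10, protocol = "pulse"),
               "protocol")
})

test_that("simulate() is deterministic and honours nsim", {
  circ <- default_circuit()
  a <- simulate(circ, horizon = 5, dt = 0.01)
  b <- simulate(circ, seed = 1, horizon = 5, dt = 0.01)
  expect_equal(as.data.frame(a), as.data.frame(b))
  pair <- simulate(circ, nsim = 2, horizon = 5, dt = 0.01)
  expect_length(pair, 2)
  expect_equal(as.data.frame(pair[[1]]), as.data.frame(pair[[2]]))
})
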