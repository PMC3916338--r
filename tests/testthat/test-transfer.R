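test_that("threshold-linear transfer clamps at threshold and scales by g", {
  # serotonergic baseline drive: g * (I - I0) by direct arithmetic
  expect_equal(rate_transfer(0.033, 151.47, 0.13), 0.033 * (151.47 - 0.13))
  expect_equal(rate_transfer(0.033, 151.47, 0.13), 4.99422, tolerance = 1e-8)
  expect_equal(rate_transfer(0.205, -10, 0), 0)
  expect_equal(rate_transfer(0.061, 246, 0), 15.006)
  # vectorized over drives
  expect_equal(rate_transfer(2, c(-1, 0.5, 3), 0.5), c(0, 0, 5))
  expect_error(rate_transfer(0.033, NaN, 0), "finite")
  expect_error(rate_transfer(-1, 10, 0), "positive")
})

test_that("drive assembly reduces to backgrounds with silent afferents", {
  circ <- default_circuit()
  slow <- stats::setNames(numeric(8), names(circ$tau))
  drives <- assemble_drive(circ, slow, c(GABA_DRN = 0, GABA_LHA = 0))
  expect_equal(drives, circ$I_bg)
})

test_that("drive assembly reproduces the baseline serotonergic input", {
  circ <- default_circuit()
  ss <- steady_state(circ)
  drives <- assemble_drive(circ, ss$currents,
                           ss$rates[c("GABA_DRN", "GABA_LHA")])
  # background - autoreceptor - local GABA + orexinergic excitation
  expect_equal(unname(drives["5HT"]),
               231.47 - 16 * ss$rates[["5HT"]] -
                 5 * ss$rates[["GABA_DRN"]] + 15 * ss$rates[["Ox"]])
  expect_equal(unname(drives["5HT"]), 151.733, tolerance = 1e-4)
  # an active stimulus enters the 5-HT drive additively and exactly
  stimmed <- assemble_drive(circ, ss$currents,
                            ss$rates[c("GABA_DRN", "GABA_LHA")],
                            stim = c(`5HT` = 150))
  expect_equal(stimmed["5HT"] - drives["5HT"], c(`5HT` = 150))
  expect_equal(stimmed[c("GABA_DRN", "Ox", "GABA_LHA")],
               drives[c("GABA_DRN", "Ox", "GABA_LHA")])
})

test_that("instantaneous GABA rates use the closed-form self-inhibition solve", {
  circ <- default_circuit()
  # LHA GABA with slow afferent sum 30 pA atop its 20.9 pA background:
  # f = g * X / (1 + g * J_self) with X = 50.9
  slow <- stats::setNames(numeric(8), names(circ$tau))
  slow["5HT_to_GABA_LHA"] <- 30
  r <- instantaneous_rates(circ, slow)
  expect_equal(unname(r$rates["GABA_LHA"]), 0.195 * 50.9 / (1 + 0.195 * 5),
               tolerance = 1e-12)
  expect_equal(unname(r$rates["GABA_LHA"]), 5.0254, tolerance = 1e-4)
  # zero currents and zero backgrounds silence the whole circuit
  dark <- set_parameter(circ, stats::setNames(
    rep(0, 4), paste0("Ibg.", c("5HT", "GABA_DRN", "Ox", "GABA_LHA"))))
  r0 <- instantaneous_rates(dark, stats::setNames(numeric(8), names(circ$tau)))
  expect_equal(unname(r0$rates), rep(0, 4))
})

test_that("closed-form algebraic rates match brute-force fixed-point iteration", {
  circ <- default_circuit()
  set.seed(42)
  for (k in 1:10) {
    slow <- stats::setNames(runif(8, 0, 120), names(circ$tau))
    r <- instantaneous_rates(circ, slow)
    # iterate the full rate map f -> g[I_bg + signed currents - J*f_gaba - I0]_+
    f <- c(GABA_DRN = 0, GABA_LHA = 0)
    for (i in 1:1500) {
      d <- assemble_drive(circ, slow, f)
      f <- c(GABA_DRN = unname(pmax(0, circ$g["GABA_DRN"] *
               (d["GABA_DRN"] - circ$I0["GABA_DRN"]))),
             GABA_LHA = unname(pmax(0, circ$g["GABA_LHA"] *
               (d["GABA_LHA"] - circ$I0["GABA_LHA"]))))
    }
    expect_equal(unname(r$rates[c("GABA_DRN", "GABA_LHA")]), unname(f),
                 tolerance = 1e-9)
  }
})

test_that("slow-current kinetics are first-order toward J * f", {
  circ <- default_circuit()
  ss <- steady_state(circ)
  # at the fixed point every derivative vanishes
  d0 <- slow_current_derivs(circ, ss$currents, ss$rates)
  expect_equal(unname(d0), rep(0, 8), tolerance = 1e-9)
  # direct substitution: autoreceptor current from zero, f = 5 Hz
  slow <- stats::setNames(numeric(8), names(circ$tau))
  rates <- c(`5HT` = 5, GABA_DRN = 0, Ox = 5, GABA_LHA = 0)
  d <- slow_current_derivs(circ, slow, rates)
  expect_equal(unname(d["5HT_auto"]), 16 * 5 / 1)
  # decaying orexinergic current above its drive
  slow["Ox_to_5HT"] <- 150
  d2 <- slow_current_derivs(circ, slow, rates)
  expect_equal(unname(d2["Ox_to_5HT"]), (-150 + 15 * 5) / 60)
})
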