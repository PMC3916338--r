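test_that("phasic metrics scalarize a constructed trace exactly", {
  tt <- seq(0, 10, by = 0.01)
  tri <- function(base, peak, trough) {
    x <- rep(base, length(tt))
    x[tt >= 1 & tt <= 1.5] <- peak
    x[tt > 1.5 & tt <= 3] <- trough
    x
  }
  ts <- data.frame(time_s = tt, f_5HT_Hz = tri(5, 9, 4),
                   f_GABA_DRN_Hz = tri(15, 15, 15),
                   f_Ox_Hz = tri(5, 5, 1), f_GABA_LHA_Hz = tri(5, 6, 5))
  m <- phasic_metrics(ts, onset = 1, duration = 0.5)
  expect_equal(m["5HT", "baseline_Hz"], 5)
  expect_equal(m["5HT", "peak_Hz"], 9)
  expect_equal(m["5HT", "fold"], 9 / 5)
  expect_equal(m["5HT", "trough_Hz"], 4)
  expect_equal(m["5HT", "rebound_Hz"], 5)
  # constant population: every metric collapses to the baseline
  expect_equal(as.numeric(m["GABA_DRN", 1:2]), c(15, 15))
  expect_equal(m["GABA_DRN", "fold"], 1)
  expect_error(phasic_metrics(ts, onset = 0, duration = 0.5), "baseline")
})

test_that("a zero-amplitude pulse leaves the circuit at baseline", {
  pl <- run_pulse(default_circuit(), "5HT", amplitude = 0, horizon = 20)
  expect_equal(pl$metrics$fold, rep(1, 4), tolerance = 1e-9)
  expect_equal(pl$metrics$baseline_Hz, pl$metrics$peak_Hz, tolerance = 1e-9)
})

test_that("the standard 150 pA pulse doubles the serotonergic rate", {
  pl <- run_pulse(default_circuit(), "5HT")
  m <- pl$metrics
  # instantaneous jump g * 150 = 4.95 Hz atop the ~5 Hz baseline
  expect_equal(m["5HT", "peak_Hz"], m["5HT", "baseline_Hz"] + 0.033 * 150,
               tolerance = 1e-6)
  expect_equal(m["5HT", "fold"], 1.9894, tolerance = 1e-3)
  # serotonergic undershoot from autoreceptor + local GABA feedback
  expect_lt(m["5HT", "trough_Hz"], m["5HT", "baseline_Hz"] - 0.1)
  # orexinergic activity is suppressed by the serotonergic volley
  expect_lt(m["Ox", "trough_Hz"], m["Ox", "baseline_Hz"])
})

test_that("fast 5-HT receptor timescales give a higher orexin rebound", {
  fast <- run_pulse(default_circuit(), "5HT", "fast", dt = 0.005)
  slow <- run_pulse(default_circuit(), "5HT", "slow", dt = 0.005)
  expect_gt(fast$metrics["Ox", "rebound_Hz"], slow$metrics["Ox", "rebound_Hz"])
  # the serotonergic transient itself is insensitive to those timescales
  # within the stimulus-driven window (before the tau = 60 s orexin loop
  # can contribute)
  w <- fast$sim$time_s <= 1 + 6
  expect_lt(max(abs(fast$sim$f_5HT_Hz[w] - slow$sim$f_5HT_Hz[w])), 0.1)
})

test_that("orexin pulses self-amplify and excite 5-HT only via fast transmission", {
  fast <- run_pulse(default_circuit(), "Ox", "fast")
  slow <- run_pulse(default_circuit(), "Ox", "slow")
  # fast Ox -> 5HT transmission transiently excites the serotonergic cells
  expect_gt(fast$metrics["5HT", "fold"], slow$metrics["5HT", "fold"])
  expect_gt(fast$metrics["5HT", "fold"], 1.1)
  expect_lt(slow$metrics["5HT", "fold"], 1.05)
  # autoreceptor self-amplification: f_Ox rises throughout the stimulus
  # under the default slow timescales
  x <- slow$sim
  during <- x$time_s >= 1 & x$time_s < 1.5
  expect_true(all(diff(x$f_Ox_Hz[during]) > 0))
  # post-stimulus undershoot from recurrent inhibition, in both populations
  expect_lt(fast$metrics["Ox", "trough_Hz"], fast$metrics["Ox", "baseline_Hz"])
  expect_lt(fast$metrics["5HT", "trough_Hz"],
            fast$metrics["5HT", "baseline_Hz"])
})

test_that("the Ox -> GABA(DRN) timescale barely shapes the 5-HT response", {
  p5 <- run_pulse(default_circuit(), "Ox",
                  timescale_variant(c(Ox_to_GABA_DRN = 5)))
  p60 <- run_pulse(default_circuit(), "Ox",
                   timescale_variant(c(Ox_to_GABA_DRN = 60)))
  rel <- abs(p5$metrics["5HT", "peak_Hz"] - p60$metrics["5HT", "peak_Hz"]) /
    p5$metrics["5HT", "peak_Hz"]
  expect_lt(rel, 0.05)
})

test_that("pulse experiments refuse an unstable baseline", {
  weak <- with_J(default_circuit(), "5HT_to_GABA_LHA", 0.4)
  expect_error(run_pulse(weak, "5HT"), "stable")
  expect_error(timescale_variant(c(bogus_connection = 1)), "dynamic")
  expect_error(timescale_variant(c(Ox_to_5HT = -2)), "positive")
})
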