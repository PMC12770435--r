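# Single-myocyte pacing, limit-cycle attainment, and AP biomarker extraction.

test_that("pacing specs count stimuli correctly", {
  expect_equal(pacing_spec(cl = 1000, duration = 15 * 60 * 1000)$n_beats, 900L)
  expect_equal(pacing_spec(cl = 700, n_beats = 5)$n_beats, 5L)
  expect_error(pacing_spec(cl = 1, width = 2), "cycle_length")
})

test_that("zero-duration pre-pacing returns the initial state unchanged", {
  s0 <- crn_initial_state()
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 0),
                initial = s0)
  expect_equal(unclass(pp$state), unclass(s0))
  expect_equal(pp$n_stimuli, 0L)
})

test_that("limit-cycle residual shrinks as the train lengthens", {
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 30))
  expect_lt(pp$residuals[30], pp$residuals[2])
  expect_equal(pp$residual, pp$residuals[30])
})

test_that("record_ap traces start at the input state and handle zero beats", {
  tr0 <- record_ap(crn_initial_state(), crn_parameters(), ref_elec(),
                   pacing_spec(cl = 1000, n_beats = 1), n_beats = 0)
  expect_equal(nrow(tr0), 0)
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 5))
  tr <- record_ap(pp$state, crn_parameters(), ref_elec(),
                  pacing_spec(cl = 1000, n_beats = 1))
  expect_equal(tr$V[1], unclass(pp$state)[["V"]])
  expect_equal(tr$time[1], 0)
})

test_that("beat-to-beat APD90 difference at the limit cycle is below 1 ms", {
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 40))
  tr <- record_ap(pp$state, crn_parameters(), ref_elec(),
                  pacing_spec(cl = 1000, n_beats = 1), n_beats = 2)
  b1 <- ap_biomarkers(tr[tr$time < 1000, ])
  tr2 <- tr[tr$time >= 1000, ]; tr2$time <- tr2$time - 1000
  b2 <- ap_biomarkers(tr2)
  expect_lt(abs(b1$APD90 - b2$APD90), 1)
})

test_that("ap_biomarkers recovers the analytic APD of a trapezoid pulse", {
  t <- seq(0, 400, by = 0.1)
  V <- rep(-80, length(t))
  up <- t >= 10 & t < 12
  V[up] <- -80 + (t[up] - 10) / 2 * 100          # linear upstroke to +20
  dec <- t >= 12 & t < 312
  V[dec] <- 20 - (t[dec] - 12) / 3               # linear decay to -80
  bm <- ap_biomarkers(data.frame(time = t, V = V))
  expect_true(bm$valid)
  expect_equal(bm$RMP, -80)
  expect_equal(bm$amplitude, 100, tolerance = 1e-6)
  # 90% recovery threshold -70 mV crossed at t = 282; upstroke argmax at 10
  expect_equal(bm$APD90, 272, tolerance = 0.3)
  expect_equal(bm$APD70, 212, tolerance = 0.3)
})

test_that("sub-threshold responses are flagged invalid", {
  t <- seq(0, 100, 0.5)
  bm <- ap_biomarkers(data.frame(time = t, V = -80 + 10 * exp(-(t - 10)^2)))
  expect_false(bm$valid)
  expect_true(is.na(bm$APD90))
})

test_that("baseline limit-cycle APD90 matches the golden value and an
           independent stiff re-integration", {
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 40))
  tr <- record_ap(pp$state, crn_parameters(), ref_elec(),
                  pacing_spec(cl = 1000, n_beats = 1))
  bm <- ap_biomarkers(tr)
  expect_equal(bm$APD90, 294.88, tolerance = 2e-3)  # frozen golden value
  p <- crn_parameters(); e <- ref_elec()
  rhs <- function(t, y, parms) {
    y[2:16] <- pmin(pmax(y[2:16], 0), 1)
    d <- crn_derivatives(y, p, e, stim = if (t < 2) 26.6 else 0)
    list(d$deriv)
  }
  sol <- deSolve::ode(unclass(pp$state), seq(0, 600, 0.1), rhs, NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  bm_ode <- ap_biomarkers(data.frame(time = sol[, 1], V = sol[, 2]))
  expect_lt(abs(bm_ode$APD90 - bm$APD90), 2)
  expect_lt(abs(bm_ode$RMP - bm$RMP), 0.2)
})

test_that("lowering Nao by 25% shortens APD70", {
  expect_lt(lc_bm(Nao = 105)$APD70, lc_bm()$APD70)
})

test_that("biomarkers are invariant to time offset and to output-step halving", {
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 40))
  tr <- record_ap(pp$state, crn_parameters(), ref_elec(),
                  pacing_spec(cl = 1000, n_beats = 1), out_dt = 0.1)
  bm <- ap_biomarkers(tr)
  sh <- tr; sh$time <- sh$time + 137
  bm_sh <- ap_biomarkers(sh)
  expect_equal(bm_sh$APD90, bm$APD90)
  expect_equal(bm_sh$upstroke_time, bm$upstroke_time + 137)
  tr2 <- record_ap(pp$state, crn_parameters(), ref_elec(),
                   pacing_spec(cl = 1000, n_beats = 1), out_dt = 0.05)
  expect_lt(abs(ap_biomarkers(tr2)$APD90 - bm$APD90), 0.5)
})

test_that("the diastolic threshold brackets the default stimulus amplitude", {
  thr <- find_diastolic_threshold(tol = 0.5)
  expect_gt(thr, 1)
  expect_lt(thr, 26.6)  # default amplitude is twice the limit-cycle threshold
})
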