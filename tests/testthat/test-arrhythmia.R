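# Induction protocols, episode tracking and binary endpoints.

test_that("the burst-pacing schedule follows the stated cycle lengths and delay", {
  s <- burst_schedule()
  expect_equal(s$onset[s$phase == "S1"], c(0, 700, 1400, 2100, 2800))
  expect_equal(s$onset[s$phase == "burst"], c(3200, 3360, 3520, 3680, 3840))
  expect_true(all(diff(s$onset) > 0))
})

fake_result <- function(acts, t_end = 5000, v_end = -80) {
  times <- seq(0, t_end, by = 10)
  nn <- length(acts)
  vm <- matrix(v_end, length(times), nn)
  structure(list(times = times, vm = vm, activations = acts,
                 record_nodes = seq_len(nn)),
            class = "tissue_result")
}

test_that("a quiescent recording is not classified as induced", {
  ep <- classify_episode(fake_result(rep(list(numeric(0)), 9)), 0)
  expect_false(ep$induced)
  expect_true(is.na(ep$terminated))
  expect_true(is.na(ep$dominant_frequency))
})

test_that("a 200-ms activation train gives a 5 Hz dominant frequency", {
  acts <- rep(list(seq(100, 4900, by = 200)), 4)
  ep <- classify_episode(fake_result(acts), final_stim_time = 0)
  expect_true(ep$induced)
  expect_equal(ep$dominant_frequency, 5)
  expect_false(ep$terminated)  # active through the final 200 ms
})

test_that("early-terminating episodes are detected via quiescence", {
  acts <- rep(list(seq(100, 1300, by = 200)), 4)
  ep <- classify_episode(fake_result(acts), 0)
  expect_true(ep$induced)
  expect_true(ep$terminated)
  expect_equal(ep$episode_duration_s, 1.3)
})

test_that("slow rhythms below the cycle-length criterion are not arrhythmias", {
  acts <- rep(list(seq(0, 4800, by = 800)), 4)  # CL 800 > 500 ms
  ep <- classify_episode(fake_result(acts), 0)
  expect_false(ep$induced)
})

test_that("endpoint records combine the two burst sites with OR logic", {
  pos <- structure(list(induced = TRUE, terminated = FALSE,
                        dominant_frequency = 4, episode_duration_s = 5,
                        n_active_nodes = 10), class = "endpoint_episode")
  post <- structure(list(induced = TRUE, terminated = TRUE,
                         dominant_frequency = 6, episode_duration_s = 1,
                         n_active_nodes = 4), class = "endpoint_episode")
  neg <- structure(list(induced = FALSE, terminated = NA,
                        dominant_frequency = NA_real_, episode_duration_s = 0,
                        n_active_nodes = 0), class = "endpoint_episode")
  r1 <- endpoint_record(pos, neg)
  expect_true(r1$induced_LAA); expect_false(r1$induced_AR)
  expect_true(r1$induced_any); expect_false(r1$terminated)
  r2 <- endpoint_record(neg, neg)
  expect_false(r2$induced_any)
  expect_true(is.na(r2$terminated))
  r3 <- endpoint_record(post, neg)
  expect_true(r3$terminated)
  r4 <- endpoint_record(pos, post)   # one sustained episode -> not terminated
  expect_false(r4$terminated)
  expect_equal(r4$dominant_frequency, 5)
  expect_equal(r1$induced_any, r1$induced_LAA || r1$induced_AR)
})

test_that("the four-spiral phase field spans [0, 2pi) with alternating chirality", {
  ic <- spiral_episode()$ic
  expect_gte(min(ic$phase), 0)
  expect_lt(max(ic$phase), 2 * pi)
  expect_equal(sort(ic$chirality), c(-1, -1, 1, 1))
  expect_equal(nrow(ic$centers), 4)
  # phases cover the full cycle
  expect_gt(mean(ic$phase > pi), 0.25)
  expect_gt(mean(ic$phase < pi), 0.25)
})

test_that("sheets too small for four spiral cores are rejected", {
  cfg <- substrate_config(size = 2.0, dx = 500)
  sub <- suppressWarnings(build_substrate(generate_iir_field(cfg, 2), cfg))
  expect_error(spiral_initial_condition(sub, ref_elec(), n_prepace_beats = 1),
               "too small")
})

test_that("four-spiral re-entry persists beyond one second on the induction sheet", {
  ep <- spiral_episode()$episode
  expect_true(ep$induced)
  expect_gt(ep$episode_duration_s, 1)
})

test_that("burst induction on a quiescent healthy substrate is a negative outcome", {
  sub <- tiny_substrate()
  run <- burst_induction(sub, "LAA", ref_elec(), n_prepace_beats = 10,
                         track_ms = 1200)
  expect_equal(run$final_stim_time, 3842)
  ep <- classify_episode(run$result, run$final_stim_time)
  expect_false(ep$induced)
})

test_that("no-stimulus tissue is never induced", {
  sub <- tiny_substrate()
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 700, n_beats = 5))
  res <- solve_monodomain(sub$geometry, sub$params, ref_elec(), list(),
                          t_end = 500, dt = 0.05, out_dt = 10,
                          initial_states = pp$state)
  expect_false(classify_episode(res, 0)$induced)
})

test_that("the single-stimulus screen is negative on a healthy baseline substrate", {
  excl <- screen_single_stimulus(tiny_substrate(), ref_elec(),
                                 result = tiny_mapping())
  expect_false(excl)
})

test_that("flagged runs are absent from the cohort QoI table, with context", {
  rec <- function(s, Ko, Nao, excl) list(
    substrate = s, Ko = Ko, Nao = Nao, Cao = 1.8, is_baseline = FALSE,
    excluded = excl, mAPD = 250, mCV = 0.6, DAPD = 10, DCV = 0.1,
    rel_mAPD = 0, rel_mCV = 0, rel_DAPD = 0, rel_DCV = 0)
  tab <- cohort_qoi_table(list(rec(1, 4.5, 140, FALSE),
                               rec(1, 3.1, 109, TRUE),
                               rec(2, 5.0, 160, FALSE)))
  expect_equal(nrow(tab), 2)
  excl <- attr(tab, "excluded")
  expect_equal(nrow(excl), 1)
  expect_equal(excl$Ko, 3.1)    # hypokalaemia + hyponatremia context retained
  expect_equal(excl$Nao, 109)
})
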