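# Monodomain solver: geometry, stability guard, decoupled limit, conservation,
# symmetry, and strand conduction velocity.

test_that("the 1-cm strand at 100-um resolution has 101 nodes", {
  g <- geometry_1d(length = 1.0, dx = 100)
  expect_equal(g$nx, 101L)
  expect_error(geometry_1d(length = 1.0, dx = 333), "integer node count")
})

test_that("a CFL-violating time step is rejected before stepping", {
  g <- geometry_1d()
  expect_error(
    solve_monodomain(g, crn_parameters(), ref_elec(), list(), t_end = 10,
                     dt = 1),
    "CFL violation")
})

test_that("with negligible coupling every node reproduces the 0D trace", {
  g <- geometry_2d(5, 5, dx = 250, sigma_l = 1e-9, sigma_t = 1e-9)
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 5))
  res <- solve_monodomain(g, crn_parameters(), ref_elec(),
                          list(stimulus_event(1:25, 0, 2, 26.6)),
                          t_end = 400, dt = 0.02, out_dt = 0.5,
                          initial_states = pp$state)
  tr <- record_ap(pp$state, crn_parameters(), ref_elec(),
                  pacing_spec(cl = 1000, n_beats = 1, amplitude = 26.6),
                  out_dt = 0.5)
  v0 <- tr$V[tr$time <= 400][seq_len(nrow(res$vm))]
  for (k in c(1, 13, 25))
    expect_lt(max(abs(res$vm[, k] - v0)), 0.5)
})

test_that("with zero ionic current and no stimulus the spatial mean is conserved", {
  p0 <- crn_parameters(gNa = 0, gK1 = 0, gto = 0, gKr = 0, gKs = 0, gCaL = 0,
                       gbCa = 0, gbNa = 0, INaKmax = 0, INaCamax = 0,
                       IpCamax = 0, gKur_scale = 0)
  g <- geometry_2d(15, 15, dx = 250)
  st <- matrix(rep(unclass(crn_initial_state()), each = 225), nrow = 225)
  xs <- rep(seq_len(15), 15); ys <- rep(seq_len(15), each = 15)
  st[, 1] <- -80 + 15 * sin(xs / 3) * cos(ys / 4)
  res <- solve_monodomain(g, p0, ref_elec(), list(), t_end = 50, dt = 0.02,
                          out_dt = 5, initial_states = st)
  means <- rowMeans(res$vm)
  expect_lt(max(abs(means - means[1])), 1e-8)
})

test_that("a mirrored stimulus produces a mirrored activation map", {
  g <- geometry_2d(21, 9, dx = 250)
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 5))
  mid_col <- 11
  nodes <- mid_col + 21 * (0:8)
  res <- solve_monodomain(g, crn_parameters(), ref_elec(),
                          list(stimulus_event(nodes, 0, 2, 53.2)),
                          t_end = 120, dt = 0.02, out_dt = 0.25,
                          initial_states = pp$state)
  maps <- activation_repolarisation_maps(res, c(0, 120))
  lat <- matrix(maps$LAT, 21, 9)
  expect_equal(lat[1:10, ], lat[21:12, ], tolerance = 1e-9)
})

test_that("strand CV: two-point formula equals the synthetic plane-wave speed", {
  g <- geometry_1d()
  theta <- 0.06  # cm/ms = 0.6 m/s
  times <- seq(0, 40, by = 0.05)
  lat <- (seq_len(g$nx) - 1) * g$dx / theta
  vm <- outer(times, lat, function(t, l) ifelse(t > l, 20, -80))
  fake <- structure(list(times = times, vm = vm, geometry = g,
                         record_nodes = seq_len(g$nx)),
                    class = "tissue_result")
  cv <- strand_cv(fake)
  expect_false(cv$block)
  expect_equal(cv$cv, theta * 10, tolerance = 0.02)
})

test_that("two-point strand CV agrees with the LAT-vs-x regression within 1%", {
  run <- healthy_strand()
  res <- run$result
  maps <- activation_repolarisation_maps(res, c(1000, 2000))
  interior <- 21:81
  fit <- coef(lm(maps$LAT[interior] ~ I((interior - 1) * res$geometry$dx)))
  cv_reg <- 10 / fit[[2]]
  expect_lt(abs(run$cv - cv_reg) / cv_reg, 0.01)
})

test_that("baseline strand CV is physiological and blocks are flagged", {
  run <- healthy_strand()
  expect_false(run$block)
  expect_gt(run$cv, 0.6)
  expect_lt(run$cv, 0.8)
  # a non-captured strand reports block, not a number
  g <- geometry_1d()
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 5))
  res <- solve_monodomain(g, crn_parameters(), ref_elec(),
                          list(stimulus_event(1:5, 0, 2, 1)),  # sub-threshold
                          t_end = 100, dt = 0.02, out_dt = 0.5,
                          initial_states = pp$state)
  cv <- strand_cv(res)
  expect_true(cv$block)
  expect_true(is.na(cv$cv))
})

test_that("halving the spatial step changes strand CV by less than 2%", {
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 40))
  cv_at <- function(dx_um, dt) {
    g <- geometry_1d(dx = dx_um)
    stim <- stimulus_event(seq_len(max(2, round(0.05 / g$dx))), 0, 2, 53.2)
    res <- solve_monodomain(g, crn_parameters(), ref_elec(), list(stim),
                            t_end = 250, dt = dt, out_dt = 0.2,
                            initial_states = pp$state)
    strand_cv(res)$cv
  }
  cv100 <- cv_at(100, 0.005)
  cv50 <- cv_at(50, 0.005)
  expect_lt(abs(cv50 - cv100) / cv100, 0.02)
})

test_that("fibrotic strand conducts more slowly than healthy", {
  expect_lt(fibrotic_strand()$cv, healthy_strand()$cv)
})

test_that("tissue results are deterministic for identical inputs", {
  g <- geometry_2d(11, 11, dx = 500)
  run <- function() solve_monodomain(g, crn_parameters(), ref_elec(),
                                     list(stimulus_event(1:3, 0, 2, 53.2)),
                                     t_end = 80, dt = 0.05, out_dt = 1)
  r1 <- run(); r2 <- run()
  expect_identical(r1$vm, r2$vm)
  expect_identical(r1$activations, r2$activations)
})
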