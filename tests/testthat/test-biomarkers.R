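# LAT/LRT/APD90/CV maps and cohort-style QoI summaries.

# synthetic plane wave on a sheet: node (i,j) activates at t = x/theta and
# repolarises apd ms later
plane_wave_result <- function(nx = 21, ny = 5, dx_um = 500, theta = 0.05,
                              apd = 200) {
  g <- geometry_2d(nx, ny, dx = dx_um)
  times <- seq(0, 600, by = 1)
  xs <- rep((seq_len(nx) - 1) * g$dx, ny)
  lat <- xs / theta + 5
  vm <- sapply(seq_len(nx * ny), function(k)
    ifelse(times > lat[k] & times < lat[k] + apd, 15, -85))
  structure(list(times = times, vm = vm, geometry = g,
                 record_nodes = seq_len(nx * ny)),
            class = "tissue_result")
}

test_that("plane-wave LAT increases linearly and APD90 = LRT - LAT", {
  res <- plane_wave_result()
  maps <- activation_repolarisation_maps(res, c(0, 600))
  expect_true(all(maps$valid))
  lat <- matrix(maps$LAT, 21, 5)
  slopes <- diff(lat[, 1])
  expect_equal(slopes, rep(slopes[1], 20), tolerance = 1e-6)
  expect_equal(maps$APD90, maps$LRT - maps$LAT)
})

test_that("the CV map of a plane wave is constant and equals the wave speed", {
  theta <- 0.05
  res <- plane_wave_result(theta = theta)
  maps <- activation_repolarisation_maps(res, c(0, 600))
  cvf <- cv_map_from_lat(maps)
  expect_equal(stats::median(cvf, na.rm = TRUE), theta * 10, tolerance = 0.05)
  expect_lt(stats::sd(cvf, na.rm = TRUE), 0.02)
})

test_that("LAT by argmax dV/dt matches the -40 mV crossing within 1 ms", {
  res <- healthy_strand()$result
  t <- res$times
  sel <- t >= 1000
  node <- 51
  V <- res$vm[sel, node]; tt <- t[sel]
  lat_grad <- tt[which.max(diff(V) / diff(tt))]
  lat_thr <- tt[which(V[-1] >= -40 & V[-length(V)] < -40)[1]]
  expect_lt(abs(lat_grad - lat_thr), 1)
})

test_that("CV is strongly reduced in regions with fibrotic parameters", {
  # left half healthy (region 1), right half dense fibrosis (region 5)
  nx <- 41; ny <- 9
  region <- rep(1L, nx * ny)
  region[rep(seq_len(nx) > 21, ny)] <- 5L
  ct <- conductivity_table()
  g <- geometry_2d(nx, ny, dx = 250, region = region,
                   sigma_l = ct$sigma_l, sigma_t = ct$sigma_t)
  params <- lapply(1:5, function(r)
    if (r >= 5) apply_fibrosis_remodelling(crn_parameters()) else crn_parameters())
  pp <- prepace(crn_parameters(), ref_elec(), pacing_spec(cl = 1000, n_beats = 10))
  stim_nodes <- c(1 + nx * (0:(ny - 1)), 2 + nx * (0:(ny - 1)))
  res <- solve_monodomain(g, params, ref_elec(),
                          list(stimulus_event(stim_nodes, 0, 3, 80)),
                          t_end = 500, dt = 0.02, out_dt = 0.5,
                          initial_states = pp$state)
  maps <- activation_repolarisation_maps(res, c(0, 500))
  cvf <- matrix(cv_map_from_lat(maps), nx, ny)
  cv_healthy <- stats::median(cvf[5:17, ], na.rm = TRUE)
  cv_fibrotic <- stats::median(cvf[25:37, ], na.rm = TRUE)
  expect_lt(cv_fibrotic, 0.7 * cv_healthy)
})

test_that("QoI percentiles match a brute-force order-statistic computation", {
  set.seed(42)
  nx <- 20; ny <- 20
  g <- geometry_2d(nx, ny, dx = 500)
  apd <- rnorm(nx * ny, 250, 30)
  maps <- structure(list(LAT = runif(nx * ny), LRT = NA, APD90 = apd,
                         valid = rep(TRUE, nx * ny), geometry = g),
                    class = "activation_maps")
  cvf <- rlnorm(nx * ny, log(0.6), 0.2)
  s <- summarise_qoi(maps, cvf)
  brute_q <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  expect_equal(s$mAPD, brute_q(apd, 0.5))
  expect_equal(s$DAPD, brute_q(apd, 0.975) - brute_q(apd, 0.025))
  expect_equal(s$mCV, brute_q(cvf, 0.5))
  expect_equal(s$DCV, brute_q(cvf, 0.975) - brute_q(cvf, 0.025))
})

test_that("summaries are permutation invariant and expose exactly four QoIs", {
  set.seed(7)
  g <- geometry_2d(10, 10, dx = 500)
  apd <- rnorm(100, 250, 20)
  mk <- function(ord) structure(
    list(APD90 = apd[ord], valid = rep(TRUE, 100), geometry = g),
    class = "activation_maps")
  cvf <- rlnorm(100, log(0.6), 0.1)
  ord <- sample(100)
  s1 <- summarise_qoi(mk(seq_len(100)), cvf)
  s2 <- summarise_qoi(mk(ord), cvf[ord])
  expect_equal(unlist(s1[c("mAPD", "mCV", "DAPD", "DCV")]),
               unlist(s2[c("mAPD", "mCV", "DAPD", "DCV")]))
  expect_named(unlist(s1), c("mAPD", "mCV", "DAPD", "DCV"))
})

test_that("a constant APD field has zero dispersion and baseline rel-QoI is 0", {
  g <- geometry_2d(10, 10, dx = 500)
  maps <- structure(list(APD90 = rep(250, 100), valid = rep(TRUE, 100),
                         geometry = g), class = "activation_maps")
  cvf <- rep(0.6, 100)
  s <- summarise_qoi(maps, cvf)
  expect_equal(s$DAPD, 0)
  # a zero baseline entry makes the relative QoI undefined
  expect_error(summarise_qoi(maps, cvf, baseline = s), "zero")
  # with a non-degenerate field the relative QoI of a run against itself is 0
  set.seed(5)
  maps2 <- structure(list(APD90 = rnorm(100, 250, 10), valid = rep(TRUE, 100),
                          geometry = g), class = "activation_maps")
  cvf2 <- rlnorm(100, log(0.6), 0.1)
  s2 <- summarise_qoi(maps2, cvf2)
  s_rel <- summarise_qoi(maps2, cvf2, baseline = s2)
  expect_equal(unname(s_rel$rel), rep(0, 4))
})

test_that("degenerate summary inputs raise errors", {
  g <- geometry_2d(3, 3, dx = 500)
  maps <- structure(list(APD90 = rep(250, 9), valid = rep(TRUE, 9),
                         geometry = g), class = "activation_maps")
  expect_error(summarise_qoi(maps, rep(0.6, 9)), "10 valid nodes")
  res <- plane_wave_result()
  expect_error(activation_repolarisation_maps(res, c(1000, 1001)), "window")
})
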