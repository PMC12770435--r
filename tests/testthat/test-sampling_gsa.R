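# LHS designs, the GP emulator, Sobol estimators and per-current attribution.

test_that("the default design has 30 stratified rows plus the baseline", {
  d <- lhs_design(seed = 1)
  expect_equal(nrow(d), 31)
  expect_equal(sum(d$is_baseline), 1)
  base <- d[d$is_baseline, ]
  expect_equal(c(base$Ko, base$Nao, base$Cao), c(4.5, 140, 1.8))
  r <- electrolyte_ranges()
  for (cn in c("Ko", "Nao", "Cao")) {
    expect_true(all(d[[cn]] >= r[1, cn] & d[[cn]] <= r[2, cn]))
    # brute-force stratification check: one sample per equal bin
    u <- (d[[cn]][!d$is_baseline] - r[1, cn]) / (r[2, cn] - r[1, cn])
    bins <- floor(u * 30)
    expect_equal(sort(bins), 0:29)
  }
})

test_that("single-row designs stay inside the ranges", {
  d <- lhs_design(n = 1, seed = 3, append_baseline = FALSE)
  expect_equal(nrow(d), 1)
  r <- electrolyte_ranges()
  expect_true(d$Ko >= r[1, "Ko"] && d$Ko <= r[2, "Ko"])
})

test_that("degenerate ranges produce a constant column with a warning", {
  r <- electrolyte_ranges()
  r[, "Cao"] <- c(1.8, 1.8)
  expect_warning(d <- lhs_design(r, n = 5, seed = 1, append_baseline = FALSE),
                 "degenerate")
  expect_equal(d$Cao, rep(1.8, 5))
})

test_that("the GP emulator interpolates its training data", {
  set.seed(1)
  X <- as.matrix(lhs_design(n = 20, seed = 5, append_baseline = FALSE)[, 1:3])
  y <- sin(X[, 1]) + X[, 2] / 50 + (X[, 3] - 1.8)^2
  em <- fit_emulator(X, y)
  pr <- predict(em, X)
  expect_lt(max(abs(pr$mean - y)), 0.05 * diff(range(y)) + sqrt(em$sn2) * em$ysd * 3)
})

test_that("the GP generalises on a smooth 3-variable function (held-out R2 > 0.9)", {
  X <- as.matrix(lhs_design(n = 30, seed = 7, append_baseline = FALSE)[, 1:3])
  f <- function(M) sin(M[, 1]) + cos(M[, 2] / 20) + 0.3 * M[, 3]^2
  em <- fit_emulator(X, f(X))
  Xt <- as.matrix(lhs_design(n = 50, seed = 8, append_baseline = FALSE)[, 1:3])
  yh <- predict(em, Xt)$mean
  r2 <- 1 - sum((f(Xt) - yh)^2) / sum((f(Xt) - mean(f(Xt)))^2)
  expect_gt(r2, 0.9)
})

test_that("emulator rejects short designs and non-finite responses", {
  X <- matrix(runif(9 * 3), 9)
  expect_error(fit_emulator(X, runif(9)), "at least 10")
  X <- matrix(runif(36), 12)
  y <- runif(12); y[c(3, 7)] <- NA
  expect_error(fit_emulator(X, y), "rows: 3, 7")
})

test_that("an additive linear model has no interactions and S1 sums to 1", {
  r <- rbind(lo = c(a = 0, b = 0, c = 0), hi = c(a = 1, b = 1, c = 1))
  f <- function(X) 2 * X[, 1] - 3 * X[, 2] + 0.5 * X[, 3]
  s <- sobol_indices(f, r, N = 4096, seed = 2)
  expect_lt(max(abs(s$S2[upper.tri(s$S2)])), 0.02)
  expect_equal(sum(s$S1), 1, tolerance = 0.02)
  av <- c(4, 9, 0.25) / 13.25  # analytic variance shares
  expect_equal(unname(s$S1), av, tolerance = 0.03)
})

test_that("Ishigami first-order indices match their closed form", {
  a <- 7; b <- 0.1
  r <- rbind(lo = rep(-pi, 3), hi = rep(pi, 3))
  colnames(r) <- c("x1", "x2", "x3")
  f <- function(X) sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
  s <- sobol_indices(f, r, N = 8192, seed = 4, n_boot = 40)
  V1 <- 0.5 * (1 + b * pi^4 / 5)^2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  truth <- c(V1 / V, V2 / V, 0)
  ci <- pmax(3 * s$ci$S1_sd, 0.02)
  expect_true(all(abs(s$S1 - truth) <= ci))
  expect_equal(unname(s$ST[3]), V13 / V, tolerance = 0.05)
  # S1_i <= ST_i within estimator noise
  expect_true(all(s$S1 <= s$ST + 3 * s$ci$ST_sd))
})

test_that("doughnut fractions are non-negative and sum to one", {
  r <- rbind(lo = c(x = 0, y = 0, z = 0), hi = c(x = 1, y = 1, z = 1))
  f <- function(X) X[, 1] * X[, 2] + X[, 3]
  s <- sobol_indices(f, r, N = 2048, seed = 6)
  expect_equal(sum(s$doughnut), 1)
  expect_true(all(s$doughnut >= 0))
})

test_that("zero-variance outputs are flagged rather than estimated", {
  r <- rbind(lo = c(x = 0, y = 0, z = 0), hi = c(x = 1, y = 1, z = 1))
  s <- sobol_indices(function(X) rep(1, nrow(X)), r, N = 512, seed = 1)
  expect_true(s$zero_variance)
  expect_true(all(is.na(s$S1)))
})

test_that("non-power-of-two N is rejected", {
  r <- rbind(lo = c(x = 0), hi = c(x = 1))
  expect_error(sobol_indices(identity, r, N = 1000), "power of two")
})

test_that("doubling N shrinks bootstrap CIs by roughly sqrt(2)", {
  a <- 7; b <- 0.1
  r <- rbind(lo = rep(-pi, 3), hi = rep(pi, 3))
  colnames(r) <- c("x1", "x2", "x3")
  f <- function(X) sin(X[, 1]) + a * sin(X[, 2])^2 + b * X[, 3]^4 * sin(X[, 1])
  s1 <- sobol_indices(f, r, N = 1024, seed = 11, n_boot = 60)
  s2 <- sobol_indices(f, r, N = 4096, seed = 11, n_boot = 60)
  ratio <- mean(s1$ci$S1_sd) / mean(s2$ci$S1_sd)
  expect_gt(ratio, 1.3)  # 4x N -> expect ~2, allow wide stochastic slack
  expect_lt(ratio, 3.2)
})

test_that("masking an electrolyte-independent current yields zero sensitivity", {
  att <- attribution_gsa("ICap", "Nao", qoi = "APD70", n_grid = 3,
                         n_prepace_beats = 10)
  expect_true(att$zero_variance)
})

test_that("an all-perturbed mask reproduces the unmasked biomarker pipeline", {
  e <- electrolyte_set(3.8, 120, 2.0)
  b1 <- limit_cycle_biomarkers(electrolytes = e, n_prepace_beats = 10,
                               reference = ref_elec(), mask = override_mask("all"))
  b2 <- limit_cycle_biomarkers(electrolytes = e, n_prepace_beats = 10)
  expect_identical(b1$APD70, b2$APD70)
  expect_identical(b1$RMP, b2$RMP)
})

test_that("per-current attribution fractions normalise to one", {
  atts <- list(
    list(variance = 3, current = "INa"),
    list(variance = 1, current = "INaCa"),
    list(variance = 0, current = "ICap"))
  d <- attribution_doughnut(atts)
  expect_equal(sum(d), 1)
  expect_equal(unname(d["INa"]), 0.75)
})
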