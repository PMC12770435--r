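# Latin-hypercube electrolyte designs, a Gaussian-process emulator, and
# variance-based Sobol sensitivity indices (Saltelli/Jansen pick-freeze
# estimators) with per-current electrolyte attribution.

#' Latin hypercube electrolyte design
#'
#' Plain (maximin-free) LHS over the given ranges: each column is stratified
#' with exactly one sample per equal-probability stratum. The reference
#' combination is appended as a baseline row by default (30 LHS rows + 1
#' baseline = the 31 models analysed per substrate).
#'
#' @param ranges 2 x k matrix with rows `lo`, `hi` (default
#'   [electrolyte_ranges()])
#' @param n number of LHS rows (default 30)
#' @param seed integer seed
#' @param append_baseline append the reference combination as final row
#' @return data.frame with the design columns plus logical `is_baseline`
#' @export
lhs_design <- function(ranges = electrolyte_ranges(), n = 30, seed = 1,
                       append_baseline = TRUE) {
  if (n < 1) stop("n must be >= 1")
  k <- ncol(ranges)
  set.seed(seed)
  u <- lhs::randomLHS(n, k)
  X <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    lo <- ranges[1, j]; hi <- ranges[2, j]
    if (lo == hi) {
      warning(sprintf("degenerate range for column %d; held constant", j))
      X[, j] <- lo
    } else X[, j] <- lo + u[, j] * (hi - lo)
  }
  colnames(X) <- colnames(ranges)
  df <- as.data.frame(X)
  df$is_baseline <- FALSE
  if (append_baseline) {
    ref <- as.list(unclass(electrolyte_reference()))
    base <- as.data.frame(ref[colnames(ranges)])
    base$is_baseline <- TRUE
    df <- rbind(df, base)
  }
  attr(df, "seed") <- seed
  df
}

# ---- Gaussian-process emulator ----------------------------------------------

#' Fit a Gaussian-process emulator
#'
#' Stationary anisotropic squared-exponential kernel with a nugget; inputs are
#' scaled to the unit cube and the output standardised internally.
#' Hyperparameters (per-dimension lengthscales, signal variance, nugget) are
#' fit by marginal-likelihood optimisation with a fixed number of seeded
#' restarts.
#'
#' @param X n x k numeric design matrix (n >= 10)
#' @param y response values (finite)
#' @param n_restarts optimiser restarts
#' @param seed seed for the restart draws
#' @return object of class `gp_emulator`
#' @export
fit_emulator <- function(X, y, n_restarts = 3, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 10) stop("need at least 10 design rows")
  if (any(!is.finite(y)))
    stop("non-finite response values at rows: ",
         paste(which(!is.finite(y)), collapse = ", "))
  k <- ncol(X)
  xlo <- apply(X, 2, min); xhi <- apply(X, 2, max)
  span <- pmax(xhi - xlo, 1e-12)
  U <- sweep(sweep(X, 2, xlo), 2, span, "/")
  ymu <- mean(y); ysd <- max(sd(y), 1e-12)
  ys <- (y - ymu) / ysd
  n <- nrow(U)

  sqdist <- lapply(seq_len(k), function(j) outer(U[, j], U[, j], "-")^2)

  nll <- function(theta) {
    # theta = log lengthscales (k), log signal sd, log nugget sd
    ls <- exp(theta[seq_len(k)]); sf2 <- exp(2 * theta[k + 1])
    sn2 <- exp(2 * theta[k + 2])
    Q <- matrix(0, n, n)
    for (j in seq_len(k)) Q <- Q + sqdist[[j]] / ls[j]^2
    K <- sf2 * exp(-0.5 * Q) + diag(sn2 + 1e-10, n)
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    as.numeric(0.5 * sum(ys * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
  }

  set.seed(seed)
  starts <- rbind(rep(0, k + 2),
                  matrix(rnorm(n_restarts * (k + 2), 0, 1), n_restarts))
  starts[, k + 2] <- starts[, k + 2] - 3  # small initial nugget
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- tryCatch(optim(starts[i, ], nll, method = "L-BFGS-B",
                         lower = rep(c(-4, -4, -8), c(k, 1, 1)),
                         upper = rep(c(3, 3, 1), c(k, 1, 1))),
                   error = function(e) NULL)
    if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
  }
  theta <- best$par
  ls <- exp(theta[seq_len(k)]); sf2 <- exp(2 * theta[k + 1])
  sn2 <- exp(2 * theta[k + 2])
  Q <- matrix(0, n, n)
  for (j in seq_len(k)) Q <- Q + sqdist[[j]] / ls[j]^2
  K <- sf2 * exp(-0.5 * Q) + diag(sn2 + 1e-10, n)
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), ys))
  structure(list(U = U, xlo = xlo, span = span, ymu = ymu, ysd = ysd,
                 ls = ls, sf2 = sf2, sn2 = sn2, chol = ch, alpha = alpha,
                 nll = best$value),
            class = "gp_emulator")
}

#' Predict from a Gaussian-process emulator
#'
#' @param object a `gp_emulator`
#' @param newdata matrix of input rows (original scale)
#' @param ... unused
#' @return list with `mean` and `var` vectors
#' @export
predict.gp_emulator <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  Un <- sweep(sweep(Xn, 2, object$xlo), 2, object$span, "/")
  k <- ncol(object$U)
  m <- nrow(Un)
  Ks <- matrix(0, m, nrow(object$U))
  for (j in seq_len(k))
    Ks <- Ks + outer(Un[, j], object$U[, j], "-")^2 / object$ls[j]^2
  Ks <- object$sf2 * exp(-0.5 * Ks)
  mu <- as.numeric(Ks %*% object$alpha)
  v <- forwardsolve(t(object$chol), t(Ks))
  var <- pmax(object$sf2 - colSums(v^2), 0) + object$sn2
  list(mean = object$ymu + object$ysd * mu, var = object$ysd^2 * var)
}

# ---- Sobol indices ----------------------------------------------------------

#' Variance-based Sobol sensitivity indices
#'
#' Saltelli pick-freeze estimation of first-order (Jansen), total-order
#' (Jansen) and closed second-order indices of `f` under independent uniform
#' inputs over `ranges`. Small negative estimates are clamped to zero only in
#' the normalised "doughnut" fractions; raw values are reported.
#'
#' @param f function taking an m x k matrix and returning m values (e.g. the
#'   mean of a [fit_emulator()] via [emulator_fun()])
#' @param ranges 2 x k matrix (rows lo, hi)
#' @param N base sample size; must be a power of two
#' @param seed integer seed
#' @param n_boot bootstrap replicates for confidence intervals (0 = none)
#' @return list of class `sobol_result`: `S1`, `ST` (named), `S2` (k x k
#'   matrix of pair indices), `doughnut` (normalised fractions of S1 and S2
#'   summing to 1), `var_total`, `N`, `seed`, `zero_variance` flag, and
#'   bootstrap `ci` when requested
#' @export
sobol_indices <- function(f, ranges = electrolyte_ranges(), N = 1024, seed = 1,
                          n_boot = 0) {
  k <- ncol(ranges)
  if (bitwAnd(N, N - 1L) != 0) stop("N must be a power of two")
  set.seed(seed)
  scale_u <- function(u) {
    x <- sweep(u, 2, ranges[2, ] - ranges[1, ], "*")
    sweep(x, 2, ranges[1, ], "+")
  }
  A <- scale_u(matrix(runif(N * k), N, k))
  B <- scale_u(matrix(runif(N * k), N, k))
  colnames(A) <- colnames(B) <- colnames(ranges)
  fA <- f(A); fB <- f(B)
  fAB <- matrix(NA_real_, N, k)  # A with column i from B
  fBA <- matrix(NA_real_, N, k)  # B with column i from A
  for (i in seq_len(k)) {
    Ai <- A; Ai[, i] <- B[, i]; fAB[, i] <- f(Ai)
    Bi <- B; Bi[, i] <- A[, i]; fBA[, i] <- f(Bi)
  }
  # centre the evaluations: the closed second-order estimator subtracts f0^2,
  # which suffers catastrophic cancellation when |mean| >> sd (e.g. RMP)
  mu <- mean(c(fA, fB))
  fA <- fA - mu; fB <- fB - mu; fAB <- fAB - mu; fBA <- fBA - mu
  est <- function(idx) {
    fa <- fA[idx]; fb <- fB[idx]
    fab <- fAB[idx, , drop = FALSE]; fba <- fBA[idx, , drop = FALSE]
    V <- var(c(fa, fb))
    f0a <- mean(fa); f0b <- mean(fb)
    S1 <- ST <- numeric(k)
    for (i in seq_len(k)) {
      S1[i] <- (V - 0.5 * mean((fb - fab[, i])^2)) / V
      ST[i] <- 0.5 * mean((fa - fab[, i])^2) / V
    }
    S2 <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      Vij_closed <- mean(fba[, i] * fab[, j]) - f0a * f0b
      S2[i, j] <- S2[j, i] <- Vij_closed / V - S1[i] - S1[j]
    }
    list(S1 = S1, ST = ST, S2 = S2, V = V)
  }
  Vtot <- var(c(fA, fB))
  if (!is.finite(Vtot) || Vtot < 1e-14) {
    nm <- colnames(ranges)
    return(structure(list(S1 = setNames(rep(NA_real_, k), nm),
                          ST = setNames(rep(NA_real_, k), nm),
                          S2 = matrix(NA_real_, k, k), doughnut = NULL,
                          var_total = Vtot, N = N, seed = seed,
                          zero_variance = TRUE),
                     class = "sobol_result"))
  }
  e <- est(seq_len(N))
  nm <- colnames(ranges)
  names(e$S1) <- names(e$ST) <- nm
  dimnames(e$S2) <- list(nm, nm)
  # doughnut: non-negative fractions over S1 and pairwise S2, summing to 1
  pieces <- c(e$S1, e$S2[upper.tri(e$S2)])
  pnames <- c(nm, combn(nm, 2, paste, collapse = ":"))
  pieces <- pmax(pieces, 0)
  doughnut <- setNames(pieces / sum(pieces), pnames)
  out <- list(S1 = e$S1, ST = e$ST, S2 = e$S2, doughnut = doughnut,
              var_total = e$V, N = N, seed = seed, zero_variance = FALSE)
  if (n_boot > 0) {
    bs1 <- matrix(NA_real_, n_boot, k)
    bst <- matrix(NA_real_, n_boot, k)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(N, N, replace = TRUE)
      eb <- est(idx)
      bs1[b, ] <- eb$S1; bst[b, ] <- eb$ST
    }
    out$ci <- list(S1_sd = apply(bs1, 2, sd), ST_sd = apply(bst, 2, sd))
  }
  structure(out, class = "sobol_result")
}

#' Wrap an emulator as a vectorised function of its inputs
#' @param em a `gp_emulator`
#' @return function mapping an input matrix to the emulator posterior mean
#' @export
emulator_fun <- function(em) function(X) predict(em, X)$mean

# ---- per-current attribution -------------------------------------------------

#' Per-current electrolyte sensitivity attribution
#'
#' Varies a single electrolyte over its range while the override mask sends
#' the perturbed value only into the named current (all other currents see
#' the reference electrolytes), evaluates the 0D biomarker pipeline on a
#' uniform grid, and reports the output variance attributable to that current.
#'
#' @param current_name one of [current_names()]
#' @param electrolyte_name "Ko", "Nao" or "Cao"
#' @param qoi biomarker name as returned by [limit_cycle_biomarkers()]
#'   (e.g. "APD70", "RMP")
#' @param params cell parameters
#' @param ranges 2 x 3 electrolyte ranges
#' @param n_grid grid resolution over the varied electrolyte
#' @param cl,n_prepace_beats pipeline pacing settings
#' @return list with `variance` (output variance over the uniform grid),
#'   `values`, `grid`, and `zero_variance` flag
#' @export
attribution_gsa <- function(current_name, electrolyte_name, qoi = "APD70",
                            params = crn_parameters(),
                            ranges = electrolyte_ranges(), n_grid = 7,
                            cl = 1000, n_prepace_beats = 30) {
  stopifnot(current_name %in% current_names(),
            electrolyte_name %in% colnames(ranges))
  mask <- override_mask(current_name)
  ref <- electrolyte_reference()
  grid <- seq(ranges[1, electrolyte_name], ranges[2, electrolyte_name],
              length.out = n_grid)
  vals <- vapply(grid, function(g) {
    e <- unclass(ref); e[[electrolyte_name]] <- g
    pert <- do.call(electrolyte_set, as.list(e))
    bm <- limit_cycle_biomarkers(params, pert, cl = cl,
                                 n_prepace_beats = n_prepace_beats,
                                 reference = ref, mask = mask)
    as.numeric(bm[[qoi]])
  }, 0)
  v <- var(vals) * (n_grid - 1) / n_grid   # population variance over the grid
  list(variance = v, values = vals, grid = grid,
       current = current_name, electrolyte = electrolyte_name, qoi = qoi,
       zero_variance = v < 1e-10)
}

#' Doughnut fractions of per-current attribution variances
#'
#' Normalises a set of [attribution_gsa()] variances for one electrolyte into
#' fractions that sum to 1.
#'
#' @param attributions list of `attribution_gsa` results
#' @return named numeric vector of fractions summing to 1
#' @export
attribution_doughnut <- function(attributions) {
  v <- vapply(attributions, function(a) max(a$variance, 0), 0)
  names(v) <- vapply(attributions, function(a) a$current, "")
  if (sum(v) <= 0) stop("all attribution variances are zero")
  v / sum(v)
}
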