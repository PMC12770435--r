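# Endpoint classification (logit, random forest, gradient boosting),
# permutation feature importance and exact Shapley attribution.

.FEATURE_COLS <- c("Ko", "Nao", "Cao", "fibrosis_fraction", "surface_area")

.feature_columns <- function(table) {
  cols <- intersect(.FEATURE_COLS, names(table))
  if (length(cols) < 3) stop("feature table must contain Ko, Nao, Cao")
  cols
}

#' Train an endpoint classifier
#'
#' Fits a seeded binary classifier for one endpoint column of a feature table
#' (electrolytes, optionally augmented with fibrosis fraction and surface
#' area). Requires at least two samples of each class. The reported score is
#' the coefficient of determination (R^2) of the predicted class probability
#' against the 0/1 labels; accuracy and AUROC are reported alongside.
#'
#' @param table data.frame with feature columns and logical endpoint columns
#' @param endpoint endpoint column name
#' @param kind "random_forest" (the reporting default), "logit" or
#'   "gradient_boost"
#' @param seed integer seed
#' @return object of class `endpoint_classifier` with `r2`, `accuracy`,
#'   `auroc`, the fitted model and a `predict_prob(newdata)` closure
#' @export
train_classifier <- function(table, endpoint,
                             kind = c("random_forest", "logit",
                                      "gradient_boost"),
                             seed = 1) {
  kind <- match.arg(kind)
  cols <- .feature_columns(table)
  y <- as.logical(table[[endpoint]])
  if (any(is.na(y))) stop("endpoint contains missing values")
  if (min(table(y)) < 2 || length(unique(y)) < 2)
    stop(sprintf("endpoint '%s' needs at least two samples per class; skipped",
                 endpoint))
  X <- as.data.frame(table[cols])
  set.seed(seed)
  if (kind == "logit") {
    dat <- cbind(X, .y = as.numeric(y))
    fit <- suppressWarnings(glm(.y ~ ., data = dat, family = "binomial"))
    predict_prob <- function(newdata)
      as.numeric(predict(fit, newdata = as.data.frame(newdata),
                         type = "response"))
  } else if (kind == "random_forest") {
    fit <- randomForest::randomForest(x = X, y = factor(y, c(FALSE, TRUE)),
                                      ntree = 500)
    predict_prob <- function(newdata)
      as.numeric(predict(fit, newdata = as.data.frame(newdata),
                         type = "prob")[, "TRUE"])
  } else {
    dm <- xgboost::xgb.DMatrix(as.matrix(X), label = as.numeric(y))
    fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                            max_depth = 3, eta = 0.1,
                                            nthread = 1, seed = seed),
                              data = dm, nrounds = 100, verbose = 0)
    predict_prob <- function(newdata)
      as.numeric(predict(fit, xgboost::xgb.DMatrix(
        as.matrix(as.data.frame(newdata)[cols]))))
  }
  p <- predict_prob(X)
  yn <- as.numeric(y)
  r2 <- 1 - sum((yn - p)^2) / sum((yn - mean(yn))^2)
  acc <- mean((p > 0.5) == y)
  # AUROC by the rank (Mann-Whitney) formula
  r <- rank(p)
  n1 <- sum(y); n0 <- sum(!y)
  auroc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(kind = kind, endpoint = endpoint, features = cols,
                 model = fit, predict_prob = predict_prob,
                 r2 = r2, accuracy = acc, auroc = auroc, seed = seed),
            class = "endpoint_classifier")
}

#' Permutation feature importance
#'
#' Score drop of the classifier's R^2 when one feature column is permuted,
#' repeated `n_permutations` times per feature (mean and sd reported).
#'
#' @param classifier an [train_classifier()] fit
#' @param table the feature table (with the endpoint column)
#' @param endpoint endpoint column name
#' @param n_permutations permutations per feature (default 100)
#' @param seed integer seed
#' @return data.frame with `feature`, `importance_mean`, `importance_sd`, and
#'   attribute `raw` (n_permutations x feature matrix of score drops)
#' @export
permutation_importance <- function(classifier, table, endpoint = classifier$endpoint,
                                   n_permutations = 100, seed = 1) {
  cols <- classifier$features
  X <- as.data.frame(table[cols])
  y <- as.numeric(as.logical(table[[endpoint]]))
  score <- function(Xp) {
    p <- classifier$predict_prob(Xp)
    1 - sum((y - p)^2) / sum((y - mean(y))^2)
  }
  base <- score(X)
  set.seed(seed)
  raw <- matrix(NA_real_, n_permutations, length(cols),
                dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    for (b in seq_len(n_permutations)) {
      Xp <- X
      Xp[[cols[j]]] <- sample(Xp[[cols[j]]])
      raw[b, j] <- base - score(Xp)
    }
  }
  out <- data.frame(feature = cols,
                    importance_mean = colMeans(raw),
                    importance_sd = apply(raw, 2, sd))
  attr(out, "raw") <- raw
  attr(out, "base_score") <- base
  out
}

#' Exact Shapley values of predicted probabilities
#'
#' Interventional Shapley values computed exactly by enumerating all feature
#' subsets against a background sample: for every explained row the values
#' satisfy local accuracy, `sum(phi) + base_value = prediction`, to machine
#' precision. Works for any probabilistic classifier; feasible because the
#' feature space here is small (3-5 features).
#'
#' @param classifier an [train_classifier()] fit
#' @param table rows to explain (feature columns used)
#' @param background background rows (default: the explained table)
#' @param max_background background subsample cap
#' @param seed seed for the background subsample
#' @return list of class `shapley_summary`: `phi` (rows x features),
#'   `base_value`, `prediction`, `additivity_error`
#' @export
shapley_summary <- function(classifier, table, background = table,
                            max_background = 64, seed = 1) {
  cols <- classifier$features
  p <- length(cols)
  if (p > 12) stop("exact enumeration limited to <= 12 features")
  X <- as.data.frame(table[cols])
  B <- as.data.frame(background[cols])
  if (nrow(B) > max_background) {
    set.seed(seed)
    B <- B[sample.int(nrow(B), max_background), , drop = FALSE]
  }
  n <- nrow(X); nb <- nrow(B)
  nsub <- 2^p
  # v[r, S]: mean prediction with features in S from row r, rest from background
  v <- matrix(NA_real_, n, nsub)
  for (S in 0:(nsub - 1)) {
    inS <- which(bitwAnd(S, bitwShiftL(1L, 0:(p - 1))) != 0)
    big <- B[rep(seq_len(nb), times = n), , drop = FALSE]
    if (length(inS) > 0) {
      rep_rows <- rep(seq_len(n), each = nb)
      for (j in inS) big[[cols[j]]] <- X[rep_rows, cols[j]]
    }
    pred <- classifier$predict_prob(big)
    v[, S + 1] <- colMeans(matrix(pred, nb, n))
  }
  fact <- factorial(0:p)
  phi <- matrix(0, n, p, dimnames = list(NULL, cols))
  for (j in seq_len(p)) {
    bitj <- bitwShiftL(1L, j - 1L)
    for (S in 0:(nsub - 1)) {
      if (bitwAnd(S, bitj) != 0) next
      s <- sum(bitwAnd(S, bitwShiftL(1L, 0:(p - 1))) != 0)
      w <- fact[s + 1] * fact[p - s] / fact[p + 1]
      phi[, j] <- phi[, j] + w * (v[, S + bitj + 1] - v[, S + 1])
    }
  }
  base <- v[, 1]
  full <- v[, nsub]
  structure(list(phi = phi, base_value = base, prediction = full,
                 additivity_error = max(abs(rowSums(phi) + base - full))),
            class = "shapley_summary")
}
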