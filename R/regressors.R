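#' @include reaction.R
NULL

# Each registry entry is a RegressorSpec: a name, a hyperparameter grid
# (named list; candidates are the rows of expand.grid() over it, the first
# grid dimension varying fastest — that row order is the declared order for
# tie-breaks), an autoscale flag (continuous, one-hot and descriptor
# columns are all scaled by training-fold statistics for linear/SVR
# methods; tree ensembles see the raw features), and fit/predict closures.

makeRegressorSpec <- function(name, grid, scale, fit, predict) {
  for (g in grid)
    if (is.numeric(g) && any(!is.finite(g)))
      stop("grid values must be finite", call. = FALSE)
  structure(list(name = name, grid = grid, scale = scale,
                 fit = fit, predict = predict),
            class = "RegressorSpec")
}

#' @export
print.RegressorSpec <- function(x, ...) {
  cat(sprintf("RegressorSpec '%s': %d grid candidate(s), autoscale = %s\n",
              x$name, nrow(gridCandidates(x)), x$scale))
  invisible(x)
}

# Grid candidates in declared order; a spec with an empty grid has a single
# parameterless candidate.
gridCandidates <- function(spec) {
  if (!length(spec$grid)) return(data.frame(row.names = 1L))
  expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

# ---- fit/predict backends ---------------------------------------------------

fitOls <- function(X, y, params, seed) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0            # aliased (collinear) columns drop out
  list(coef = coef)
}
predictOls <- function(model, X) drop(cbind(1, X) %*% model$coef)

# PLS1 by NIPALS with deflation. Component extraction stops early when the
# residual covariance vanishes (duplicated ligand descriptor rows and
# one-hot blocks make reaction design matrices low-rank, so the requested
# component count routinely exceeds the effective rank).
fitPls <- function(X, y, params, seed) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm); yc <- y - ym
  A <- max(1L, min(params$ncomp, ncol(X), nrow(X) - 1L))
  W <- P <- matrix(0, ncol(X), A); q <- numeric(A)
  tol <- 1e-10 * max(1, sum(Xc^2))
  a <- 0L
  for (comp in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (!is.finite(nw) || nw^2 <= tol) break
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt <= tol) break
    p <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p)
    yc <- yc - t_ * q_
    a <- comp
    W[, a] <- w; P[, a] <- p; q[a] <- q_
  }
  if (a == 0L) return(list(coef = rep(0, ncol(X)), intercept = ym))
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  beta <- drop(W %*% solve(crossprod(P, W), q[seq_len(a)]))
  list(coef = beta, intercept = ym - sum(xm * beta))
}
predictPls <- function(model, X) drop(X %*% model$coef) + model$intercept

fitGlmnet <- function(alpha) function(X, y, params, seed) {
  a <- if (is.null(params$alpha)) alpha else params$alpha
  path <- sort(unique(c(params$lambda, 10^seq(-3, 3, length.out = 7))),
               decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, alpha = a, lambda = path, standardize = FALSE)
  list(fit = fit, lambda = params$lambda)
}
predictGlmnet <- function(model, X)
  drop(predict(model$fit, X, s = model$lambda))

fitSvr <- function(kernel) function(X, y, params, seed) {
  args <- list(x = X, y = y, type = "eps-regression", kernel = kernel,
               cost = params$C, epsilon = params$epsilon, scale = FALSE)
  if (kernel == "radial") args$gamma <- params$gamma
  list(fit = do.call(e1071::svm, args))
}
predictSvr <- function(model, X) unname(predict(model$fit, X))

fitRf <- function(X, y, params, seed) {
  p <- ncol(X)
  mtry <- switch(params$mtry,
                 sqrt = max(1L, floor(sqrt(p))),
                 third = max(1L, floor(p / 3)),
                 all = p)
  fit <- ranger::ranger(y = y, x = as.data.frame(X), num.trees = 500L,
                        mtry = mtry, seed = seed, num.threads = 1L)
  list(fit = fit)
}
predictRf <- function(model, X)
  predict(model$fit, data = as.data.frame(X), num.threads = 1L)$predictions

fitGbm <- function(X, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  fit <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = params$learning_rate,
                  max_leaves = params$leaves, max_depth = 0,
                  grow_policy = "lossguide", tree_method = "hist",
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = 500L, verbose = 0)
  list(fit = fit)
}
predictGbm <- function(model, X)
  predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1))

# ---- registry ---------------------------------------------------------------

#' Default regression-method registry
#'
#' Nine regressors spanning linear, kernel and tree-ensemble families, the
#' breadth appropriate for small HTE yield datasets: ordinary least squares
#' (OLS), partial least squares (PLS), ridge (RR), lasso (LASSO), elastic
#' net (EN), linear-kernel support vector regression (LSVR),
#' Gaussian-kernel SVR (SVRG), random forest (RF), and a leaf-wise gradient
#' boosting machine (GBM). Hyperparameter grids: PLS components 1-10
#' (clamped to the feature count); RR/LASSO/EN penalty lambda on a 7-point
#' log grid 1e-3..1e3, EN mixing in {0.25, 0.5, 0.75}; SVR cost 0.1..100,
#' epsilon in {0.1, 1}, Gaussian gamma on a 5-point log2 grid 2^-10..1; RF
#' 500 trees, mtry in {sqrt(p), p/3, p}; GBM 500 rounds, leaves in
#' {7, 15, 31}, learning rate in {0.05, 0.1}. OLS has no hyperparameters.
#' Grids are plain list entries on each spec and can be overridden.
#'
#' @param methods optional character vector selecting a subset, in registry
#'   order
#' @return named list of `RegressorSpec` objects
#' @examples
#' names(defaultRegistry())
#' defaultRegistry(c("OLS", "RR"))
#' @export
defaultRegistry <- function(methods = NULL) {
  lambdaGrid <- 10^seq(-3, 3, length.out = 7)
  reg <- list(
    OLS = makeRegressorSpec("OLS", list(), TRUE, fitOls, predictOls),
    PLS = makeRegressorSpec("PLS", list(ncomp = 1:10), TRUE,
                            fitPls, predictPls),
    RR = makeRegressorSpec("RR", list(lambda = lambdaGrid), TRUE,
                           fitGlmnet(0), predictGlmnet),
    LASSO = makeRegressorSpec("LASSO", list(lambda = lambdaGrid), TRUE,
                              fitGlmnet(1), predictGlmnet),
    EN = makeRegressorSpec("EN", list(lambda = lambdaGrid,
                                      alpha = c(0.25, 0.5, 0.75)), TRUE,
                           fitGlmnet(0.5), predictGlmnet),
    LSVR = makeRegressorSpec("LSVR", list(C = 10^(-1:2),
                                          epsilon = c(0.1, 1)), TRUE,
                             fitSvr("linear"), predictSvr),
    SVRG = makeRegressorSpec("SVRG", list(C = 10^(-1:2),
                                          epsilon = c(0.1, 1),
                                          gamma = 2^seq(-10, 0,
                                                        length.out = 5)),
                             TRUE, fitSvr("radial"), predictSvr),
    RF = makeRegressorSpec("RF", list(mtry = c("sqrt", "third", "all")),
                           FALSE, fitRf, predictRf),
    GBM = makeRegressorSpec("GBM", list(leaves = c(7, 15, 31),
                                        learning_rate = c(0.05, 0.1)),
                            FALSE, fitGbm, predictGbm)
  )
  if (is.null(methods)) return(reg)
  unknown <- setdiff(methods, names(reg))
  if (length(unknown))
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  reg[intersect(names(reg), methods)]
}
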