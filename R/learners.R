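#' Tuning policy for a learner
#'
#' Returns the default hyperparameter policy for a method; any element can
#' be overridden through `...`.  Defaults follow the benchmarking
#' protocol: elastic-net penalty `lambda` tuned by internal 10-fold CV on
#' the training fold over a 100-value log-spaced path auto-scaled from the
#' data; GBM tuned on a depth \{1, 2, 3\} x shrinkage
#' \{0.001, 0.01, 0.1\} grid with 1000 trees, subsampling rate 0.5, and
#' the prediction iteration count chosen on an internal 70/30 validation
#' split; random forest with 700 trees, `p/3` split candidates, minimum
#' node size 5; SVR (epsilon-insensitive, Gaussian kernel) tuned on a
#' logarithmic grid of `epsilon`, cost `C` and kernel width `gamma`
#' against an internal 70/30 validation split.
#'
#' @param method one of `"lasso"`, `"ridge"`, `"enet"`, `"rf"`, `"gbm"`,
#'   `"svr"`, `"gblup"`, `"bloom"`, `"mean"`.
#' @param ... overrides (e.g. `num_trees = 200` or `depths = c(1, 3)`).
#' @return a list of class `tuning_policy`.
#' @export
tuning_policy <- function(method, ...) {
  base <- switch(method,
    lasso = list(alpha = 1, nfolds = 10, nlambda = 100),
    ridge = list(alpha = 0, nfolds = 10, nlambda = 100),
    enet  = list(alpha = 0.5, nfolds = 10, nlambda = 100),
    rf    = list(num_trees = 700, mtry_frac = 1 / 3, min_node = 5),
    gbm   = list(depths = c(1, 2, 3), shrinkages = c(0.001, 0.01, 0.1),
                 n_trees = 1000, subsample = 0.5, val_fraction = 0.3),
    svr   = list(epsilons = c(0.01, 0.1, 0.5), costs = c(0.1, 1, 10, 100),
                 gammas = 10^seq(-4, 0, length.out = 10),
                 val_fraction = 0.3),
    gblup = list(),
    bloom = list(max_stages = 4, B = 1000, fdr_level = 0.05),
    mean  = list(),
    stop("unknown method tag: ", method))
  override <- list(...)
  base[names(override)] <- override
  structure(c(list(method = method), base), class = "tuning_policy")
}

learner_methods <- c("lasso", "ridge", "enet", "rf", "gbm", "svr")

# one-hot expansion for learners that need a numeric design (gbm, svr,
# linear); tree learner ranger consumes factors natively.
as_numeric_design <- function(x) {
  if (is.matrix(x)) return(x)
  stats::model.matrix(~ . - 1, data = x)
}

learner_matrix <- function(G) {
  if (inherits(G, "genotype_matrix")) G$values else G
}

#' Fit a regression learner under the uniform contract
#'
#' Hyperparameters are chosen only from the supplied training data — by
#' internal cross-validation (penalised fits) or an internal 70/30
#' train/validation split (GBM, SVR) — and the final model is refit on the
#' whole training set with the chosen values.  Test-fold phenotypes are
#' never seen.
#'
#' @param method a learner tag (see [tuning_policy()]).
#' @param G a [genotype_matrix()], plain matrix, or data frame (the latter
#'   may carry factor columns, e.g. a multi-task trait indicator; these
#'   are one-hot expanded for numeric backends).
#' @param y response vector, no missing values.
#' @param policy a [tuning_policy()]; defaults per method.
#' @param seed integer seed controlling every stochastic step.
#' @return an object of class `fitted_learner` with `method`, `params`
#'   (chosen hyperparameters), `fit`, `markers` (training attribute
#'   names).
#' @export
fit_learner <- function(method, G, y, policy = NULL, seed = 1L) {
  if (!(method %in% learner_methods)) stop("unknown method tag: ", method)
  if (is.null(policy)) policy <- tuning_policy(method)
  x <- learner_matrix(G)
  markers <- colnames(x)
  if (anyNA(y)) stop("training response contains missing values")
  if (stats::var(y) == 0) {
    return(structure(list(method = method, params = list(constant = TRUE),
                          fit = mean(y), markers = markers),
                     class = "fitted_learner"))
  }
  fit <- switch(method,
    lasso = , ridge = , enet = fit_glmnet(x, y, policy, seed),
    rf  = fit_rf(x, y, policy, seed),
    gbm = fit_gbm(x, y, policy, seed),
    svr = fit_svr(x, y, policy, seed))
  structure(c(fit, list(method = method, markers = markers)),
            class = "fitted_learner")
}

fit_glmnet <- function(x, y, policy, seed) {
  xm <- as_numeric_design(x)
  set.seed(child_seed(seed, 21L))
  cvfit <- glmnet::cv.glmnet(xm, y, alpha = policy$alpha,
                             nfolds = policy$nfolds,
                             nlambda = policy$nlambda)
  list(fit = cvfit,
       params = list(alpha = policy$alpha, lambda = cvfit$lambda.min))
}

fit_rf <- function(x, y, policy, seed) {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  mtry <- max(1L, floor(ncol(df) * policy$mtry_frac))
  fit <- ranger::ranger(x = df, y = y, num.trees = policy$num_trees,
                        mtry = mtry, min.node.size = policy$min_node,
                        num.threads = 1, seed = child_seed(seed, 22L),
                        respect.unordered.factors = "order")
  list(fit = fit, params = list(num_trees = policy$num_trees, mtry = mtry,
                                min_node = policy$min_node))
}

fit_gbm <- function(x, y, policy, seed) {
  xm <- as_numeric_design(x)
  set.seed(child_seed(seed, 23L))
  n <- nrow(xm)
  val <- sample.int(n, max(2L, round(policy$val_fraction * n)))
  dtr <- xgboost::xgb.DMatrix(xm[-val, , drop = FALSE], label = y[-val])
  dva <- xgboost::xgb.DMatrix(xm[val, , drop = FALSE], label = y[val])
  grid <- expand.grid(depth = policy$depths, shrinkage = policy$shrinkages)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    params <- xgboost::xgb.params(
      max_depth = grid$depth[g], eta = grid$shrinkage[g],
      subsample = policy$subsample, objective = "reg:squarederror",
      nthread = 1, seed = child_seed(seed, 23L + g))
    bst <- xgboost::xgb.train(params, dtr, nrounds = policy$n_trees,
                              evals = list(val = dva), verbose = 0)
    log <- attributes(bst)$evaluation_log
    it <- which.min(log$val_rmse)
    if (is.null(best) || log$val_rmse[it] < best$rmse)
      best <- list(depth = grid$depth[g], shrinkage = grid$shrinkage[g],
                   nrounds = it, rmse = log$val_rmse[it])
  }
  dall <- xgboost::xgb.DMatrix(xm, label = y)
  params <- xgboost::xgb.params(
    max_depth = best$depth, eta = best$shrinkage,
    subsample = policy$subsample, objective = "reg:squarederror",
    nthread = 1, seed = child_seed(seed, 23L))
  fit <- xgboost::xgb.train(params, dall, nrounds = best$nrounds,
                            verbose = 0)
  list(fit = fit, params = best[c("depth", "shrinkage", "nrounds")])
}

fit_svr <- function(x, y, policy, seed) {
  xm <- as_numeric_design(x)
  set.seed(child_seed(seed, 24L))
  n <- nrow(xm)
  val <- sample.int(n, max(2L, round(policy$val_fraction * n)))
  grid <- expand.grid(epsilon = policy$epsilons, C = policy$costs,
                      gamma = policy$gammas)
  best <- NULL
  for (g in seq_len(nrow(grid))) {
    m <- kernlab::ksvm(xm[-val, , drop = FALSE], y[-val], type = "eps-svr",
                       kernel = "rbfdot",
                       kpar = list(sigma = grid$gamma[g]),
                       C = grid$C[g], epsilon = grid$epsilon[g],
                       scaled = FALSE)
    pr <- kernlab::predict(m, xm[val, , drop = FALSE])
    rmse <- sqrt(mean((pr - y[val])^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(epsilon = grid$epsilon[g], C = grid$C[g],
                   gamma = grid$gamma[g], rmse = rmse)
  }
  fit <- kernlab::ksvm(xm, y, type = "eps-svr", kernel = "rbfdot",
                       kpar = list(sigma = best$gamma), C = best$C,
                       epsilon = best$epsilon, scaled = FALSE)
  list(fit = fit, params = best[c("epsilon", "C", "gamma")])
}

#' Predict with a fitted learner
#'
#' @param object a `fitted_learner`.
#' @param G test genotypes whose attribute set matches the training set
#'   exactly (marker-set mismatch is an error).
#' @param ... unused.
#' @return numeric predictions, one per test sample.
#' @export
predict.fitted_learner <- function(object, G, ...) {
  x <- learner_matrix(G)
  if (!identical(colnames(x), object$markers))
    stop("test attribute set does not match the training attribute set")
  if (isTRUE(object$params$constant))
    return(rep(object$fit, nrow(x)))
  switch(object$method,
    lasso = , ridge = , enet =
      as.vector(stats::predict(object$fit, as_numeric_design(x),
                               s = "lambda.min")),
    rf = stats::predict(object$fit,
                        as.data.frame(x, stringsAsFactors = FALSE),
                        num.threads = 1)$predictions,
    gbm = stats::predict(object$fit, as_numeric_design(x)),
    svr = as.vector(kernlab::predict(object$fit, as_numeric_design(x))))
}

#' @export
print.fitted_learner <- function(x, ...) {
  cat(sprintf("fitted_learner[%s]: %s\n", x$method,
              paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", ")))
  invisible(x)
}
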