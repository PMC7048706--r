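#' Compute a genomic similarity matrix (GSM)
#'
#' `K = Z Z' / p` where `Z` is the column-standardized (mean 0, unit
#' sample variance) marker matrix over the `p` polymorphic markers;
#' constant markers carry no relatedness information and are dropped from
#' `p`.  This standardized cross-product is the common VanRaden-style
#' kinship (up to scaling) and makes genomic BLUP a ridge regression on
#' standardized markers.
#'
#' @param G a [genotype_matrix()] with no missing values (impute first).
#' @return an object of class `gsm`: list with `K` (n x n symmetric
#'   matrix), `sample_ids`, `n_markers` used, `scheme`.
#' @export
compute_gsm <- function(G) {
  v <- G$values
  if (anyNA(v)) stop("genotypes contain missing values: impute first")
  if (nrow(v) < 2) stop("need at least 2 samples")
  sds <- apply(v, 2, stats::sd)
  poly <- sds > 0
  if (!any(poly)) stop("all markers are constant: GSM undefined")
  Z <- scale(v[, poly, drop = FALSE])
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  structure(list(K = K, sample_ids = rownames(v), n_markers = ncol(Z),
                 scheme = "standardized-crossproduct"),
            class = "gsm")
}

#' @export
print.gsm <- function(x, ...) {
  cat(sprintf("gsm: %d samples, %d polymorphic markers (%s)\n",
              nrow(x$K), x$n_markers, x$scheme))
  invisible(x)
}

as_gsm <- function(K, ids = rownames(K)) {
  if (inherits(K, "gsm")) return(K)
  structure(list(K = K, sample_ids = ids, n_markers = NA_integer_,
                 scheme = "user"), class = "gsm")
}

#' Eigendecomposition of a GSM, cached for reuse across traits
#'
#' Fitting many traits against one genotype matrix repeats the same
#' decomposition; compute it once and pass it to [fit_gblup()].
#'
#' @param K a `gsm` or symmetric matrix.
#' @return `eigen()` result (symmetric).
#' @export
gsm_eigen <- function(K) {
  K <- as_gsm(K)
  eigen(K$K, symmetric = TRUE)
}

# Restricted log-likelihood of the intercept model y = 1*mu + g + e with
# g ~ N(0, sg2*K), e ~ N(0, se2*I), profiled over sg2 at fixed variance
# ratio delta = se2/sg2, using the eigendecomposition K = U Xi U'.
reml_profile <- function(delta, xi, yt, xt) {
  n <- length(yt)
  w <- 1 / (xi + delta)
  xwx <- sum(xt^2 * w)
  beta <- sum(xt * yt * w) / xwx
  r <- yt - xt * beta
  rss <- sum(r^2 * w)
  sg2 <- rss / (n - 1)
  ll <- -0.5 * ((n - 1) * log(2 * pi * sg2) + (n - 1) +
                  sum(log(xi + delta)) + log(xwx))
  list(ll = ll, sg2 = sg2, mu = beta)
}

#' Fit genomic BLUP by REML
#'
#' Model: `y = 1 mu + g + e`, `g ~ N(0, sigma_g^2 K)`,
#' `e ~ N(0, sigma_e^2 I)`.  The variance components maximize the
#' restricted likelihood, found by a single eigendecomposition of `K`
#' followed by a 1-D optimization of the profiled restricted
#' log-likelihood over `log(lambda)` with `lambda = sigma_e^2/sigma_g^2`
#' bracketed in `[1e-6, 1e6]` (tolerance 1e-8).
#'
#' @param K a `gsm` (or symmetric matrix) over the training samples.
#' @param y phenotype vector, one value per training sample, no missing
#'   values (drop missing samples, and the matching rows/cols of `K`,
#'   first).
#' @param eig optional cached [gsm_eigen()] of `K`.
#' @return an object of class `gblup_model` with fields `sigma_g2`,
#'   `sigma_e2`, `lambda`, `h2`, `mu`, `loglik` (restricted, at the
#'   optimum), `alpha` (weights `(K + lambda I)^{-1}(y - mu)` used for
#'   prediction), `sample_ids`.
#' @export
fit_gblup <- function(K, y, eig = NULL) {
  K <- as_gsm(K)
  n <- length(y)
  if (n < 3) stop("need at least 3 training samples")
  if (anyNA(y)) stop("y contains missing values: drop those samples first")
  if (nrow(K$K) != n) stop("K dimension does not match y")
  if (max(abs(K$K - t(K$K))) > 1e-10) stop("K is not symmetric")
  if (is.null(eig)) eig <- eigen(K$K, symmetric = TRUE)
  xi <- eig$values
  if (min(xi) < -1e-8 * max(abs(xi), 1))
    stop("K is not positive semi-definite within tolerance")
  xi <- pmax(xi, 0)
  yt <- as.vector(crossprod(eig$vectors, y))
  xt <- as.vector(crossprod(eig$vectors, rep(1, n)))
  obj <- function(ld) reml_profile(exp(ld), xi, yt, xt)$ll
  opt <- stats::optimize(obj, interval = log(c(1e-6, 1e6)),
                         maximum = TRUE, tol = 1e-8)
  lambda <- exp(opt$maximum)
  prof <- reml_profile(lambda, xi, yt, xt)
  sg2 <- prof$sg2
  se2 <- lambda * sg2
  h2 <- sg2 / (sg2 + se2)
  mu <- prof$mu
  # prediction weights: (K + lambda I)^{-1} (y - mu)
  w <- 1 / (xi + lambda)
  alpha <- eig$vectors %*% (w * as.vector(crossprod(eig$vectors, y - mu)))
  structure(list(sigma_g2 = sg2, sigma_e2 = se2, lambda = lambda, h2 = h2,
                 mu = mu, loglik = opt$objective,
                 alpha = as.vector(alpha),
                 sample_ids = K$sample_ids),
            class = "gblup_model")
}

#' @export
print.gblup_model <- function(x, ...) {
  cat(sprintf(
    "gblup_model: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f, mu = %.4g, logREML = %.4g\n",
    x$sigma_g2, x$sigma_e2, x$h2, x$mu, x$loglik))
  invisible(x)
}

#' Predict phenotypes for unseen individuals with a fitted GBLUP model
#'
#' `yhat = mu + K_cross (K_train + lambda I)^{-1} (y_train - mu)`; the
#' inverse-weighted residual is precomputed at fit time.  When the genetic
#' variance collapsed to the boundary (`h2` at its lower bracket), every
#' prediction is the fitted mean (documented degenerate contract).
#'
#' @param model a `gblup_model`.
#' @param K_cross test x train similarity block, built with the same
#'   scheme and marker set as the training GSM (e.g. by computing the GSM
#'   on all samples at once and slicing).
#' @return numeric predictions, one per row of `K_cross`.
#' @export
predict_gblup <- function(model, K_cross) {
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != length(model$alpha))
    stop("K_cross column count does not match the training set")
  if (model$sigma_g2 <= 0 || model$h2 < 1e-6)
    return(rep(model$mu, nrow(K_cross)))
  as.vector(model$mu + K_cross %*% model$alpha)
}
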