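# Correlations of every marker column with a vector (or matrix of
# vectors), with constant markers scored 0.
marker_cor <- function(X, r) {
  cc <- suppressWarnings(stats::cor(X, r))
  cc[is.na(cc)] <- 0
  cc
}

# rho^2 is clipped just below 1 so a perfectly collinear marker yields a
# large finite LOD of (n/2)*12 instead of +Inf.
LOD_RHO2_CLIP <- 1 - 1e-12

#' Single-marker LOD scan
#'
#' For each marker `j`, `LOD_j = (n/2) log10(SS0 / SS1_j)` where `SS0` is
#' the residual sum of squares of the intercept-only model for `r` and
#' `SS1_j` that of the one-marker regression of `r` on marker `j`;
#' equivalently `(n/2) log10(1 / (1 - rho_j^2))` with `rho_j` the Pearson
#' correlation.  Constant markers score 0; a perfectly collinear marker is
#' capped at `(n/2) * 12`.
#'
#' @param G a [genotype_matrix()] with complete values.
#' @param r residual (or phenotype) vector, observed for all samples.
#' @return named numeric vector of LOD scores, one per marker.
#' @export
lod_scan <- function(G, r) {
  if (anyNA(r)) stop("residual vector contains missing values")
  rho2 <- pmin(as.vector(marker_cor(G$values, r))^2, LOD_RHO2_CLIP)
  lod <- -(length(r) / 2) * log10(1 - rho2)
  names(lod) <- marker_ids(G)
  lod
}

#' Permutation-based LOD significance threshold at a target FDR
#'
#' Permutations shuffle the residual vector while keeping the genotypes
#' fixed, giving `B` null genome scans.  The plug-in (Storey-type) FDR
#' estimate at a candidate threshold `t` is the mean null count of LOD
#' scores `>= t` divided by the observed count `>= t`; the returned
#' threshold `t*` is the smallest observed LOD value at which the
#' estimated FDR is `<= fdr_level`.  If no observed value qualifies the
#' threshold is `+Inf` (nothing selected).
#'
#' @param G a [genotype_matrix()].
#' @param r residual vector.
#' @param B number of permutations (>= 100 recommended for production;
#'   tests may use fewer).
#' @param fdr_level target false discovery rate.
#' @param seed integer seed for the permutation stream.
#' @return an object of class `permutation_null`: list with `B`,
#'   `threshold`, `fdr_at_threshold`, `null_max` (per-permutation maximum
#'   LOD), `n_selected` at the threshold.
#' @export
permutation_threshold <- function(G, r, B = 1000, fdr_level = 0.05,
                                  seed = 1L) {
  stopifnot(B >= 1, fdr_level > 0, fdr_level <= 1)
  obs <- lod_scan(G, r)
  set.seed(child_seed(seed, 11L))
  R <- vapply(seq_len(B), function(b) sample(r), numeric(length(r)))
  rho2 <- pmin(marker_cor(G$values, R)^2, LOD_RHO2_CLIP)   # p x B
  null_lod <- -(length(r) / 2) * log10(1 - rho2)
  cand <- sort(unique(obs[obs > 0]), decreasing = TRUE)
  threshold <- Inf; attained <- NA_real_; nsel <- 0L
  null_sorted <- sort(as.vector(null_lod))
  obs_sorted <- sort(obs)
  if (length(cand) > 0) {
    n_null_ge <- length(null_sorted) -
      findInterval(cand - 1e-12, null_sorted)
    n_obs_ge <- length(obs_sorted) - findInterval(cand - 1e-12, obs_sorted)
    fdr <- (n_null_ge / B) / n_obs_ge
    ok <- which(fdr <= fdr_level)
    if (length(ok) > 0) {
      pick <- max(ok)              # candidates are in decreasing order
      threshold <- cand[pick]
      attained <- fdr[pick]
      nsel <- n_obs_ge[pick]
    }
  }
  structure(list(B = B, threshold = threshold, fdr_at_threshold = attained,
                 null_max = apply(null_lod, 2, max), n_selected = nsel),
            class = "permutation_null")
}

# Reduce significant markers to region peaks: within each chromosome,
# a contiguous run of significant markers collapses to its highest-LOD
# member, so an LD block contributes one model term.
peak_reduce <- function(sig_idx, lod, map) {
  if (length(sig_idx) == 0) return(integer(0))
  if (is.null(map)) chrom <- rep("all", max(sig_idx)) else chrom <- map$chrom
  out <- integer(0)
  for (cc in unique(chrom[sig_idx])) {
    idx <- sig_idx[chrom[sig_idx] == cc]
    runs <- cumsum(c(1L, diff(idx) != 1L))
    for (rr in unique(runs)) {
      run_idx <- idx[runs == rr]
      out <- c(out, run_idx[which.max(lod[run_idx])])
    }
  }
  sort(out)
}

#' Sequential forward selection of additive QTLs with permutation-FDR
#' thresholds
#'
#' Iterative procedure of at most `max_stages` stages.  Each stage scans
#' the current residuals marker by marker, derives a permutation-FDR LOD
#' threshold ([permutation_threshold()]), collapses significant markers to
#' one peak per contiguous significant run per chromosome, refits the
#' joint linear model of all markers selected so far, and recomputes
#' residuals for the next stage.  Selection stops early when a stage
#' selects nothing.  Thresholding and selection use only the data passed
#' in: in cross-validation this must be the training fold alone.
#'
#' @param G a [genotype_matrix()] (complete values).
#' @param y observed phenotype vector.
#' @param max_stages stage cap (default 4).
#' @param B permutations per stage.
#' @param fdr_level target FDR per stage.
#' @param seed integer master seed; each stage derives its own stream.
#' @return an object of class `qtl_model`: `markers` (ids), `coef`
#'   (intercept first, refit jointly), `stage` (entry stage per marker),
#'   `thresholds`, `interactions` (`NULL` until [interaction_scan()]),
#'   `train_mean`.
#' @export
bloom_forward_selection <- function(G, y, max_stages = 4, B = 1000,
                                    fdr_level = 0.05, seed = 1L) {
  if (anyNA(y)) stop("y contains missing values")
  X <- G$values
  selected <- integer(0)
  stage_of <- integer(0)
  thresholds <- numeric(0)
  r <- y - mean(y)
  for (stage in seq_len(max_stages)) {
    lod <- lod_scan(G, r)
    pt <- permutation_threshold(G, r, B = B, fdr_level = fdr_level,
                                seed = child_seed(seed, 100L + stage))
    thresholds <- c(thresholds, pt$threshold)
    sig <- which(lod >= pt$threshold)
    sig <- setdiff(sig, selected)
    peaks <- peak_reduce(sig, lod, G$map)
    if (length(peaks) == 0) break
    selected <- c(selected, peaks)
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1,
                               X[, selected, drop = FALSE]), y)
    dropped <- which(is.na(fit$coefficients[-1]))
    if (length(dropped) > 0) {
      warning("dropping ", length(dropped),
              " collinear marker(s) from the QTL model")
      selected <- selected[-dropped]
      fit <- stats::lm.fit(cbind(`(Intercept)` = 1,
                                 X[, selected, drop = FALSE]), y)
    }
    stage_of <- c(stage_of, rep(stage, length(selected) - length(stage_of)))
    r <- y - as.vector(cbind(1, X[, selected, drop = FALSE]) %*%
                         fit$coefficients)
  }
  coef <- if (length(selected) > 0)
    stats::lm.fit(cbind(1, X[, selected, drop = FALSE]), y)$coefficients
  else mean(y)
  names(coef) <- c("(Intercept)",
                   if (length(selected)) marker_ids(G)[selected])
  structure(list(markers = if (length(selected)) marker_ids(G)[selected]
                 else character(0),
                 coef = coef, stage = stage_of, thresholds = thresholds,
                 B = B, fdr_level = fdr_level, seed = seed,
                 interactions = NULL, train_mean = mean(y)),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("qtl_model: %d additive marker(s) over %d stage(s)%s\n",
              length(x$markers), length(x$thresholds),
              if (!is.null(x$interactions) && nrow(x$interactions) > 0)
                sprintf(", %d interaction(s)", nrow(x$interactions)) else ""))
  invisible(x)
}

# Likelihood-ratio statistics for adding marker j's main effect plus the
# m x j product to the additive base model, versus the main effect alone:
# LR_j = n * ln(RSS_reduced / RSS_full).  Vectorized over j by projecting
# everything off the base design once; Pg holds projected marker columns,
# Pw projected product columns (g_m * g_j), ry the projected response.
lr_from_projections <- function(ry, Pg, Pw) {
  g_g <- colSums(Pg^2); g_y <- colSums(Pg * ry)
  rss0 <- sum(ry^2)
  rss_red <- rss0 - ifelse(g_g > 0, g_y^2 / g_g, 0)
  w_w <- colSums(Pw^2); w_g <- colSums(Pw * Pg); w_y <- colSums(Pw * ry)
  det <- g_g * w_w - w_g^2
  gain <- ifelse(det > 1e-12,
                 (w_w * g_y^2 - 2 * w_g * g_y * w_y + g_g * w_y^2) / det,
                 ifelse(g_g > 0, g_y^2 / g_g, 0))
  rss_full <- pmax(rss0 - gain, 1e-12)
  n <- length(ry)
  pmax(n * log(pmax(rss_red, 1e-12) / rss_full), 0)
}

#' Likelihood-ratio scan for interactions with one anchor marker
#'
#' For each marker `j`, the statistic `n ln(RSS_reduced / RSS_full)`
#' compares the additive model of `additive` markers plus the main effect
#' of `j`, with versus without the `m x j` product term.
#'
#' @param G a [genotype_matrix()].
#' @param y phenotype vector.
#' @param additive marker ids forming the additive base model.
#' @param m anchor marker id (must be among `additive`).
#' @return named numeric vector of LR statistics, one per marker (zero at
#'   the additive markers themselves).
#' @export
interaction_lr_scan <- function(G, y, additive, m) {
  X <- G$values
  sel <- match(additive, marker_ids(G))
  if (anyNA(sel)) stop("additive markers absent from G")
  base <- cbind(1, X[, sel, drop = FALSE])
  qr_base <- qr(base)
  Pg <- X - base %*% qr.coef(qr_base, X)
  Pw <- {
    W <- X * X[, match(m, marker_ids(G))]
    W - base %*% qr.coef(qr_base, W)
  }
  out <- lr_from_projections(as.vector(qr.resid(qr_base, y)), Pg, Pw)
  out[sel] <- 0
  names(out) <- marker_ids(G)
  out
}

#' Scan for pairwise marker interactions involving selected QTLs
#'
#' For each additive marker `m` already in the model and every marker `j`,
#' compares the joint additive model augmented with the main effect of `j`
#' and the `m x j` product term against the same model without the product
#' term, by the likelihood-ratio statistic `n ln(RSS_reduced/RSS_full)`.
#' Pair significance uses the same plug-in permutation FDR as the additive
#' stage, with null scans generated by shuffling the additive-model
#' residuals onto the fitted values.  Significant pairs are appended with
#' jointly refit coefficients.
#'
#' @param G a [genotype_matrix()].
#' @param y phenotype vector.
#' @param model a `qtl_model` with at least one additive marker.
#' @param B permutations.
#' @param fdr_level target FDR.
#' @param seed integer seed.
#' @return the augmented `qtl_model` with an `interactions` data frame
#'   (`m`, `j`, `lr`) and refit `coef` including `m:j` product terms.
#' @export
interaction_scan <- function(G, y, model, B = 200, fdr_level = 0.05,
                             seed = 1L) {
  if (length(model$markers) == 0)
    stop("model has no additive markers to scan from")
  X <- G$values
  sel <- match(model$markers, marker_ids(G))
  base <- cbind(1, X[, sel, drop = FALSE])
  qr_base <- qr(base)
  proj <- function(M) M - base %*% qr.coef(qr_base, M)
  resid_y <- as.vector(qr.resid(qr_base, y))
  fitted_y <- y - resid_y
  Pg <- proj(X)
  Pw_list <- lapply(seq_along(sel), function(k) proj(X * X[, sel[k]]))

  scan_stats <- function(yy) {
    ry <- as.vector(qr.resid(qr_base, yy))
    out <- matrix(0, length(sel), ncol(X))
    for (k in seq_along(sel))
      out[k, ] <- lr_from_projections(ry, Pg, Pw_list[[k]])
    out[, sel] <- 0   # model markers carry no new product information
    out
  }
  obs <- scan_stats(y)

  set.seed(child_seed(seed, 211L))
  null_vals <- numeric(0)
  for (b in seq_len(B)) {
    yb <- fitted_y + sample(resid_y)
    null_vals <- c(null_vals, as.vector(scan_stats(yb)))
  }
  null_sorted <- sort(null_vals)
  obs_v <- as.vector(obs)
  cand <- sort(unique(obs_v[obs_v > 0]), decreasing = TRUE)
  threshold <- Inf
  for (t in cand) {
    n_null <- length(null_sorted) - findInterval(t - 1e-9, null_sorted)
    fdr <- (n_null / B) / sum(obs_v >= t)
    if (fdr <= fdr_level) threshold <- t else break
  }
  ints <- data.frame(m = character(0), j = character(0), lr = numeric(0))
  if (is.finite(threshold)) {
    hits <- which(obs >= threshold, arr.ind = TRUE)
    if (nrow(hits) > 0) {
      # one pair per (model marker, chromosome run) of significant j's
      for (k in unique(hits[, 1])) {
        js <- sort(hits[hits[, 1] == k, 2])
        pk <- peak_reduce(js, obs[k, ], G$map)
        ints <- rbind(ints, data.frame(
          m = model$markers[k], j = marker_ids(G)[pk],
          lr = obs[k, pk], stringsAsFactors = FALSE))
      }
    }
  }
  model$interactions <- ints
  # refit jointly with main effects of every involved marker + products
  mains <- union(model$markers, ints$j)
  mi <- match(mains, marker_ids(G))
  D <- X[, mi, drop = FALSE]
  colnames(D) <- mains
  if (nrow(ints) > 0) {
    Prod <- sapply(seq_len(nrow(ints)), function(r)
      X[, match(ints$m[r], marker_ids(G))] *
        X[, match(ints$j[r], marker_ids(G))])
    colnames(Prod) <- paste(ints$m, ints$j, sep = ":")
    D <- cbind(D, Prod)
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, D), y)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  model$coef <- coef
  model$markers <- mains
  model
}

#' Predict phenotypes from a fitted QTL model
#'
#' Evaluates the linear model (intercept + selected main effects +
#' interaction products) on new genotypes.  An empty model predicts the
#' training mean; markers outside the model never influence predictions.
#'
#' @param model a `qtl_model`.
#' @param G_test a [genotype_matrix()] whose markers are a superset of the
#'   model's markers.
#' @return named numeric predictions.
#' @export
predict_qtl <- function(model, G_test) {
  n <- nrow(G_test$values)
  if (length(model$markers) == 0)
    return(stats::setNames(rep(model$train_mean, n), sample_ids(G_test)))
  miss <- setdiff(model$markers, marker_ids(G_test))
  if (length(miss) > 0)
    stop("model markers absent from test data: ",
         paste(utils::head(miss, 3), collapse = ", "))
  X <- G_test$values
  terms <- names(model$coef)[-1]
  D <- sapply(terms, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) X[, parts]
    else X[, parts[1]] * X[, parts[2]]
  })
  if (is.null(dim(D))) D <- matrix(D, nrow = n)
  stats::setNames(as.vector(cbind(1, D) %*% model$coef), sample_ids(G_test))
}
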