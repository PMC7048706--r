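#' Cross-validated R-squared
#'
#' `cvR2 = 1 - sum((y_i - ytilde_i)^2) / sum((y_i - ybar)^2)` with `ybar`
#' the mean of the observed values — the proportion of variance explained
#' by the accumulated out-of-fold predictions.  Equals 1 for perfect
#' prediction, 0 for constantly predicting the mean, and can be negative.
#'
#' @param y observed values (length >= 2, non-constant).
#' @param yhat predictions aligned to `y`.
#' @return a single number `<= 1`.
#' @export
compute_cvr2 <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  if (length(y) < 2) stop("need at least 2 observations")
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("constant y: cvR2 undefined")
  1 - sum((y - yhat)^2) / tss
}

# Dispatch a single fit/predict cycle for any registered method.
# `context` carries precomputed structures (GSM + eigen for gblup).
fit_predict <- function(method, G, y, train, test, policy, seed, context) {
  if (method == "mean")
    return(rep(mean(y[train]), length(test)))
  if (method == "gblup") {
    K <- context$K
    m <- fit_gblup(as_gsm(K[train, train, drop = FALSE]), y[train])
    return(predict_gblup(m, K[test, train, drop = FALSE]))
  }
  if (method == "bloom") {
    if (is.null(policy)) policy <- tuning_policy("bloom")
    m <- bloom_forward_selection(subset_genotypes(G, samples = train),
                                 y[train],
                                 max_stages = policy$max_stages,
                                 B = policy$B,
                                 fdr_level = policy$fdr_level, seed = seed)
    return(unname(predict_qtl(m, subset_genotypes(G, samples = test))))
  }
  fl <- fit_learner(method, subset_genotypes(G, samples = train), y[train],
                    policy = policy, seed = seed)
  predict(fl, subset_genotypes(G, samples = test))
}

prepare_context <- function(method, G) {
  if (method == "gblup") list(K = compute_gsm(G)$K) else list()
}

#' Cross-validated evaluation of one method on one trait
#'
#' Random fold partition per repeat; within each fold the method is tuned
#' and fitted on the training fold only ([fit_learner()] /
#' [fit_gblup()] / [bloom_forward_selection()]) and used to predict the
#' held-out fold.  cvR2 is computed from the accumulated out-of-fold
#' predictions of each repeat and averaged over repeats.
#'
#' @param G a [genotype_matrix()].
#' @param y phenotype vector (samples with missing values are dropped).
#' @param method method tag (see [tuning_policy()]).
#' @param k_folds number of folds (>= 2).
#' @param policy optional [tuning_policy()] override.
#' @param n_repeats independent fold partitions to average over.
#' @param seed integer master seed.
#' @return an object of class `cv_result`: `cvr2` (mean over repeats),
#'   `per_repeat`, `predictions` (out-of-fold, last repeat), `folds`
#'   (last repeat), `method`, `n`.
#' @export
run_cv <- function(G, y, method, k_folds = 10, policy = NULL,
                   n_repeats = 1, seed = 1L) {
  stopifnot(k_folds >= 2)
  obs <- which(!is.na(y))
  G <- subset_genotypes(G, samples = obs)
  y <- y[obs]
  n <- length(y)
  if (n < 2 * k_folds) stop("a fold would have fewer than 2 samples")
  context <- prepare_context(method, G)
  per_repeat <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    set.seed(child_seed(seed, 31L + rep_i))
    folds <- sample(rep_len(seq_len(k_folds), n))
    yhat <- rep(NA_real_, n)
    for (k in seq_len(k_folds)) {
      test <- which(folds == k); train <- which(folds != k)
      yhat[test] <- fit_predict(method, G, y, train, test, policy,
                                child_seed(seed, 1000L * rep_i + k),
                                context)
    }
    stopifnot(!anyNA(yhat))   # every observed sample predicted exactly once
    per_repeat[rep_i] <- compute_cvr2(y, yhat)
  }
  structure(list(cvr2 = mean(per_repeat), per_repeat = per_repeat,
                 predictions = yhat, observed = y, folds = folds,
                 method = method, n = n),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result[%s]: cvR2 = %.4f (n = %d, %d repeat%s)\n",
              x$method, x$cvr2, x$n, length(x$per_repeat),
              if (length(x$per_repeat) > 1) "s" else ""))
  invisible(x)
}

#' Single train/test split evaluation
#'
#' As [run_cv()] but with one random split; R2 is computed on the test
#' portion against the test-set mean.
#'
#' @inheritParams run_cv
#' @param test_fraction fraction of samples held out (default 0.30).
#' @return list with `r2`, `predictions`, `test` (indices into the
#'   observed samples), `method`.
#' @export
run_train_test <- function(G, y, method, test_fraction = 0.30,
                           policy = NULL, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  obs <- which(!is.na(y))
  G <- subset_genotypes(G, samples = obs)
  y <- y[obs]
  n <- length(y)
  context <- prepare_context(method, G)
  set.seed(child_seed(seed, 41L))
  test <- sort(sample.int(n, max(2L, round(test_fraction * n))))
  train <- setdiff(seq_len(n), test)
  yhat <- fit_predict(method, G, y, train, test, policy,
                      child_seed(seed, 42L), context)
  list(r2 = compute_cvr2(y[test], yhat), predictions = yhat, test = test,
       method = method)
}

#' Define a data-degradation plan
#'
#' Three degradation kinds emulate practical data pathologies:
#' `"class-noise"` adds or subtracts (random sign) twice the trait's
#' pre-contamination standard deviation for a random fraction of samples;
#' `"marker-deletion"` removes random nested subsets of markers (the set
#' deleted at one level contains every smaller level's set);
#' `"sample-deletion"` removes nested random subsets of samples.  Default
#' fraction schedules follow the benchmarking protocol.
#'
#' @param kind one of `"class-noise"`, `"marker-deletion"`,
#'   `"sample-deletion"`.
#' @param fractions strictly increasing schedule in `[0, 1]`; defaults by
#'   kind: noise 5--90%, markers 10--99%, samples 10--85%.
#' @param repetitions independent randomizations (default 10).
#' @param noise_sd_mult noise magnitude in trait standard deviations
#'   (default 2).
#' @return a list of class `degradation_plan`.
#' @export
degradation_plan <- function(kind = c("class-noise", "marker-deletion",
                                      "sample-deletion"),
                             fractions = NULL, repetitions = 10,
                             noise_sd_mult = 2) {
  kind <- match.arg(kind)
  if (is.null(fractions))
    fractions <- switch(kind,
      "class-noise" = c(.05, .10, .20, .30, .40, .50, .75, .90),
      "marker-deletion" = c(.10, .25, .50, .60, .70, .80, .90, .95, .99),
      "sample-deletion" = c(.10, .25, .50, .60, .70, .80, .85))
  stopifnot(all(fractions >= 0), all(fractions <= 1),
            all(diff(fractions) > 0), repetitions >= 1)
  structure(list(kind = kind, fractions = fractions,
                 repetitions = repetitions, noise_sd_mult = noise_sd_mult),
            class = "degradation_plan")
}

#' Apply a degradation plan to a dataset
#'
#' Returns, for each repetition, the sequence of degraded datasets along
#' the plan's fraction schedule.  Within a repetition the affected
#' items are nested: the items degraded at one level are a subset of
#' those degraded at every higher level (variance reduction across the
#' schedule), and noise signs are fixed per sample.
#'
#' @param G a [genotype_matrix()].
#' @param y phenotype vector aligned to `G`.
#' @param plan a [degradation_plan()].
#' @param seed integer master seed; repetition `r` derives its own stream.
#' @return nested list: `[[rep]][[level]]` with elements `G`, `y`,
#'   `fraction`, plus `affected` (indices degraded at that level).
#' @export
apply_degradation <- function(G, y, plan, seed = 1L) {
  stopifnot(inherits(plan, "degradation_plan"))
  n <- nrow(G$values); p <- ncol(G$values)
  lapply(seq_len(plan$repetitions), function(rep_i) {
    set.seed(child_seed(seed, 500L + rep_i))
    if (plan$kind == "class-noise") {
      ord <- sample.int(n)
      signs <- sample(c(-1, 1), n, replace = TRUE)
      sd_y <- stats::sd(y, na.rm = TRUE)
      lapply(plan$fractions, function(f) {
        aff <- ord[seq_len(floor(f * n))]
        y2 <- y
        y2[aff] <- y2[aff] + signs[aff] * plan$noise_sd_mult * sd_y
        list(G = G, y = y2, fraction = f, affected = aff)
      })
    } else if (plan$kind == "marker-deletion") {
      ord <- sample.int(p)
      lapply(plan$fractions, function(f) {
        del <- ord[seq_len(floor(f * p))]
        keep <- setdiff(seq_len(p), del)
        list(G = subset_genotypes(G, markers = sort(keep)), y = y,
             fraction = f, affected = del)
      })
    } else {
      ord <- sample.int(n)
      lapply(plan$fractions, function(f) {
        del <- ord[seq_len(floor(f * n))]
        keep <- sort(setdiff(seq_len(n), del))
        list(G = subset_genotypes(G, samples = keep), y = y[keep],
             fraction = f, affected = del)
      })
    }
  })
}

#' Run a degradation experiment
#'
#' For each repetition a 70/30 train/test split is drawn; the clean
#' baseline R2 of every method is measured on it, then the degradation is
#' applied and each level re-evaluated with the same protocol.  Class
#' noise contaminates training-fold phenotypes only (the test fold stays
#' clean so that accuracy loss reflects corrupted learning, not corrupted
#' scoring); marker deletion applies to both folds; sample deletion
#' removes training samples only, keeping the test fold fixed across
#' levels for comparability.
#'
#' @param G a [genotype_matrix()].
#' @param y phenotype vector.
#' @param methods character vector of method tags.
#' @param plan a [degradation_plan()].
#' @param test_fraction held-out fraction (default 0.30).
#' @param policies named list of [tuning_policy()] overrides per method.
#' @param seed integer master seed.
#' @return data frame (method, kind, fraction, rep, r2, baseline_r2).
#' @export
run_degradation <- function(G, y, methods, plan, test_fraction = 0.30,
                            policies = list(), seed = 1L) {
  obs <- which(!is.na(y))
  G <- subset_genotypes(G, samples = obs); y <- y[obs]
  n <- length(y)
  out <- list()
  for (rep_i in seq_len(plan$repetitions)) {
    set.seed(child_seed(seed, 600L + rep_i))
    test <- sort(sample.int(n, round(test_fraction * n)))
    train <- setdiff(seq_len(n), test)
    degs <- apply_degradation(subset_genotypes(G, samples = train),
                              y[train], plan,
                              seed = child_seed(seed, 700L + rep_i))[[1]]
    for (m in methods) {
      pol <- policies[[m]]
      context <- prepare_context(m, G)
      base_hat <- fit_predict(m, G, y, train, test, pol,
                              child_seed(seed, 800L + rep_i), context)
      base_r2 <- compute_cvr2(y[test], base_hat)
      for (lv in degs) {
        if (plan$kind == "marker-deletion") {
          keepm <- marker_ids(lv$G)
          Gd <- subset_genotypes(G, markers = keepm)
          ctx <- prepare_context(m, Gd)
          hat <- fit_predict(m, Gd, y, train, test, pol,
                             child_seed(seed, 900L + rep_i), ctx)
        } else if (plan$kind == "class-noise") {
          y2 <- y; y2[train] <- lv$y
          hat <- fit_predict(m, G, y2, train, test, pol,
                             child_seed(seed, 900L + rep_i), context)
        } else {  # sample-deletion: shrink the training fold
          tr2 <- train[match(sample_ids(lv$G), sample_ids(G)[train])]
          hat <- fit_predict(m, G, y, tr2, test, pol,
                             child_seed(seed, 900L + rep_i), context)
        }
        out[[length(out) + 1L]] <- data.frame(
          method = m, kind = plan$kind, fraction = lv$fraction,
          rep = rep_i, r2 = compute_cvr2(y[test], hat),
          baseline_r2 = base_r2, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Summarise degradation results as ratio and absolute curves
#'
#' Per method and fraction: the mean over repetitions of
#' `r2 / baseline_r2` (the relative accuracy retained) and of the
#' absolute `r2`.  Repetitions with non-positive baseline have no defined
#' ratio and are dropped from the ratio mean (emitted as `NA` when none
#' remain).
#'
#' @param results data frame from [run_degradation()].
#' @return data frame (method, fraction, ratio, r2, n_reps).
#' @export
degradation_curves <- function(results) {
  key <- interaction(results$method, results$fraction, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    ok <- d$baseline_r2 > 0
    data.frame(method = d$method[1], fraction = d$fraction[1],
               ratio = if (any(ok)) mean(d$r2[ok] / d$baseline_r2[ok])
                       else NA_real_,
               r2 = mean(d$r2), n_reps = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$method, out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lasso support size as a mechanistic-complexity proxy
#'
#' Splits the data 70/30, fits a cross-validated lasso on the training
#' portion, and reports the number of non-zero coefficients together with
#' the test-set R2 — a proxy for how many attributes are relevant to the
#' trait.
#'
#' @param G a [genotype_matrix()].
#' @param y phenotype vector.
#' @param test_fraction held-out fraction (default 0.30).
#' @param seed integer seed.
#' @return list with `support` (non-zero coefficient count, intercept
#'   excluded) and `r2`.
#' @export
lasso_support_size <- function(G, y, test_fraction = 0.30, seed = 1L) {
  obs <- which(!is.na(y))
  G <- subset_genotypes(G, samples = obs); y <- y[obs]
  n <- length(y)
  set.seed(child_seed(seed, 51L))
  test <- sort(sample.int(n, max(2L, round(test_fraction * n))))
  train <- setdiff(seq_len(n), test)
  fl <- fit_learner("lasso", subset_genotypes(G, samples = train), y[train],
                    seed = child_seed(seed, 52L))
  beta <- stats::coef(fl$fit, s = "lambda.min")
  support <- sum(beta[-1] != 0)
  r2 <- compute_cvr2(y[test], predict(fl, subset_genotypes(G, samples = test)))
  list(support = support, r2 = r2)
}

#' Stack several traits into one multi-task regression problem
#'
#' One row per (sample, trait) observation: the sample's marker vector
#' plus a categorical trait-indicator attribute, with the trait's
#' phenotype as response.  Tree learners consume the indicator natively;
#' numeric backends one-hot expand it.
#'
#' @param G a [genotype_matrix()] shared by all traits.
#' @param traits named list of phenotype vectors aligned to `G`'s samples
#'   (missing values drop that row); at least 2 traits unless a group of
#'   one is explicitly wanted.
#' @return an object of class `multitask_dataset`: `x` (data frame of
#'   markers + `trait` factor), `y`, `trait`, `sample_index`.
#' @export
build_multitask <- function(G, traits) {
  if (length(traits) == 0) stop("empty trait group")
  if (is.null(names(traits)) || any(names(traits) == ""))
    stop("traits must be named")
  xs <- list(); ys <- list(); tr <- list(); si <- list()
  for (tn in names(traits)) {
    y <- traits[[tn]]
    keep <- which(!is.na(y))
    xs[[tn]] <- G$values[keep, , drop = FALSE]
    ys[[tn]] <- y[keep]
    tr[[tn]] <- rep(tn, length(keep))
    si[[tn]] <- keep
  }
  x <- as.data.frame(do.call(rbind, xs), stringsAsFactors = FALSE)
  rownames(x) <- NULL
  x$trait <- factor(unlist(tr), levels = names(traits))
  structure(list(x = x, y = unname(unlist(ys)),
                 trait = x$trait, sample_index = unname(unlist(si))),
            class = "multitask_dataset")
}

#' Evaluate grouped (multi-task) learning against single-trait fits
#'
#' Holds out `test_fraction` of each trait's observations; the aggregated
#' test set is the union of the per-trait test sets.  One model is fitted
#' on the stacked training rows and scored per trait, next to reference
#' models trained on each trait alone with the same splits.
#'
#' @param G a [genotype_matrix()].
#' @param traits named list of phenotype vectors (see [build_multitask()]).
#' @param method learner tag, typically `"rf"` or `"gbm"`.
#' @param test_fraction held-out fraction per trait.
#' @param policy optional [tuning_policy()].
#' @param seed integer seed.
#' @return list with `per_trait` (data frame: trait, r2_grouped,
#'   r2_single) and `overall_r2` of the grouped model on the aggregated
#'   test set.
#' @export
evaluate_multitask <- function(G, traits, method = "rf",
                               test_fraction = 0.30, policy = NULL,
                               seed = 1L) {
  mt <- build_multitask(G, traits)
  set.seed(child_seed(seed, 61L))
  test_rows <- unlist(lapply(names(traits), function(tn) {
    rows <- which(mt$trait == tn)
    sample(rows, max(2L, round(test_fraction * length(rows))))
  }))
  test_rows <- sort(test_rows)
  train_rows <- setdiff(seq_along(mt$y), test_rows)
  fl <- fit_learner(method, mt$x[train_rows, , drop = FALSE],
                    mt$y[train_rows], policy = policy,
                    seed = child_seed(seed, 62L))
  pred <- predict(fl, mt$x[test_rows, , drop = FALSE])
  overall <- compute_cvr2(mt$y[test_rows], pred)
  per <- lapply(names(traits), function(tn) {
    sel <- mt$trait[test_rows] == tn
    r2g <- compute_cvr2(mt$y[test_rows][sel], pred[sel])
    # single-trait reference on the same rows
    rows <- which(mt$trait == tn)
    tt <- intersect(test_rows, rows); tt_in <- match(tt, rows)
    tr <- match(setdiff(rows, tt), rows)
    Xt <- G$values[mt$sample_index[rows], , drop = FALSE]
    fls <- fit_learner(method, Xt[tr, , drop = FALSE],
                       mt$y[rows][tr], policy = policy,
                       seed = child_seed(seed, 63L))
    r2s <- compute_cvr2(mt$y[rows][tt_in],
                        predict(fls, Xt[tt_in, , drop = FALSE]))
    data.frame(trait = tn, r2_grouped = r2g, r2_single = r2s,
               stringsAsFactors = FALSE)
  })
  list(per_trait = do.call(rbind, per), overall_r2 = overall)
}
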