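test_that("cvR2 implements proportion of variance explained", {
  expect_equal(compute_cvr2(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(compute_cvr2(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(compute_cvr2(c(1, 2, 3), c(1, 2, 2)), 0.5)
  expect_error(compute_cvr2(c(1, 1), c(1, 2)), "constant")
  expect_error(compute_cvr2(1:3, 1:2), "length")
})

test_that("every observed sample is predicted exactly once per CV run", {
  G <- tiny_cross(123, seed = 47)
  y <- as.vector(simulate_trait(G, additive_arch(G, c(5, 44), h2 = .6),
                                seed = 1))
  y[c(3, 17, 95)] <- NA
  cv <- run_cv(G, y, "mean", k_folds = 7, seed = 3)
  expect_equal(cv$n, 120)
  expect_false(anyNA(cv$predictions))
  expect_equal(sort(unique(cv$folds)), 1:7)
})

test_that("the mean-predictor baseline never beats zero cvR2", {
  G <- tiny_cross(150, seed = 49)
  for (s in 1:3) {
    y <- as.vector(simulate_trait(G, additive_arch(G, 9, h2 = .5),
                                  seed = 50 + s))
    expect_lte(run_cv(G, y, "mean", k_folds = 5, seed = s)$cvr2, 0)
  }
})

test_that("cvR2 of a heritable trait respects the heritability ceiling", {
  G <- tiny_cross(400, seed = 51)
  vals <- vapply(1:3, function(s) {
    y <- as.vector(simulate_trait(
      G, additive_arch(G, seq(5, 85, by = 10), h2 = 0.5), seed = 60 + s))
    run_cv(G, y, "lasso", k_folds = 10, seed = s)$cvr2
  }, numeric(1))
  expect_true(all(vals > 0.25 & vals < 0.62))
})

test_that("shuffling phenotypes destroys predictive accuracy", {
  G <- tiny_cross(200, seed = 53)
  y <- as.vector(simulate_trait(G, additive_arch(G, c(5, 45), h2 = .7),
                                seed = 1))
  set.seed(9); ys <- sample(y)
  for (m in c("lasso", "gblup")) {
    expect_lte(run_cv(G, ys, m, k_folds = 5, seed = 2)$cvr2, 0.05)
  }
})

test_that("train/test evaluation is deterministic and seed-sensitive", {
  G <- tiny_cross(150, seed = 55)
  y <- as.vector(simulate_trait(G, additive_arch(G, c(5, 45), h2 = .6),
                                seed = 2))
  a <- run_train_test(G, y, "lasso", seed = 4)
  b <- run_train_test(G, y, "lasso", seed = 4)
  expect_identical(a$r2, b$r2)
  expect_identical(a$test, b$test)
})

test_that("degradation operators implement the planned contamination", {
  G <- tiny_cross(100, seed = 57)
  y <- as.vector(simulate_trait(G, additive_arch(G, 7, h2 = .8), seed = 1))
  # full contamination moves every value by exactly 2 sd
  plan <- degradation_plan("class-noise", fractions = c(0.5, 1),
                           repetitions = 2)
  degs <- apply_degradation(G, y, plan, seed = 3)
  lv <- degs[[1]][[2]]
  expect_equal(abs(lv$y - y), rep(2 * sd(y), 100), tolerance = 1e-12)
  # nesting: the half-level affected set is inside the full set
  expect_true(all(degs[[1]][[1]]$affected %in% degs[[1]][[2]]$affected))

  # marker deletion: nested retained sets, decreasing along the schedule
  planm <- degradation_plan("marker-deletion", fractions = c(.2, .5, .8),
                            repetitions = 1)
  dm <- apply_degradation(G, y, planm, seed = 5)[[1]]
  k1 <- marker_ids(dm[[1]]$G); k2 <- marker_ids(dm[[2]]$G)
  k3 <- marker_ids(dm[[3]]$G)
  expect_true(all(k3 %in% k2) && all(k2 %in% k1))
  # sample deletion shrinks the sample set
  plans <- degradation_plan("sample-deletion", fractions = c(.25, .5),
                            repetitions = 1)
  ds <- apply_degradation(G, y, plans, seed = 7)[[1]]
  expect_equal(nrow(ds[[2]]$G$values), 50)
  expect_true(all(sample_ids(ds[[2]]$G) %in% sample_ids(ds[[1]]$G)))
})

test_that("degradation curves summarise ratios and guard zero baselines", {
  res <- data.frame(method = rep(c("a", "b"), each = 4),
                    kind = "class-noise",
                    fraction = rep(c(.1, .1, .5, .5), 2),
                    rep = rep(1:2, 4),
                    r2 = c(.4, .44, .2, .24, .1, .1, .05, .05),
                    baseline_r2 = c(rep(.5, 4), rep(0, 4)))
  cur <- degradation_curves(res)
  expect_equal(cur$ratio[cur$method == "a" & cur$fraction == .1], 0.84)
  expect_true(all(is.na(cur$ratio[cur$method == "b"])))
  expect_equal(cur$r2[cur$method == "a" & cur$fraction == .5], 0.22)
})

test_that("degradation ratios reproduce bit-identically at a fixed seed", {
  G <- tiny_cross(120, seed = 59)
  y <- as.vector(simulate_trait(G, additive_arch(G, c(5, 40), h2 = .7),
                                seed = 1))
  plan <- degradation_plan("class-noise", fractions = c(.3, .6),
                           repetitions = 2)
  r1 <- run_degradation(G, y, "lasso", plan, seed = 11)
  r2 <- run_degradation(G, y, "lasso", plan, seed = 11)
  expect_identical(r1, r2)
  # accuracy deteriorates with contamination on average
  cur <- degradation_curves(r1)
  expect_lt(cur$ratio[cur$fraction == .6], 1.02)
})

test_that("lasso support size tracks mechanistic complexity", {
  # longer chromosomes keep linkage moderate, so the support of a
  # near-monogenic trait stays a handful of markers
  G <- tiny_cross(400, seed = 61, n_chr = 2, len = 2, m = 25)
  # near-monogenic trait: few non-zero attributes, high test R2
  y1 <- as.vector(simulate_trait(G, additive_arch(G, 20, effects = 2,
                                                  h2 = 0.95), seed = 1))
  s1 <- lasso_support_size(G, y1, seed = 3)
  expect_lte(s1$support, 10)
  expect_gt(s1$r2, 0.7)
  # null trait: hardly any support
  set.seed(5); y0 <- rnorm(400)
  s0 <- lasso_support_size(G, y0, seed = 3)
  expect_lte(s0$support, 10)
  # support grows as lambda shrinks along the path; individual variables
  # may leave the active set, so the trend (not every step) is monotone
  fl <- fit_learner("lasso", G, y1, seed = 9)
  nz <- as.vector(fl$fit$nzero)         # indexed by decreasing lambda
  expect_gte(cor(seq_along(nz), nz, method = "spearman"), 0.9)
  expect_lte(nz[1], nz[length(nz)])
  expect_true(all(diff(nz) >= -2))
})

test_that("multi-task stacking preserves rows and degenerates for one trait", {
  G <- tiny_cross(90, seed = 63)
  arch <- additive_arch(G, c(5, 40), h2 = .7)
  y1 <- as.vector(simulate_trait(G, arch, seed = 1))
  y2 <- as.vector(simulate_trait(G, arch, seed = 2))
  y2[1:10] <- NA
  mt <- build_multitask(G, list(t1 = y1, t2 = y2))
  expect_equal(nrow(mt$x), 90 + 80)
  expect_equal(levels(mt$trait), c("t1", "t2"))

  single <- build_multitask(G, list(only = y1))
  expect_equal(nrow(single$x), 90)
  expect_equal(nlevels(droplevels(single$trait)), 1)
  expect_equal(as.matrix(single$x[, marker_ids(G)]), G$values,
               ignore_attr = TRUE)
  expect_error(build_multitask(G, list()), "empty")
})

test_that("grouped learning helps sparsely observed correlated traits", {
  # three traits driven by the same QTLs (highly correlated phenotypes),
  # each with half its readings missing: stacking lets the forest borrow
  # the shared genetic signal across traits
  G <- tiny_cross(300, seed = 65)
  idx <- c(8, 35, 70)
  set.seed(17)
  e1 <- rnorm(3, 1, 0.2)
  ys <- lapply(1:3, function(s)
    inject_missing(as.vector(simulate_trait(
      G, additive_arch(G, idx, e1, h2 = .6), seed = 2 + s)), 0.5, seed = s))
  names(ys) <- c("a", "b", "c")
  em <- evaluate_multitask(G, ys, method = "rf",
                           policy = tuning_policy("rf", num_trees = 400),
                           seed = 7)
  expect_gte(mean(em$per_trait$r2_grouped - em$per_trait$r2_single), 0)
  expect_gt(em$overall_r2, 0.3)
})
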