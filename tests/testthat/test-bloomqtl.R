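test_that("LOD scores agree between the SS-ratio and correlation forms", {
  set.seed(3)
  G <- bernoulli_genotypes(6, 6, seed = 8)
  r <- rnorm(6)
  lod <- lod_scan(G, r)
  oracle <- vapply(1:6, function(j) {
    ss0 <- sum((r - mean(r))^2)
    ss1 <- sum(resid(lm(r ~ G$values[, j]))^2)
    (6 / 2) * log10(ss0 / ss1)
  }, numeric(1))
  expect_lt(max(abs(lod - oracle)), 1e-10)
})

test_that("LOD scan handles null, duplicated and collinear markers", {
  set.seed(5)
  G <- bernoulli_genotypes(500, 10, seed = 12)
  r <- rnorm(500)
  lod <- lod_scan(G, r)
  expect_lt(median(lod), 0.5)               # typical null marker stays tiny
  expect_true(all(lod >= 0 & lod < 3))

  v <- G$values; v[, 7] <- v[, 2]
  lod2 <- lod_scan(genotype_matrix(v), r)
  expect_identical(lod2[[2]], lod2[[7]])

  # perfectly collinear marker capped at a large finite value
  lodc <- lod_scan(genotype_matrix(cbind(v[, 1:2], x = as.numeric(r > 0))),
                   as.numeric(r > 0))
  expect_true(is.finite(lodc[["x"]]))
  expect_gt(lodc[["x"]], 100)
  # constant marker scores zero
  lod0 <- lod_scan(genotype_matrix(cbind(v[, 1, drop = FALSE], k = 1)), r)
  expect_identical(lod0[["k"]], 0)
})

test_that("permutation threshold degenerates correctly at fdr_level 1", {
  G <- bernoulli_genotypes(60, 15, seed = 3)
  set.seed(9); r <- rnorm(60)
  pt <- permutation_threshold(G, r, B = 50, fdr_level = 1, seed = 2)
  obs <- lod_scan(G, r)
  expect_equal(pt$threshold, min(obs[obs > 0]))
})

test_that("null traits rarely pass the 5% FDR threshold", {
  G <- tiny_cross(250, seed = 7, n_chr = 2, m = 40)
  hits <- 0
  for (i in 1:30) {
    set.seed(1000 + i)
    r <- rnorm(250)
    pt <- permutation_threshold(G, r, B = 100, fdr_level = 0.05,
                                seed = 2000 + i)
    if (is.finite(pt$threshold) && pt$n_selected > 0) hits <- hits + 1
  }
  expect_lte(hits / 30, 0.15)
})

test_that("a strong single QTL is detected almost always", {
  G <- tiny_cross(400, seed = 9, n_chr = 2, m = 40)
  found <- 0
  for (i in 1:20) {
    y <- as.vector(simulate_trait(G, additive_arch(G, 20, h2 = 0.9),
                                  seed = 3000 + i))
    pt <- permutation_threshold(G, y - mean(y), B = 100, seed = 4000 + i)
    lod <- lod_scan(G, y - mean(y))
    sig <- which(lod >= pt$threshold)
    if (any(abs(sig - 20) <= 5)) found <- found + 1
  }
  expect_gte(found / 20, 0.95)
})

test_that("forward selection recovers a noise-free model exactly", {
  G <- tiny_cross(300, seed = 11)
  m0 <- bloom_forward_selection(
    G, as.vector(simulate_trait(G, additive_arch(G, c(10, 50), h2 = .8),
                                seed = 1)),
    B = 60, seed = 5)
  expect_gt(length(m0$markers), 0)
  # regenerate y from the fitted linear predictor with zero noise
  y2 <- as.vector(predict_qtl(m0, G))
  m1 <- bloom_forward_selection(G, y2, B = 60, seed = 6)
  expect_true(all(m1$markers %in% m0$markers) ||
                length(m1$markers) >= length(m0$markers))
  fit <- lm.fit(cbind(1, G$values[, m0$markers, drop = FALSE]), y2)
  expect_lt(max(abs(fit$coefficients - m0$coef)), 1e-6)
  # training predictions of the refit are exact
  expect_lt(max(abs(predict_qtl(m0, G) - y2)), 1e-10)
})

test_that("lowering the FDR level never admits more markers in a stage", {
  # the monotone property belongs to the single-stage selection operator;
  # across stages the refit residuals couple the levels
  G <- tiny_cross(300, seed = 13, n_chr = 2, m = 40)
  y <- as.vector(simulate_trait(G, additive_arch(G, c(10, 60), h2 = 0.7),
                                seed = 2))
  sizes <- vapply(c(0.01, 0.05, 0.2, 0.5), function(f) {
    pt <- permutation_threshold(G, y - mean(y), B = 80, fdr_level = f,
                                seed = 77)
    pt$n_selected
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  expect_gt(sizes[1], 0)
})

test_that("interaction LR statistics match nested dense least-squares fits", {
  G <- bernoulli_genotypes(8, 5, seed = 21)
  set.seed(4)
  y <- rnorm(8) + G$values[, 1] * G$values[, 3]
  add <- marker_ids(G)[1]
  lr <- interaction_lr_scan(G, y, add, add)
  for (j in 2:5) {
    Xs <- G$values[, 1]
    gj <- G$values[, j]
    rss_red <- sum(resid(lm(y ~ Xs + gj))^2)
    rss_full <- sum(resid(lm(y ~ Xs + gj + I(Xs * gj)))^2)
    oracle <- max(8 * log(rss_red / max(rss_full, 1e-12)), 0)
    expect_lt(abs(lr[[j]] - oracle), 1e-8)
  }
})

test_that("interaction scan finds planted epistasis and ignores additive traits", {
  G <- tiny_cross(500, seed = 23, n_chr = 2, m = 30)
  a <- marker_ids(G)[8]; b <- marker_ids(G)[45]
  arch <- trait_architecture(
    additive = stats::setNames(c(0.8, 0.8), c(a, b)),
    epistatic = data.frame(a = a, b = b, effect = 1.5), h2 = 0.85)
  y <- as.vector(simulate_trait(G, arch, seed = 3))
  m <- bloom_forward_selection(G, y, B = 60, seed = 9)
  expect_gt(length(m$markers), 0)
  m2 <- interaction_scan(G, y, m, B = 30, fdr_level = 0.05, seed = 10)
  hit <- FALSE
  if (nrow(m2$interactions) > 0) {
    ia <- match(m2$interactions$m, marker_ids(G))
    ib <- match(m2$interactions$j, marker_ids(G))
    hit <- any((abs(ia - 8) <= 5 & abs(ib - 45) <= 5) |
                 (abs(ia - 45) <= 5 & abs(ib - 8) <= 5))
  }
  expect_true(hit)

  # purely additive trait: no interactions retained
  ya <- as.vector(simulate_trait(G, additive_arch(G, c(8, 45), h2 = .8),
                                 seed = 5))
  ma <- bloom_forward_selection(G, ya, B = 60, seed = 11)
  expect_gt(length(ma$markers), 0)
  ma2 <- interaction_scan(G, ya, ma, B = 30, fdr_level = 0.05, seed = 12)
  expect_lte(nrow(ma2$interactions), 1)
})

test_that("QTL predictions are local to model markers", {
  G <- tiny_cross(150, seed = 27)
  y <- as.vector(simulate_trait(G, additive_arch(G, c(5, 40), h2 = .9),
                                seed = 1))
  m <- bloom_forward_selection(G, y, B = 50, seed = 3)
  # empty model predicts the training mean
  me <- m; me$markers <- character(0); me$coef <- me$train_mean
  expect_equal(unname(predict_qtl(me, G)), rep(m$train_mean, 150))
  expect_gt(length(m$markers), 0)
  # perturbing markers outside the model leaves predictions unchanged
  v <- G$values
  outside <- setdiff(marker_ids(G), m$markers)[1:10]
  v[, outside] <- 1 - v[, outside]
  G2 <- genotype_matrix(v, map = G$map)
  expect_identical(predict_qtl(m, G), predict_qtl(m, G2))
  # missing model markers in the test data is an error
  expect_error(predict_qtl(m, subset_genotypes(G, markers = outside)),
               "absent")
})
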