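test_that("map validation rejects malformed maps", {
  expect_error(genome_map(2, -1, 10), "negative")
  m <- genome_map(2, 1, 10)
  m$positions[[1]][2] <- m$positions[[1]][1]   # non-increasing
  expect_error(validate_genome_map(m), "increasing")
  expect_equal(n_markers(genome_map(4, 1, c(5, 10, 15, 20))), 50)
})

test_that("a zero-length chromosome yields uniform segregants", {
  map <- genome_map(1, 0, 12)
  G <- simulate_cross(map, 30, seed = 1)
  per_seg <- apply(G$values, 1, function(r) length(unique(r)))
  expect_true(all(per_seg == 1))
})

test_that("allele-1 proportion is near one half at every marker", {
  G <- simulate_cross(genome_map(4, 2, 30), 2000, seed = 3)
  prop <- colMeans(G$values)
  se <- sqrt(0.25 / 2000)
  # each marker is marginally Bernoulli(1/2): nearly all within 3 SEs,
  # none far outside
  expect_gte(mean(abs(prop - 0.5) <= 3 * se), 0.95)
  expect_true(all(abs(prop - 0.5) <= 5 * se))
  expect_lt(abs(mean(prop) - 0.5), 0.02)
})

test_that("recombination fraction follows the Haldane map function", {
  # two markers d Morgans apart: r = (1 - exp(-2d)) / 2
  for (d in c(0.05, 0.2, 0.5)) {
    map <- genome_map(1, d, positions = list(c(1e-9, d - 1e-9)))
    G <- simulate_cross(map, 5000, seed = round(100 * d))
    obs_r <- mean(G$values[, 1] != G$values[, 2])
    exp_r <- (1 - exp(-2 * d)) / 2
    expect_lt(abs(obs_r - exp_r), 4 * sqrt(exp_r * (1 - exp_r) / 5000))
  }
})

test_that("crossover counts per chromosome are Poisson with mean = length", {
  len <- 1.5
  map <- genome_map(1, len, 400)   # dense markers resolve most crossovers
  G <- simulate_cross(map, 5000, seed = 11)
  switches <- apply(G$values, 1, function(r) sum(diff(r) != 0))
  # chi-square GOF against Poisson(len), tail-binned
  brk <- c(-0.5, 0.5, 1.5, 2.5, 3.5, 4.5, Inf)
  obs <- table(cut(switches, brk))
  pr <- diff(ppois(c(-1, 0, 1, 2, 3, 4, Inf), len))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = pr))
  expect_gt(gof$p.value, 0.01)
})

test_that("adjacent-marker agreement decreases with genetic distance", {
  G <- simulate_cross(genome_map(1, 2, 80), 1500, seed = 5)
  pos <- G$map$pos
  d <- outer(pos, pos, function(a, b) abs(a - b))
  agree <- crossprod(G$values == 1) + crossprod(G$values == 0)
  agree <- agree / nrow(G$values)
  ut <- upper.tri(d)
  bins <- cut(d[ut], breaks = quantile(d[ut], 0:5 / 5),
              include.lowest = TRUE)
  means <- tapply(agree[ut], bins, mean)
  expect_true(all(diff(means) < 0))
})

test_that("stored seed regenerates genotypes and phenotypes bit-identically", {
  map <- tiny_map()
  G1 <- simulate_cross(map, 60, seed = 17)
  G2 <- simulate_cross(map, 60, seed = 17)
  expect_identical(G1$values, G2$values)
  a <- additive_arch(G1, c(3, 25), h2 = 0.5)
  expect_identical(simulate_trait(G1, a, seed = 9),
                   simulate_trait(G1, a, seed = 9))
})

test_that("simulated traits are standardized and decompose as requested", {
  G <- tiny_cross(1000, seed = 21)
  a <- additive_arch(G, c(5, 30, 55, 80), effects = c(1, .8, .6, .4),
                     h2 = 0.6)
  y <- simulate_trait(G, a, seed = 2)
  expect_lt(abs(mean(y)), 1e-9)
  expect_lt(abs(var(y) - 1), 1e-9)
  # correlation with the true genetic score approx sqrt(h2)
  expect_lt(abs(cor(as.vector(y), attr(y, "genetic")) - sqrt(0.6)), 0.05)
})

test_that("h2 = 1 gives a deterministic phenotype", {
  G <- tiny_cross(100, seed = 4)
  a <- additive_arch(G, c(2, 40), h2 = 1)
  expect_identical(as.vector(simulate_trait(G, a, seed = 1)),
                   as.vector(simulate_trait(G, a, seed = 999)))
})

test_that("a single large-effect QTL at high h2 gives a bimodal phenotype", {
  G <- tiny_cross(800, seed = 31)
  y <- as.vector(simulate_trait(G, additive_arch(G, 10, h2 = 0.95), seed = 3))
  cl <- kmeans(y, centers = 2, nstart = 5)
  expect_gt(cl$betweenss / cl$totss, 0.8)
})

test_that("degenerate architectures are rejected", {
  G <- tiny_cross(50, seed = 1)
  expect_error(trait_architecture(numeric(0)), "at least one")
  expect_error(trait_architecture(c(m1 = 1), h2 = 0), "h2")
  expect_error(trait_architecture(c(m1 = 1), h2 = 1.2), "h2")
  expect_error(
    simulate_trait(G, trait_architecture(c(nonexistent = 1), h2 = .5)),
    "absent")
  ep <- data.frame(a = "m1", b = "m1", effect = 1)
  expect_error(trait_architecture(c(m1 = 1), epistatic = ep), "distinct")
})

test_that("structured population with 2 founders and 1 generation matches a cross", {
  map <- tiny_map(2, 1, 20)
  Gs <- simulate_structured_population(2, 1, map, 400, "haploid01", seed = 8)
  Gc <- simulate_cross(map, 400, seed = 8)
  # same marginal allele frequencies and block structure statistics
  expect_lt(abs(mean(Gs$values) - 0.5), 0.04)
  sw_s <- mean(apply(Gs$values[, 1:20], 1, function(r) sum(diff(r) != 0)))
  sw_c <- mean(apply(Gc$values[, 1:20], 1, function(r) sum(diff(r) != 0)))
  expect_lt(abs(sw_s - sw_c), 0.2)
})

test_that("full sibs are more similar than unrelated lines", {
  map <- tiny_map(3, 1, 25)
  Gs <- simulate_structured_population(4, 4, map, 200, "haploid01", seed = 13)
  fam <- attr(Gs, "family")
  K <- compute_gsm(Gs)$K
  sib <- outer(fam, fam, "==") & row(K) != col(K)
  expect_gt(mean(K[sib]), mean(K[!sib & row(K) != col(K)]))
})

test_that("diploid coding restricts the output alphabet to -1/0/1", {
  Gd <- simulate_structured_population(4, 2, tiny_map(2, 1, 15), 60,
                                       "diploid", seed = 2)
  expect_true(all(Gd$values %in% c(-1, 0, 1)))
})

test_that("simulated annotations respect bounds, nesting and uniqueness", {
  map <- tiny_map(2, 1, 20)
  a1 <- simulate_annotation(map, 1, seed = 3)
  expect_equal(nrow(a1), 1)
  expect_true(a1$start >= 0 && a1$end <= 1)

  ann <- simulate_annotation(map, 14, overlap_fraction = 0,
                             nested_fraction = 0, seed = 5)
  nested <- vapply(seq_len(nrow(ann)), function(i)
    any(ann$chrom == ann$chrom[i] & ann$start <= ann$start[i] &
          ann$end >= ann$end[i] & seq_len(nrow(ann)) != i), logical(1))
  expect_false(any(nested))
  # interval-sweep oracle: every marker in at most one gene
  mt <- phenobench:::map_table(map)
  hits <- vapply(seq_len(nrow(mt)), function(i)
    sum(ann$chrom == mt$chrom[i] & ann$start <= mt$pos[i] &
          mt$pos[i] < ann$end), numeric(1))
  expect_true(all(hits <= 1))
})
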