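# Deterministic child seed derivation: one master seed, per-purpose streams.
# Keeps results reproducible while decoupling, e.g., meiosis from noise.
child_seed <- function(seed, offset) {
  (as.integer(seed) %% 2147400000L + 104729L * (as.integer(offset) %% 20000L)) %%
    2147483647L
}

# One gamete for a single chromosome: crossover points form a Poisson
# process with rate 1 per Morgan (Haldane model, no interference); the
# starting parent is chosen with probability 1/2.  Returns the 0/1
# parent-of-origin indicator at each marker position.
meiosis_indicator <- function(positions, chr_length) {
  n_x <- stats::rpois(1L, chr_length)
  start <- stats::rbinom(1L, 1L, 0.5)
  if (n_x == 0L) return(rep.int(start, length(positions)))
  xpts <- sort(stats::runif(n_x, 0, chr_length))
  (start + findInterval(positions, xpts)) %% 2L
}

#' Simulate haploid segregants from a biparental cross
#'
#' Each segregant's chromosome is a random patchwork of contiguous blocks
#' inherited from the two parents, delimited by crossover points drawn as a
#' Poisson process with rate 1 per Morgan (Haldane model).  Markers are
#' coded 1 if inherited from parent 1 and 0 if from parent 0, so each
#' marker has expected allele-1 proportion 0.5.
#'
#' @param map a [genome_map()].
#' @param n_segregants number of offspring to simulate (>= 1).
#' @param seed integer seed; the same seed reproduces the population
#'   bit-identically.
#' @return a [genotype_matrix()] with coding `"haploid01"`.
#' @export
simulate_cross <- function(map, n_segregants, seed = 1L) {
  validate_genome_map(map)
  if (n_segregants < 1) stop("n_segregants must be >= 1")
  set.seed(child_seed(seed, 1L))
  ch <- map$chrom
  blocks <- lapply(seq_len(nrow(ch)), function(c) {
    pos <- map$positions[[c]]
    t(vapply(seq_len(n_segregants),
             function(i) meiosis_indicator(pos, ch$length[c]),
             integer(length(pos))))
  })
  values <- do.call(cbind, blocks)
  mt <- map_table(map)
  dimnames(values) <- list(sprintf("seg%04d", seq_len(n_segregants)), mt$marker)
  genotype_matrix(values, coding = "haploid01", map = mt)
}

#' Define the genetic architecture of a simulated trait
#'
#' @param additive named or index-addressed numeric vector of additive
#'   marker effects; names are marker ids (or integer indices).
#' @param epistatic optional data frame with columns `a`, `b`, `effect`
#'   giving pairwise interaction effects between distinct markers; the
#'   interaction term is the product of the coded alleles.
#' @param h2 narrow-sense heritability in (0, 1]: the fraction of the
#'   phenotypic variance explained by the genetic score on the simulated
#'   sample.
#' @param name trait name.
#' @return an object of class `trait_architecture`.
#' @export
trait_architecture <- function(additive, epistatic = NULL, h2 = 0.5,
                               name = "trait") {
  if (length(additive) == 0 && (is.null(epistatic) || nrow(epistatic) == 0))
    stop("architecture must have at least one nonzero effect")
  if (!is.numeric(h2) || h2 <= 0 || h2 > 1)
    stop("h2 must lie in (0, 1]")
  if (!is.null(epistatic)) {
    stopifnot(all(c("a", "b", "effect") %in% names(epistatic)))
    if (any(epistatic$a == epistatic$b))
      stop("interaction pairs must involve distinct markers")
  }
  structure(list(additive = additive, epistatic = epistatic, h2 = h2,
                 name = name),
            class = "trait_architecture")
}

# Resolve marker references (names or indices) against a genotype matrix.
resolve_markers <- function(G, ref) {
  idx <- if (is.character(ref)) match(ref, marker_ids(G)) else as.integer(ref)
  if (any(is.na(idx)) || any(idx < 1 | idx > ncol(G$values)))
    stop("architecture refers to markers absent from the genotype matrix")
  idx
}

#' Simulate a phenotype from a genotype matrix and a trait architecture
#'
#' The genetic score is `sum(beta * g) + sum(gamma * g_a * g_b)`; Gaussian
#' noise is added with variance calibrated on the realized genetic score so
#' that `var(genetic) / var(total)` equals `h2` in expectation for this
#' sample.  The returned vector is standardized to mean 0 and variance 1
#' (sample variance).
#'
#' @param G a [genotype_matrix()].
#' @param arch a [trait_architecture()].
#' @param seed integer seed for the noise stream.
#' @return named numeric phenotype vector (one value per sample), with the
#'   realized genetic score attached as attribute `"genetic"` (standardized
#'   by the same location and scale).
#' @export
simulate_trait <- function(G, arch, seed = 1L) {
  stopifnot(inherits(arch, "trait_architecture"))
  X <- G$values
  g <- numeric(nrow(X))
  if (length(arch$additive) > 0) {
    idx <- resolve_markers(G, if (is.null(names(arch$additive)))
      seq_along(arch$additive) else names(arch$additive))
    if (!is.null(names(arch$additive)))
      g <- g + as.vector(X[, idx, drop = FALSE] %*% unname(arch$additive))
    else g <- g + as.vector(X[, idx, drop = FALSE] %*% arch$additive)
  }
  if (!is.null(arch$epistatic) && nrow(arch$epistatic) > 0) {
    ia <- resolve_markers(G, arch$epistatic$a)
    ib <- resolve_markers(G, arch$epistatic$b)
    for (r in seq_len(nrow(arch$epistatic)))
      g <- g + arch$epistatic$effect[r] * X[, ia[r]] * X[, ib[r]]
  }
  vg <- stats::var(g)
  if (vg == 0) stop("genetic score is constant: no segregating effect")
  if (arch$h2 < 1) {
    set.seed(child_seed(seed, 2L))
    e <- stats::rnorm(length(g), 0, sqrt(vg * (1 - arch$h2) / arch$h2))
  } else e <- numeric(length(g))
  y <- g + e
  mu <- mean(y); s <- stats::sd(y)
  y <- (y - mu) / s
  names(y) <- rownames(X)
  attr(y, "genetic") <- (g - mean(g)) / s
  attr(y, "h2") <- arch$h2
  y
}

#' Inject missing values into a phenotype vector
#'
#' Missingness is injected uniformly at random at a configurable rate,
#' emulating incompletely observed traits.
#'
#' @param y numeric phenotype vector.
#' @param rate fraction of entries to set missing, in `[0, 1)`.
#' @param seed integer seed.
#' @return `y` with `NA` at the selected positions.
#' @export
inject_missing <- function(y, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(y)
  set.seed(child_seed(seed, 3L))
  y[sample.int(length(y), floor(rate * length(y)))] <- NA_real_
  y
}

#' Simulate a structured breeding population
#'
#' Lines descend from a small set of founder haplotypes through repeated
#' generations of random pairing and meiosis, so that lines sharing recent
#' ancestors are more related than distant ones.  Founders alternate
#' between the two parental haplotypes (all-0 and all-1), as in breeding
#' programmes derived from a biparental elite pool; with `n_founders = 2`
#' and one generation this reduces exactly to [simulate_cross()].  In the
#' final generation, lines are produced two per parent pair, so the
#' population contains full-sib pairs (recorded in attribute `"family"`).
#'
#' @param n_founders number of founder haplotypes (>= 2).
#' @param n_generations generations of random crossing (>= 1).
#' @param map a [genome_map()].
#' @param n_lines number of lines to output.
#' @param ploidy_coding `"haploid01"` for haploid lines coded 0/1, or
#'   `"diploid"` for diploid lines coded -1/0/1 (aa, aA, AA); the coding
#'   determines only the output alphabet.
#' @param seed integer seed.
#' @return a [genotype_matrix()]; attribute `"family"` gives the final
#'   parent-pair id of each line.
#' @export
simulate_structured_population <- function(n_founders, n_generations, map,
                                           n_lines,
                                           ploidy_coding = c("haploid01",
                                                             "diploid"),
                                           seed = 1L) {
  ploidy_coding <- match.arg(ploidy_coding)
  validate_genome_map(map)
  if (n_founders < 2) stop("n_founders must be >= 2")
  if (n_generations < 1) stop("n_generations must be >= 1")
  set.seed(child_seed(seed, 4L))
  mt <- map_table(map)
  p <- nrow(mt)
  ch <- map$chrom
  chrom_index <- split(seq_len(p), factor(mt$chrom, levels = ch$name))

  gamete <- function(h1, h2) {
    out <- integer(p)
    for (c in seq_len(nrow(ch))) {
      idx <- chrom_index[[c]]
      z <- meiosis_indicator(map$positions[[c]], ch$length[c])
      out[idx] <- ifelse(z == 0L, h1[idx], h2[idx])
    }
    out
  }

  # founders: alternating parental haplotypes
  pop <- lapply(seq_len(n_founders), function(f) rep.int((f - 1L) %% 2L, p))
  n_pop <- max(n_founders, n_lines)
  for (gen in seq_len(n_generations - 1L)) {
    pop <- lapply(seq_len(n_pop), function(i) {
      pr <- sample.int(length(pop), 2L)
      gamete(pop[[pr[1]]], pop[[pr[2]]])
    })
  }
  # final generation: two offspring per parent pair -> full-sib families
  n_fam <- ceiling(n_lines / 2)
  fam_of <- rep(seq_len(n_fam), each = 2L)[seq_len(n_lines)]
  pairs <- lapply(seq_len(n_fam), function(f) sample.int(length(pop), 2L))
  haplos <- lapply(seq_len(n_lines), function(i) {
    pr <- pairs[[fam_of[i]]]
    gamete(pop[[pr[1]]], pop[[pr[2]]])
  })
  if (ploidy_coding == "haploid01") {
    values <- do.call(rbind, haplos)
  } else {
    values <- do.call(rbind, lapply(seq_len(n_lines), function(i) {
      pr <- pairs[[fam_of[i]]]
      haplos[[i]] + gamete(pop[[pr[1]]], pop[[pr[2]]]) - 1L
    }))
  }
  dimnames(values) <- list(sprintf("line%04d", seq_len(n_lines)), mt$marker)
  G <- genotype_matrix(values,
                       coding = if (ploidy_coding == "haploid01")
                         "haploid01" else "diploid",
                       map = mt)
  attr(G, "family") <- fam_of
  G
}

#' Simulate a gene annotation on a genetic map
#'
#' Places mostly non-overlapping gene intervals along the chromosomes, with
#' configurable small fractions of partially overlapping and fully nested
#' genes to exercise fusion edge rules.  Coordinates are 0-based half-open
#' on the map's Morgan scale: a marker at position `x` lies in a gene iff
#' `start <= x < end`.
#'
#' @param map a [genome_map()].
#' @param n_genes total number of genes (>= 1).
#' @param overlap_fraction fraction of genes that partially overlap a
#'   neighbouring gene.
#' @param nested_fraction fraction of genes fully nested inside another.
#' @param seed integer seed.
#' @return a [gene_annotation()] data frame (gene, chrom, start, end).
#' @export
simulate_annotation <- function(map, n_genes, overlap_fraction = 0,
                                nested_fraction = 0, seed = 1L) {
  validate_genome_map(map)
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(child_seed(seed, 5L))
  n_over <- floor(n_genes * overlap_fraction)
  n_nest <- floor(n_genes * nested_fraction)
  n_base <- n_genes - n_over - n_nest
  if (n_base < 1) stop("overlap/nested fractions leave no base genes")
  ch <- map$chrom
  w <- ch$length / sum(ch$length)
  per_chr <- diff(round(cumsum(c(0, w)) * n_base))
  # ensure every requested base gene lands somewhere
  per_chr[1] <- per_chr[1] + (n_base - sum(per_chr))
  rows <- list()
  for (c in seq_len(nrow(ch))) {
    k <- per_chr[c]
    if (k < 1) next
    L <- ch$length[c]
    slot <- L / k
    for (j in seq_len(k)) {
      lo <- (j - 1) * slot; hi <- j * slot
      a <- stats::runif(1, lo, lo + 0.35 * slot)
      b <- stats::runif(1, hi - 0.35 * slot, hi)
      rows[[length(rows) + 1L]] <- data.frame(chrom = ch$name[c],
                                              start = a, end = b)
    }
  }
  base <- do.call(rbind, rows)
  extra <- list()
  if (n_over > 0) for (j in seq_len(n_over)) {
    i <- sample.int(nrow(base), 1L)
    len <- (base$end[i] - base$start[i])
    a <- base$end[i] - 0.4 * len            # starts inside gene i
    b <- base$end[i] + 0.6 * len            # ends beyond it
    extra[[length(extra) + 1L]] <- data.frame(chrom = base$chrom[i],
                                              start = a, end = b)
  }
  if (n_nest > 0) for (j in seq_len(n_nest)) {
    i <- sample.int(nrow(base), 1L)
    len <- base$end[i] - base$start[i]
    a <- base$start[i] + 0.25 * len
    b <- base$end[i] - 0.25 * len
    extra[[length(extra) + 1L]] <- data.frame(chrom = base$chrom[i],
                                              start = a, end = b)
  }
  ann <- rbind(base, if (length(extra)) do.call(rbind, extra))
  ann <- ann[order(match(ann$chrom, ch$name), ann$start), , drop = FALSE]
  ann <- data.frame(gene = sprintf("g%04d", seq_len(nrow(ann))), ann,
                    stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  gene_annotation(ann)
}
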