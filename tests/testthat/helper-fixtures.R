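# Small fixtures shared across tests, all built in code.

tiny_map <- function(n_chr = 3, len = 1, m = 30)
  genome_map(n_chromosomes = n_chr, chr_length = len, markers_per_chr = m)

# A modest cross plus one additive trait, reused by several suites.
tiny_cross <- function(n = 200, seed = 42, n_chr = 3, len = 1, m = 30)
  simulate_cross(tiny_map(n_chr, len, m), n, seed = seed)

additive_arch <- function(G, idx, effects = NULL, h2 = 0.6) {
  if (is.null(effects)) effects <- rep(1, length(idx))
  trait_architecture(additive = stats::setNames(effects, marker_ids(G)[idx]),
                     h2 = h2)
}

# deterministic small genotype matrix without linkage structure
bernoulli_genotypes <- function(n, p, seed = 1) {
  set.seed(seed)
  genotype_matrix(matrix(rbinom(n * p, 1, 0.5), n, p))
}
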