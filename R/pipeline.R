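#' Run a configured simulate / benchmark / rank pipeline
#'
#' Single entry point wiring the simulator, the evaluation engine and the
#' rank statistics into a reproducible run.  The configuration is a YAML
#' (or already-parsed list) with blocks:
#'
#' \preformatted{
#' seed: 1
#' simulate:
#'   chromosomes: 5        # genome_map arguments
#'   chr_length: 1.5
#'   markers_per_chr: 30
#'   segregants: 300
#'   traits:               # one entry per trait
#'     - {name: t1, n_qtl: 3, h2: 0.6}
#'     - {name: t2, n_qtl: 8, h2: 0.4}
#' benchmark:
#'   methods: [lasso, gblup]
#'   k_folds: 5
#'   n_repeats: 1
#' rank: true
#' }
#'
#' Every stochastic stage derives its seed from the master seed; the
#' manifest records the config, all derived seeds and package version so
#' any stage can be replayed in isolation.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory (created if needed).
#' @return the output directory, invisibly; writes `genotypes.tsv`,
#'   `phenotypes.tsv`, `results.tsv`, `avg_ranks.tsv`, `friedman.json`
#'   and `manifest.json` there.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  for (field in c("seed", "simulate", "benchmark"))
    if (is.null(cfg[[field]]))
      stop("config: missing required field '", field, "'")
  sim <- cfg$simulate
  for (field in c("segregants", "traits"))
    if (is.null(sim[[field]]))
      stop("config: missing required field 'simulate.", field, "'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  map <- genome_map(n_chromosomes = sim$chromosomes %||% 5,
                    chr_length = sim$chr_length %||% 1.5,
                    markers_per_chr = sim$markers_per_chr %||% 30)
  G <- simulate_cross(map, sim$segregants, seed = child_seed(seed, 1L))
  traits <- list()
  for (i in seq_along(sim$traits)) {
    ts <- sim$traits[[i]]
    tseed <- child_seed(seed, 10L + i)
    set.seed(tseed)
    idx <- sample.int(ncol(G$values), ts$n_qtl %||% 3)
    arch <- trait_architecture(
      additive = stats::setNames(stats::rnorm(length(idx), 0, 1),
                                 marker_ids(G)[idx]),
      h2 = ts$h2 %||% 0.5, name = ts$name %||% paste0("trait", i))
    traits[[arch$name]] <- simulate_trait(G, arch, seed = tseed)
  }
  write_genotypes(G, file.path(out_dir, "genotypes.tsv"))
  write_phenotypes(phenotype_table(do.call(cbind, traits)),
                   file.path(out_dir, "phenotypes.tsv"))

  bm <- cfg$benchmark
  methods <- unlist(bm$methods)
  res <- list()
  bench_seeds <- list()
  for (tn in names(traits)) for (m in methods) {
    bseed <- child_seed(seed, 100L + length(res))
    bench_seeds[[paste(tn, m, sep = "/")]] <- bseed
    cv <- run_cv(G, traits[[tn]], m, k_folds = bm$k_folds %||% 5,
                 n_repeats = bm$n_repeats %||% 1, seed = bseed)
    res[[length(res) + 1L]] <- data.frame(trait = tn, method = m,
                                          cvr2 = cv$cvr2,
                                          stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  utils::write.table(res, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  if (isTRUE(cfg$rank) && length(methods) >= 2 && length(traits) >= 1) {
    wide <- stats::reshape(res, idvar = "trait", timevar = "method",
                           direction = "wide")
    names(wide) <- sub("^cvr2\\.", "", names(wide))
    rc <- rank_table(result_table(wide))
    utils::write.table(
      data.frame(method = names(rc$avg_ranks), avg_rank = rc$avg_ranks),
      file.path(out_dir, "avg_ranks.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ft <- friedman_rank_test(rc)
    jsonlite::write_json(ft, file.path(out_dir, "friedman.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    config = cfg,
    seeds = list(master = seed, meiosis = child_seed(seed, 1L),
                 traits = lapply(seq_along(sim$traits), function(i)
                   child_seed(seed, 10L + i)),
                 benchmark = bench_seeds),
    package_version = as.character(utils::packageVersion("phenobench")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
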