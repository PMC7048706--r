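#' Construct a genotype matrix
#'
#' The substrate of every predictor: a samples-by-markers numeric matrix
#' with a coding scheme and per-marker map metadata.  Haploid coding uses
#' the alphabet \{0, 1\}, diploid uses \{-1, 0, 1\} (aa, aA, AA); `NA`
#' marks missing calls.  After mean imputation values may be fractional,
#' recorded via the `imputed` flag.
#'
#' @param values numeric matrix (samples x markers) with dimnames.
#' @param coding `"haploid01"` or `"diploid"`.
#' @param map data frame with columns `marker`, `chrom`, `pos` aligned to
#'   the columns of `values` (may be `NULL` when no map is known).
#' @param imputed logical; `TRUE` once missing values have been imputed
#'   (fractional values are then permitted).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, coding = c("haploid01", "diploid"),
                            map = NULL, imputed = FALSE) {
  coding <- match.arg(coding)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("m%05d", seq_len(ncol(values)))
  if (anyDuplicated(colnames(values)))
    stop("duplicate marker ids")
  if (!is.null(map)) {
    stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
    if (!identical(map$marker, colnames(values)))
      map <- map[match(colnames(values), map$marker), , drop = FALSE]
    if (anyNA(map$marker)) stop("map does not cover all markers")
    for (cc in unique(map$chrom)) {
      pos <- map$pos[map$chrom == cc]
      if (is.unsorted(pos)) stop("map positions decrease within ", cc)
    }
  }
  if (!imputed) check_alphabet(values, coding)
  structure(list(values = values, coding = coding, map = map,
                 imputed = imputed),
            class = "genotype_matrix")
}

check_alphabet <- function(values, coding) {
  alphabet <- if (coding == "haploid01") c(0, 1) else c(-1, 0, 1)
  bad <- !(values %in% alphabet) & !is.na(values)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "genotype alphabet violation at sample '%s', marker '%s': value %s not in {%s}",
      rownames(values)[ij[1]], colnames(values)[ij[2]],
      format(values[ij[1], ij[2]]), paste(alphabet, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers, coding %s%s%s\n",
              nrow(x$values), ncol(x$values), x$coding,
              if (x$imputed) ", imputed" else "",
              if (anyNA(x$values)) sprintf(", %d missing", sum(is.na(x$values)))
              else ""))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Sample and marker identifiers
#' @param G a [genotype_matrix()].
#' @return character vector of ids.
#' @export
sample_ids <- function(G) rownames(G$values)

#' @rdname sample_ids
#' @export
marker_ids <- function(G) colnames(G$values)

#' Subset a genotype matrix
#'
#' @param G a [genotype_matrix()].
#' @param samples,markers index vectors (integer, logical, or ids).
#' @return the subsetted `genotype_matrix` (map subset accordingly).
#' @export
subset_genotypes <- function(G, samples = NULL, markers = NULL) {
  v <- G$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(markers)) v <- v[, markers, drop = FALSE]
  map <- G$map
  if (!is.null(map) && !is.null(markers))
    map <- map[match(colnames(v), map$marker), , drop = FALSE]
  genotype_matrix(v, coding = G$coding, map = map, imputed = G$imputed)
}

# ---------------------------------------------------------------------------
# file I/O: plain TSV, first row marker ids, first column sample ids, "NA"
# for missing; map in a companion 3-column TSV (marker, chromosome, position)

default_map_path <- function(path)
  paste0(tools::file_path_sans_ext(path), ".map.tsv")

#' Read / write genotype matrices as TSV
#'
#' The genotype dialect is a tab-separated matrix whose first row holds
#' marker ids and first column sample ids, with `NA` for missing calls.
#' The marker map travels in a companion 3-column TSV (marker,
#' chromosome, position), by default at `<path minus extension>.map.tsv`.
#' Writing then reading reproduces values, ids and map exactly.
#'
#' @param path genotype TSV path.
#' @param coding `"haploid01"` or `"diploid"`.
#' @param map_path companion map TSV path; `NULL` for the default; for
#'   reading, a missing map file yields a map-less matrix.
#' @param imputed logical, see [genotype_matrix()].
#' @return `read_genotypes` returns a [genotype_matrix()];
#'   `write_genotypes` returns `path` invisibly.
#' @export
read_genotypes <- function(path, coding = c("haploid01", "diploid"),
                           map_path = NULL, imputed = FALSE) {
  coding <- match.arg(coding)
  if (is.null(map_path)) map_path <- default_map_path(path)
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  values <- as.matrix(tab)
  storage.mode(values) <- "double"
  map <- NULL
  if (file.exists(map_path)) {
    map <- utils::read.delim(map_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    names(map) <- c("marker", "chrom", "pos")
  }
  genotype_matrix(values, coding = coding, map = map, imputed = imputed)
}

#' @rdname read_genotypes
#' @param G a [genotype_matrix()] to write.
#' @export
write_genotypes <- function(G, path, map_path = NULL) {
  if (is.null(map_path)) map_path <- default_map_path(path)
  out <- data.frame(sample = rownames(G$values), G$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(G$map)) {
    mp <- G$map
    mp$pos <- sprintf("%.17g", mp$pos)   # lossless double round trip
    utils::write.table(mp, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Construct a phenotype table
#'
#' Per-trait response vectors aligned on sample ids, with missing values
#' permitted and a per-trait normalization flag.
#'
#' @param values numeric matrix or data frame, samples x traits, with row
#'   names as sample ids.
#' @param normalized logical vector (recycled) recording which traits are
#'   standardized.
#' @return an object of class `phenotype_table`.
#' @export
phenotype_table <- function(values, normalized = FALSE) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  structure(list(values = values,
                 normalized = rep_len(normalized, ncol(values))),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples x %d traits (%d missing values)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Read / write phenotype tables as TSV
#'
#' Wide tab-separated layout: first column `sample`, one column per trait,
#' `NA` for missing.  Rows sharing a sample id are treated as replicates
#' and can be averaged with [average_replicates()].
#'
#' @param path TSV path.
#' @return `read_phenotypes` returns a [phenotype_table()] (replicate rows
#'   preserved); `write_phenotypes` returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- as.character(tab[[1]])
  phenotype_table(values)
}

#' @rdname read_phenotypes
#' @param P a [phenotype_table()].
#' @export
write_phenotypes <- function(P, path) {
  out <- data.frame(sample = rownames(P$values), P$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate phenotype measurements
#'
#' Rows sharing a sample id are replicates; they are averaged ignoring
#' missing replicates (mean of the available readings).  Averaging must
#' precede normalization.
#'
#' @param P a [phenotype_table()].
#' @return a [phenotype_table()] with one row per distinct sample id, in
#'   first-appearance order.
#' @export
average_replicates <- function(P) {
  ids <- rownames(P$values)
  uid <- unique(ids)
  v <- do.call(rbind, lapply(uid, function(s) {
    block <- P$values[ids == s, , drop = FALSE]
    apply(block, 2, function(col)
      if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE))
  }))
  rownames(v) <- uid
  phenotype_table(v, normalized = FALSE)
}

#' Standardize each trait to mean 0, variance 1
#'
#' Statistics are computed over the observed (non-missing) entries only,
#' using the sample (n-1) variance; missing entries stay missing.  The
#' operation is idempotent.
#'
#' @param P a [phenotype_table()].
#' @return the normalized [phenotype_table()].
#' @export
normalize_phenotypes <- function(P) {
  v <- P$values
  for (j in seq_len(ncol(v))) {
    obs <- v[, j][!is.na(v[, j])]
    if (length(unique(obs)) < 2)
      stop("trait '", colnames(v)[j], "' is constant: cannot normalize")
    v[, j] <- (v[, j] - mean(obs)) / stats::sd(obs)
  }
  phenotype_table(v, normalized = TRUE)
}

#' Impute missing genotype values
#'
#' `"column-mean"` replaces each missing call with the mean of the
#' observed calls for that marker (standard for dense SNP panels);
#' `"heterozygote"` replaces missing diploid calls with the heterozygote
#' code 0 (aA).  Observed entries are never altered.
#'
#' @param G a [genotype_matrix()].
#' @param strategy `"column-mean"` or `"heterozygote"`.
#' @return an imputed [genotype_matrix()] with no missing values.
#' @export
impute_genotypes <- function(G, strategy = c("column-mean", "heterozygote")) {
  strategy <- match.arg(strategy)
  v <- G$values
  if (!anyNA(v)) return(G)
  if (strategy == "heterozygote") {
    if (G$coding != "diploid")
      stop("heterozygote imputation requires diploid coding")
    v[is.na(v)] <- 0
  } else {
    mis <- which(colSums(is.na(v)) > 0)
    for (j in mis) {
      obs <- v[, j][!is.na(v[, j])]
      if (length(obs) == 0)
        stop("marker '", colnames(v)[j],
             "' is entirely missing: no column mean defined")
      v[is.na(v[, j]), j] <- mean(obs)
    }
  }
  genotype_matrix(v, coding = G$coding, map = G$map, imputed = TRUE)
}

#' Prune markers by pairwise linkage disequilibrium
#'
#' Sliding-window greedy scan: within each window of `window` markers
#' (advanced by `step`), marker pairs are examined left to right and the
#' later marker of any pair whose squared Pearson correlation exceeds
#' `r2_threshold` is removed.  The earlier marker in position order is
#' always the one kept.  Constant markers have undefined correlation and
#' are treated as r^2 = 0 with everything (never removed for correlation).
#' Exact output parity with external pruning tools is not claimed.
#'
#' @param G a [genotype_matrix()]; markers must be in map order.
#' @param window window size in markers (>= 2).
#' @param step window slide in markers (>= 1).
#' @param r2_threshold retain only pairs with r^2 <= this value (in (0,1)).
#' @return character vector of retained marker ids, in original order.
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_threshold = 0.02) {
  stopifnot(window >= 2, step >= 1,
            r2_threshold > 0, r2_threshold < 1)
  v <- G$values
  p <- ncol(v)
  keep <- rep(TRUE, p)
  sds <- apply(v, 2, stats::sd)
  starts <- seq(1L, max(1L, p - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, p)
    idx <- idx[keep[idx]]
    if (length(idx) < 2) next
    cc <- suppressWarnings(stats::cor(v[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0      # constant markers: r2 treated as 0
    r2 <- cc^2
    for (jj in 2:length(idx)) {
      if (!keep[idx[jj]]) next
      for (ii in 1:(jj - 1)) {
        if (keep[idx[ii]] && r2[ii, jj] > r2_threshold) {
          keep[idx[jj]] <- FALSE
          break
        }
      }
    }
    if (max(idx) >= p) break
  }
  marker_ids(G)[keep]
}

#' Construct / read / write a gene annotation
#'
#' Gene intervals in 0-based half-open coordinates on the same scale as
#' the marker map: a marker at position `x` belongs to a gene iff
#' `start <= x < end`.  The file format is BED-like 4-column TSV
#' (chromosome, start, end, gene id).
#'
#' @param df data frame with columns `gene`, `chrom`, `start`, `end`.
#' @return an object of classes `gene_annotation` and `data.frame`.
#' @export
gene_annotation <- function(df) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(df)))
  if (any(df$start >= df$end)) stop("gene interval with start >= end")
  if (anyDuplicated(df$gene)) stop("duplicate gene ids")
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' @rdname gene_annotation
#' @param path BED-like TSV path.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("chrom", "start", "end", "gene")
  gene_annotation(tab[, c("gene", "chrom", "start", "end")])
}

#' @rdname gene_annotation
#' @param ann a `gene_annotation`.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann[, c("chrom", "start", "end", "gene")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
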