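#' Construct a traits-by-methods result table
#'
#' @param x matrix or data frame of accuracy values (cvR2 or R2), traits
#'   in rows, methods in columns; a first column named `trait` is used as
#'   row names.  No missing cells; at least 2 methods and 1 trait.
#' @return an object of classes `result_table` and `matrix`.
#' @export
result_table <- function(x) {
  if (is.data.frame(x)) {
    if ("trait" %in% names(x)) {
      rn <- x$trait
      x <- as.matrix(x[, setdiff(names(x), "trait"), drop = FALSE])
      rownames(x) <- rn
    } else x <- as.matrix(x)
  }
  if (anyNA(x)) stop("result table has missing cells")
  if (ncol(x) < 2) stop("need at least 2 methods")
  if (nrow(x) < 1) stop("need at least 1 trait")
  class(x) <- c("result_table", class(x))
  x
}

#' Published benchmark tables
#'
#' The cvR2 / R2 tables of the yeast (46 growth traits x 7 methods),
#' wheat (4 agronomic traits x 6 methods) and rice (12 agronomic traits x
#' 6 methods) benchmarks, shipped with the package as transcribed
#' fixtures.
#'
#' @param dataset `"yeast"`, `"wheat"` or `"rice"`.
#' @return a [result_table()].
#' @export
published_table <- function(dataset = c("yeast", "wheat", "rice")) {
  dataset <- match.arg(dataset)
  file <- switch(dataset, yeast = "yeast_cvr2.tsv", wheat = "wheat_cvr2.tsv",
                 rice = "rice_r2.tsv")
  path <- system.file("extdata", file, package = "phenobench")
  result_table(utils::read.delim(path, check.names = FALSE))
}

#' Rank methods within each trait
#'
#' Rank 1 is the most accurate method; ties receive midranks, so each
#' trait's ranks sum to `k(k+1)/2`.
#'
#' @param T a [result_table()] (or coercible).
#' @return an object of class `rank_comparison`: `ranks` (traits x
#'   methods), `avg_ranks`, `rank_sums`, `k`, `n`.
#' @export
rank_table <- function(T) {
  T <- result_table(unclass(T))
  R <- t(apply(-T, 1, rank))
  colnames(R) <- colnames(T)
  structure(list(ranks = R, avg_ranks = colMeans(R), rank_sums = colSums(R),
                 k = ncol(R), n = nrow(R)),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("rank_comparison: %d methods over %d traits\naverage ranks:\n",
              x$k, x$n))
  print(round(x$avg_ranks, 2))
  invisible(x)
}

#' Friedman test on a rank comparison
#'
#' Tests the null hypothesis that all methods have equal average rank.
#' The statistic is
#' `chi2 = 12 sum_j (R_j - n(k+1)/2)^2 / (n k (k+1) - C)` where `R_j` are
#' rank sums and `C = sum(t^3 - t)/(k - 1)` over tied groups `t` within
#' each trait (tie correction; `tie_correction = FALSE` gives the
#' uncorrected denominator `n k (k+1)`).  The p-value comes from the
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param rc a `rank_comparison` (or a [result_table()], ranked first).
#' @param tie_correction apply the tied-group correction (default TRUE).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
friedman_rank_test <- function(rc, tie_correction = TRUE) {
  if (!inherits(rc, "rank_comparison")) rc <- rank_table(rc)
  if (rc$n < 2) stop("need at least 2 traits")
  R <- rc$ranks; n <- rc$n; k <- rc$k
  num <- 12 * sum((rc$rank_sums - n * (k + 1) / 2)^2)
  C <- if (tie_correction)
    sum(apply(R, 1, function(u) { tt <- table(u); sum(tt^3 - tt) })) / (k - 1)
  else 0
  den <- n * k * (k + 1) - C
  # every method tied on every trait: no evidence against the null
  if (den <= 0 || num == 0)
    return(list(statistic = 0, df = k - 1, p_value = 1))
  stat <- num / den
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

#' Nemenyi post-hoc pairwise comparison
#'
#' For each pair of methods,
#' `z = |Rbar_i - Rbar_j| / sqrt(k(k+1)/(6n))`; the p-value is the tail
#' of the studentized-range distribution with `k` groups and infinite
#' degrees of freedom evaluated at `z * sqrt(2)`.
#'
#' @param rc a `rank_comparison` (or a [result_table()]); `k >= 3`.
#' @return symmetric matrix of pairwise p-values with unit diagonal.
#' @export
nemenyi_posthoc <- function(rc) {
  if (!inherits(rc, "rank_comparison")) rc <- rank_table(rc)
  if (rc$k < 3) stop("Nemenyi test needs at least 3 methods")
  se <- sqrt(rc$k * (rc$k + 1) / (6 * rc$n))
  d <- abs(outer(rc$avg_ranks, rc$avg_ranks, "-")) / se
  P <- stats::ptukey(d * sqrt(2), rc$k, Inf, lower.tail = FALSE)
  diag(P) <- 1
  dimnames(P) <- list(names(rc$avg_ranks), names(rc$avg_ranks))
  P
}

#' Count per-trait wins for each method
#'
#' A method wins a trait when it is the strict maximum; traits whose
#' maximum is tied are reported separately, with every tied method
#' credited in `tie_counts`.
#'
#' @param T a [result_table()].
#' @return list with `counts` (strict wins per method), `tie_counts`,
#'   `tied_traits`.
#' @export
best_method_counts <- function(T) {
  T <- result_table(unclass(T))
  counts <- stats::setNames(integer(ncol(T)), colnames(T))
  tie_counts <- counts
  tied <- character(0)
  for (i in seq_len(nrow(T))) {
    mx <- max(T[i, ])
    at <- which(T[i, ] == mx)
    if (length(at) == 1) counts[at] <- counts[at] + 1L
    else {
      tie_counts[at] <- tie_counts[at] + 1L
      tied <- c(tied, rownames(T)[i])
    }
  }
  list(counts = counts, tie_counts = tie_counts, tied_traits = tied)
}

#' Advantage margins of a reference method over a challenger set
#'
#' Identifies the traits where the reference method beats every
#' challenger, and reports the margins (reference minus best challenger)
#' in percentage points; symmetric figures for the challengers'
#' advantage over the reference are also returned.
#'
#' @param T a [result_table()].
#' @param reference reference method name.
#' @param challengers character vector of challenger method names.
#' @return list with `winning_traits`, `mean_margin`, `max_margin` (in
#'   percentage points, for the reference), and `challenger_mean_margin`,
#'   `challenger_max_margin` (advantage of the best challenger on the
#'   traits where it wins).
#' @export
advantage_margins <- function(T, reference, challengers) {
  T <- result_table(unclass(T))
  stopifnot(reference %in% colnames(T), all(challengers %in% colnames(T)))
  best_ch <- apply(T[, challengers, drop = FALSE], 1, max)
  ref <- T[, reference]
  win <- ref > best_ch
  margins <- (ref - best_ch) * 100
  list(winning_traits = rownames(T)[win],
       mean_margin = if (any(win)) mean(margins[win]) else NA_real_,
       max_margin = if (any(win)) max(margins[win]) else NA_real_,
       challenger_mean_margin = if (any(!win)) mean(-margins[!win])
                                else NA_real_,
       challenger_max_margin = if (any(!win)) max(-margins[!win])
                               else NA_real_)
}
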