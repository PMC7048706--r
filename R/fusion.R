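# A marker at position x belongs to interval [start, end) iff
# start <= x < end (0-based half-open convention).
markers_in <- function(pos, start, end) which(pos >= start & pos < end)

# Majority vote over member marker columns; an exact split resolves to 0
# (configurable-by-argument tie value).
majority_vote <- function(values, members, tie_value = 0) {
  m <- rowMeans(values[, members, drop = FALSE])
  out <- ifelse(m > 0.5, 1, ifelse(m < 0.5, 0, tie_value))
  as.numeric(out)
}

fused_genotype <- function(cols, members, chrom, midpos, G) {
  values <- do.call(cbind, cols)
  mt <- data.frame(marker = names(cols), chrom = chrom, pos = midpos,
                   stringsAsFactors = FALSE)
  ord <- order(match(mt$chrom, unique(G$map$chrom)), mt$pos)
  values <- values[, ord, drop = FALSE]
  mt <- mt[ord, , drop = FALSE]
  rownames(values) <- rownames(G$values)
  list(G = genotype_matrix(values, coding = "haploid01", map = mt),
       scheme = members[ord])
}

#' Gene + intergenic marker fusion
#'
#' Builds one fused binary attribute per gene containing at least one
#' marker (value 1 for a sample iff the majority of the gene's markers
#' are 1, ties resolving to `tie_value`), and one per contiguous run of
#' markers lying in no gene (intergenic runs, including chromosome ends).
#' Partially and fully overlapping genes are treated as separate
#' attributes: a marker inside two genes contributes to both.  Every
#' marker belongs to at least one fused attribute.
#'
#' @param G a [genotype_matrix()] with haploid 0/1 coding and a map.
#' @param annotation a [gene_annotation()] on the same coordinate system.
#' @param tie_value value taken on an exact majority split (default 0).
#' @return list with `G` (the fused [genotype_matrix()]; fused attribute
#'   positions are interval midpoints) and `scheme` (named list mapping
#'   fused attribute id to constituent marker ids).
#' @export
fuse_gene_intergenic <- function(G, annotation, tie_value = 0) {
  stopifnot(G$coding == "haploid01", !is.null(G$map))
  cols <- list(); members <- list(); chrom <- character(0); mid <- numeric(0)
  for (cc in unique(G$map$chrom)) {
    midx <- which(G$map$chrom == cc)
    pos <- G$map$pos[midx]
    genes <- annotation[annotation$chrom == cc, , drop = FALSE]
    in_gene <- rep(FALSE, length(midx))
    for (gi in seq_len(nrow(genes))) {
      mm <- markers_in(pos, genes$start[gi], genes$end[gi])
      if (length(mm) == 0) next           # gene without markers: no attribute
      id <- paste0("gene_", genes$gene[gi])
      cols[[id]] <- majority_vote(G$values, midx[mm], tie_value)
      members[[id]] <- marker_ids(G)[midx[mm]]
      chrom <- c(chrom, cc)
      mid <- c(mid, (genes$start[gi] + genes$end[gi]) / 2)
      in_gene[mm] <- TRUE
    }
    # intergenic runs: maximal stretches of consecutive non-gene markers
    if (any(!in_gene)) {
      free <- which(!in_gene)
      runs <- cumsum(c(1L, diff(free) != 1L))
      for (rr in unique(runs)) {
        mm <- free[runs == rr]
        id <- sprintf("inter_%s_%02d", cc, rr)
        cols[[id]] <- majority_vote(G$values, midx[mm], tie_value)
        members[[id]] <- marker_ids(G)[midx[mm]]
        chrom <- c(chrom, cc)
        mid <- c(mid, mean(range(pos[mm])))
      }
    }
  }
  fused_genotype(cols, members, chrom, mid, G)
}

#' Gene + flanking-region marker fusion
#'
#' Divides each chromosome into regions, one per gene, spanning the gene
#' plus half of the gap separating it from each neighbouring gene (the
#' first and last regions extend to the chromosome ends).  Genes
#' contained entirely within another gene are ignored; partially
#' overlapping genes are treated separately (their regions may overlap,
#' and a marker then contributes to each).  Markers falling in a region
#' are fused by the dominant (majority) value.
#'
#' @inheritParams fuse_gene_intergenic
#' @return as [fuse_gene_intergenic()]; markers falling in no region
#'   (possible only on gene-less chromosomes) are dropped.
#' @export
fuse_gene_flanks <- function(G, annotation, tie_value = 0) {
  stopifnot(G$coding == "haploid01", !is.null(G$map))
  cols <- list(); members <- list(); chrom <- character(0); mid <- numeric(0)
  for (cc in unique(G$map$chrom)) {
    midx <- which(G$map$chrom == cc)
    pos <- G$map$pos[midx]
    genes <- annotation[annotation$chrom == cc, , drop = FALSE]
    if (nrow(genes) == 0) next
    # drop genes fully nested inside another gene
    nested <- vapply(seq_len(nrow(genes)), function(i) {
      any(genes$start <= genes$start[i] & genes$end >= genes$end[i] &
            seq_len(nrow(genes)) != i &
            !(genes$start == genes$start[i] & genes$end == genes$end[i]))
    }, logical(1))
    genes <- genes[!nested, , drop = FALSE]
    genes <- genes[order(genes$start), , drop = FALSE]
    k <- nrow(genes)
    lo <- c(-Inf, (genes$end[-k] + genes$start[-1]) / 2)
    hi <- c((genes$end[-k] + genes$start[-1]) / 2, Inf)
    for (gi in seq_len(k)) {
      mm <- markers_in(pos, lo[gi], hi[gi])
      if (length(mm) == 0) next
      id <- paste0("region_", genes$gene[gi])
      cols[[id]] <- majority_vote(G$values, midx[mm], tie_value)
      members[[id]] <- marker_ids(G)[midx[mm]]
      chrom <- c(chrom, cc)
      mid <- c(mid, (genes$start[gi] + genes$end[gi]) / 2)
    }
  }
  fused_genotype(cols, members, chrom, mid, G)
}
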