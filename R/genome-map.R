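#' Construct a genetic map
#'
#' A genome map describes chromosomes by genetic length (Morgans) and the
#' genetic positions of the markers on them.  Positions are strictly
#' increasing within a chromosome; by default markers are evenly spaced.
#'
#' Defaults emulate a budding-yeast-like genome at desk scale: 16
#' chromosomes of 3 Morgans each.  Real map lengths are not calibrated to
#' any particular cross; they are free parameters of the simulator.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chr_length genetic length in Morgans; recycled across chromosomes.
#' @param markers_per_chr marker count per chromosome; recycled.
#' @param positions optional list (one numeric vector per chromosome) of
#'   marker positions in Morgans, overriding even spacing.
#' @return an object of class `genome_map`: a list with `chrom` (data frame
#'   of name, length, n_markers) and `positions` (list of numeric vectors).
#' @export
genome_map <- function(n_chromosomes = 16, chr_length = 3,
                       markers_per_chr = 45, positions = NULL) {
  chr_length <- rep_len(chr_length, n_chromosomes)
  markers_per_chr <- rep_len(as.integer(markers_per_chr), n_chromosomes)
  name <- sprintf("chr%02d", seq_len(n_chromosomes))
  if (is.null(positions)) {
    positions <- lapply(seq_len(n_chromosomes), function(c) {
      m <- markers_per_chr[c]
      chr_length[c] * (seq_len(m) - 0.5) / m
    })
  } else {
    markers_per_chr <- vapply(positions, length, integer(1))
  }
  names(positions) <- name
  map <- structure(
    list(chrom = data.frame(name = name, length = chr_length,
                            n_markers = markers_per_chr,
                            stringsAsFactors = FALSE),
         positions = positions),
    class = "genome_map")
  validate_genome_map(map)
  map
}

#' Validate a genome map
#'
#' Checks the structural invariants: positive lengths (zero length is
#' allowed and means no recombination is possible), strictly increasing
#' marker positions within each chromosome, positions inside `[0, length]`.
#'
#' @param map a `genome_map`.
#' @return the map, invisibly; stops with a map-validation error otherwise.
#' @export
validate_genome_map <- function(map) {
  if (!inherits(map, "genome_map"))
    stop("map validation: not a 'genome_map' object")
  ch <- map$chrom
  if (any(ch$length < 0)) stop("map validation: negative chromosome length")
  if (any(ch$n_markers < 1)) stop("map validation: chromosome without markers")
  for (c in seq_len(nrow(ch))) {
    p <- map$positions[[c]]
    if (length(p) != ch$n_markers[c])
      stop("map validation: marker count mismatch on ", ch$name[c])
    if (length(p) > 1 && any(diff(p) <= 0) && ch$length[c] > 0)
      stop("map validation: positions not strictly increasing on ", ch$name[c])
    if (any(p < 0 | p > ch$length[c]))
      stop("map validation: position outside chromosome on ", ch$name[c])
  }
  invisible(map)
}

#' Total marker count of a map
#' @param map a `genome_map`.
#' @return integer marker count summed over chromosomes.
#' @export
n_markers <- function(map) sum(map$chrom$n_markers)

# Flat (chromosome, position) table for all markers, with generated ids.
map_table <- function(map) {
  ch <- map$chrom
  data.frame(
    marker = unlist(lapply(seq_len(nrow(ch)), function(c)
      sprintf("%s_m%03d", ch$name[c], seq_len(ch$n_markers[c])))),
    chrom = rep(ch$name, ch$n_markers),
    pos = unlist(map$positions, use.names = FALSE),
    stringsAsFactors = FALSE)
}
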