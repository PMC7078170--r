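#' Define a genome map for simulation
#'
#' A genome map lists the chromosomes of the simulated genome with their
#' physical (bp) and genetic (cM) lengths. Genetic positions are converted to
#' physical positions by linear interpolation, i.e. a uniform recombination
#' density along each chromosome.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length_bp Numeric vector of physical lengths in base pairs (> 0).
#' @param length_cM Optional numeric vector of genetic lengths in centimorgan.
#'   When `NULL`, genetic lengths are derived as `length_bp / 1e6 * cm_per_mb`.
#' @param cm_per_mb Uniform recombination density (cM per Mb) used when
#'   `length_cM` is not supplied.
#'
#' @return A `data.frame` of class `genome_map` with columns `chrom`,
#'   `length_bp`, `length_cM`.
#' @examples
#' genome_map(c("chrA", "chrB"), c(10e6, 20e6), cm_per_mb = 3)
#' @export
genome_map <- function(chrom, length_bp, length_cM = NULL, cm_per_mb = 2.5) {
  chrom <- as.character(chrom)
  if (length(chrom) == 0L) stop("genome map must contain at least one chromosome")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(length_bp) != length(chrom)) {
    stop("`length_bp` must have one entry per chromosome")
  }
  if (any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop("physical chromosome lengths must be positive")
  }
  if (is.null(length_cM)) {
    if (!is.finite(cm_per_mb) || cm_per_mb < 0) stop("`cm_per_mb` must be >= 0")
    length_cM <- length_bp / 1e6 * cm_per_mb
  }
  if (length(length_cM) != length(chrom) || any(length_cM < 0)) {
    stop("genetic lengths must be >= 0, one per chromosome")
  }
  structure(
    data.frame(chrom = chrom, length_bp = as.numeric(length_bp),
               length_cM = as.numeric(length_cM), stringsAsFactors = FALSE),
    class = c("genome_map", "data.frame")
  )
}

#' Watermelon-like default genome
#'
#' Eleven chromosomes with physical lengths close to the public watermelon
#' reference assembly (26-35 Mb each, ~330 Mb total) and a uniform genetic
#' density of 2.5 cM/Mb, giving a total map length in the range reported for
#' watermelon linkage maps.
#'
#' @param cm_per_mb Recombination density in cM per Mb.
#' @return A [genome_map()].
#' @export
watermelon_genome <- function(cm_per_mb = 2.5) {
  sizes_mb <- c(34.3, 33.9, 29.5, 26.4, 33.9, 26.6, 31.9, 26.2, 34.8, 25.9, 26.3)
  genome_map(sprintf("Chr%02d", seq_along(sizes_mb)), sizes_mb * 1e6,
             cm_per_mb = cm_per_mb)
}

#' Define the causal locus of the simulated trait
#'
#' @param chrom Chromosome name.
#' @param pos 1-based physical position in bp.
#' @param mode Dominance mode of the yellow-parent allele; only `"dominant"`
#'   is supported (the simulated trait is a dominant monogenic trait).
#' @return An object of class `causal_locus`.
#' @export
causal_locus <- function(chrom, pos, mode = "dominant") {
  mode <- match.arg(mode, "dominant")
  if (!is.finite(pos) || pos < 1) stop("locus position must be >= 1")
  structure(list(chrom = as.character(chrom), pos = as.numeric(pos), mode = mode),
            class = "causal_locus")
}

# row of the map for one chromosome; error when absent
.map_row <- function(map, chrom) {
  i <- match(chrom, map$chrom)
  if (is.na(i)) stop("chromosome '", chrom, "' is not in the genome map")
  map[i, , drop = FALSE]
}

.check_locus <- function(map, locus) {
  row <- .map_row(map, locus$chrom)
  if (locus$pos > row$length_bp) {
    stop("causal locus at ", locus$chrom, ":", locus$pos,
         " lies outside the chromosome (length ", row$length_bp, " bp)")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
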