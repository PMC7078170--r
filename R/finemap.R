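#' Genotype a simulated F2 population at marker positions
#'
#' Reads marker genotypes (dosage of the yellow-parent allele, 0/1/2)
#' directly off the simulated haplotype mosaics, standing in for SSR/indel
#' genotyping of a mapping population.
#'
#' @param pop An [simulate_f2()] population.
#' @param markers `data.frame(name, chrom, pos)` of markers; positions must
#'   lie on chromosomes of the population's map.
#' @param missing_rate Probability that a genotype call is missing.
#' @param seed Optional integer seed (used only for missing-data masking).
#' @return An object of class `marker_matrix`: list with `markers` (sorted by
#'   chromosome and position), `geno` (individuals x markers integer matrix,
#'   `NA` = missing) and `phenotype`.
#' @export
simulate_marker_genotypes <- function(pop, markers, missing_rate = 0,
                                      seed = NULL) {
  if (!inherits(pop, "f2_pop")) stop("`pop` must be an f2_pop")
  need <- c("name", "chrom", "pos")
  if (!all(need %in% names(markers))) {
    stop("`markers` needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(markers$name)) stop("marker names must be unique")
  for (k in seq_len(nrow(markers))) {
    row <- .map_row(pop$map, markers$chrom[k])
    if (markers$pos[k] < 1 || markers$pos[k] > row$length_bp) {
      stop("marker ", markers$name[k], " at ", markers$chrom[k], ":",
           markers$pos[k], " lies outside its chromosome")
    }
  }
  markers <- markers[order(match(markers$chrom, pop$map$chrom), markers$pos), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  if (!is.null(seed)) set.seed(seed)
  geno <- matrix(NA_integer_, nrow = pop$n, ncol = nrow(markers),
                 dimnames = list(NULL, markers$name))
  for (ch in unique(markers$chrom)) {
    sel <- markers$chrom == ch
    geno[, sel] <- pop_dosage(pop, ch, markers$pos[sel])
  }
  if (missing_rate > 0) {
    geno[stats::runif(length(geno)) < missing_rate] <- NA_integer_
  }
  structure(list(markers = markers, geno = geno, phenotype = pop$phenotype),
            class = "marker_matrix")
}

#' Build a marker matrix from explicit genotype data
#'
#' @param markers `data.frame(name, chrom, pos)`.
#' @param geno Integer matrix (individuals x markers) of yellow-parent allele
#'   dosages in 0/1/2 or `NA`; column names must match marker names.
#' @param phenotype Character vector `"yellow"`/`"green"` per individual.
#' @return A `marker_matrix`.
#' @export
marker_matrix <- function(markers, geno, phenotype) {
  geno <- as.matrix(geno)
  if (ncol(geno) != nrow(markers)) stop("one genotype column per marker required")
  if (nrow(geno) != length(phenotype)) stop("one phenotype per individual required")
  if (!all(geno %in% c(0L, 1L, 2L, NA))) stop("dosages must be 0, 1, 2 or NA")
  if (!all(phenotype %in% c("yellow", "green"))) {
    stop("phenotype must be 'yellow' or 'green'")
  }
  o <- order(markers$chrom, markers$pos)
  markers <- markers[o, , drop = FALSE]
  rownames(markers) <- NULL
  geno <- geno[, o, drop = FALSE]
  colnames(geno) <- markers$name
  structure(list(markers = markers, geno = geno, phenotype = phenotype),
            class = "marker_matrix")
}

#' Count recombinant individuals at a marker
#'
#' For a dominant yellow allele, an individual is a recombinant at a marker
#' when its marker genotype is incompatible with complete marker-locus
#' linkage: a green (recessive, hence homozygous green at the locus) plant
#' carrying any yellow-parent allele at the marker, or a yellow plant
#' homozygous green at the marker. Each rule can be switched off. Missing
#' genotypes are excluded from the informative count.
#'
#' @param mm A `marker_matrix`.
#' @param marker Marker name.
#' @param green_rule Count green plants with dosage >= 1 as recombinants.
#' @param yellow_rule Count yellow plants with dosage 0 as recombinants.
#' @return Named integer vector `c(n_recombinant, n_informative)`.
#' @export
count_recombinants <- function(mm, marker, green_rule = TRUE,
                               yellow_rule = TRUE) {
  j <- match(marker, mm$markers$name)
  if (is.na(j)) stop("unknown marker '", marker, "'")
  g <- mm$geno[, j]
  ok <- !is.na(g)
  green <- mm$phenotype == "green"
  rec <- (green_rule & green & g >= 1L) | (yellow_rule & !green & g == 0L)
  c(n_recombinant = sum(rec & ok), n_informative = sum(ok))
}

#' Recessive-class estimate of the marker-locus recombination fraction
#'
#' Green (recessive) plants are homozygous for the green-parent allele at the
#' causal locus, so every yellow-parent allele they carry at a marker arose
#' from a recombination event: `r_hat = (yellow alleles among green plants) /
#' (2 * green plants genotyped)`.
#'
#' @param mm A `marker_matrix`.
#' @param marker Marker name.
#' @return The estimate in `[0, 1]`; values above 0.5 trigger a warning and
#'   carry attribute `flagged = TRUE` (likely marker mis-orientation).
#' @export
recessive_class_r <- function(mm, marker) {
  j <- match(marker, mm$markers$name)
  if (is.na(j)) stop("unknown marker '", marker, "'")
  g <- mm$geno[, j]
  use <- mm$phenotype == "green" & !is.na(g)
  if (!any(use)) stop("zero informative green plants at marker '", marker, "'")
  r <- sum(g[use]) / (2 * sum(use))
  if (r > 0.5) {
    warning("recombination estimate ", signif(r, 3), " > 0.5 at '", marker,
            "': likely allele mis-orientation")
    attr(r, "flagged") <- TRUE
  }
  r
}

#' Refine the locus interval by recombinant exclusion
#'
#' Markers carrying at least one recombinant cannot cosegregate with the
#' locus and exclude the genome beyond them; markers with zero recombinants
#' lie inside the interval. The interval is bounded on each side by the
#' nearest recombinant marker outside the cosegregating block, or by the
#' chromosome terminus when no recombinant marker exists on that side
#' (a locus near a chromosome end is mapped "to the terminal").
#'
#' @param mm A `marker_matrix`.
#' @param chrom Chromosome to refine on.
#' @param chrom_length Chromosome length in bp (right terminus).
#' @param max_recombinants Markers with at most this many recombinants are
#'   treated as cosegregating (default 0: exact exclusion; raise for
#'   tolerance to genotyping error).
#' @param green_rule,yellow_rule Passed to [count_recombinants()].
#' @return List of class `map_interval`: `chrom`, `start`, `end`, `length`,
#'   `left_marker`, `right_marker` (marker name or `"chromosome start"` /
#'   `"chromosome end"`), and `markers`, the per-marker recombinant table.
#' @export
refine_interval <- function(mm, chrom, chrom_length,
                            max_recombinants = 0,
                            green_rule = TRUE, yellow_rule = TRUE) {
  sel <- which(mm$markers$chrom == chrom)
  if (length(sel) < 1L) stop("no markers on chromosome '", chrom, "'")
  mk <- mm$markers[sel, , drop = FALSE]
  rec <- vapply(mk$name, function(m) {
    count_recombinants(mm, m, green_rule, yellow_rule)[["n_recombinant"]]
  }, integer(1))
  tab <- data.frame(name = mk$name, pos = mk$pos, n_recombinant = rec,
                    stringsAsFactors = FALSE)
  coseg <- rec <= max_recombinants
  if (!any(coseg)) {
    stop("no cosegregating interval on ", chrom, "; recombinants per marker: ",
         paste(sprintf("%s=%d", tab$name, tab$n_recombinant), collapse = ", "))
  }
  lo <- min(which(coseg))
  hi <- max(which(coseg))
  if (any(!coseg[lo:hi])) {
    warning("recombinant marker(s) inside the cosegregating span on ", chrom,
            "; possible genotyping inconsistency")
  }
  left <- which(!coseg & seq_along(coseg) < lo)
  right <- which(!coseg & seq_along(coseg) > hi)
  start <- if (length(left)) mk$pos[max(left)] else 0
  left_marker <- if (length(left)) mk$name[max(left)] else "chromosome start"
  end <- if (length(right)) mk$pos[min(right)] else chrom_length
  right_marker <- if (length(right)) mk$name[min(right)] else "chromosome end"
  structure(list(chrom = chrom, start = start, end = end,
                 length = end - start, left_marker = left_marker,
                 right_marker = right_marker, markers = tab),
            class = "map_interval")
}

#' @export
print.map_interval <- function(x, ...) {
  cat("Refined locus interval on", x$chrom, "\n")
  cat(sprintf("  [%s, %s] bp  (%.2f kb)\n",
              format(x$start, big.mark = ",", scientific = FALSE),
              format(x$end, big.mark = ",", scientific = FALSE),
              x$length / 1000))
  cat("  bounded by:", x$left_marker, "|", x$right_marker, "\n")
  cat("  per-marker recombinants:\n")
  print(x$markers, row.names = FALSE)
  invisible(x)
}
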