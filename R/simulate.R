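#' Haldane map function
#'
#' Converts a genetic distance to a recombination fraction assuming crossovers
#' occur as a Poisson process with no interference:
#' `r = (1 - exp(-2 d / 100)) / 2` for `d` in centimorgan.
#'
#' @param d Genetic distance in cM (>= 0); vectorized.
#' @return Recombination fraction in `[0, 0.5)`.
#' @examples
#' haldane_r(10) # 0.0906...
#' @export
haldane_r <- function(d) {
  if (any(!is.finite(d)) || any(d < 0)) stop("genetic distance must be >= 0")
  (1 - exp(-2 * d / 100)) / 2
}

#' Simulate a panel of parent-differential biallelic SNPs
#'
#' Draws SNP sites uniformly along each chromosome at the requested density.
#' Every site is biallelic with distinct alleles assigned to the yellow parent
#' (`allele_Y`) and the green parent (`allele_G`); the nucleotide letters are
#' cosmetic, the analysis tracks parent of origin.
#'
#' @param map A [genome_map()].
#' @param density Expected number of sites per Mb (> 0). The realized count
#'   per chromosome is Poisson with mean `density * length_Mb`.
#' @param seed Optional integer seed for reproducibility.
#' @param ensure_positions Optional `data.frame(chrom, pos)` of positions that
#'   must be present in the panel (e.g. the causal locus).
#' @return A `data.frame` of class `snp_panel` with columns `chrom`, `pos`
#'   (1-based, sorted, unique per chromosome), `allele_Y`, `allele_G`.
#' @export
simulate_parent_snps <- function(map, density, seed = NULL,
                                 ensure_positions = NULL) {
  if (!inherits(map, "genome_map")) stop("`map` must be a genome_map")
  if (!is.finite(density) || density <= 0) stop("`density` must be > 0")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  out <- vector("list", nrow(map))
  for (i in seq_len(nrow(map))) {
    n <- stats::rpois(1, density * map$length_bp[i] / 1e6)
    pos <- sort(unique(round(stats::runif(n, 1, map$length_bp[i]))))
    if (!is.null(ensure_positions)) {
      extra <- ensure_positions$pos[ensure_positions$chrom == map$chrom[i]]
      pos <- sort(unique(c(pos, extra)))
    }
    n <- length(pos)
    a1 <- sample(bases, n, replace = TRUE)
    # second allele: shift 1-3 places around the base alphabet, never equal
    shift <- sample.int(3, n, replace = TRUE)
    a2 <- bases[((match(a1, bases) - 1L + shift) %% 4L) + 1L]
    out[[i]] <- data.frame(chrom = rep(map$chrom[i], n), pos = pos,
                           allele_Y = a1, allele_G = a2,
                           stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

# Draw n gametes for every chromosome of the map.
# A gamete on one chromosome is a mosaic of the two parental haplotypes,
# stored as the parental phase at the chromosome start (1 = yellow parent)
# plus strictly increasing crossover breakpoints in bp. Crossover counts are
# Poisson(length_cM / 100) -- Haldane, no interference -- with breakpoints
# uniform in genetic coordinates and mapped to bp linearly.
.sim_gametes <- function(map, n) {
  out <- vector("list", nrow(map))
  names(out) <- map$chrom
  for (i in seq_len(nrow(map))) {
    l_cm <- map$length_cM[i]
    l_bp <- map$length_bp[i]
    k <- if (l_cm > 0) stats::rpois(n, l_cm / 100) else integer(n)
    start <- stats::rbinom(n, 1L, 0.5)
    bp <- vector("list", n)
    if (sum(k) > 0) {
      cm <- stats::runif(sum(k), 0, l_cm)
      bp <- lapply(
        split(cm / l_cm * l_bp, factor(rep.int(seq_len(n), k), levels = seq_len(n))),
        sort
      )
      names(bp) <- NULL
    }
    out[[i]] <- list(start = start, bp = bp)
  }
  out
}

#' Simulate a single gamete
#'
#' Produces one recombinant haplotype mosaic per chromosome: a Poisson number
#' of crossovers (mean `length_cM / 100`), breakpoints uniform in genetic
#' coordinates (linear cM-bp interpolation), and a fair-coin starting parental
#' phase (1 = yellow parent, 0 = green parent).
#'
#' @param map A [genome_map()].
#' @param seed Optional integer seed.
#' @return A list per chromosome with elements `start` (0/1 phase at the
#'   chromosome start) and `breakpoints` (sorted crossover positions in bp).
#' @export
simulate_gamete <- function(map, seed = NULL) {
  if (!inherits(map, "genome_map")) stop("`map` must be a genome_map")
  if (!is.null(seed)) set.seed(seed)
  g <- .sim_gametes(map, 1L)
  lapply(g, function(ch) list(start = ch$start[1L],
                              breakpoints = ch$bp[[1L]] %||% numeric(0)))
}

#' Simulate an F2 population segregating for a dominant locus
#'
#' Each individual is formed from two independent gametes (see
#' [simulate_gamete()] for the meiosis model). The phenotype is determined by
#' the genotype at the causal locus: individuals carrying at least one
#' yellow-parent allele are `"yellow"` (dominant class), homozygous
#' green-parent individuals are `"green"` (recessive class), so the expected
#' segregation is 3:1.
#'
#' @param map A [genome_map()].
#' @param locus A [causal_locus()] inside the map.
#' @param n Population size (> 0).
#' @param seed Optional integer seed.
#' @param pheno_error Probability that a plant's phenotype is recorded in the
#'   wrong class (default 0: visual scoring is treated as error-free).
#' @return An object of class `f2_pop`: a list with the map, locus, `n`, the
#'   per-chromosome gamete store, `dosage_locus` (0/1/2 copies of the
#'   yellow-parent allele at the causal locus) and `phenotype`
#'   (`"yellow"`/`"green"`).
#' @export
simulate_f2 <- function(map, locus, n, seed = NULL, pheno_error = 0) {
  if (!inherits(map, "genome_map")) stop("`map` must be a genome_map")
  if (!inherits(locus, "causal_locus")) stop("`locus` must be a causal_locus")
  if (!is.finite(n) || n < 1) stop("population size `n` must be >= 1")
  .check_locus(map, locus)
  if (pheno_error < 0 || pheno_error >= 1) stop("`pheno_error` must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  pop <- structure(
    list(map = map, locus = locus, n = n, gametes = .sim_gametes(map, 2L * n)),
    class = "f2_pop"
  )
  dos <- as.integer(pop_dosage(pop, locus$chrom, locus$pos))
  phen <- ifelse(dos >= 1L, "yellow", "green")
  if (pheno_error > 0) {
    flip <- stats::runif(n) < pheno_error
    phen[flip] <- ifelse(phen[flip] == "yellow", "green", "yellow")
  }
  pop$dosage_locus <- dos
  pop$phenotype <- phen
  pop
}

#' @export
print.f2_pop <- function(x, ...) {
  cat("F2 population:", x$n, "plants,", nrow(x$map), "chromosomes\n")
  cat("  causal locus:", x$locus$chrom, "at",
      format(x$locus$pos, big.mark = ",", scientific = FALSE),
      "bp (yellow allele dominant)\n")
  tab <- table(factor(x$phenotype, levels = c("yellow", "green")))
  cat("  phenotypes:", tab[["yellow"]], "yellow :", tab[["green"]], "green\n")
  invisible(x)
}

#' Genotype dosages of simulated individuals at arbitrary positions
#'
#' Reads the number of yellow-parent-origin chromosomes (0, 1 or 2) carried by
#' each individual at each queried position directly off the stored haplotype
#' mosaics.
#'
#' @param pop An [simulate_f2()] population.
#' @param chrom Chromosome name.
#' @param positions Numeric vector of bp positions on `chrom`.
#' @param ids Individual indices (default: all).
#' @return Integer matrix, individuals x positions.
#' @export
pop_dosage <- function(pop, chrom, positions, ids = seq_len(pop$n)) {
  ch <- pop$gametes[[chrom]]
  if (is.null(ch)) stop("chromosome '", chrom, "' is not in the population")
  if (any(ids < 1L | ids > pop$n)) stop("individual ids outside the population")
  gid <- as.vector(rbind(2L * ids - 1L, 2L * ids))
  npos <- length(positions)
  ph <- vapply(gid, function(g) {
    b <- ch$bp[[g]]
    if (is.null(b)) rep.int(ch$start[g], npos)
    else (ch$start[g] + findInterval(positions, b)) %% 2L
  }, integer(npos))
  ph <- matrix(ph, nrow = npos)
  d <- ph[, seq(1L, ncol(ph), by = 2L), drop = FALSE] +
       ph[, seq(2L, ncol(ph), by = 2L), drop = FALSE]
  t(d)
}

#' Select phenotype-extreme bulks from an F2 population
#'
#' Samples `n_per_bulk` plants uniformly without replacement within each
#' phenotype class, mirroring the random selection of pool members from a
#' segregating population.
#'
#' @param pop An [simulate_f2()] population.
#' @param n_per_bulk Plants per bulk (default 30).
#' @param seed Optional integer seed.
#' @param ignore_phenotype If `TRUE`, both "bulks" are drawn from the whole
#'   population regardless of phenotype. This breaks the phenotype-genotype
#'   link and is the null configuration used for threshold calibration.
#' @return An object of class `bulks`: list with integer id vectors `yellow`
#'   and `green` and the bulk size.
#' @export
make_bulks <- function(pop, n_per_bulk = 30, seed = NULL,
                       ignore_phenotype = FALSE) {
  if (!inherits(pop, "f2_pop")) stop("`pop` must be an f2_pop")
  n_per_bulk <- as.integer(n_per_bulk)
  if (n_per_bulk < 1L) stop("`n_per_bulk` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  if (ignore_phenotype) {
    if (2L * n_per_bulk > pop$n) stop("population too small for two bulks of ", n_per_bulk)
    ids <- sample.int(pop$n, 2L * n_per_bulk)
    return(structure(list(yellow = sort(ids[seq_len(n_per_bulk)]),
                          green = sort(ids[n_per_bulk + seq_len(n_per_bulk)]),
                          n_per_bulk = n_per_bulk, phenotype_selected = FALSE),
                     class = "bulks"))
  }
  yid <- which(pop$phenotype == "yellow")
  gid <- which(pop$phenotype == "green")
  if (length(yid) < n_per_bulk) {
    stop("insufficient dominant (yellow) plants: have ", length(yid),
         ", need ", n_per_bulk)
  }
  if (length(gid) < n_per_bulk) {
    stop("insufficient recessive (green) plants: have ", length(gid),
         ", need ", n_per_bulk)
  }
  structure(list(yellow = sort(yid[sample.int(length(yid), n_per_bulk)]),
                 green = sort(gid[sample.int(length(gid), n_per_bulk)]),
                 n_per_bulk = n_per_bulk, phenotype_selected = TRUE),
            class = "bulks")
}

#' Simulate pooled sequencing read counts for one bulk
#'
#' Per site, the bulk's true yellow-allele frequency is the mean allele dosage
#' of its members. Sequencing depth is Poisson(`mean_depth`); reads supporting
#' the yellow-parent allele are Binomial(depth, `f(1-e) + (1-f)e`) where `e`
#' is the per-read error rate (an error flips the observed allele); the
#' remaining reads support the green-parent allele.
#'
#' @param bulk Integer ids of the bulk members (e.g. `bulks$yellow`).
#' @param pop The [simulate_f2()] population the ids refer to.
#' @param panel A [simulate_parent_snps()] panel.
#' @param mean_depth Mean pooled sequencing depth per site (> 0; default 29).
#' @param error_rate Per-read allele error probability in `[0, 0.5)`.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `chrom`, `pos`, `reads_Y`, `reads_G`.
#' @export
simulate_bulk_readcounts <- function(bulk, pop, panel, mean_depth = 29,
                                     error_rate = 0.01, seed = NULL) {
  if (!inherits(pop, "f2_pop")) stop("`pop` must be an f2_pop")
  if (!is.finite(mean_depth) || mean_depth <= 0) stop("`mean_depth` must be > 0")
  if (error_rate < 0 || error_rate >= 0.5) stop("`error_rate` must be in [0, 0.5)")
  ids <- as.integer(bulk)
  if (any(ids < 1L | ids > pop$n)) {
    stop("bulk references individuals absent from the population")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- numeric(nrow(panel))
  for (ch in unique(panel$chrom)) {
    sel <- panel$chrom == ch
    d <- pop_dosage(pop, ch, panel$pos[sel], ids)
    f[sel] <- colSums(d) / (2 * length(ids))
  }
  depth <- stats::rpois(nrow(panel), mean_depth)
  p_obs <- f * (1 - error_rate) + (1 - f) * error_rate
  yr <- stats::rbinom(nrow(panel), depth, p_obs)
  data.frame(chrom = panel$chrom, pos = panel$pos,
             reads_Y = yr, reads_G = depth - yr, stringsAsFactors = FALSE)
}

#' Pooled allele-count table for both bulks
#'
#' Convenience wrapper running [simulate_bulk_readcounts()] for the yellow and
#' green bulk and assembling the standard count table consumed by
#' [filter_sites()] and [snp_index()].
#'
#' @inheritParams simulate_bulk_readcounts
#' @param bulks A [make_bulks()] object.
#' @return `data.frame` of class `bulk_counts` with columns `chrom`, `pos`,
#'   `allele_Y`, `allele_G`, `ypool_Y_reads`, `ypool_G_reads`,
#'   `gpool_Y_reads`, `gpool_G_reads`.
#' @export
bulk_allele_counts <- function(pop, bulks, panel, mean_depth = 29,
                               error_rate = 0.01, seed = NULL) {
  if (!inherits(bulks, "bulks")) stop("`bulks` must come from make_bulks()")
  if (!is.null(seed)) set.seed(seed)
  y <- simulate_bulk_readcounts(bulks$yellow, pop, panel, mean_depth, error_rate)
  g <- simulate_bulk_readcounts(bulks$green, pop, panel, mean_depth, error_rate)
  out <- data.frame(chrom = panel$chrom, pos = panel$pos,
                    allele_Y = panel$allele_Y, allele_G = panel$allele_G,
                    ypool_Y_reads = y$reads_Y, ypool_G_reads = y$reads_G,
                    gpool_Y_reads = g$reads_Y, gpool_G_reads = g$reads_G,
                    stringsAsFactors = FALSE)
  class(out) <- c("bulk_counts", "data.frame")
  out
}
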