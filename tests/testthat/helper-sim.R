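# shared fixtures: everything is generated in code at test time

study_map <- function() watermelon_genome()
study_locus <- function() causal_locus("Chr04", 5e5)

# one study-scale replicate: genome, panel, F2, bulks, pooled counts
sim_study_counts <- function(seed, n = 1106, n_per_bulk = 30, density = 30,
                             mean_depth = 29, error_rate = 0.01,
                             ignore_phenotype = FALSE) {
  map <- study_map()
  locus <- study_locus()
  set.seed(seed)
  panel <- simulate_parent_snps(map, density,
                                ensure_positions = data.frame(
                                  chrom = locus$chrom, pos = locus$pos))
  pop <- simulate_f2(map, locus, n)
  bulks <- make_bulks(pop, n_per_bulk, ignore_phenotype = ignore_phenotype)
  counts <- bulk_allele_counts(pop, bulks, panel, mean_depth, error_rate)
  list(map = map, locus = locus, panel = panel, pop = pop, bulks = bulks,
       counts = counts)
}

# random pooled count tables for oracle comparisons
rand_count_table <- function(n_sites, mean_depth = 30) {
  d <- matrix(stats::rpois(4 * n_sites, mean_depth / 2), ncol = 4)
  out <- data.frame(chrom = rep("c1", n_sites), pos = seq_len(n_sites) * 1000,
                    allele_Y = "A", allele_G = "T",
                    ypool_Y_reads = d[, 1], ypool_G_reads = d[, 2],
                    gpool_Y_reads = d[, 3], gpool_G_reads = d[, 4],
                    stringsAsFactors = FALSE)
  class(out) <- c("bulk_counts", "data.frame")
  out
}

# parental phase of one stored gamete at given positions (1 = yellow parent)
gamete_phase_at <- function(pop, chrom, g, positions) {
  ch <- pop$gametes[[chrom]]
  b <- ch$bp[[g]]
  if (is.null(b)) rep.int(ch$start[g], length(positions))
  else (ch$start[g] + findInterval(positions, b)) %% 2L
}
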