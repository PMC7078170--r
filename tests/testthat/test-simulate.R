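test_that("haldane map function matches its closed form and limits", {
  expect_identical(haldane_r(0), 0)
  expect_equal(haldane_r(10), (1 - exp(-0.2)) / 2)     # 0.0906346...
  expect_equal(haldane_r(10), 0.0906346234610091, tolerance = 1e-12)
  expect_lt(abs(haldane_r(10000) - 0.5), 1e-12)
  expect_true(all(haldane_r(c(0, 1, 50, 500)) >= 0 &
                    haldane_r(c(0, 1, 50, 500)) < 0.5))
  expect_error(haldane_r(-1), "must be >= 0")
})

test_that("genome map validates its invariants", {
  m <- genome_map(c("a", "b"), c(1e6, 2e6), cm_per_mb = 3)
  expect_equal(m$length_cM, c(3, 6))
  expect_error(genome_map(c("a", "a"), c(1e6, 2e6)), "unique")
  expect_error(genome_map("a", 0), "positive")
  expect_error(genome_map("a", 1e6, length_cM = -1), ">= 0")
  expect_error(causal_locus("a", 0), ">= 1")
})

test_that("SNP panel simulation hits density, sortedness and determinism", {
  map <- genome_map("c1", 10e6)
  p1 <- simulate_parent_snps(map, density = 10, seed = 1)
  expect_gt(nrow(p1), 60)   # Poisson(100)
  expect_lt(nrow(p1), 140)
  expect_true(all(p1$allele_Y != p1$allele_G))
  expect_true(!is.unsorted(p1$pos))
  expect_true(!anyDuplicated(p1$pos))
  expect_identical(p1, simulate_parent_snps(map, density = 10, seed = 1))

  # near-zero density: an empty panel is a valid result
  p0 <- simulate_parent_snps(genome_map("c1", 1e6), density = 1e-4, seed = 1)
  expect_true(nrow(p0) >= 0)
  expect_error(simulate_parent_snps(map, density = 0), "> 0")
})

test_that("gametes carry Poisson crossovers consistent with the map function", {
  flat <- genome_map("c0", 1e6, length_cM = 0)
  g <- replicate(20, length(simulate_gamete(flat)$c0$breakpoints))
  expect_true(all(g == 0))

  map <- genome_map("c1", 10e6, length_cM = 100)
  set.seed(42)
  k <- replicate(2000, length(simulate_gamete(map)$c1$breakpoints))
  expect_lt(abs(mean(k) - 1), 3 / sqrt(2000))  # Poisson mean 1, 3 s.e.

  # recombinant fraction between loci 10 cM apart ~ haldane_r(10)
  pop <- simulate_f2(map, causal_locus("c1", 1), n = 5000, seed = 7)
  pos <- c(1e6, 2e6)  # 10 cM apart at 10 cM/Mb
  ph <- vapply(seq_len(2 * 5000), function(g) gamete_phase_at(pop, "c1", g, pos),
               integer(2))
  rec <- mean(ph[1, ] != ph[2, ])
  r <- haldane_r(10)
  expect_lt(abs(rec - r), 3 * sqrt(r * (1 - r) / 10000))
})

test_that("F2 phenotypes segregate 3:1 and genotypes 1:2:1", {
  map <- study_map()
  locus <- study_locus()
  yellow <- integer(10)
  dos <- integer(0)
  for (s in seq_len(10)) {
    pop <- simulate_f2(map, locus, 1106, seed = 100 + s)
    yellow[s] <- sum(pop$phenotype == "yellow")
    dos <- c(dos, pop$dosage_locus)
    expect_true(all((pop$dosage_locus == 0) == (pop$phenotype == "green")))
  }
  # pooled 3:1 test across seeds should not reject
  n <- 10 * 1106
  expect_gt(chisq_ratio_test(sum(yellow), n - sum(yellow))$p.value, 0.01)
  # 1:2:1 at the causal locus
  expect_gt(stats::chisq.test(table(factor(dos, levels = 0:2)),
                              p = c(1, 2, 1) / 4)$p.value, 0.01)
  # degenerate n = 1 still yields a valid individual
  one <- simulate_f2(map, locus, 1, seed = 1)
  expect_true(one$phenotype %in% c("yellow", "green"))
  expect_error(simulate_f2(map, causal_locus("Chr04", 1e9), 10),
               "outside the chromosome")
  expect_error(simulate_f2(map, causal_locus("nope", 5), 10), "not in the genome map")
})

test_that("bulk selection respects phenotype classes and is seeded", {
  pop <- simulate_f2(study_map(), study_locus(), 300, seed = 5)
  b1 <- make_bulks(pop, 30, seed = 9)
  expect_true(all(pop$phenotype[b1$yellow] == "yellow"))
  expect_true(all(pop$phenotype[b1$green] == "green"))
  expect_length(intersect(b1$yellow, b1$green), 0)
  expect_identical(b1, make_bulks(pop, 30, seed = 9))
  small <- simulate_f2(study_map(), study_locus(), 20, seed = 5)
  expect_error(make_bulks(small, 30), "insufficient")
})

test_that("pooled read counts follow the binomial error model", {
  pop <- simulate_f2(study_map(), study_locus(), 400, seed = 11)
  b <- make_bulks(pop, 30, seed = 11)
  site <- data.frame(chrom = "Chr04", pos = 5e5,
                     allele_Y = "A", allele_G = "T")

  # green bulk is fixed for the green allele at the causal locus:
  # error-free reads are all green, index exactly 0
  g0 <- simulate_bulk_readcounts(b$green, pop, site, mean_depth = 200,
                                 error_rate = 0, seed = 1)
  expect_identical(g0$reads_Y, 0L)
  expect_gt(g0$reads_G, 0)

  # members homozygous yellow at the locus give index exactly 1
  hom <- which(pop$dosage_locus == 2)[1:10]
  y1 <- simulate_bulk_readcounts(hom, pop, site, mean_depth = 200,
                                 error_rate = 0, seed = 2)
  expect_identical(y1$reads_G, 0L)

  # with error e and true frequency 0 the expected observed frequency is e
  set.seed(3)
  ge <- simulate_bulk_readcounts(b$green, pop,
                                 site[rep(1, 400), ], mean_depth = 100,
                                 error_rate = 0.01)
  obs <- sum(ge$reads_Y) / sum(ge$reads_Y + ge$reads_G)
  expect_lt(abs(obs - 0.01), 3 * sqrt(0.01 * 0.99 / 40000))

  # unlinked sites average to frequency ~ 0.5
  far <- data.frame(chrom = "Chr09", pos = seq(1e6, 30e6, by = 1e5),
                    allele_Y = "A", allele_G = "T")
  u <- simulate_bulk_readcounts(b$yellow, pop, far, mean_depth = 50,
                                error_rate = 0, seed = 4)
  expect_lt(abs(sum(u$reads_Y) / sum(u$reads_Y + u$reads_G) - 0.5), 0.03)

  expect_error(simulate_bulk_readcounts(c(1, 9999), pop, site),
               "absent from the population")
  # reproducible bit-for-bit
  expect_identical(
    simulate_bulk_readcounts(b$yellow, pop, far, 30, 0.01, seed = 8),
    simulate_bulk_readcounts(b$yellow, pop, far, 30, 0.01, seed = 8))
})
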