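one_site <- function(yY, yG, gY, gG) {
  x <- data.frame(chrom = "c1", pos = 100, allele_Y = "A", allele_G = "T",
                  ypool_Y_reads = yY, ypool_G_reads = yG,
                  gpool_Y_reads = gY, gpool_G_reads = gG)
  class(x) <- c("bulk_counts", "data.frame")
  x
}

test_that("SNP-index is the yellow-allele read fraction, NA at zero depth", {
  t1 <- snp_index(one_site(20, 10, 5, 15))
  expect_equal(t1$snp_index_Y, 2 / 3, tolerance = 1e-12)
  expect_equal(round(t1$snp_index_Y, 4), 0.6667)
  expect_equal(t1$snp_index_G, 0.25)
  # fixed bulks sit at the boundaries
  expect_equal(snp_index(one_site(30, 0, 0, 30))$snp_index_Y, 1)
  expect_equal(snp_index(one_site(30, 0, 0, 30))$snp_index_G, 0)
  # zero depth in one bulk: missing value, not a division error
  t0 <- snp_index(one_site(10, 10, 0, 0))
  expect_true(is.na(t0$snp_index_G) && !is.na(t0$snp_index_Y))
  expect_warning(snp_index(one_site(0, 0, 0, 0)), "all-zero")
})

test_that("delta-SNP-index has the printed F2 threshold value and sign", {
  # idealized causal-locus bulks: indices (2/3, 0)
  tr <- delta_snp_index(snp_index(one_site(2e6, 1e6, 0, 3e6)))
  expect_equal(tr$delta, 2 / 3, tolerance = 1e-9)
  expect_equal(round(tr$delta, 2), 0.67)
  expect_equal(delta_snp_index(one_site(10, 10, 5, 5))$delta, 0)
  # orientation flips are visible, not clipped
  expect_equal(delta_snp_index(one_site(0, 30, 30, 0))$delta, -1)
})

test_that("ED statistic matches its closed form and the biallelic identity", {
  tr <- euclidean_distance(one_site(30, 0, 0, 30))
  expect_equal(tr$ed, sqrt(2), tolerance = 1e-12)
  expect_equal(tr$ed_pow, 4, tolerance = 1e-12)
  expect_equal(euclidean_distance(one_site(10, 10, 5, 5))$ed, 0)
  tr2 <- euclidean_distance(one_site(20, 10, 0, 30))
  expect_equal(tr2$ed, sqrt(2) * 2 / 3, tolerance = 1e-12)   # 0.94281...
  expect_equal(tr2$ed_pow, 64 / 81, tolerance = 1e-12)        # 0.79012...
  set.seed(31)
  x <- euclidean_distance(delta_snp_index(rand_count_table(300)))
  expect_equal(x$ed, sqrt(2) * abs(x$delta), tolerance = 1e-12)
})

test_that("theoretical thresholds follow the bulk genotype-class expectations", {
  expect_equal(theoretical_delta_threshold(f2_design("dominant", "recessive")),
               2 / 3, tolerance = 1e-15)
  expect_identical(round(theoretical_delta_threshold(f2_design()), 2), 0.67)
  expect_equal(theoretical_delta_threshold(f2_design("AA", "aa")), 1)
  expect_equal(theoretical_delta_threshold(f2_design("random", "random")), 0)
  expect_error(f2_design("backcross", "recessive"), "supported classes")
})

test_that("sliding-window fit averages sites and flags thin windows", {
  tr <- data.frame(chrom = "c1", pos = c(100, 200, 300),
                   delta = c(0.2, 0.4, 0.6))
  w <- smooth_track(tr, "delta", window_bp = 1000, step_bp = 1000,
                    min_sites = 1, chrom_lengths = c(c1 = 1000))
  expect_equal(nrow(w), 1L)
  expect_equal(w$value, 0.4)
  expect_equal(w$n_sites, 3L)

  # mean of constants is the constant wherever a window is informative
  set.seed(5)
  trc <- data.frame(chrom = "c1", pos = sort(sample.int(1e6, 500)), delta = 0.3)
  wc <- smooth_track(trc, "delta", window_bp = 1e5, step_bp = 1e4, min_sites = 5)
  expect_true(all(abs(wc$value[!is.na(wc$value)] - 0.3) < 1e-12))
  # tricube weighting of a constant is still the constant
  wt <- smooth_track(trc, "delta", 1e5, 1e4, min_sites = 5, kernel = "tricube")
  expect_true(all(abs(wt$value[!is.na(wt$value)] - 0.3) < 1e-12))

  # windows below min_sites are missing, not fabricated
  wm <- smooth_track(tr, "delta", window_bp = 1000, step_bp = 1000,
                     min_sites = 10, chrom_lengths = c(c1 = 1000))
  expect_true(all(is.na(wm$value)))
  expect_warning(
    smooth_track(tr, "delta", 1000, 1000, chrom_lengths = c(c1 = 1000, c2 = 1000)),
    "no sites on chromosome")
  expect_error(smooth_track(tr, "nope", 1000, 1000), "not found")
  expect_error(smooth_track(tr, "delta", 10, 1000), "window_bp")
})

test_that("region calling finds runs, merges gaps and reports near misses", {
  w <- structure(
    data.frame(chrom = "c1",
               start = seq(0, 900, 100), end = seq(100, 1000, 100),
               midpoint = seq(50, 950, 100), n_sites = 10,
               value = c(0.1, 0.8, 0.9, 0.1, 0.85, 0.1, 0.1, 0.2, 0.1, 0.3)),
    class = c("assoc_windows", "data.frame"), stat = "delta")
  r0 <- call_regions(w, threshold = 0.7)
  expect_equal(nrow(r0), 2L)
  expect_equal(r0$start, c(100, 400))
  expect_equal(r0$end, c(300, 500))
  expect_equal(r0$peak_value[1], 0.9)
  expect_equal(r0$peak_pos[1], 250)

  # gap of 100 bp between the runs merges them into one region
  rm <- call_regions(w, threshold = 0.7, merge_gap_bp = 100)
  expect_equal(nrow(rm), 1L)
  expect_equal(c(rm$start, rm$end), c(100, 500))

  # nothing above threshold: zero regions, but the peak is still reported
  expect_message(r1 <- call_regions(w, threshold = 0.95), "sub-threshold peak")
  expect_equal(nrow(r1), 0L)
  nm <- attr(r1, "near_miss")
  expect_equal(nm$midpoint, 250)
  expect_equal(nm$value, 0.9)

  # single window above threshold spans exactly that window
  r2 <- call_regions(w, threshold = 0.88)
  expect_equal(nrow(r2), 1L)
  expect_equal(c(r2$start, r2$end), c(200, 300))

  # raising the threshold never increases total candidate length
  lens <- vapply(c(0.05, 0.3, 0.7, 0.88, 0.95), function(th) {
    r <- suppressMessages(call_regions(w, th))
    sum(r$end - r$start)
  }, numeric(1))
  expect_true(all(diff(lens) <= 0))
})

test_that("empirical ED thresholds follow documented conventions", {
  expect_equal(ed_threshold(rep(0.5, 30)), 0.5)
  expect_equal(ed_threshold(1:100, q = 0.99), 99.01)  # type-7 interpolation
  expect_error(ed_threshold(1:10), "at least 20")
  v <- c(seq(0.1, 5, length.out = 50), 10)
  expect_equal(ed_threshold(v, method = "mad", k = 3),
               median(v) + 3 * mad(v))
})
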