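#' Per-site SNP-index of the two bulks
#'
#' The SNP-index of a bulk at a site is the fraction of that bulk's reads
#' carrying the yellow-parent allele. At a site fully linked to the causal
#' locus the expected index is 2/3 in the dominant-class (yellow) bulk
#' (members are 1/3 homozygous : 2/3 heterozygous) and 0 in the
#' recessive-class (green) bulk.
#'
#' @param counts A pooled allele-count table (see [bulk_allele_counts()]).
#' @return The table with columns `snp_index_Y` and `snp_index_G` added
#'   (class `assoc_track`). Sites with zero depth in a bulk get `NA` for that
#'   bulk, never a division error.
#' @export
snp_index <- function(counts) {
  dy <- counts$ypool_Y_reads + counts$ypool_G_reads
  dg <- counts$gpool_Y_reads + counts$gpool_G_reads
  if (nrow(counts) == 0L || all(dy + dg == 0)) {
    warning("all-zero count table; returning empty association track")
    counts <- counts[dy + dg > 0, , drop = FALSE]
    dy <- dg <- numeric(0)
  }
  out <- counts
  out$snp_index_Y <- ifelse(dy > 0, counts$ypool_Y_reads / dy, NA_real_)
  out$snp_index_G <- ifelse(dg > 0, counts$gpool_Y_reads / dg, NA_real_)
  class(out) <- unique(c("assoc_track", class(out)))
  out
}

#' Delta-SNP-index
#'
#' `delta = snp_index_Y - snp_index_G`: approximately 0 at unlinked sites and
#' approaching the theoretical design value (+2/3 for a dominant/recessive F2
#' bulk pair) at the causal locus. Missing if either bulk's index is missing.
#'
#' @param track Output of [snp_index()], or a raw count table (indices are
#'   computed first).
#' @return The track with a `delta` column added.
#' @export
delta_snp_index <- function(track) {
  if (is.null(track$snp_index_Y)) track <- snp_index(track)
  track$delta <- track$snp_index_Y - track$snp_index_G
  track
}

#' Euclidean-distance statistic between bulk allele frequencies
#'
#' Per site, the distance between the two bulks' allele-frequency vectors over
#' the two alleles: `ed = sqrt((fY - fG)^2 + ((1 - fY) - (1 - fG))^2)`, where
#' `f` is the bulk's yellow-allele read fraction. For biallelic sites this
#' equals `sqrt(2) * |fY - fG|`. The statistic is raised to a power (default
#' 4) before smoothing to suppress background noise, following common pooled
#' mapping practice.
#'
#' @param track Output of [snp_index()] (or a raw count table).
#' @param power Exponent applied to `ed` to form `ed_pow`.
#' @return The track with `ed` and `ed_pow` columns added.
#' @export
euclidean_distance <- function(track, power = 4) {
  if (is.null(track$snp_index_Y)) track <- snp_index(track)
  fy <- track$snp_index_Y
  fg <- track$snp_index_G
  track$ed <- sqrt((fy - fg)^2 + ((1 - fy) - (1 - fg))^2)
  track$ed_pow <- track$ed^power
  attr(track, "ed_power") <- power
  track
}

#' Describe an F2 bulk design
#'
#' @param high_bulk,low_bulk Selection rule of each bulk: `"dominant"`
#'   (dominant-phenotype class: genotypes 1/3 AA : 2/3 Aa), `"recessive"`
#'   (all aa), `"AA"`, `"aa"` (codominant-extreme selection) or `"random"`
#'   (no phenotype selection).
#' @return An object of class `f2_design`.
#' @export
f2_design <- function(high_bulk = "dominant", low_bulk = "recessive") {
  ok <- names(.f2_bulk_freq)
  if (!high_bulk %in% ok || !low_bulk %in% ok) {
    stop("unsupported bulk class; supported classes: ", paste(ok, collapse = ", "))
  }
  structure(list(cross = "F2", high_bulk = high_bulk, low_bulk = low_bulk),
            class = "f2_design")
}

# expected yellow-allele frequency in a bulk, by phenotype-conditional
# genotype-class proportions at a fully linked locus
.f2_bulk_freq <- c(dominant = 1 / 3 * 1 + 2 / 3 * 0.5,  # = 2/3
                   recessive = 0, AA = 1, aa = 0, random = 0.5)

#' Theoretical delta-SNP-index threshold of a bulk design
#'
#' The threshold used to call candidate regions is the expected delta at a
#' fully linked locus: the dosage-weighted mean yellow-allele frequency of the
#' high bulk minus that of the low bulk. For an F2 with a dominant-phenotype
#' bulk (1/3 AA : 2/3 Aa, expected frequency 2/3) against a
#' recessive-phenotype bulk (all aa, frequency 0) the threshold is 2/3,
#' conventionally printed as 0.67.
#'
#' @param design An [f2_design()].
#' @return The exact threshold as a number (e.g. `2/3`).
#' @examples
#' round(theoretical_delta_threshold(f2_design("dominant", "recessive")), 2)
#' @export
theoretical_delta_threshold <- function(design) {
  if (!inherits(design, "f2_design")) stop("`design` must be an f2_design")
  unname(.f2_bulk_freq[design$high_bulk] - .f2_bulk_freq[design$low_bulk])
}

#' Sliding-window smoothing of a per-site statistic
#'
#' Fits the per-site statistic along each chromosome with a deterministic
#' sliding window: windows of width `window_bp` anchored at midpoints every
#' `step_bp`, fitted value = (optionally tricube-weighted) mean of the
#' statistic over the non-missing sites in the window. Windows with fewer
#' than `min_sites` informative sites are reported with a missing value.
#'
#' @param track A per-site track with `chrom`, `pos` and the statistic column.
#' @param stat Name of the statistic column to smooth (e.g. `"delta"`,
#'   `"ed_pow"`).
#' @param window_bp Window width in bp (>= `step_bp`).
#' @param step_bp Distance between window midpoints in bp (> 0).
#' @param min_sites Minimum informative sites per window (default 10).
#' @param kernel `"uniform"` (plain mean, default) or `"tricube"` (distance
#'   weights `(1 - (|d|/h)^3)^3` with `h = window_bp / 2`).
#' @param chrom_lengths Optional named vector of chromosome lengths in bp;
#'   defaults to the last site position per chromosome.
#' @return `data.frame` of class `assoc_windows` with columns `chrom`,
#'   `start`, `end`, `midpoint`, `n_sites` (informative sites) and `value`.
#' @export
smooth_track <- function(track, stat, window_bp = 1e6, step_bp = 1e4,
                         min_sites = 10, kernel = c("uniform", "tricube"),
                         chrom_lengths = NULL) {
  kernel <- match.arg(kernel)
  if (!stat %in% names(track)) {
    stop("statistic column '", stat, "' not found; compute it first ",
         "(snp_index / delta_snp_index / euclidean_distance)")
  }
  if (!is.finite(step_bp) || step_bp <= 0) stop("`step_bp` must be > 0")
  if (window_bp < step_bp) stop("`window_bp` must be >= `step_bp`")
  chroms <- unique(track$chrom)
  if (!is.null(chrom_lengths)) {
    extra <- setdiff(names(chrom_lengths), chroms)
    if (length(extra)) {
      warning("no sites on chromosome(s) ", paste(extra, collapse = ", "),
              "; no windows produced there")
    }
  }
  out <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    ch <- chroms[ci]
    sel <- track$chrom == ch
    pos <- track$pos[sel]
    v <- track[[stat]][sel]
    o <- order(pos)
    pos <- pos[o]; v <- v[o]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else {
      max(pos)
    }
    mids <- seq(step_bp / 2, len, by = step_bp)
    lo <- pmax(mids - window_bp / 2, 0)
    hi <- pmin(mids + window_bp / 2, len)
    ok <- !is.na(v)
    if (kernel == "uniform") {
      cs_v <- c(0, cumsum(ifelse(ok, v, 0)))
      cs_n <- c(0, cumsum(ok))
      i <- findInterval(lo, pos, left.open = TRUE) + 1L  # first site >= lo
      j <- findInterval(hi, pos)                          # last site <= hi
      n_ok <- cs_n[j + 1L] - cs_n[i]
      s <- cs_v[j + 1L] - cs_v[i]
      val <- ifelse(n_ok >= max(min_sites, 1L), s / n_ok, NA_real_)
    } else {
      h <- window_bp / 2
      n_ok <- integer(length(mids))
      val <- rep(NA_real_, length(mids))
      for (k in seq_along(mids)) {
        inw <- which(pos >= lo[k] & pos <= hi[k] & ok)
        n_ok[k] <- length(inw)
        if (n_ok[k] >= max(min_sites, 1L)) {
          w <- (1 - (abs(pos[inw] - mids[k]) / h)^3)^3
          val[k] <- sum(w * v[inw]) / sum(w)
        }
      }
    }
    out[[ci]] <- data.frame(chrom = rep(ch, length(mids)), start = lo, end = hi,
                            midpoint = mids, n_sites = n_ok, value = val,
                            stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  structure(win, class = c("assoc_windows", "data.frame"),
            stat = stat, window_bp = window_bp, step_bp = step_bp)
}

#' Call candidate regions from fitted windows
#'
#' A candidate region is a maximal run of consecutive windows whose fitted
#' value meets the threshold; runs separated by at most `merge_gap_bp` are
#' merged. Region boundaries are the outer window edges; the peak is the
#' leftmost maximal window. When nothing exceeds the threshold an empty region
#' set is returned but the highest sub-threshold peak is still reported (as
#' the `"near_miss"` attribute and a message), since a clear peak below the
#' theoretical line is itself informative in a genome scan.
#'
#' @param windows Output of [smooth_track()].
#' @param threshold Finite calling threshold on the fitted value.
#' @param merge_gap_bp Maximum gap (bp) between runs that are merged.
#' @return `data.frame` of class `candidate_regions` with columns `chrom`,
#'   `start`, `end`, `peak_value`, `peak_pos`, `n_windows`, plus attributes
#'   `stat`, `threshold` and `near_miss` (one-row data.frame of the global
#'   peak window).
#' @export
call_regions <- function(windows, threshold, merge_gap_bp = 0) {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  regions <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    above <- !is.na(w$value) & w$value >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(i = starts[r$values], j = ends[r$values])
    # merge runs whose bp gap is small
    if (nrow(runs) > 1L) {
      merged <- runs[1L, , drop = FALSE]
      for (k in 2L:nrow(runs)) {
        gap <- w$start[runs$i[k]] - w$end[merged$j[nrow(merged)]]
        if (gap <= merge_gap_bp) {
          merged$j[nrow(merged)] <- runs$j[k]
        } else {
          merged <- rbind(merged, runs[k, ])
        }
      }
      runs <- merged
    }
    for (k in seq_len(nrow(runs))) {
      idx <- runs$i[k]:runs$j[k]
      vals <- w$value[idx]
      pk <- idx[which.max(vals)]  # which.max: leftmost maximum
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, start = w$start[runs$i[k]], end = w$end[runs$j[k]],
        peak_value = w$value[pk], peak_pos = w$midpoint[pk],
        n_windows = sum(!is.na(vals) & vals >= threshold),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(regions)) do.call(rbind, regions) else
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               peak_value = numeric(0), peak_pos = numeric(0),
               n_windows = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  nm <- windows[!is.na(windows$value), , drop = FALSE]
  near <- if (nrow(nm)) nm[which.max(nm$value), , drop = FALSE] else nm
  if (nrow(out) == 0L && nrow(near)) {
    message("call_regions: no window reached the threshold (", signif(threshold, 3),
            "); top sub-threshold peak at ", near$chrom, ":",
            format(near$midpoint, big.mark = ",", scientific = FALSE),
            " (fitted ", signif(near$value, 4), ")")
  }
  structure(out, class = c("candidate_regions", "data.frame"),
            stat = attr(windows, "stat"), threshold = threshold,
            near_miss = near)
}

#' Empirical threshold for the smoothed ED statistic
#'
#' The study design provides a theoretical threshold for delta-SNP-index but
#' none for ED, so an empirical genome-wide cutoff is derived from the fitted
#' values themselves: either a quantile (default 0.99, linear-interpolation
#' convention of [stats::quantile()] type 7) or `median + k * MAD`.
#'
#' @param windows Output of [smooth_track()], or a numeric vector of fitted
#'   values.
#' @param method `"quantile"` or `"mad"`.
#' @param q Quantile for `method = "quantile"`.
#' @param k MAD multiplier for `method = "mad"` (MAD with the usual 1.4826
#'   normal-consistency constant).
#' @return The threshold value.
#' @export
ed_threshold <- function(windows, method = c("quantile", "mad"), q = 0.99, k = 3) {
  method <- match.arg(method)
  v <- if (is.data.frame(windows)) windows$value else windows
  v <- v[!is.na(v)]
  if (length(v) < 20L) stop("need at least 20 non-missing fitted values")
  if (method == "quantile") {
    unname(stats::quantile(v, q))
  } else {
    stats::median(v) + k * stats::mad(v)
  }
}

#' Plot a fitted association track
#'
#' Simple per-chromosome scatter of per-site values with the fitted window
#' line and a horizontal threshold line.
#'
#' @param track Per-site track containing the statistic.
#' @param windows Fitted windows from [smooth_track()].
#' @param chrom Chromosome to draw.
#' @param threshold Optional horizontal threshold line.
#' @param ... Passed to [plot()].
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_track <- function(track, windows, chrom, threshold = NULL, ...) {
  stat <- attr(windows, "stat")
  s <- track[track$chrom == chrom, ]
  w <- windows[windows$chrom == chrom, ]
  graphics::plot(s$pos / 1e6, s[[stat]], pch = 16, cex = 0.3, col = "grey60",
                 xlab = paste(chrom, "position (Mb)"), ylab = stat, ...)
  graphics::lines(w$midpoint / 1e6, w$value, col = "black", lwd = 2)
  if (!is.null(threshold)) graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(NULL)
}
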