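#' Quality-filter a pooled allele-count table
#'
#' Applies the site filters used before association testing, in order:
#'
#' 1. depth: both bulks must have total depth >= `min_depth` at the site;
#' 2. monomorphic: sites where one of the two alleles has zero reads summed
#'    over both pools carry no frequency contrast and are dropped;
#' 3. parental genotypes (only when `parent_gt` is supplied): sites whose
#'    parents are not homozygous for different alleles are dropped;
#' 4. whitelist (only when supplied): sites not present in an externally
#'    provided consensus site list (e.g. the intersection of two variant
#'    callers) are dropped.
#'
#' The number of sites removed by each rule is reported via `message()` and
#' attached as the `"drops"` attribute. Filtering is idempotent and preserves
#' the input row order.
#'
#' @param counts A count table as produced by [bulk_allele_counts()] or read
#'   by [read_counts_tsv()] / [read_counts_vcf()].
#' @param min_depth Minimum per-bulk depth (default 5, applied to each bulk).
#' @param parent_gt Optional `data.frame(chrom, pos, gt_Y, gt_G)` of parental
#'   genotypes, e.g. `"A/A"`; sites absent from it are left untouched.
#' @param whitelist Optional `data.frame(chrom, pos)` of allowed sites.
#' @param quiet Suppress the per-rule drop messages.
#' @return The filtered count table (subset of input rows) with attribute
#'   `"drops"`, a named integer vector of per-rule removal counts.
#' @export
filter_sites <- function(counts, min_depth = 5, parent_gt = NULL,
                         whitelist = NULL, quiet = FALSE) {
  if (min_depth < 0) stop("`min_depth` must be >= 0")
  need <- c("chrom", "pos", "ypool_Y_reads", "ypool_G_reads",
            "gpool_Y_reads", "gpool_G_reads")
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("count table lacks columns: ", paste(miss, collapse = ", "))
  cnt <- counts[, c("ypool_Y_reads", "ypool_G_reads",
                    "gpool_Y_reads", "gpool_G_reads")]
  if (any(as.matrix(cnt) < 0, na.rm = TRUE)) stop("negative read counts in table")

  keep <- rep(TRUE, nrow(counts))
  drops <- c(low_depth = 0L, monomorphic = 0L, parental = 0L, whitelist = 0L)

  dy <- counts$ypool_Y_reads + counts$ypool_G_reads
  dg <- counts$gpool_Y_reads + counts$gpool_G_reads
  bad <- keep & (dy < min_depth | dg < min_depth)
  drops["low_depth"] <- sum(bad)
  keep[bad] <- FALSE

  tot_y <- counts$ypool_Y_reads + counts$gpool_Y_reads
  tot_g <- counts$ypool_G_reads + counts$gpool_G_reads
  bad <- keep & (tot_y == 0 | tot_g == 0)
  drops["monomorphic"] <- sum(bad)
  keep[bad] <- FALSE

  if (!is.null(parent_gt)) {
    key <- paste(counts$chrom, counts$pos)
    i <- match(key, paste(parent_gt$chrom, parent_gt$pos))
    ay <- .hom_allele(parent_gt$gt_Y)[i]
    ag <- .hom_allele(parent_gt$gt_G)[i]
    # only judge sites the parental table covers
    bad <- keep & !is.na(i) & (is.na(ay) | is.na(ag) | ay == ag)
    drops["parental"] <- sum(bad)
    keep[bad] <- FALSE
  }

  if (!is.null(whitelist)) {
    ok <- paste(counts$chrom, counts$pos) %in% paste(whitelist$chrom, whitelist$pos)
    bad <- keep & !ok
    drops["whitelist"] <- sum(bad)
    keep[bad] <- FALSE
  }

  if (!quiet) {
    message("filter_sites: ", nrow(counts), " sites in, ", sum(keep),
            " retained (dropped: low_depth=", drops["low_depth"],
            ", monomorphic=", drops["monomorphic"],
            ", parental=", drops["parental"],
            ", whitelist=", drops["whitelist"], ")")
  }
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  out
}

# homozygous genotype -> its allele; heterozygous or unparseable -> NA
.hom_allele <- function(gt) {
  gt <- as.character(gt)
  vapply(gt, function(g) {
    if (is.na(g)) return(NA_character_)
    al <- strsplit(g, "[/|]")[[1]]
    if (length(al) == 1L) al <- strsplit(al, "")[[1]]
    if (length(al) >= 1L && all(al == al[1L])) al[1L] else NA_character_
  }, character(1), USE.NAMES = FALSE)
}
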