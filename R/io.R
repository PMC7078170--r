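#' Read and write pooled allele-count tables
#'
#' The flat TSV dialect has one row per site with columns `chrom`, `pos`
#' (1-based), `allele_Y`, `allele_G`, `ypool_Y_reads`, `ypool_G_reads`,
#' `gpool_Y_reads`, `gpool_G_reads`.
#'
#' @param counts A count table ([bulk_allele_counts()]).
#' @param path File path.
#' @return `write_counts_tsv` returns `path` invisibly; `read_counts_tsv`
#'   returns the count table.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  chr_cols <- intersect(c("chrom", "allele_Y", "allele_G"), hdr)
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = stats::setNames(
                             rep("character", length(chr_cols)), chr_cols))
  need <- c("chrom", "pos", "ypool_Y_reads", "ypool_G_reads",
            "gpool_Y_reads", "gpool_G_reads")
  miss <- setdiff(need, names(out))
  if (length(miss)) stop("count TSV lacks columns: ", paste(miss, collapse = ", "))
  class(out) <- c("bulk_counts", "data.frame")
  out
}

#' Write pooled counts as a minimal VCF 4.2
#'
#' Emits one record per site with `REF` = yellow-parent allele, `ALT` =
#' green-parent allele and two samples, `Y_pool` and `G_pool`, each carrying
#' an `AD` (allele depth) field ordered REF,ALT. Positions are 1-based.
#'
#' @param counts A count table.
#' @param path Output path (`.vcf`, uncompressed).
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_counts_vcf <- function(counts, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bulkmap",
           if (!is.null(contigs)) {
             sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                     as.integer(contigs))
           },
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (REF=yellow-parent allele, ",
                  "ALT=green-parent allele)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "Y_pool", "G_pool"), collapse = "\t"))
  body <- paste(counts$chrom, counts$pos, ".", counts$allele_Y,
                counts$allele_G, ".", "PASS", ".", "AD",
                paste0(counts$ypool_Y_reads, ",", counts$ypool_G_reads),
                paste0(counts$gpool_Y_reads, ",", counts$gpool_G_reads),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read pooled counts from the VCF dialect
#'
#' Parses a VCF with `Y_pool` / `G_pool` samples carrying `AD` fields (as
#' written by [write_counts_vcf()]) back into the standard count table.
#'
#' @param path VCF path.
#' @return A `bulk_counts` table.
#' @export
read_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!all(c("Y_pool", "G_pool") %in% colnames(ad))) {
    stop("VCF must contain samples Y_pool and G_pool")
  }
  split2 <- function(x) {
    m <- do.call(rbind, strsplit(x, ",", fixed = TRUE))
    matrix(as.integer(m), ncol = 2)
  }
  y <- split2(ad[, "Y_pool"])
  g <- split2(ad[, "G_pool"])
  fix <- vcfR::getFIX(v)
  out <- data.frame(chrom = fix[, "CHROM"], pos = as.numeric(fix[, "POS"]),
                    allele_Y = fix[, "REF"], allele_G = fix[, "ALT"],
                    ypool_Y_reads = y[, 1], ypool_G_reads = y[, 2],
                    gpool_Y_reads = g[, 1], gpool_G_reads = g[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bulk_counts", "data.frame")
  out
}

#' Write candidate regions as BED
#'
#' BED is 0-based half-open; the score column is the peak fitted value scaled
#' by 1000 and capped to the BED range 0-1000.
#'
#' @param regions A [call_regions()] result.
#' @param path Output path.
#' @param name_prefix Region name prefix.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path, name_prefix = "region") {
  if (nrow(regions) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  score <- pmin(pmax(round(regions$peak_value * 1000), 0), 1000)
  bed <- paste(regions$chrom,
               format(pmax(regions$start - 1, 0), scientific = FALSE, trim = TRUE),
               format(regions$end, scientific = FALSE, trim = TRUE),
               paste0(name_prefix, "_", seq_len(nrow(regions))),
               score, sep = "\t")
  writeLines(bed, path)
  invisible(path)
}

#' Read and write marker-genotype matrices
#'
#' The TSV layout is individuals x markers: a `phenotype` column followed by
#' one column per marker with dosage codes 0/1/2 or `NA`. Marker positions
#' travel in two comment-style header rows (`#chrom`, `#pos`).
#'
#' @param mm A `marker_matrix`.
#' @param path File path.
#' @return `write_marker_tsv` returns `path` invisibly; `read_marker_tsv`
#'   a `marker_matrix`.
#' @export
write_marker_tsv <- function(mm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#chrom", mm$markers$chrom), collapse = "\t"), con)
  writeLines(paste(c("#pos", mm$markers$pos), collapse = "\t"), con)
  df <- data.frame(phenotype = mm$phenotype, mm$geno, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @export
read_marker_tsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  chrom <- strsplit(hdr[1], "\t")[[1]][-1]
  pos <- as.numeric(strsplit(hdr[2], "\t")[[1]][-1])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                          stringsAsFactors = FALSE, check.names = FALSE)
  geno <- as.matrix(df[, -1, drop = FALSE])
  mode(geno) <- "integer"
  marker_matrix(data.frame(name = colnames(df)[-1], chrom = chrom, pos = pos,
                           stringsAsFactors = FALSE),
                geno, df$phenotype)
}
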