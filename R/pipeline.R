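#' Default pipeline configuration
#'
#' Mirrors the study design the simulator emulates: an 11-chromosome
#' watermelon-like genome, 1,106 F2 plants segregating 3:1 for a dominant
#' locus near the top of chromosome 4, bulks of 30 + 30, mean pooled depth
#' 29x with 1% read error, a per-bulk depth filter of 5, a 1 Mb / 10 kb
#' sliding-window scan of delta-SNP-index (theoretical threshold) and ED^4
#' (0.99-quantile threshold), and six fine-mapping markers flanking the
#' locus.
#'
#' @param seed Integer seed for the whole run.
#' @return A nested list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    simulation = list(
      genome = "watermelon",
      cm_per_mb = 2.5,
      density = 30,          # SNP sites per Mb
      n = 1106,
      n_per_bulk = 30,
      mean_depth = 29,
      error_rate = 0.01,
      locus = list(chrom = "Chr04", pos = 500000)
    ),
    filter = list(min_depth = 5),
    scan = list(stats = c("delta", "ed_pow"), window_bp = 1e6, step_bp = 1e4,
                min_sites = 10, ed_power = 4, ed_quantile = 0.99,
                merge_gap_bp = 0),
    finemap = list(marker_pos = c(500000, 700000, 1000000, 2000000,
                                  4000000, 6000000))
  )
}

#' Read a pipeline configuration file
#'
#' @param path YAML file with the [default_run_config()] schema.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}

#' Validate a pipeline configuration
#'
#' A configuration must contain exactly one of a `simulation` block or an
#' `input` block (`input$counts`, optionally `input$markers`); referenced
#' files must exist. Missing optional blocks are filled from
#' [default_run_config()].
#'
#' @param config Configuration list.
#' @return The completed configuration, or an error.
#' @export
validate_run_config <- function(config) {
  has_sim <- !is.null(config$simulation)
  has_in <- !is.null(config$input)
  if (has_sim == has_in) {
    stop("config must contain exactly one of `simulation` or `input`")
  }
  if (is.null(config$seed)) stop("config must set `seed`")
  if (has_in) {
    if (is.null(config$input$counts)) stop("`input$counts` path is required")
    paths <- c(config$input$counts, config$input$markers)
    bad <- paths[!file.exists(paths)]
    if (length(bad)) stop("input file(s) not found: ", paste(bad, collapse = ", "))
  }
  def <- default_run_config(config$seed)
  config$filter <- utils::modifyList(def$filter, config$filter %||% list())
  config$scan <- utils::modifyList(def$scan, config$scan %||% list())
  if (has_sim) {
    config$simulation <- utils::modifyList(def$simulation, config$simulation)
    config$finemap <- utils::modifyList(def$finemap, config$finemap %||% list())
  }
  config
}

.build_map <- function(sim) {
  if (identical(sim$genome, "watermelon")) {
    watermelon_genome(cm_per_mb = sim$cm_per_mb %||% 2.5)
  } else {
    genome_map(sim$genome$chrom, sim$genome$length_bp,
               sim$genome$length_cM %||% NULL,
               cm_per_mb = sim$cm_per_mb %||% 2.5)
  }
}

#' Run the full mapping pipeline
#'
#' Executes simulate (or load) -> filter -> scan -> fine-map -> segregation
#' test in fixed order, writing every intermediate (TSV/VCF/BED), a run log
#' and a JSON report to `out_dir`. Identical configuration and seed give
#' identical outputs. On a stage failure the run aborts with the failing
#' stage named and a `MANIFEST` file marks the output directory incomplete.
#'
#' @param config Configuration list (see [default_run_config()]) or a YAML
#'   path.
#' @param out_dir Output directory (created if needed).
#' @return The run report (list of class `run_report`), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  report <- list(tool = "bulkmap",
                 version = as.character(utils::packageVersion("bulkmap")),
                 seed = config$seed, stages = list())
  stage <- "setup"
  manifest <- character(0)
  res <- tryCatch({
    set.seed(config$seed)

    if (!is.null(config$simulation)) {
      stage <- "simulate"
      sim <- config$simulation
      map <- .build_map(sim)
      locus <- causal_locus(sim$locus$chrom, sim$locus$pos)
      panel <- simulate_parent_snps(map, sim$density,
                                    ensure_positions = data.frame(
                                      chrom = locus$chrom, pos = locus$pos))
      pop <- simulate_f2(map, locus, sim$n)
      bulks <- make_bulks(pop, sim$n_per_bulk)
      counts <- bulk_allele_counts(pop, bulks, panel, sim$mean_depth,
                                   sim$error_rate)
      write_counts_tsv(counts, file.path(out_dir, "counts_raw.tsv"))
      write_counts_vcf(counts, file.path(out_dir, "counts_raw.vcf"),
                       contigs = stats::setNames(map$length_bp, map$chrom))
      manifest <- c(manifest, "counts_raw.tsv", "counts_raw.vcf")
      n_yellow <- sum(pop$phenotype == "yellow")
      report$stages$simulate <- list(
        n = sim$n, n_yellow = n_yellow, n_green = sim$n - n_yellow,
        n_sites = nrow(counts), mean_depth = sim$mean_depth,
        error_rate = sim$error_rate,
        locus = paste0(locus$chrom, ":", locus$pos))
      logmsg("simulate: ", sim$n, " plants (", n_yellow, " yellow), ",
             nrow(counts), " sites")
      chrom_lengths <- stats::setNames(map$length_bp, map$chrom)
    } else {
      stage <- "load"
      p <- config$input$counts
      counts <- if (grepl("\\.vcf$", p)) read_counts_vcf(p) else read_counts_tsv(p)
      pop <- NULL
      chrom_lengths <- NULL
      report$stages$load <- list(path = p, n_sites = nrow(counts))
      logmsg("load: ", nrow(counts), " sites from ", p)
    }

    stage <- "filter"
    filtered <- filter_sites(counts, config$filter$min_depth, quiet = TRUE)
    write_counts_tsv(filtered, file.path(out_dir, "counts_filtered.tsv"))
    manifest <- c(manifest, "counts_filtered.tsv")
    report$stages$filter <- list(min_depth = config$filter$min_depth,
                                 n_in = nrow(counts), n_out = nrow(filtered),
                                 drops = as.list(attr(filtered, "drops")))
    logmsg("filter: ", nrow(filtered), "/", nrow(counts),
           " sites kept at min_depth ", config$filter$min_depth)

    stage <- "scan"
    track <- euclidean_distance(delta_snp_index(snp_index(filtered)),
                                power = config$scan$ed_power)
    write_counts_tsv(track, file.path(out_dir, "track_sites.tsv"))
    manifest <- c(manifest, "track_sites.tsv")
    report$stages$scan <- list(window_bp = config$scan$window_bp,
                               step_bp = config$scan$step_bp, regions = list())
    for (st in config$scan$stats) {
      win <- smooth_track(track, st, config$scan$window_bp, config$scan$step_bp,
                          min_sites = config$scan$min_sites,
                          chrom_lengths = chrom_lengths)
      thr <- if (st == "delta") {
        theoretical_delta_threshold(f2_design("dominant", "recessive"))
      } else {
        ed_threshold(win, "quantile", q = config$scan$ed_quantile)
      }
      regs <- suppressMessages(call_regions(win, thr, config$scan$merge_gap_bp))
      wf <- file.path(out_dir, paste0("windows_", st, ".tsv"))
      bf <- file.path(out_dir, paste0("regions_", st, ".bed"))
      write_counts_tsv(win, wf)
      write_regions_bed(regs, bf, name_prefix = st)
      manifest <- c(manifest, basename(wf), basename(bf))
      report$stages$scan$regions[[st]] <- list(
        threshold = thr, n_regions = nrow(regs),
        regions = if (nrow(regs)) regs else NULL,
        near_miss = if (nrow(regs) == 0L) attr(regs, "near_miss") else NULL)
      logmsg("scan[", st, "]: threshold ", signif(thr, 4), ", ",
             nrow(regs), " region(s)")
    }

    if (!is.null(config$simulation)) {
      stage <- "finemap"
      mpos <- config$finemap$marker_pos
      markers <- data.frame(
        name = paste0("mk_", format(mpos, scientific = FALSE, trim = TRUE)),
        chrom = locus$chrom, pos = mpos, stringsAsFactors = FALSE)
      mm <- simulate_marker_genotypes(pop, markers)
      write_marker_tsv(mm, file.path(out_dir, "markers.tsv"))
      interval <- refine_interval(mm, locus$chrom,
                                  chrom_lengths[[locus$chrom]])
      int_txt <- file.path(out_dir, "interval.txt")
      utils::capture.output(print(interval), file = int_txt)
      manifest <- c(manifest, "markers.tsv", "interval.txt")
      report$stages$finemap <- list(
        chrom = interval$chrom, start = interval$start, end = interval$end,
        length_bp = interval$length, left_marker = interval$left_marker,
        right_marker = interval$right_marker,
        recombinants = stats::setNames(as.list(interval$markers$n_recombinant),
                                       interval$markers$name))
      logmsg("finemap: interval ", interval$chrom, ":", interval$start, "-",
             interval$end, " (", signif(interval$length / 1000, 4), " kb)")

      stage <- "segtest"
      n_y <- sum(pop$phenotype == "yellow")
      seg <- chisq_ratio_test(n_y, pop$n - n_y)
      report$stages$segtest <- list(n_dominant = n_y, n_recessive = pop$n - n_y,
                                    statistic = seg$statistic,
                                    p_value = seg$p.value)
      logmsg("segtest: X-squared ", signif(seg$statistic, 3), ", p ",
             signif(seg$p.value, 3))
    }

    stage <- "report"
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    manifest <- c(manifest, "run.log", "report.json")
    writeLines(c("status: complete", manifest),
               file.path(out_dir, "MANIFEST"))
    structure(report, class = "run_report")
  }, error = function(e) {
    writeLines(c(paste0("status: incomplete (failed at stage: ", stage, ")"),
                 manifest),
               file.path(out_dir, "MANIFEST"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' @export
print.run_report <- function(x, ...) {
  cat("bulkmap run (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$stages)) {
    cat("  stage ", nm, ":\n", sep = "")
    s <- x$stages[[nm]]
    flat <- s[!vapply(s, is.list, logical(1))]
    for (f in names(flat)) cat("    ", f, ": ", paste(format(flat[[f]]), collapse = " "), "\n", sep = "")
  }
  invisible(x)
}
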