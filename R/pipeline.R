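#' Scan configuration
#'
#' Aggregates every parameter of the end-to-end introgression scan.
#' Defaults are the conventional desk values: 100 kb windows, top 0.1%
#' outliers, 1 Mbp signal merging, 5 Mbp jackknife blocks.
#'
#' @param h1,h2,h3,h4 Quartet population labels (H2 = putative recipient,
#'   H3 = donor, H4 = outgroup).
#' @param window_size fd window size in bp.
#' @param quantile Outlier upper-tail fraction.
#' @param merge_distance Signal merge distance in bp.
#' @param block_size Jackknife block size in bp.
#' @param min_sites Minimum informative sites per fd window.
#' @param min_maf,min_call_rate,allowed_chroms Variant filter settings
#'   (see [filter_config()]); `allowed_chroms = NULL` keeps all.
#' @param exclude_samples Optional sample ids dropped before any analysis.
#' @param seed Integer seed recorded in the run log (the scan itself is
#'   deterministic).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(h1, h2, h3, h4, window_size = 1e5, quantile = 0.001,
                        merge_distance = 1e6, block_size = 5e6,
                        min_sites = 10, min_maf = 0.01, min_call_rate = 0.9,
                        allowed_chroms = NULL, exclude_samples = NULL,
                        seed = 1L) {
  structure(
    list(h1 = h1, h2 = h2, h3 = h3, h4 = h4, window_size = window_size,
         quantile = quantile, merge_distance = merge_distance,
         block_size = block_size, min_sites = min_sites, min_maf = min_maf,
         min_call_rate = min_call_rate, allowed_chroms = allowed_chroms,
         exclude_samples = exclude_samples, seed = as.integer(seed)),
    class = "scan_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full introgression scan
#'
#' Executes filter -> allele frequencies -> genome-wide D -> fd scan ->
#' outlier signals -> per-signal validation statistics (Weir-Cockerham
#' FST, dxy, nucleotide diversity and Tajima's D for recipient and donor),
#' plus LD r-squared and EHH on the top signal's peak window when the
#' panel is phased. All outputs are written as deterministic TSV/BED/JSON
#' under `out_dir`; rerunning with the same inputs and config reproduces
#' them byte for byte.
#'
#' @param vcf Path to the input VCF.
#' @param popmap_path Path to the popmap TSV.
#' @param cfg A [scan_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory results: `dstat`,
#'   `fd_windows`, `signals`, `signal_stats`, `validation`, and the paths
#'   written (`files`).
#' @export
run_scan <- function(vcf, popmap_path, cfg, out_dir) {
  stopifnot(inherits(cfg, "scan_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(x, path)
    files[[name]] <<- path
    path
  }

  panel <- stage("read_vcf", read_vcf(vcf))
  pm <- stage("read_popmap", read_popmap(popmap_path))
  if (!is.null(cfg$exclude_samples)) {
    pm <- pm[!pm$sample %in% cfg$exclude_samples, ]
    panel <- subset_panel(panel,
                          samples = setdiff(panel$samples,
                                            cfg$exclude_samples))
  }
  panel <- stage("filter_variants", filter_variants(
    panel, filter_config(cfg$min_maf, cfg$min_call_rate, cfg$allowed_chroms)))
  emit(filter_report(panel), "filter_report.tsv")

  freqs <- stage("allele_freqs", allele_freqs(panel, pm))
  q <- quartet(cfg$h1, cfg$h2, cfg$h3, cfg$h4)
  dres <- stage("d_statistic",
                d_statistic(freqs, q, block_size = cfg$block_size))
  emit(tidy(dres), "dstat.tsv")

  fdw <- stage("fd_scan", fd_scan(freqs, q, window_size = cfg$window_size,
                                  min_sites = cfg$min_sites))
  emit(fdw, "fd_windows.tsv")

  signals <- stage("detect_outliers",
                   detect_outliers(fdw, quantile = cfg$quantile,
                                   merge_distance = cfg$merge_distance))
  sig_flat <- dplyr::select(signals, -"windows")
  emit(sig_flat, "signals.tsv")
  write_bed(sig_flat, file.path(out_dir, "signals.bed"), score = "peak_fd")
  files[["signals.bed"]] <- file.path(out_dir, "signals.bed")

  windows <- make_windows(panel$sites, cfg$window_size)
  stats_tbl <- stage("window_stats", {
    fst <- fst_wc_window(panel, pm, cfg$h2, cfg$h3, windows)
    dxy <- dxy_window(panel, pm, cfg$h2, cfg$h3, windows)
    out <- dplyr::select(windows, "chrom", "start", "end")
    out$n_sites <- fst$n_sites
    out$fst <- fst$fst
    out$dxy <- dxy$dxy
    for (pop in c(cfg$h2, cfg$h3)) {
      out[[paste0("pi_", pop)]] <- pi_window(panel, pm, pop, windows)$pi
      out[[paste0("tajima_d_", pop)]] <-
        tajimas_d_window(panel, pm, pop, windows)$tajima_d
    }
    out
  })
  emit(stats_tbl, "window_stats.tsv")

  validation <- stage("validate_signal",
                      validate_signals(signals, fdw, stats_tbl,
                                       recipient = cfg$h2))
  emit(validation, "signal_validation.tsv")

  if (panel$phased && nrow(signals) > 0) {
    stage("haplotype_evidence", {
      top <- signals[1, ]
      region <- sprintf("%s:%d-%d", top$chrom, top$peak_start, top$peak_end)
      hp <- as_haplotypes(panel, pm, region)
      p <- colMeans(hp$hap)
      core_idx <- which.max(ifelse(p > 0 & p < 1, p * (1 - p), -1))
      core_pos <- hp$sites$pos[core_idx]
      e <- ehh(hp, core_pos, core_allele = 1L)
      emit(e, "peak_ehh.tsv")
      r2 <- ld_r2(hp)
      r2_tbl <- tibble::as_tibble(r2, .name_repair = "minimal")
      r2_tbl <- tibble::add_column(r2_tbl, pos = rownames(r2), .before = 1)
      emit(r2_tbl, "peak_ld_r2.tsv")
    })
  }

  run_log <- c(
    list(config = unclass(cfg), vcf = vcf, popmap = popmap_path,
         n_sites_post_filter = n_sites(panel),
         fd_threshold = attr(signals, "threshold"))
  )
  jsonlite::write_json(run_log, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  files[["run.json"]] <- file.path(out_dir, "run.json")
  writeLines(sort(names(files)), file.path(out_dir, "MANIFEST"))

  invisible(list(dstat = dres, fd_windows = fdw, signals = signals,
                 signal_stats = stats_tbl, validation = validation,
                 files = files))
}

#' Classify outlier signals against genome-wide window statistics
#'
#' A signal is `supported` when all of its member windows have
#' recipient-donor dxy and FST below the genome-wide medians and fd at or
#' above the outlier threshold — the pattern expected of a true
#' introgressed tract (locally reduced divergence between recipient and
#' donor). The recipient's Tajima's D sign over the signal span is
#' recorded alongside.
#'
#' @param signals An `introgression_signals` tibble from
#'   [detect_outliers()].
#' @param fd_windows The `fd_scan` tibble the signals came from.
#' @param window_stats A per-window statistics tibble with columns `chrom`,
#'   `start`, `fst`, `dxy` and `tajima_d_<recipient>`.
#' @param recipient Recipient population label (for the Tajima's D
#'   column).
#' @return A tibble with one row per signal: span, `supported`, and the
#'   member-window medians used.
#' @export
validate_signals <- function(signals, fd_windows, window_stats, recipient) {
  if (nrow(signals) == 0) stop("empty signal list", call. = FALSE)
  thr <- attr(signals, "threshold")
  med_fst <- stats::median(window_stats$fst, na.rm = TRUE)
  med_dxy <- stats::median(window_stats$dxy, na.rm = TRUE)
  td_col <- paste0("tajima_d_", recipient)
  purrr::map_dfr(seq_len(nrow(signals)), function(i) {
    sg <- signals[i, ]
    member <- window_stats$chrom == sg$chrom &
      window_stats$start >= sg$start & window_stats$start <= sg$end
    w <- window_stats[member, , drop = FALSE]
    fd_member <- sg$windows[[1]]$fd
    supported <- all(w$fst < med_fst, na.rm = TRUE) &&
      all(w$dxy < med_dxy, na.rm = TRUE) &&
      all(fd_member >= thr) &&
      any(!is.na(w$fst)) && any(!is.na(w$dxy))
    td <- if (td_col %in% names(w)) {
      stats::median(w[[td_col]], na.rm = TRUE)
    } else NA_real_
    tibble::tibble(
      chrom = sg$chrom, start = sg$start, end = sg$end,
      n_windows = sg$n_windows, peak_fd = sg$peak_fd,
      supported = supported,
      member_fst_median = stats::median(w$fst, na.rm = TRUE),
      member_dxy_median = stats::median(w$dxy, na.rm = TRUE),
      genome_fst_median = med_fst, genome_dxy_median = med_dxy,
      recipient_tajima_d = td,
      recipient_tajima_d_sign = sign(td)
    )
  })
}
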