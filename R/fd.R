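#' Windowed fd admixture-fraction scan
#'
#' For each window the ABBA-BABA numerator `sum(abba - baba)` is divided by
#' the same sum evaluated with both H2 and H3 replaced, at every site, by
#' the donor proxy PD — whichever of H2/H3 has the larger derived-allele
#' frequency there. The ratio fd estimates the local admixture fraction
#' from the donor (H3) into the recipient (H2). fd is reported missing
#' where the window D is negative (the statistic is only meaningful for
#' excess ABBA sharing), where fewer than `min_sites` informative sites
#' fall in the window, or where the denominator is zero. Values above 1
#' can occur in noise and are kept unclamped.
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param q A [quartet()] with H2 the putative recipient and H3 the donor.
#' @param window_size Window size in bp (default 1e5, i.e. 100 kb).
#' @param min_sites Minimum informative sites per window (default 10).
#' @param max_outgroup_maf Outgroup-polymorphism drop rule, as in
#'   [d_statistic()].
#' @param chrom_length Optional named chromosome lengths for tiling.
#' @return A tibble of class `fd_scan`: `chrom`, `start`, `end`,
#'   `n_informative`, `d_num`, `d_den`, `window_d`, `fd`.
#' @export
fd_scan <- function(freqs, q, window_size = 1e5, min_sites = 10,
                    max_outgroup_maf = 0.1, chrom_length = NULL) {
  pol <- polarize_quartet(freqs, q, max_outgroup_maf)
  p1 <- pol$p[, "H1"]; p2 <- pol$p[, "H2"]
  p3 <- pol$p[, "H3"]; p4 <- pol$p[, "H4"]
  w <- site_abba_baba(p1, p2, p3, p4)
  pd <- pmax(p2, p3)
  wd <- site_abba_baba(p1, pd, pd, p4)
  windows <- make_windows(pol$sites, window_size, chrom_length)
  idx <- window_index(pol$sites, windows)
  use <- !is.na(idx)
  mat <- cbind(w$abba - w$baba, w$abba + w$baba, wd$abba - wd$baba,
               as.numeric(w$abba + w$baba > 0))[use, , drop = FALSE]
  sums <- rowsum_by(mat, idx[use], nrow(windows))
  out <- windows
  out$partial <- NULL
  out$n_informative <- as.integer(sums[, 4])
  out$d_num <- sums[, 1]
  out$d_den <- sums[, 2]
  out$window_d <- ifelse(out$d_den > 0, out$d_num / out$d_den, NA_real_)
  fd <- ifelse(sums[, 3] != 0, out$d_num / sums[, 3], NA_real_)
  fd[is.na(out$window_d) | out$window_d < 0 |
       out$n_informative < min_sites] <- NA_real_
  out$fd <- fd
  out <- tibble::as_tibble(out)
  class(out) <- c("fd_scan", class(out))
  attr(out, "quartet") <- q
  out
}

#' Detect and merge outlier windows of an fd scan
#'
#' Ranks non-missing fd values, takes the empirical `1 - quantile` quantile
#' as the outlier threshold (windows at or above it are outliers), and
#' chains same-chromosome outlier windows whose gap is at most
#' `merge_distance` into single signals. When fewer than `1/quantile`
#' windows are available a warning is issued and the top
#' `max(1, round(n * quantile))` windows are taken.
#'
#' @param fd_windows An `fd_scan` tibble (or any tibble with `chrom`,
#'   `start`, `end`, `fd`).
#' @param quantile Upper tail fraction defining outliers (default 0.001,
#'   i.e. the top 0.1%; the 99.9% quantile threshold).
#' @param merge_distance Maximum gap in bp between outlier windows merged
#'   into one signal (default 1e6).
#' @return A tibble of class `introgression_signals`: one row per signal
#'   with `chrom`, `start`, `end`, `n_windows`, `peak_fd`, `peak_start`,
#'   `peak_end`, and a `windows` list-column of member windows. The fd
#'   threshold is attached as attribute `threshold`.
#' @export
detect_outliers <- function(fd_windows, quantile = 0.001,
                            merge_distance = 1e6) {
  ok <- !is.na(fd_windows$fd)
  x <- fd_windows[ok, , drop = FALSE]
  n <- nrow(x)
  if (n == 0) stop("no windows with non-missing fd", call. = FALSE)
  if (n < 1 / quantile) {
    warning("fewer than 1/quantile windows; taking top ",
            max(1, round(n * quantile)), " window(s)", call. = FALSE)
    k <- max(1, round(n * quantile))
    thr <- sort(x$fd, decreasing = TRUE)[k]
  } else {
    thr <- stats::quantile(x$fd, 1 - quantile, names = FALSE)
  }
  out_w <- x[x$fd >= thr, , drop = FALSE]
  out_w <- dplyr::arrange(out_w, .data$chrom, .data$start)
  grp <- integer(nrow(out_w))
  gid <- 0L
  for (i in seq_len(nrow(out_w))) {
    new_grp <- i == 1 ||
      out_w$chrom[i] != out_w$chrom[i - 1] ||
      out_w$start[i] - out_w$end[i - 1] > merge_distance
    if (new_grp) gid <- gid + 1L
    grp[i] <- gid
  }
  out_w$.grp <- grp
  signals <- out_w |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      chrom = dplyr::first(.data$chrom),
      n_windows = dplyr::n(),
      peak_fd = max(.data$fd),
      peak_start = .data$start[which.max(.data$fd)],
      peak_end = .data$end[which.max(.data$fd)],
      windows = list(dplyr::pick(dplyr::everything())),
      start = min(.data$start),
      end = max(.data$end),
      .groups = "drop"
    ) |>
    dplyr::relocate("chrom", "start", "end") |>
    dplyr::select(-".grp") |>
    dplyr::arrange(dplyr::desc(.data$peak_fd))
  class(signals) <- c("introgression_signals", class(signals))
  attr(signals, "threshold") <- thr
  signals
}

#' Manhattan-style plot of an fd scan
#'
#' @param object An `fd_scan` tibble.
#' @param threshold Optional horizontal threshold line (e.g. the outlier
#'   threshold from [detect_outliers()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fd_scan
#' @export
autoplot.fd_scan <- function(object, threshold = NULL, ...) {
  df <- object[!is.na(object$fd), ]
  mid <- (df$start + df$end) / 2
  gg <- ggplot2::ggplot(
    data.frame(df, mid = mid),
    ggplot2::aes(x = .data$mid, y = .data$fd, colour = .data$chrom)
  ) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "fd") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    gg <- gg + ggplot2::geom_hline(yintercept = threshold,
                                   linetype = "dashed", colour = "red")
  }
  gg
}

#' Export windows or signals as BED
#'
#' Converts the package's 1-based inclusive intervals to BED's 0-based
#' half-open convention.
#'
#' @param x A tibble with `chrom`, `start`, `end` (and optionally a score
#'   column named by `score`).
#' @param path Output path.
#' @param score Optional column name written as the BED score field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, score = NULL) {
  bed <- data.frame(x$chrom, x$start - 1L, x$end)
  if (!is.null(score)) {
    bed$name <- "."
    bed$score <- x[[score]]
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
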