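#' Tile chromosomes with fixed non-overlapping windows
#'
#' Windows are anchored at position 1 and tile each chromosome present in
#' the site table; coordinates are 1-based inclusive (window k spans
#' `[(k-1) * size + 1, k * size]`). The final window of a chromosome is the
#' (possibly partial) tile containing its last site and is flagged.
#'
#' @param sites A site tibble (`chrom`, `pos`), e.g. `panel$sites`.
#' @param window_size Window size in bp (default 100000, i.e. 100 kb).
#' @param chrom_length Optional named vector of chromosome lengths in bp;
#'   when given, windows tile the full length rather than stopping at the
#'   last observed site.
#' @return A tibble with columns `chrom`, `start`, `end`, `partial`.
#' @export
make_windows <- function(sites, window_size = 1e5, chrom_length = NULL) {
  stopifnot(window_size >= 1)
  out <- lapply(unique(sites$chrom), function(ch) {
    len <- if (!is.null(chrom_length) && ch %in% names(chrom_length)) {
      chrom_length[[ch]]
    } else {
      max(sites$pos[sites$chrom == ch])
    }
    n_win <- ceiling(len / window_size)
    start <- (seq_len(n_win) - 1) * window_size + 1
    end <- pmin(start + window_size - 1, len)
    tibble::tibble(chrom = ch, start = start, end = end,
                   partial = end - start + 1 < window_size)
  })
  dplyr::bind_rows(out)
}

# index of the window (row of `windows`) containing each site; NA if none
window_index <- function(sites, windows) {
  idx <- rep(NA_integer_, nrow(sites))
  for (ch in unique(sites$chrom)) {
    w <- which(windows$chrom == ch)
    if (!length(w)) next
    s <- which(sites$chrom == ch)
    k <- findInterval(sites$pos[s], windows$start[w])
    ok <- k >= 1 & sites$pos[s] <= windows$end[w[pmax(k, 1)]]
    idx[s[ok]] <- w[k[ok]]
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse "chr:start-end" (1-based inclusive) into a list
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) {
    stop("malformed region string (expected \"chr:start-end\"): ", region,
         call. = FALSE)
  }
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}
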