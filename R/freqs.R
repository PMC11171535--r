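#' Per-population allele counts and frequencies
#'
#' Tabulates, for every site and population, the number of called alleles
#' (two per fully called diploid genotype), the alternate-allele count, and
#' the alternate-allele frequency. Missing genotypes never enter the
#' denominators; a population with zero called alleles at a site gets a
#' missing frequency there.
#'
#' @param panel A [genotype_panel()].
#' @param pm A popmap tibble ([popmap()] / [read_popmap()]); every mapped
#'   sample must be present in the panel.
#' @return An object of class `freq_table`: site tibble plus
#'   sites x populations matrices `alt` (alternate-allele counts), `called`
#'   (called-allele counts) and `freq` (alt frequencies, `NA` where
#'   uncalled). Use [tidy()] for a long tibble.
#' @export
allele_freqs <- function(panel, pm) {
  absent <- setdiff(pm$sample, panel$samples)
  if (length(absent)) {
    stop("popmap sample(s) absent from panel: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  pops <- levels(pm$population)
  dos <- dosage_matrix(panel)
  called <- called_matrix(panel)
  alt <- matrix(0L, n_sites(panel), length(pops),
                dimnames = list(NULL, pops))
  tot <- alt
  for (pop in pops) {
    cols <- pm$sample[pm$population == pop]
    alt[, pop] <- as.integer(rowSums(dos[, cols, drop = FALSE], na.rm = TRUE))
    tot[, pop] <- as.integer(2L * rowSums(called[, cols, drop = FALSE]))
  }
  freq <- ifelse(tot > 0, alt / tot, NA_real_)
  structure(
    list(sites = panel$sites, alt = alt, called = tot, freq = freq,
         populations = pops),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d sites x %d populations (%s)\n",
              nrow(x$sites), length(x$populations),
              paste(x$populations, collapse = ", ")))
  invisible(x)
}

#' Tidy an allele-frequency table into long form
#'
#' @param x A `freq_table` from [allele_freqs()].
#' @param ... Unused.
#' @return A tibble with one row per site x population: `chrom`, `pos`,
#'   `population`, `alt_count`, `called_count`, `alt_freq`.
#' @method tidy freq_table
#' @export
tidy.freq_table <- function(x, ...) {
  tibble::tibble(
    chrom = rep(x$sites$chrom, times = length(x$populations)),
    pos = rep(x$sites$pos, times = length(x$populations)),
    population = rep(x$populations, each = nrow(x$sites)),
    alt_count = as.integer(x$alt),
    called_count = as.integer(x$called),
    alt_freq = as.numeric(x$freq)
  )
}
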