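#' Windowed nucleotide diversity (pi)
#'
#' Per window, `sum over sites of 2 p (1-p) n/(n-1)` divided by the window
#' length in bp, where `p` is the alt frequency and `n` the number of called
#' alleles at the site. The bp denominator makes the statistic
#' monomorphic-site aware (invariant sites contribute length but no
#' diversity); set `per_site = TRUE` to divide by the number of sites with
#' data instead.
#'
#' @param panel A [genotype_panel()].
#' @param pm A popmap tibble.
#' @param pop Population label.
#' @param windows A window tibble from [make_windows()].
#' @param per_site Normalize by sites with data rather than window bp.
#' @return `windows` plus columns `n_sites` and `pi`.
#' @export
pi_window <- function(panel, pm, pop, windows, per_site = FALSE) {
  freqs <- allele_freqs(panel, pm[pm$population == pop, ])
  p <- freqs$freq[, pop]
  n <- freqs$called[, pop]
  site_pi <- ifelse(!is.na(p) & n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
  window_stat_sum(panel$sites, site_pi, windows, per_site, "pi")
}

#' Windowed between-population divergence (dxy)
#'
#' Per window, `sum over sites of pA (1-pB) + pB (1-pA)` divided by the
#' window length in bp (or by sites with data when `per_site = TRUE`): the
#' average per-bp difference between one sequence drawn from each
#' population.
#'
#' @inheritParams pi_window
#' @param pop_a,pop_b Population labels.
#' @return `windows` plus columns `n_sites` and `dxy`.
#' @export
dxy_window <- function(panel, pm, pop_a, pop_b, windows, per_site = FALSE) {
  freqs <- allele_freqs(panel, pm[pm$population %in% c(pop_a, pop_b), ])
  pa <- freqs$freq[, pop_a]
  pb <- freqs$freq[, pop_b]
  site_dxy <- ifelse(!is.na(pa) & !is.na(pb),
                     pa * (1 - pb) + pb * (1 - pa), NA_real_)
  window_stat_sum(panel$sites, site_dxy, windows, per_site, "dxy")
}

window_stat_sum <- function(sites, site_stat, windows, per_site, name) {
  idx <- window_index(sites, windows)
  use <- !is.na(idx) & !is.na(site_stat)
  sums <- rowsum_by(matrix(site_stat[use]), idx[use], nrow(windows))[, 1]
  n <- as.integer(rowsum_by(matrix(1, sum(use)), idx[use], nrow(windows))[, 1])
  denom <- if (per_site) n else windows$end - windows$start + 1
  out <- windows
  out$n_sites <- n
  out[[name]] <- ifelse(n > 0, sums / denom, NA_real_)
  tibble::as_tibble(out)
}

#' Windowed Tajima's D
#'
#' Standardized difference between the diversity-based and segregating-site
#' estimators of the population mutation rate:
#' `D = (pi_sum - S/a1) / sqrt(e1 S + e2 S (S-1))`, with the 1989 constants
#' computed from the sample size. `pi_sum` uses per-site called-allele
#' counts (`2 p (1-p) n/(n-1)`, unnormalized); the constants use the
#' minimum called-allele count over the window's segregating sites, which
#' reduces to the usual estimator on complete data. Windows with no
#' segregating site or fewer than 4 alleles get `NA`.
#'
#' @inheritParams pi_window
#' @return `windows` plus columns `n_sites` (sites with data), `S`
#'   (segregating sites) and `tajima_d`.
#' @export
tajimas_d_window <- function(panel, pm, pop, windows) {
  freqs <- allele_freqs(panel, pm[pm$population == pop, ])
  p <- freqs$freq[, pop]
  n <- freqs$called[, pop]
  idx <- window_index(panel$sites, windows)
  has_data <- !is.na(idx) & !is.na(p) & n >= 2
  out <- windows
  out$n_sites <- 0L
  out$S <- 0L
  out$tajima_d <- NA_real_
  for (w in unique(idx[has_data])) {
    s <- which(has_data & idx == w)
    seg <- s[p[s] > 0 & p[s] < 1]
    out$n_sites[w] <- length(s)
    out$S[w] <- length(seg)
    if (!length(seg)) next
    n_min <- min(n[seg])
    if (n_min < 4) next
    pi_sum <- sum(2 * p[seg] * (1 - p[seg]) * n[seg] / (n[seg] - 1))
    out$tajima_d[w] <- tajima_d_value(pi_sum, length(seg), n_min)
  }
  tibble::as_tibble(out)
}

# Tajima (1989) D from unnormalized pi, segregating sites S, sample size n
tajima_d_value <- function(pi_sum, S, n) {
  if (S < 1 || n < 4) return(NA_real_)
  k <- tajima_constants(n)
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (pi_sum - S / k$a1) / denom
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}
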