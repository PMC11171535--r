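#' Hudson ratio-of-sums FST for one population pair
#'
#' Per site, with alt frequencies `pA`, `pB` and called allele counts `nA`,
#' `nB`, the numerator is `(pA - pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)`
#' and the denominator `pA(1-pB) + pB(1-pA)`; FST is the ratio of the sums
#' over all sites where both populations have at least two called alleles.
#' This "ratio of sums" form is the estimator used for population-level
#' differentiation matrices; it is not interchangeable with the
#' Weir-Cockerham windowed estimator ([fst_wc_window()]).
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param pop_a,pop_b Population labels.
#' @return A single numeric FST (small negatives possible and reported raw).
#' @export
fst_hudson_pair <- function(freqs, pop_a, pop_b) {
  stopifnot(pop_a %in% freqs$populations, pop_b %in% freqs$populations)
  pa <- freqs$freq[, pop_a]
  pb <- freqs$freq[, pop_b]
  na <- freqs$called[, pop_a]
  nb <- freqs$called[, pop_b]
  use <- !is.na(pa) & !is.na(pb) & na >= 2 & nb >= 2
  if (!any(use)) {
    stop("no jointly called sites for ", pop_a, " vs ", pop_b, call. = FALSE)
  }
  pa <- pa[use]; pb <- pb[use]; na <- na[use]; nb <- nb[use]
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  sum(num) / sum(den)
}

#' Island-model gene-flow level from FST
#'
#' Applies the island-model relation `Nm = (1 - FST) / (4 FST)`, the
#' effective number of migrants per generation implied by a given level of
#' differentiation.
#'
#' @param fst Numeric vector of FST values.
#' @return Numeric vector of Nm values; `Inf` (with a warning) where
#'   `fst <= 0`.
#' @export
nm_from_fst <- function(fst) {
  out <- ifelse(fst > 0, (1 - fst) / (4 * fst), Inf)
  if (any(fst <= 0, na.rm = TRUE)) {
    warning("FST <= 0: Nm reported as Inf", call. = FALSE)
  }
  out
}

#' Pairwise FST / Nm matrix over all populations
#'
#' Applies [fst_hudson_pair()] to every population pair and converts each
#' FST to a gene-flow level with [nm_from_fst()].
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @return An object of class `fst_matrix`: symmetric `fst` and `nm`
#'   matrices (diagonal FST 0, Nm `Inf`). Pairs with no jointly called
#'   sites become `NA` cells with a warning. [tidy()] returns one row per
#'   unordered pair.
#' @export
fst_matrix <- function(freqs) {
  pops <- freqs$populations
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      val <- tryCatch(fst_hudson_pair(freqs, pops[i], pops[j]),
                      error = function(e) {
                        warning(conditionMessage(e), call. = FALSE)
                        NA_real_
                      })
      fst[i, j] <- fst[j, i] <- val
    }
  }
  nm <- suppressWarnings(nm_from_fst(fst))
  diag(nm) <- Inf
  structure(list(populations = pops, fst = fst, nm = nm),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("<fst_matrix>\n")
  print(round(x$fst, 4))
  invisible(x)
}

#' Tidy a pairwise FST matrix
#' @param x An `fst_matrix`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `pop_a`, `pop_b`,
#'   `fst`, `nm`.
#' @method tidy fst_matrix
#' @export
tidy.fst_matrix <- function(x, ...) {
  k <- length(x$populations)
  idx <- which(upper.tri(x$fst), arr.ind = TRUE)
  tibble::tibble(
    pop_a = x$populations[idx[, 1]],
    pop_b = x$populations[idx[, 2]],
    fst = x$fst[idx],
    nm = x$nm[idx]
  )
}

#' Windowed Weir-Cockerham FST for one population pair
#'
#' Per window, the weighted (ratio of summed variance components)
#' Weir-Cockerham theta for two populations, computed from genotypes so the
#' observed heterozygosity enters the components. Windows with no usable
#' site get `NA`.
#'
#' @param panel A [genotype_panel()].
#' @param pm A popmap tibble.
#' @param pop_a,pop_b Population labels.
#' @param windows A window tibble from [make_windows()].
#' @return `windows` with columns `n_sites` (sites contributing) and `fst`.
#' @export
fst_wc_window <- function(panel, pm, pop_a, pop_b, windows) {
  comp <- wc_components(panel, pm, pop_a, pop_b)
  idx <- window_index(panel$sites, windows)
  use <- !is.na(idx) & !is.na(comp$a)
  sums <- rowsum_by(cbind(comp$a, comp$a + comp$b + comp$c)[use, , drop = FALSE],
                    idx[use], nrow(windows))
  out <- windows
  out$n_sites <- as.integer(rowsum_by(matrix(1, sum(use)), idx[use],
                                      nrow(windows)))
  out$fst <- ifelse(out$n_sites > 0 & sums[, 2] != 0, sums[, 1] / sums[, 2],
                    NA_real_)
  tibble::as_tibble(out)
}

# Weir & Cockerham (1984) per-site variance components for two populations.
wc_components <- function(panel, pm, pop_a, pop_b) {
  r <- 2
  stats_for <- function(pop) {
    cols <- pm$sample[pm$population == pop]
    if (!length(cols)) stop("unknown population: ", pop, call. = FALSE)
    a1 <- panel$a1[, cols, drop = FALSE]
    a2 <- panel$a2[, cols, drop = FALSE]
    called <- !is.na(a1) & !is.na(a2)
    n <- rowSums(called)                                  # called diploids
    p <- ifelse(n > 0, rowSums(a1 + a2, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(a1 != a2, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  A <- stats_for(pop_a)
  B <- stats_for(pop_b)
  ok <- A$n >= 1 & B$n >= 1 & (A$n + B$n) >= 2
  nbar <- (A$n + B$n) / r
  nc <- ifelse(nbar > 0, (r * nbar - (A$n^2 + B$n^2) / (r * nbar)) / (r - 1),
               NA_real_)
  pbar <- (A$n * A$p + B$n * B$p) / (r * nbar)
  s2 <- (A$n * (A$p - pbar)^2 + B$n * (B$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (A$n * A$h + B$n * B$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  bad <- !ok | !is.finite(a) | !is.finite(b) | !is.finite(cc) | nbar <= 1 |
    is.na(nc) | nc <= 0
  a[bad] <- NA_real_; b[bad] <- NA_real_; cc[bad] <- NA_real_
  list(a = a, b = b, c = cc)
}

# rowsum over a fixed number of groups, returning zeros for empty groups
rowsum_by <- function(x, group, n_groups) {
  out <- matrix(0, n_groups, ncol(x))
  if (nrow(x)) {
    rs <- rowsum(x, group)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}
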