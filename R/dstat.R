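#' Four-population quartet specification
#'
#' Orders populations on the asymmetric tree `(((H1, H2), H3), H4)`: H1 and
#' H2 are the sister pair, H3 the candidate donor, H4 the outgroup used to
#' polarize ancestral vs derived alleles.
#'
#' @param h1,h2,h3,h4 Distinct population labels.
#' @return A named character vector of class `quartet`.
#' @export
quartet <- function(h1, h2, h3, h4) {
  q <- c(H1 = h1, H2 = h2, H3 = h3, H4 = h4)
  if (anyDuplicated(q)) stop("quartet labels must be distinct", call. = FALSE)
  structure(q, class = "quartet")
}

#' Per-site ABBA and BABA weights
#'
#' Frequency-weighted discordant-pattern probabilities on the quartet tree:
#' `abba = (1-p1) p2 p3 (1-p4)` and `baba = p1 (1-p2) p3 (1-p4)`, with
#' `p1..p4` the derived-allele frequencies of H1..H4 (polarize first; see
#' [polarize_quartet()]).
#'
#' @param p1,p2,p3,p4 Numeric vectors of derived-allele frequencies.
#' @return A tibble with columns `abba` and `baba`.
#' @export
site_abba_baba <- function(p1, p2, p3, p4) {
  tibble::tibble(
    abba = (1 - p1) * p2 * p3 * (1 - p4),
    baba = p1 * (1 - p2) * p3 * (1 - p4)
  )
}

# Extract per-site derived-allele frequencies for a quartet, polarized so
# the outgroup (H4) carries the ancestral allele. Sites where the outgroup
# minor-allele frequency exceeds `max_outgroup_maf` (polymorphic outgroup)
# and sites with any missing frequency are dropped.
polarize_quartet <- function(freqs, q, max_outgroup_maf = 0.1) {
  stopifnot(inherits(q, "quartet"))
  absent <- setdiff(unname(q), freqs$populations)
  if (length(absent)) {
    stop("quartet population(s) absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  p <- freqs$freq[, unname(q), drop = FALSE]
  colnames(p) <- names(q)
  complete <- stats::complete.cases(p)
  p4 <- p[, "H4"]
  flip <- complete & p4 >= 1 - max_outgroup_maf
  keep <- complete & (p4 <= max_outgroup_maf | flip)
  p[flip, ] <- 1 - p[flip, ]
  list(
    sites = freqs$sites[keep, , drop = FALSE],
    p = p[keep, , drop = FALSE],
    n_dropped_polymorphic = sum(complete) - sum(keep),
    n_dropped_missing = sum(!complete)
  )
}

#' Genome-wide Patterson's D with block-jackknife significance
#'
#' Computes `D = (sum ABBA - sum BABA) / (sum ABBA + sum BABA)` from
#' polarized allele frequencies, with a weighted delete-one block jackknife
#' over contiguous coordinate blocks (default 5 Mbp) for the standard error
#' and Z-score. Blocks are weighted by their informative-site count
#' (ABBA + BABA > 0), the Busing weighted-jackknife form; with equal block
#' weights it reduces to the unweighted delete-one formula. Positive D
#' means H3 shares more derived alleles with H2 than with H1; `|Z| > 3` is
#' the conventional significance rule.
#'
#' @param freqs A `freq_table` from [allele_freqs()].
#' @param q A [quartet()].
#' @param block_size Jackknife block size in bp (default 5e6).
#' @param max_outgroup_maf Sites with outgroup minor-allele frequency above
#'   this are dropped before polarization (default 0.1).
#' @return An object of class `dstat` with fields `D`, `se`, `z`,
#'   `abba_sum`, `baba_sum`, `n_blocks`, `n_sites`, `block_size`,
#'   `zero_variance`; see [tidy.dstat()].
#' @export
d_statistic <- function(freqs, q, block_size = 5e6, max_outgroup_maf = 0.1) {
  pol <- polarize_quartet(freqs, q, max_outgroup_maf)
  w <- site_abba_baba(pol$p[, "H1"], pol$p[, "H2"], pol$p[, "H3"],
                      pol$p[, "H4"])
  abba_sum <- sum(w$abba)
  baba_sum <- sum(w$baba)
  if (abba_sum + baba_sum == 0) {
    stop("no informative sites for D statistic", call. = FALSE)
  }
  D <- (abba_sum - baba_sum) / (abba_sum + baba_sum)

  block <- paste0(pol$sites$chrom, ":",
                  (pol$sites$pos - 1) %/% block_size)
  informative <- w$abba + w$baba > 0
  tab <- tapply(informative, block, sum)
  blocks <- names(tab)[tab > 0]
  g <- length(blocks)
  if (g < 2) stop("need at least 2 non-empty jackknife blocks", call. = FALSE)

  num_b <- tapply(w$abba - w$baba, block, sum)[blocks]
  den_b <- tapply(w$abba + w$baba, block, sum)[blocks]
  m <- as.numeric(tab[blocks])           # informative sites per block
  n_tot <- sum(m)
  num <- abba_sum - baba_sum
  den <- abba_sum + baba_sum
  theta_j <- (num - num_b) / (den - den_b)   # delete-one estimates
  h <- n_tot / m
  theta_jack <- g * D - sum((1 - m / n_tot) * theta_j)
  tau <- h * D - (h - 1) * theta_j           # pseudovalues
  var_d <- sum((tau - theta_jack)^2 / (h - 1)) / g
  se <- sqrt(var_d)
  zero_var <- se == 0 || !is.finite(se)
  z <- if (zero_var) sign(D) * Inf else D / se
  structure(
    list(D = D, se = se, z = z, abba_sum = abba_sum, baba_sum = baba_sum,
         n_blocks = g, n_sites = nrow(pol$sites), block_size = block_size,
         zero_variance = zero_var, quartet = q),
    class = "dstat"
  )
}

#' @export
print.dstat <- function(x, ...) {
  cat(sprintf(
    "<dstat> (((%s,%s),%s),%s)\n  D = %.4f  SE = %.4g  Z = %.2f  (%d blocks of %g bp, %d sites)\n",
    x$quartet["H1"], x$quartet["H2"], x$quartet["H3"], x$quartet["H4"],
    x$D, x$se, x$z, x$n_blocks, x$block_size, x$n_sites))
  invisible(x)
}

#' Tidy a D-statistic result
#' @param x A `dstat` object.
#' @param ... Unused.
#' @return A one-row tibble: `h1`, `h2`, `h3`, `h4`, `d`, `se`, `z`,
#'   `abba`, `baba`, `n_blocks`, `n_sites`.
#' @method tidy dstat
#' @export
tidy.dstat <- function(x, ...) {
  tibble::tibble(
    h1 = unname(x$quartet["H1"]), h2 = unname(x$quartet["H2"]),
    h3 = unname(x$quartet["H3"]), h4 = unname(x$quartet["H4"]),
    d = x$D, se = x$se, z = x$z,
    abba = x$abba_sum, baba = x$baba_sum,
    n_blocks = x$n_blocks, n_sites = x$n_sites
  )
}

#' One-line summary of a D-statistic result
#' @param x A `dstat` object.
#' @param ... Unused.
#' @return A one-row tibble: `d`, `z`, `significant` (`|z| > 3`).
#' @method glance dstat
#' @export
glance.dstat <- function(x, ...) {
  tibble::tibble(d = x$D, z = x$z, significant = abs(x$z) > 3)
}

#' D statistics across a set of H3 candidates
#'
#' Runs [d_statistic()] for each candidate donor H3 against a fixed
#' (H1, H2, outgroup) frame. By convention figures of differential affinity
#' report positive D when H3 shares more derived alleles with H1; set
#' `positive = "H2"` for the raw Patterson orientation.
#'
#' @param freqs A `freq_table`.
#' @param h3_candidates Character vector of candidate donor populations.
#' @param h1,h2,h4 Fixed populations (h4 = outgroup).
#' @param positive Which sister taxon positive D points to (`"H1"` flips
#'   the sign of the raw statistic; default).
#' @param ... Passed to [d_statistic()].
#' @return A tibble with one row per candidate (columns as [tidy.dstat()]).
#' @export
d_matrix <- function(freqs, h3_candidates, h1, h2, h4,
                     positive = c("H1", "H2"), ...) {
  positive <- match.arg(positive)
  s <- if (positive == "H1") -1 else 1
  purrr::map_dfr(h3_candidates, function(h3) {
    res <- tidy(d_statistic(freqs, quartet(h1, h2, h3, h4), ...))
    res$d <- s * res$d
    res$z <- s * res$z
    res$abba <- NULL
    res$baba <- NULL
    res
  })
}
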