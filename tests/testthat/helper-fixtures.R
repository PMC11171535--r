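# Shared fixture builders and independent brute-force oracles.

# Panel from a haplotype matrix (rows = haplotypes, in sample pairs; columns
# = sites). Positions default to 1..n_sites on one chromosome.
panel_from_haps <- function(haps, pos = NULL, chrom = "1", phased = TRUE,
                            sample_prefix = "s") {
  stopifnot(nrow(haps) %% 2 == 0)
  n_samp <- nrow(haps) / 2
  ns <- ncol(haps)
  if (is.null(pos)) pos <- seq_len(ns)
  a1 <- t(haps[seq(1, nrow(haps), 2), , drop = FALSE])
  a2 <- t(haps[seq(2, nrow(haps), 2), , drop = FALSE])
  genotype_panel(
    tibble::tibble(chrom = chrom, pos = pos, ref = "A", alt = "T"),
    a1, a2, paste0(sample_prefix, seq_len(n_samp)), phased = phased
  )
}

# Build a freq_table directly from per-population frequency vectors and
# called-allele counts (constant per population).
freq_table_from <- function(freq_list, called, pos = NULL, chrom = "1") {
  pops <- names(freq_list)
  ns <- length(freq_list[[1]])
  if (is.null(pos)) pos <- seq_len(ns)
  freq <- do.call(cbind, freq_list)
  colnames(freq) <- pops
  called_m <- matrix(rep(called, each = ns), ns, length(pops),
                     dimnames = list(NULL, pops))
  alt <- round(freq * called_m)
  structure(
    list(sites = tibble::tibble(chrom = chrom, pos = pos, ref = "A",
                                alt = "T"),
         alt = alt, called = called_m, freq = freq, populations = pops),
    class = "freq_table"
  )
}

# --- independent oracles ----------------------------------------------------

# average pairwise Hamming distance per bp within a haplotype set
oracle_pi <- function(haps, length_bp) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(haps[i, ] != haps[j, ])
  }
  tot / choose(n, 2) / length_bp
}

# average pairwise Hamming distance per bp between two haplotype sets
oracle_dxy <- function(haps_a, haps_b, length_bp) {
  tot <- 0
  for (i in seq_len(nrow(haps_a))) {
    for (j in seq_len(nrow(haps_b))) {
      tot <- tot + sum(haps_a[i, ] != haps_b[j, ])
    }
  }
  tot / (nrow(haps_a) * nrow(haps_b)) / length_bp
}

# Tajima's D computed stepwise from first principles on a haplotype matrix
oracle_tajima_d <- function(haps) {
  n <- nrow(haps)
  p <- colMeans(haps)
  seg <- p > 0 & p < 1
  S <- sum(seg)
  if (S == 0 || n < 4) return(NA_real_)
  # pi as the all-pairs average number of differences (not per bp)
  pi_sum <- oracle_pi(haps, 1)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# per-site Hudson FST sums evaluated term by term
oracle_hudson <- function(pa, pb, na, nb) {
  num <- den <- 0
  for (s in seq_along(pa)) {
    num <- num + (pa[s] - pb[s])^2 - pa[s] * (1 - pa[s]) / (na[s] - 1) -
      pb[s] * (1 - pb[s]) / (nb[s] - 1)
    den <- den + pa[s] * (1 - pb[s]) + pb[s] * (1 - pa[s])
  }
  num / den
}

# textbook Weir-Cockerham theta for a single biallelic site, two populations
oracle_wc_site <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# EHH at every extension step recomputed from a bifurcation tree: the sum of
# C(count, 2) over nodes at a given depth, divided by C(n_carriers, 2)
oracle_ehh_from_tree <- function(tree) {
  counts_at_depth <- list()
  walk <- function(node, depth) {
    if (length(node$children) == 0) return(invisible())
    for (ch in node$children) {
      d <- as.character(depth + 1)
      counts_at_depth[[d]] <<- c(counts_at_depth[[d]], ch$count)
      walk(ch, depth + 1)
    }
  }
  walk(tree$root, 0)
  vapply(counts_at_depth, function(k) {
    sum(choose(k, 2)) / choose(tree$n_carriers, 2)
  }, numeric(1))
}

# The documented 10-site filter toy: 100 diploid samples, sites constructed
# so that exactly 2 fail MAF (0.005), 1 fails call rate (0.8), 1 sits on a
# sex chromosome, and 6 pass all rules.
toy_filter_panel <- function() {
  n_samp <- 100
  a1 <- matrix(0L, 10, n_samp)
  a2 <- matrix(0L, 10, n_samp)
  # sites 1-6: common variant, fully called (MAF 0.25)
  for (s in 1:6) a2[s, 1:50] <- 1L
  # sites 7-8: MAF 0.005 (1 alt allele in 200)
  a2[7, 1] <- 1L
  a2[8, 1] <- 1L
  # site 9: call rate 0.8, MAF fine among called (20/160)
  a1[9, 1:20] <- NA_integer_; a2[9, 1:20] <- NA_integer_
  a2[9, 21:40] <- 1L
  # site 10 goes on chromosome X (common variant otherwise)
  a2[10, 1:50] <- 1L
  sites <- tibble::tibble(
    chrom = c(rep("1", 9), "X"), pos = c(1:9, 1) * 100L,
    ref = "A", alt = "T"
  )
  genotype_panel(sites, a1, a2, paste0("s", seq_len(n_samp)))
}
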