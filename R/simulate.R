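#' Simulation configuration for a four-population panel
#'
#' The simulator emulates the fixed topology `((P1, P2), P3), O` with
#' Balding-Nichols drift on each branch and one optional introgression
#' episode from the donor P3 into the recipient P2, confined to a known
#' contiguous tract. Defaults describe the standard recovery experiment:
#' a 10 Mb chromosome carrying 50,000 SNPs, 20 diploids per population,
#' and a 0.8 Mb tract introgressed at admixture fraction 0.5.
#'
#' @param n_sites Number of biallelic sites (default 50000).
#' @param chrom_length_bp Chromosome length in bp (default 1e7).
#' @param samples_per_pop Named integer vector of diploid counts for
#'   `P1`, `P2`, `P3`, `O` (default 20 each).
#' @param drift_f Named vector of Balding-Nichols drift coefficients in
#'   (0, 1) per branch: `p12` (shared P1/P2 ancestor), `p1`, `p2`, `p3`,
#'   `o`. The defaults (0.1, 0.03, 0.03, 0.35, 0.5) yield a weakly
#'   differentiated sister pair (Hudson FST about 0.03), a moderately
#'   diverged donor (about 0.23 to the recipient) and a strongly drifted
#'   outgroup (about 0.3) — the differentiation structure of closely
#'   related domestic populations probed with a congeneric outgroup.
#' @param f Admixture fraction: the fraction of recipient haplotypes whose
#'   tract alleles are resampled from the donor's frequencies (default
#'   0.5; set 0 for the no-gene-flow null).
#' @param tract `c(start, end)` of the introgressed tract in bp, 1-based
#'   inclusive (default `c(5000001, 5800000)`, a 0.8 Mb tract).
#' @param ancestral_freq_beta `c(a, b)` shape of the Beta distribution of
#'   ancestral derived-allele frequencies (default `c(0.8, 0.8)`).
#' @param chrom Chromosome label (default `"1"`, an autosome).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 5e4, chrom_length_bp = 1e7,
                       samples_per_pop = c(P1 = 20, P2 = 20, P3 = 20, O = 20),
                       drift_f = c(p12 = 0.1, p1 = 0.03, p2 = 0.03,
                                   p3 = 0.35, o = 0.5),
                       f = 0.5, tract = c(5000001, 5800000),
                       ancestral_freq_beta = c(0.8, 0.8),
                       chrom = "1", seed = 1L) {
  stopifnot(
    n_sites >= 1, chrom_length_bp >= n_sites,
    all(c("P1", "P2", "P3", "O") %in% names(samples_per_pop)),
    all(samples_per_pop >= 1),
    all(c("p12", "p1", "p2", "p3", "o") %in% names(drift_f)),
    all(drift_f > 0 & drift_f < 1),
    f >= 0, f <= 1, length(tract) == 2
  )
  if (tract[1] < 1 || tract[2] > chrom_length_bp || tract[2] < tract[1]) {
    stop("introgression tract outside the chromosome", call. = FALSE)
  }
  structure(
    list(n_sites = as.integer(n_sites),
         chrom_length_bp = as.integer(chrom_length_bp),
         samples_per_pop = samples_per_pop, drift_f = drift_f, f = f,
         tract = as.integer(tract),
         ancestral_freq_beta = ancestral_freq_beta,
         chrom = as.character(chrom), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Balding-Nichols drift: child frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F)
bn_drift <- function(p, f) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate a phased four-population panel with a planted tract
#'
#' Per site an ancestral derived-allele frequency is drawn from a Beta
#' distribution, drifted down each branch of `((P1, P2), P3), O` under the
#' Balding-Nichols model, and haplotypes are sampled binomially from the
#' resulting population frequencies. With `f > 0`, `round(f * n_hap)`
#' recipient (P2) haplotypes have their alleles inside the tract resampled
#' from the donor (P3) frequencies — contiguous replacement on whole
#' haplotypes, so phase-based statistics see realistic tract structure.
#' Sites are independent outside the tract (no background linkage). With
#' `f = 0` and the same seed the panel is identical to the
#' no-introgression model.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `panel` (phased [genotype_panel()], derived
#'   allele coded 1), `popmap` (popmap tibble), and `truth` (tract, f,
#'   drift coefficients, seed, and the introgressed haplotype indices).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ns <- cfg$n_sites
  pos <- sort(sample.int(cfg$chrom_length_bp, ns))
  p0 <- stats::rbeta(ns, cfg$ancestral_freq_beta[1], cfg$ancestral_freq_beta[2])
  fE <- cfg$drift_f
  p_o <- bn_drift(p0, fE["o"])
  p_3 <- bn_drift(p0, fE["p3"])
  p_12 <- bn_drift(p0, fE["p12"])
  p_1 <- bn_drift(p_12, fE["p1"])
  p_2 <- bn_drift(p_12, fE["p2"])
  pop_freq <- list(P1 = p_1, P2 = p_2, P3 = p_3, O = p_o)

  pops <- c("P1", "P2", "P3", "O")
  haps <- lapply(pops, function(pop) {
    nh <- 2L * cfg$samples_per_pop[[pop]]
    matrix(stats::rbinom(ns * nh, 1L, pop_freq[[pop]]), nrow = ns, ncol = nh)
  })
  names(haps) <- pops

  intro_haps <- integer(0)
  if (cfg$f > 0) {
    nh <- ncol(haps$P2)
    n_intro <- round(cfg$f * nh)
    if (n_intro > 0) {
      intro_haps <- sort(sample.int(nh, n_intro))
      in_tract <- pos >= cfg$tract[1] & pos <= cfg$tract[2]
      n_t <- sum(in_tract)
      if (n_t > 0) {
        repl <- matrix(stats::rbinom(n_t * n_intro, 1L, p_3[in_tract]),
                       nrow = n_t, ncol = n_intro)
        haps$P2[in_tract, intro_haps] <- repl
      }
    }
  }

  samples <- unlist(lapply(pops, function(pop) {
    sprintf("%s_%02d", pop, seq_len(cfg$samples_per_pop[[pop]]))
  }))
  hap_all <- do.call(cbind, haps)
  a1 <- hap_all[, seq(1, ncol(hap_all), by = 2), drop = FALSE]
  a2 <- hap_all[, seq(2, ncol(hap_all), by = 2), drop = FALSE]
  sites <- tibble::tibble(chrom = cfg$chrom, pos = pos, ref = "A", alt = "T")
  panel <- genotype_panel(sites, a1, a2, samples, phased = TRUE)
  pm <- popmap(samples, rep(pops, times = unlist(cfg$samples_per_pop[pops])))
  truth <- list(tract_start = cfg$tract[1], tract_end = cfg$tract[2],
                f = cfg$f, drift_f = as.list(cfg$drift_f), seed = cfg$seed,
                introgressed_haplotypes = intro_haps)
  list(panel = panel, popmap = pm, truth = truth)
}

#' Write a simulated panel as a reusable fixture
#'
#' Emits a phased VCF 4.2, a popmap TSV and a `truth.json` with the planted
#' tract, admixture fraction, drift coefficients and seed. The VCF header
#' records the seed for provenance; the files round-trip through
#' [read_vcf()] / [read_popmap()].
#'
#' @param sim A list from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @return Named character vector of the paths written.
#' @export
write_fixture <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vcf <- file.path(dir, paste0(prefix, ".vcf"))
  pop <- file.path(dir, paste0(prefix, ".popmap.tsv"))
  truth <- file.path(dir, paste0(prefix, ".truth.json"))
  hdr <- c(
    paste0("##source=introscan_simulate_seed_", sim$truth$seed),
    paste0("##introscan_truth=f=", sim$truth$f, ";tract=",
           sim$truth$tract_start, "-", sim$truth$tract_end)
  )
  write_vcf(sim$panel, vcf, extra_header = hdr)
  write_popmap(sim$popmap, pop)
  jsonlite::write_json(sim$truth, truth, auto_unbox = TRUE, digits = NA)
  c(vcf = vcf, popmap = pop, truth = truth)
}
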