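pm4 <- popmap(paste0("s", 1:4), c("A", "A", "B", "B"))

test_that("allele frequencies match a per-sample brute-force recount", {
  set.seed(42)
  sim <- simulate_panel(sim_config(n_sites = 300, chrom_length_bp = 1e5,
                                   samples_per_pop = c(P1 = 4, P2 = 4,
                                                       P3 = 4, O = 4),
                                   tract = c(1, 2e4), seed = 5))
  fr <- allele_freqs(sim$panel, sim$popmap)
  # recount one population sample by sample
  pop <- "P3"
  cols <- sim$popmap$sample[sim$popmap$population == pop]
  for (i in c(1, 57, 300)) {
    alt <- 0L; called <- 0L
    for (s in cols) {
      g <- c(sim$panel$a1[i, s], sim$panel$a2[i, s])
      if (!anyNA(g)) {
        alt <- alt + sum(g)
        called <- called + 2L
      }
    }
    expect_equal(unname(fr$alt[i, pop]), alt)
    expect_equal(unname(fr$called[i, pop]), called)
    expect_equal(unname(fr$freq[i, pop]), alt / called)
  }
})

test_that("allele frequencies handle direct counts and all-missing sites", {
  # pop of two samples 0/0 and 0/1 -> alt_freq 0.25 over 4 called alleles
  p <- panel_from_haps(rbind(c(0L, 0L), c(0L, 0L), c(0L, 1L), c(1L, 0L)),
                       phased = FALSE)
  p$a1[2, 1:2] <- NA_integer_; p$a2[2, 1:2] <- NA_integer_
  pm <- popmap(c("s1", "s2"), c("A", "A"))
  fr <- allele_freqs(p, pm)
  expect_equal(unname(fr$freq[1, "A"]), 0.25)
  expect_equal(unname(fr$called[1, "A"]), 4L)
  expect_true(is.na(fr$freq[2, "A"]))    # site fully missing in the pop
})

test_that("Hudson FST equals the per-site oracle and respects frequency symmetry", {
  set.seed(7)
  ns <- 20
  fr <- freq_table_from(
    list(A = runif(ns), B = runif(ns)),
    called = c(A = 24, B = 18)
  )
  expect_equal(
    fst_hudson_pair(fr, "A", "B"),
    oracle_hudson(fr$freq[, "A"], fr$freq[, "B"], fr$called[, "A"],
                  fr$called[, "B"]),
    tolerance = 1e-12
  )
  # allele relabelling (p -> 1 - p at every site) leaves FST unchanged
  fr_flip <- fr
  fr_flip$freq <- 1 - fr$freq
  fr_flip$alt <- fr$called - fr$alt
  expect_equal(fst_hudson_pair(fr_flip, "A", "B"),
               fst_hudson_pair(fr, "A", "B"), tolerance = 1e-12)
  # fixed difference with large n approaches 1; identical pops sit near 0
  frx <- freq_table_from(list(A = rep(1, 5), B = rep(0, 5)),
                         called = c(A = 1000, B = 1000))
  expect_gt(fst_hudson_pair(frx, "A", "B"), 0.99)
  fri <- freq_table_from(list(A = c(0.3, 0.6), B = c(0.3, 0.6)),
                         called = c(A = 200, B = 200))
  expect_lt(abs(fst_hudson_pair(fri, "A", "B")), 0.02)
})

test_that("Nm follows the island-model closed form and is monotone decreasing", {
  expect_equal(round(nm_from_fst(0.001), 3), 249.750)
  expect_equal(round(nm_from_fst(0.004), 3), 62.250)
  expect_equal(round(nm_from_fst(0.726), 3), 0.094)
  expect_equal(nm_from_fst(1), 0)
  expect_warning(res <- nm_from_fst(0), "Inf")
  expect_identical(res, Inf)
  grid <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(nm_from_fst(grid)) < 0))
})

test_that("the pairwise FST matrix is symmetric and reflects the topology", {
  sim <- simulate_panel(sim_config(n_sites = 5000, chrom_length_bp = 1e6,
                                   tract = c(1, 2e5), f = 0, seed = 2))
  fr <- allele_freqs(sim$panel, sim$popmap)
  m <- fst_matrix(fr)
  expect_equal(m$fst, t(m$fst))
  expect_equal(unname(diag(m$fst)), rep(0, 4))
  # nested topology: sisters are closer than either is to the outgroup
  expect_lt(m$fst["P1", "P2"], m$fst["P1", "O"])
  expect_lt(m$fst["P1", "P2"], m$fst["P1", "P3"])
  td <- tidy(m)
  expect_equal(nrow(td), 6L)
  expect_equal(td$nm, suppressWarnings(nm_from_fst(td$fst)))
})

test_that("windowed Weir-Cockerham FST matches the closed-form single-site oracle", {
  # single site, balanced samples: 4 diploids per pop
  haps <- rbind(
    c(1L), c(1L), c(1L), c(0L), c(1L), c(0L), c(0L), c(0L),  # pop A
    c(0L), c(0L), c(0L), c(0L), c(1L), c(0L), c(0L), c(0L)   # pop B
  )
  p <- panel_from_haps(haps)
  pm <- popmap(paste0("s", 1:8), rep(c("A", "B"), each = 4))
  w <- make_windows(p$sites, 10)
  got <- fst_wc_window(p, pm, "A", "B", w)
  # per-pop observed stats read straight off the haplotypes
  expected <- oracle_wc_site(n1 = 4, p1 = 4 / 8, h1 = 2 / 4,
                             n2 = 4, p2 = 1 / 8, h2 = 1 / 4)
  expect_equal(got$fst, expected, tolerance = 1e-12)

  # identical populations give near-zero windowed FST
  sim <- simulate_panel(sim_config(n_sites = 2000, chrom_length_bp = 4e5,
                                   tract = c(1, 1e5), f = 0, seed = 9))
  pm_same <- sim$popmap
  levels(pm_same$population)[levels(pm_same$population) == "P2"] <- "P1"
  w2 <- make_windows(sim$panel$sites, 1e5)
  # split P1 into two halves labelled A/B: same population, expect ~0
  s1 <- sim$popmap$sample[sim$popmap$population == "P1"]
  pm_split <- popmap(s1, rep(c("A", "B"), each = length(s1) / 2))
  got2 <- fst_wc_window(sim$panel, pm_split, "A", "B", w2)
  expect_true(all(abs(got2$fst) < 0.05, na.rm = TRUE))
})

test_that("genome-wide Weir-Cockerham agrees with Hudson on balanced simulated data", {
  sim <- simulate_panel(sim_config(n_sites = 5000, chrom_length_bp = 1e6,
                                   tract = c(1, 2e5), f = 0, seed = 4))
  fr <- allele_freqs(sim$panel, sim$popmap)
  one_window <- tibble::tibble(chrom = "1", start = 1, end = 1e6,
                               partial = FALSE)
  wc <- fst_wc_window(sim$panel, sim$popmap, "P1", "P3", one_window)$fst
  hud <- fst_hudson_pair(fr, "P1", "P3")
  expect_lt(abs(wc - hud), 0.05)
})

test_that("pi equals all-pairs Hamming enumeration on phased toy data", {
  # two haplotypes differing at 1 site of a 10 bp window -> pi = 0.1
  haps <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L))
  p <- panel_from_haps(haps, pos = c(2L, 5L, 9L))
  pm <- popmap("s1", "A")
  w <- tibble::tibble(chrom = "1", start = 1, end = 10, partial = FALSE)
  expect_equal(pi_window(p, pm, "A", w)$pi, 0.1)
  expect_equal(pi_window(p, pm, "A", w)$pi, oracle_pi(haps, 10))

  # random phased panel, larger n
  set.seed(31)
  haps2 <- matrix(rbinom(8 * 40, 1, 0.3), nrow = 8)
  p2 <- panel_from_haps(haps2)
  pm2 <- popmap(paste0("s", 1:4), rep("A", 4))
  w2 <- tibble::tibble(chrom = "1", start = 1, end = 40, partial = FALSE)
  expect_equal(pi_window(p2, pm2, "A", w2)$pi, oracle_pi(haps2, 40),
               tolerance = 1e-9)
  # monomorphic window
  p3 <- panel_from_haps(matrix(0L, 4, 5))
  expect_equal(pi_window(p3, pm2[1:2, ], "A",
                         tibble::tibble(chrom = "1", start = 1, end = 5,
                                        partial = FALSE))$pi, 0)
})

test_that("dxy equals between-population Hamming enumeration", {
  # one site with pA = pB = 0.5 in a 1 bp window -> dxy = 0.5
  fr <- freq_table_from(list(A = 0.5, B = 0.5), called = c(A = 4, B = 4))
  haps_a <- rbind(c(0L), c(1L))
  haps_b <- rbind(c(0L), c(1L))
  p <- panel_from_haps(rbind(haps_a, haps_b))
  pm <- popmap(c("s1", "s2"), c("A", "B"))
  w <- tibble::tibble(chrom = "1", start = 1, end = 1, partial = FALSE)
  expect_equal(dxy_window(p, pm, "A", "B", w)$dxy, 0.5)
  expect_equal(dxy_window(p, pm, "A", "B", w)$dxy,
               oracle_dxy(haps_a, haps_b, 1))

  set.seed(13)
  ha <- matrix(rbinom(6 * 30, 1, 0.4), nrow = 6)
  hb <- matrix(rbinom(4 * 30, 1, 0.2), nrow = 4)
  p2 <- panel_from_haps(rbind(ha, hb))
  pm2 <- popmap(paste0("s", 1:5), c(rep("A", 3), rep("B", 2)))
  w2 <- tibble::tibble(chrom = "1", start = 1, end = 30, partial = FALSE)
  expect_equal(dxy_window(p2, pm2, "A", "B", w2)$dxy,
               oracle_dxy(ha, hb, 30), tolerance = 1e-9)
  # identical monomorphic populations diverge by zero
  pmono <- panel_from_haps(matrix(1L, 4, 6))
  pmm <- popmap(c("s1", "s2"), c("A", "B"))
  w3 <- tibble::tibble(chrom = "1", start = 1, end = 6, partial = FALSE)
  expect_equal(dxy_window(pmono, pmm, "A", "B", w3)$dxy, 0)
})

test_that("Tajima's D reproduces the n=4 worked instance and the brute-force oracle", {
  haps <- rbind(c(0L, 0L, 0L), c(0L, 1L, 1L), c(1L, 0L, 1L), c(1L, 1L, 0L))
  p <- panel_from_haps(haps)
  pm <- popmap(c("s1", "s2"), c("A", "A"))
  w <- tibble::tibble(chrom = "1", start = 1, end = 3, partial = FALSE)
  got <- tajimas_d_window(p, pm, "A", w)
  expect_equal(got$S, 3L)
  expect_equal(got$tajima_d, oracle_tajima_d(haps), tolerance = 1e-9)
  expect_equal(got$tajima_d, 2.01, tolerance = 0.005)

  # random instances agree with the oracle to numerical precision
  set.seed(99)
  for (rep in 1:5) {
    n_hap <- sample(c(4, 6, 10), 1)
    h <- matrix(rbinom(n_hap * 25, 1, runif(1, 0.1, 0.5)), nrow = n_hap)
    pp <- panel_from_haps(h)
    pmx <- popmap(paste0("s", seq_len(n_hap / 2)), rep("A", n_hap / 2))
    ww <- tibble::tibble(chrom = "1", start = 1, end = 25, partial = FALSE)
    expect_equal(tajimas_d_window(pp, pmx, "A", ww)$tajima_d,
                 oracle_tajima_d(h), tolerance = 1e-9)
  }

  # all-singleton configuration shows the rare-variant excess (D < 0)
  hs <- diag(1L, 10)
  ps <- panel_from_haps(hs)
  pms <- popmap(paste0("s", 1:5), rep("A", 5))
  ws <- tibble::tibble(chrom = "1", start = 1, end = 10, partial = FALSE)
  expect_lt(tajimas_d_window(ps, pms, "A", ws)$tajima_d, 0)

  # degenerate windows are missing, not errors
  pmono <- panel_from_haps(matrix(0L, 4, 3))
  expect_true(is.na(tajimas_d_window(pmono, pm, "A", w)$tajima_d))
})

test_that("windows tile chromosomes from position 1 and flag the partial tail", {
  sites <- tibble::tibble(chrom = c("1", "1", "2"), pos = c(5L, 250001L, 99L))
  w <- make_windows(sites, 1e5)
  expect_equal(w$start[w$chrom == "1"], c(1, 100001, 200001))
  expect_true(w$partial[3])
  idx <- introscan:::window_index(sites, w)
  expect_equal(idx, c(1L, 3L, 4L))
})
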