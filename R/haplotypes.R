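#' Extract phased haplotypes over a region
#'
#' Builds a haplotype matrix (2 rows per sample; columns are sites) from a
#' phased panel. Sites inside the region with any missing call are dropped
#' and counted; the panel must be phased — pseudo-phasing is refused
#' because it corrupts haplotype statistics.
#'
#' @param panel A phased [genotype_panel()].
#' @param pm Optional popmap tibble; when given, haplotypes carry a
#'   population attribute and rows are ordered by population.
#' @param region Optional region string `"chr:start-end"` (1-based
#'   inclusive); default uses all sites.
#' @return An object of class `haplotype_panel`: binary matrix `hap`
#'   (haplotypes x sites, dimnames sample_1/sample_2 x positions), site
#'   tibble `sites`, vectors `sample` and `population` per haplotype row,
#'   and `n_dropped` (sites dropped for missingness).
#' @export
as_haplotypes <- function(panel, pm = NULL, region = NULL) {
  if (!panel$phased) {
    stop("panel is not phased; haplotype statistics need phased input",
         call. = FALSE)
  }
  keep <- rep(TRUE, n_sites(panel))
  if (!is.null(region)) {
    r <- parse_region(region)
    keep <- panel$sites$chrom == r$chrom &
      panel$sites$pos >= r$start & panel$sites$pos <= r$end
  }
  full <- rowSums(!called_matrix(panel)) == 0
  n_dropped <- sum(keep & !full)
  keep <- keep & full
  if (!any(keep)) stop("no fully called phased sites in region", call. = FALSE)
  samples <- panel$samples
  if (!is.null(pm)) {
    absent <- setdiff(pm$sample, samples)
    if (length(absent)) {
      stop("popmap sample(s) absent from panel: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    pm <- dplyr::arrange(pm, .data$population)
    samples <- pm$sample
  }
  a1 <- t(panel$a1[keep, samples, drop = FALSE])
  a2 <- t(panel$a2[keep, samples, drop = FALSE])
  hap <- matrix(0L, 2 * length(samples), ncol(a1))
  hap[seq(1, nrow(hap), by = 2), ] <- a1
  hap[seq(2, nrow(hap), by = 2), ] <- a2
  rownames(hap) <- paste0(rep(samples, each = 2), "_", 1:2)
  colnames(hap) <- panel$sites$pos[keep]
  pop <- if (is.null(pm)) rep(NA_character_, nrow(hap)) else {
    rep(as.character(pm$population), each = 2)
  }
  structure(
    list(hap = hap, sites = panel$sites[keep, , drop = FALSE],
         sample = rep(samples, each = 2), population = pop,
         n_dropped = n_dropped),
    class = "haplotype_panel"
  )
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d haplotypes x %d sites (%d site(s) dropped)\n",
              nrow(x$hap), ncol(x$hap), x$n_dropped))
  invisible(x)
}

#' Major-allele haplotype sharing matrix
#'
#' For each site the major allele is determined over all haplotypes pooled
#' across populations (a 50/50 tie deterministically designates the
#' alternate allele major); the returned binary matrix has a 1 wherever a
#' haplotype carries the major allele. Rows are grouped by population,
#' mirroring haplotype-sharing heatmaps where the pooled major allele gets
#' one colour.
#'
#' @param panel A phased [genotype_panel()].
#' @param pm A popmap tibble.
#' @param region Region string `"chr:start-end"`.
#' @return A list with `matrix` (haplotypes x sites, 1 = carries major
#'   allele), `major_allele` (0/1 per site), `population` (per row), and
#'   `sites`.
#' @export
major_allele_matrix <- function(panel, pm, region = NULL) {
  hp <- as_haplotypes(panel, pm, region)
  p_alt <- colMeans(hp$hap)
  major <- as.integer(p_alt >= 0.5)  # tie -> alt
  m <- 1L * (hp$hap == matrix(major, nrow(hp$hap), ncol(hp$hap),
                              byrow = TRUE))
  dimnames(m) <- dimnames(hp$hap)
  list(matrix = m, major_allele = major, population = hp$population,
       sites = hp$sites)
}

#' Extended haplotype homozygosity around a core site
#'
#' Among haplotypes carrying `core_allele` at `core_pos`,
#' `EHH(x) = sum over prefix groups of C(k, 2) / C(n, 2)`: the probability
#' that two random carriers are identical from the core out to x. EHH is 1
#' at the core and non-increasing with distance; each direction is reported
#' until EHH drops below `truncate` or the region ends.
#'
#' @param hp A `haplotype_panel` from [as_haplotypes()].
#' @param core_pos Core site position (bp; must be a panel site).
#' @param core_allele Core allele (0 or 1).
#' @param truncate Stop extending once EHH falls below this (default 0.05).
#' @return A tibble with columns `pos`, `distance` (bp from core, signed),
#'   `direction` (`"left"`/`"right"`; the core row is `"core"`), `ehh`.
#' @export
ehh <- function(hp, core_pos, core_allele, truncate = 0.05) {
  pos <- hp$sites$pos
  core_idx <- match(core_pos, pos)
  if (is.na(core_idx)) stop("core position not in panel: ", core_pos,
                            call. = FALSE)
  carriers <- hp$hap[, core_idx] == core_allele
  n <- sum(carriers)
  if (n < 2) stop("fewer than 2 carriers of the core allele", call. = FALSE)
  H <- hp$hap[carriers, , drop = FALSE]
  run <- function(idx_seq, direction) {
    grp <- rep(1L, n)
    out <- vector("list", length(idx_seq))
    for (k in seq_along(idx_seq)) {
      j <- idx_seq[k]
      grp <- as.integer(interaction(grp, H[, j], drop = TRUE))
      e <- sum(choose(table(grp), 2)) / choose(n, 2)
      out[[k]] <- tibble::tibble(pos = pos[j], distance = pos[j] - core_pos,
                                 direction = direction, ehh = e)
      if (e < truncate) break
    }
    dplyr::bind_rows(out)
  }
  left <- if (core_idx > 1) run(seq(core_idx - 1, 1), "left") else NULL
  right <- if (core_idx < ncol(H)) {
    run(seq(core_idx + 1, ncol(H)), "right")
  } else NULL
  dplyr::bind_rows(
    left,
    tibble::tibble(pos = core_pos, distance = 0L, direction = "core",
                   ehh = 1),
    right
  ) |> dplyr::arrange(.data$pos)
}

#' Haplotype bifurcation tree from a core site
#'
#' Starting from the carriers of the core allele, haplotypes are
#' partitioned site by site outward from the core; each node records the
#' site, the allele taken and the number of carrier haplotypes following
#' that prefix. Branch counts are non-increasing along any path and the
#' leaf counts always sum to the carrier count.
#'
#' @param hp A `haplotype_panel`.
#' @param core_pos Core site position (bp).
#' @param core_allele Core allele (0 or 1).
#' @param direction `"left"` or `"right"` extension from the core.
#' @param max_steps Maximum number of sites to extend (default all).
#' @return A list of class `bifurcation_tree`: `core_pos`, `core_allele`,
#'   `direction`, `n_carriers`, and `root` — a nested node list
#'   (`pos`, `allele`, `count`, `children`). Serialize with
#'   [bifurcation_json()].
#' @export
bifurcation <- function(hp, core_pos, core_allele,
                        direction = c("right", "left"), max_steps = Inf) {
  direction <- match.arg(direction)
  pos <- hp$sites$pos
  core_idx <- match(core_pos, pos)
  if (is.na(core_idx)) stop("core position not in panel: ", core_pos,
                            call. = FALSE)
  carriers <- which(hp$hap[, core_idx] == core_allele)
  if (length(carriers) < 1) stop("no carriers of the core allele",
                                 call. = FALSE)
  idx_seq <- if (direction == "right") {
    seq(core_idx + 1, length.out = max(0, ncol(hp$hap) - core_idx))
  } else {
    seq(core_idx - 1, length.out = max(0, core_idx - 1), by = -1)
  }
  if (is.finite(max_steps)) idx_seq <- utils::head(idx_seq, max_steps)
  build <- function(rows, depth) {
    if (depth > length(idx_seq) || length(rows) == 0) return(list())
    j <- idx_seq[depth]
    lapply(sort(unique(hp$hap[rows, j])), function(al) {
      sub <- rows[hp$hap[rows, j] == al]
      list(pos = pos[j], allele = as.integer(al), count = length(sub),
           children = build(sub, depth + 1))
    })
  }
  structure(
    list(core_pos = core_pos, core_allele = as.integer(core_allele),
         direction = direction, n_carriers = length(carriers),
         root = list(pos = core_pos, allele = as.integer(core_allele),
                     count = length(carriers),
                     children = build(carriers, 1L))),
    class = "bifurcation_tree"
  )
}

#' Serialize a bifurcation tree as JSON
#' @param tree A `bifurcation_tree`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
bifurcation_json <- function(tree, path = NULL) {
  js <- jsonlite::toJSON(tree[c("core_pos", "core_allele", "direction",
                                "n_carriers", "root")],
                         auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

# leaf counts of a bifurcation tree (depth-first)
bifurcation_leaf_counts <- function(node) {
  if (length(node$children) == 0) return(node$count)
  unlist(lapply(node$children, bifurcation_leaf_counts))
}

#' Pairwise LD r-squared matrix from phased haplotypes
#'
#' `r^2 = (p_AB - p_A p_B)^2 / (p_A (1-p_A) p_B (1-p_B))` computed from
#' haplotype counts. Monomorphic sites get missing rows/columns; the
#' statistic is invariant to allele relabelling at either site.
#'
#' @param hp A `haplotype_panel`.
#' @return A symmetric sites x sites matrix of r-squared values (dimnames
#'   are positions), diagonal 1 for polymorphic sites.
#' @export
ld_r2 <- function(hp) {
  H <- hp$hap
  n <- nrow(H)
  p <- colMeans(H)
  pab <- crossprod(H) / n
  d <- pab - outer(p, p)
  v <- p * (1 - p)
  r2 <- d^2 / outer(v, v)
  r2[v == 0, ] <- NA_real_
  r2[, v == 0] <- NA_real_
  dimnames(r2) <- list(colnames(H), colnames(H))
  r2
}
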