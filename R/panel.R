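#' Construct a genotype panel
#'
#' A genotype panel holds diploid biallelic genotypes for a set of named
#' samples at a set of genomic sites. Sites live in a tibble (`chrom`, `pos`,
#' `ref`, `alt`); genotypes are two integer matrices (`a1`, `a2`) of allele
#' codes, one row per site and one column per sample, with `0` = reference,
#' `1` = alternate and `NA` = missing. Half-calls (one allele missing) are
#' treated as fully missing.
#'
#' @param sites A data frame with columns `chrom` (character), `pos`
#'   (integer, 1-based bp), `ref` and `alt` (single-nucleotide strings).
#'   Positions must be strictly increasing within each chromosome.
#' @param a1,a2 Integer matrices of first/second allele codes,
#'   `nrow(sites)` x `length(samples)`, values in `{0, 1, NA}`.
#' @param samples Character vector of unique sample names.
#' @param phased Logical; `TRUE` if genotypes carry haplotype phase
#'   (panel-wide flag, recorded from the `|` separator on input).
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(sites, a1, a2, samples, phased = FALSE) {
  sites <- tibble::as_tibble(sites)
  stopifnot(
    all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
    is.matrix(a1), is.matrix(a2),
    nrow(a1) == nrow(sites), nrow(a2) == nrow(sites),
    ncol(a1) == length(samples), ncol(a2) == length(samples),
    !anyDuplicated(samples)
  )
  sites$pos <- as.integer(sites$pos)
  ok <- c(0L, 1L, NA_integer_)
  if (!all(a1 %in% ok) || !all(a2 %in% ok)) {
    stop("genotype allele codes must be 0, 1 or NA", call. = FALSE)
  }
  # half-calls collapse to fully missing
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    a1[half] <- NA_integer_
    a2[half] <- NA_integer_
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
    }
  }
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  dimnames(a1) <- dimnames(a2) <- list(NULL, samples)
  structure(
    list(sites = sites, a1 = a1, a2 = a2,
         samples = as.character(samples), phased = isTRUE(phased)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d sites x %d samples (%s), chromosomes: %s\n",
    n_sites(x), length(x$samples),
    if (x$phased) "phased" else "unphased",
    paste(unique(x$sites$chrom), collapse = ", ")
  ))
  invisible(x)
}

#' Number of sites in a panel
#' @param panel A `genotype_panel`.
#' @return Integer site count.
#' @export
n_sites <- function(panel) nrow(panel$sites)

#' Subset a panel by site index and/or samples
#'
#' @param panel A `genotype_panel`.
#' @param sites Integer or logical index over sites (default all).
#' @param samples Character vector of sample names to keep (default all).
#' @return A `genotype_panel`.
#' @export
subset_panel <- function(panel, sites = NULL, samples = NULL) {
  i <- if (is.null(sites)) seq_len(n_sites(panel)) else sites
  j <- if (is.null(samples)) panel$samples else samples
  missing_s <- setdiff(j, panel$samples)
  if (length(missing_s)) {
    stop("samples not in panel: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  }
  genotype_panel(panel$sites[i, , drop = FALSE],
                 panel$a1[i, j, drop = FALSE],
                 panel$a2[i, j, drop = FALSE],
                 j, phased = panel$phased)
}

#' Genotypes as a tidy tibble
#'
#' One row per site x sample, with allele codes and the diploid dosage.
#'
#' @param x A `genotype_panel`.
#' @param ... Unused.
#' @return A tibble with columns `chrom`, `pos`, `sample`, `allele1`,
#'   `allele2`, `dosage`.
#' @method as_tibble genotype_panel
#' @export
as_tibble.genotype_panel <- function(x, ...) {
  tibble::tibble(
    chrom = rep(x$sites$chrom, times = length(x$samples)),
    pos = rep(x$sites$pos, times = length(x$samples)),
    sample = rep(x$samples, each = n_sites(x)),
    allele1 = as.integer(x$a1),
    allele2 = as.integer(x$a2),
    dosage = as.integer(x$a1 + x$a2)
  )
}

# dosage matrix (0/1/2, NA when missing), sites x samples
dosage_matrix <- function(panel) panel$a1 + panel$a2

# logical matrix: site x sample has a full diploid call
called_matrix <- function(panel) !is.na(panel$a1) & !is.na(panel$a2)
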