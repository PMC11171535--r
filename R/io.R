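#' Read a VCF file into a genotype panel
#'
#' Reads a VCF 4.x file (only the GT field is used) and keeps biallelic SNP
#' records. Multiallelic records and records whose REF/ALT are not single
#' nucleotides are skipped with a message. Genotypes are mapped REF -> 0,
#' ALT -> 1, `./.` -> missing; half-calls are treated as fully missing. The
#' panel-wide phase flag is `TRUE` when every called genotype uses the `|`
#' separator.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param samples Optional character vector restricting the panel to these
#'   samples; an absent sample is an error.
#' @return A [genotype_panel()].
#' @export
read_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::tibble(
    chrom = as.character(v@fix[, "CHROM"]),
    pos = as.integer(v@fix[, "POS"]),
    ref = as.character(v@fix[, "REF"]),
    alt = as.character(v@fix[, "ALT"])
  )
  nt <- c("A", "C", "G", "T")
  keep <- !is.na(fix$alt) & fix$ref %in% nt & fix$alt %in% nt
  n_skip <- sum(!keep)
  if (n_skip > 0) {
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  all_samples <- colnames(gt)
  if (!is.null(samples)) {
    absent <- setdiff(samples, all_samples)
    if (length(absent)) {
      stop("requested sample(s) absent from VCF: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    gt <- gt[, samples, drop = FALSE]
    all_samples <- samples
  }
  code <- function(x) {
    out <- rep(NA_integer_, length(x))
    out[x == "0"] <- 0L
    out[x == "1"] <- 1L
    out
  }
  c1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  c2 <- substr(gt, 3L, 3L)
  a1 <- matrix(code(c1), nrow = nrow(fix))
  a2 <- matrix(code(c2), nrow = nrow(fix))
  called <- !is.na(a1) & !is.na(a2)
  phased <- length(gt) > 0 && all(sep[called] == "|")
  genotype_panel(fix, a1, a2, all_samples, phased = phased)
}

#' Write a genotype panel as VCF 4.2 text
#'
#' Emits a minimal deterministic VCF body (GT-only FORMAT). Phased panels
#' use `|` as the genotype separator, unphased panels `/`; missing genotypes
#' are written `./.`.
#'
#' @param panel A [genotype_panel()].
#' @param path Output file path.
#' @param extra_header Optional character vector of additional `##` header
#'   lines (e.g. provenance) inserted after the fileformat line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, extra_header = character()) {
  sep <- if (panel$phased) "|" else "/"
  g1 <- ifelse(is.na(panel$a1), ".", as.character(panel$a1))
  g2 <- ifelse(is.na(panel$a2), ".", as.character(panel$a2))
  gt <- matrix(paste0(g1, sep, g2), nrow = n_sites(panel))
  gt[gt == paste0(".", sep, ".")] <- "./."
  body <- paste(
    panel$sites$chrom, panel$sites$pos,
    paste0(panel$sites$chrom, "_", panel$sites$pos),
    panel$sites$ref, panel$sites$alt, ".", "PASS", ".", "GT",
    apply(gt, 1L, paste, collapse = "\t"),
    sep = "\t"
  )
  header <- c(
    "##fileformat=VCFv4.2",
    extra_header,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$samples), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' Expects a headerless two-column TSV: sample id, population label.
#' Populations keep their first-appearance order.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample` and `population` (factor with
#'   first-appearance level order).
#' @export
read_popmap <- function(path) {
  pm <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "population"),
                          colClasses = "character")
  if (nrow(pm) == 0) stop("empty population map: ", path, call. = FALSE)
  popmap(pm$sample, pm$population)
}

#' Build a population map
#'
#' @param sample Character vector of unique sample ids.
#' @param population Character vector of population labels, same length.
#' @return A tibble with columns `sample`, `population`.
#' @export
popmap <- function(sample, population) {
  if (anyDuplicated(sample)) {
    stop("duplicate sample id(s) in population map: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    sample = as.character(sample),
    population = factor(population, levels = unique(population))
  )
}

#' Write a population map as headerless TSV
#' @param pm A popmap tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(
    data.frame(pm$sample, as.character(pm$population)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Variant filter configuration
#'
#' Defaults reflect cohort-level filtering of a merged diploid call set:
#' minor allele frequency at least 0.01, call rate at least 0.9, and sites
#' restricted to autosomes 1-18.
#'
#' @param min_maf Minimum minor allele frequency (inclusive), in `[0, 0.5]`.
#' @param min_call_rate Minimum fraction of samples with a full diploid
#'   call (inclusive), in `[0, 1]`.
#' @param allowed_chroms Character vector of chromosome labels to keep, or
#'   `NULL` to keep all chromosomes.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_maf = 0.01, min_call_rate = 0.9,
                          allowed_chroms = as.character(1:18)) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            min_call_rate >= 0, min_call_rate <= 1)
  structure(list(min_maf = min_maf, min_call_rate = min_call_rate,
                 allowed_chroms = allowed_chroms),
            class = "filter_config")
}

#' Filter panel variants by chromosome, call rate and MAF
#'
#' Sites are kept when chromosome is allowed, call rate (fraction of samples
#' with a full diploid call) is at least `min_call_rate`, and minor allele
#' frequency (computed over non-missing alleles, all samples pooled) is at
#' least `min_maf`; all boundaries are inclusive. Each removed site is
#' attributed to a single rule (precedence: chromosome, then call rate, then
#' MAF), so rule counts plus retained sites always sum to the input count.
#' Sites with no called alleles have undefined MAF and are removed under the
#' MAF rule unless `min_maf == 0`.
#'
#' @param panel A [genotype_panel()].
#' @param cfg A [filter_config()].
#' @return The filtered `genotype_panel`, with a `filter_report` attribute
#'   (see [filter_report()]). Removing every site warns but does not error.
#' @export
filter_variants <- function(panel, cfg = filter_config()) {
  called <- called_matrix(panel)
  n_called_gt <- rowSums(called)
  call_rate <- n_called_gt / length(panel$samples)
  dos <- dosage_matrix(panel)
  alt_alleles <- rowSums(dos, na.rm = TRUE)
  tot_alleles <- 2 * n_called_gt
  p <- ifelse(tot_alleles > 0, alt_alleles / tot_alleles, NA_real_)
  maf <- pmin(p, 1 - p)

  chrom_ok <- if (is.null(cfg$allowed_chroms)) {
    rep(TRUE, n_sites(panel))
  } else {
    panel$sites$chrom %in% cfg$allowed_chroms
  }
  rate_ok <- call_rate >= cfg$min_call_rate
  maf_ok <- ifelse(is.na(maf), cfg$min_maf == 0, maf >= cfg$min_maf)

  fail_chrom <- !chrom_ok
  fail_rate <- chrom_ok & !rate_ok
  fail_maf <- chrom_ok & rate_ok & !maf_ok
  keep <- chrom_ok & rate_ok & maf_ok

  report <- tibble::tibble(
    rule = c("chromosome", "call_rate", "maf", "retained"),
    count = c(sum(fail_chrom), sum(fail_rate), sum(fail_maf), sum(keep))
  )
  if (!any(keep)) {
    warning("all sites removed by variant filters", call. = FALSE)
  }
  out <- subset_panel(panel, sites = which(keep))
  attr(out, "filter_report") <- report
  out
}

#' Per-rule removal counts from the last filter
#'
#' @param panel A panel returned by [filter_variants()].
#' @return A tibble with columns `rule` and `count`; rows for the
#'   `chromosome`, `call_rate` and `maf` rules plus a `retained` row, which
#'   sum to the pre-filter site count.
#' @export
filter_report <- function(panel) {
  rep <- attr(panel, "filter_report")
  if (is.null(rep)) stop("panel has no filter report", call. = FALSE)
  rep
}
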