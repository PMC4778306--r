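#' Define a genome for simulation and binning
#'
#' A genome spec is a tibble with one row per chromosome carrying the physical
#' length, the meiotic map length, and the biparental SNP positions used by the
#' GBS observation model. It is the first argument of the simulator and of the
#' bin builder.
#'
#' @param length_bp Numeric vector of chromosome physical lengths in base
#'   pairs.
#' @param length_cm Numeric vector of chromosome map lengths in centiMorgans
#'   (meiotic scale, i.e. expected crossovers per gamete times 100).
#' @param n_snps Integer vector: number of segregating SNPs to place on each
#'   chromosome (evenly spaced). Ignored when `snp_pos` is given.
#' @param snp_pos Optional list of integer vectors of strictly increasing
#'   1-based SNP positions, one per chromosome.
#' @param chrom Optional chromosome names; defaults to `"chr1"..`.
#'
#' @return A tibble of class `genome_spec` with columns `chrom`, `length_bp`,
#'   `length_cm`, `n_snps` and list-column `snp_pos`.
#' @examples
#' genome_spec(length_bp = c(5e6, 4e6), length_cm = c(90, 70), n_snps = 200)
#' @export
genome_spec <- function(length_bp, length_cm, n_snps = 1000, snp_pos = NULL,
                        chrom = NULL) {
  k <- length(length_bp)
  stopifnot(length(length_cm) == k)
  if (sum(length_bp) <= 0) abort("total physical genome length must be > 0")
  if (any(length_cm <= 0) || any(length_cm >= 400)) {
    abort("per-chromosome map length must lie in (0, 400) cM")
  }
  chrom <- chrom %||% paste0("chr", seq_len(k))
  if (is.null(snp_pos)) {
    n_snps <- rep_len(as.integer(n_snps), k)
    snp_pos <- map2(length_bp, n_snps, function(L, n) {
      as.integer(round(seq(L / (n + 1), L * n / (n + 1), length.out = n)))
    })
  } else {
    stopifnot(length(snp_pos) == k)
    snp_pos <- map(snp_pos, function(p) as.integer(sort(p)))
  }
  ok <- map2(snp_pos, length_bp, function(p, L) {
    length(p) == 0 || (p[1] >= 1 && tail(p, 1) <= L && all(diff(p) > 0))
  })
  if (!all(unlist(ok))) {
    abort("SNP positions must be strictly increasing, 1-based, within the chromosome")
  }
  out <- tibble(
    chrom = as.character(chrom),
    length_bp = as.numeric(length_bp),
    length_cm = as.numeric(length_cm),
    n_snps = lengths(snp_pos),
    snp_pos = snp_pos
  )
  class(out) <- c("genome_spec", class(out))
  out
}

#' Default maize-like genome spec
#'
#' Ten chromosomes with the physical and genetic lengths of the published
#' Ye478 x Qi319 RIL bin map (2059.7 Mb, 1545.65 cM in total) and a SNP
#' density chosen to match its 88,268 segregating GBS SNPs (about 43 per Mb).
#'
#' @param snps_per_mb SNP density per Mb (default 43).
#' @return A [genome_spec()] tibble with 10 chromosomes.
#' @examples
#' spec <- maize_genome_spec(snps_per_mb = 2)
#' sum(spec$length_cm)
#' @export
maize_genome_spec <- function(snps_per_mb = 43) {
  mb <- c(301.43, 237.89, 232.23, 242.03, 217.93,
          169.38, 176.81, 175.35, 157.02, 149.63)
  cm <- c(239.48, 151.46, 163.33, 163.22, 170.86,
          120.38, 143.24, 142.66, 122.05, 128.97)
  genome_spec(
    length_bp = mb * 1e6,
    length_cm = cm,
    n_snps = pmax(2L, as.integer(round(mb * snps_per_mb)))
  )
}

assert_genome_spec <- function(spec) {
  if (!inherits(spec, "genome_spec")) {
    abort("`spec` must be a genome_spec (see genome_spec())")
  }
  invisible(spec)
}
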