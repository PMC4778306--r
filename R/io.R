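#' Read and write the pipeline's tabular formats
#'
#' SNP matrices travel as TSV (rows = SNPs: `snp_id`, `chrom`, `pos`, one
#' call column per line, calls in `A/B/H/N`) or as a minimal GT-only VCF in
#' which the two parents are the first two samples (always `0/0` and `1/1`).
#' Phenotypes travel as CSV (`ril`, `env`, `rep`, one column per trait).
#'
#' @param snp,pheno Tibbles as produced by [observe_gbs()] /
#'   [simulate_phenotypes()].
#' @param path File path.
#' @name rilqtl-io
NULL

#' @rdname rilqtl-io
#' @export
write_snp_tsv <- function(snp, path) {
  readr::write_tsv(snp, path)
  invisible(path)
}

#' @rdname rilqtl-io
#' @param call_symbols Named character vector mapping the file's call symbols
#'   onto `A/B/H/N` (names = file symbols), for external matrices using a
#'   different alphabet.
#' @export
read_snp_tsv <- function(path, call_symbols = NULL) {
  snp <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           snp_id = "c", chrom = "c", pos = "d",
                           .default = "c"
                         ))
  if (!is.null(call_symbols)) {
    for (col in snp_call_cols(snp)) {
      snp[[col]] <- unname(call_symbols[snp[[col]]])
    }
  }
  bad <- !vapply(snp[snp_call_cols(snp)],
                 function(x) all(x %in% CALL_LEVELS), logical(1))
  if (any(bad)) abort("SNP calls outside the A/B/H/N alphabet after mapping")
  snp
}

#' @rdname rilqtl-io
#' @param parents Sample names used for the two parental columns in the VCF.
#' @export
write_snp_vcf <- function(snp, path, parents = c("Ye478", "Qi319")) {
  rils <- snp_call_cols(snp)
  gt <- c(A = "0/0", B = "1/1", H = "0/1", N = "./.")
  mat <- vapply(rils, function(id) unname(gt[snp[[id]]]),
                character(nrow(snp)))
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", parents, rils), collapse = "\t")
  )
  body <- paste(
    snp$chrom, as.integer(snp$pos), snp$snp_id, "A", "T", ".", "PASS", ".",
    "GT", "0/0", "1/1",
    apply(mat, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname rilqtl-io
#' @export
read_snp_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("reading VCF requires the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  samples <- colnames(gt)
  # first two samples are the parents; their phases define A and B
  rils <- samples[-(1:2)]
  map_gt <- c("0/0" = "A", "0|0" = "A", "1/1" = "B", "1|1" = "B",
              "0/1" = "H", "1/0" = "H", "0|1" = "H", "1|0" = "H")
  calls <- map(rils, function(id) {
    out <- unname(map_gt[gt[, id]])
    out[is.na(out)] <- "N"
    out
  })
  names(calls) <- rils
  bind_cols(
    tibble(
      snp_id = rownames(gt),
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = BiocGenerics::start(rr)
    ),
    as_tibble(calls)
  )
}

#' @rdname rilqtl-io
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_csv(pheno, path)
  invisible(path)
}

#' @rdname rilqtl-io
#' @export
read_phenotypes <- function(path) {
  pheno <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             ril = "c", env = "c", rep = "i",
                             .default = "d"
                           ))
  if (!all(c("ril", "env", "rep") %in% names(pheno))) {
    abort("phenotype file needs columns ril, env, rep")
  }
  pheno
}
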