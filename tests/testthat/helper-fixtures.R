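# Shared fixtures and independent oracles used across test files.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# small three-chromosome genome used by most pipeline-level tests
small_spec <- function(n_snps = c(900, 750, 600)) {
  genome_spec(
    length_bp = c(3e7, 2.5e7, 2e7),
    length_cm = c(120, 100, 90),
    n_snps = n_snps
  )
}

# Brute-force sliding-window oracle: recount every window directly from the
# call vector, independent of the cumsum implementation.
oracle_windows <- function(calls, window = 15, hom_threshold = 11) {
  inf <- which(calls %in% c("A", "B"))
  n <- length(inf)
  if (n == 0) return(character(0))
  if (n < window) {
    th <- ceiling(hom_threshold / window * n)
    starts <- 1
    ends <- n
  } else {
    th <- hom_threshold
    starts <- seq_len(n - window + 1)
    ends <- starts + window - 1
  }
  vapply(seq_along(starts), function(k) {
    v <- calls[inf[starts[k]:ends[k]]]
    na <- sum(v == "A")
    nb <- sum(v == "B")
    if (na >= th) "A" else if (nb >= th) "B" else "H"
  }, character(1))
}

# Closed-form simple-regression LOD oracle via explicit normal equations.
oracle_lod <- function(x, y) {
  n <- length(y)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  rss1 <- sum((y - b0 - b1 * x)^2)
  rss0 <- sum((y - mean(y))^2)
  list(lod = n / 2 * log10(rss0 / rss1), beta = b1,
       pve = 100 * (1 - rss1 / rss0))
}

# Build a wide SNP matrix tibble directly from per-line call vectors.
make_snp_matrix <- function(calls_by_ril, pos = NULL, chrom = "chr1") {
  n <- length(calls_by_ril[[1]])
  tibble(
    snp_id = sprintf("snp%05d", seq_len(n)),
    chrom = chrom,
    pos = pos %||% as.numeric(seq_len(n) * 1000)
  ) %>% bind_cols(as_tibble(calls_by_ril))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# a hand-made qtl_scan-shaped tibble for interval logic tests
fake_scan <- function(lod, chrom = "chr1", trait = "PH", env = "E1") {
  n <- length(lod)
  out <- tibble(
    point = seq_len(n),
    bin_id = sprintf("mk%04d", seq_len(n)),
    chrom = chrom,
    pos_cm = as.numeric(seq_len(n)),
    pos_bp = as.numeric(seq_len(n)) * 1e6,
    start_bp = (seq_len(n) - 1) * 1e6,
    end_bp = seq_len(n) * 1e6,
    is_bin = TRUE,
    lod = lod,
    effect = 1,
    pve = lod
  )
  structure(out, n = 100L, trait = trait, env = env,
            class = c("qtl_scan", class(out)))
}

ref_path <- function(file) system.file("extdata", file, package = "rilqtl")

# reference QTL table (published Ye478 x Qi319 map) in qtl_result shape
ref_qtl_table <- function() {
  readr::read_tsv(ref_path("ye478_qi319_qtl_reference.tsv"),
                  show_col_types = FALSE) %>%
    mutate(ci_start_bp = ci_start_mb * 1e6, ci_end_bp = ci_end_mb * 1e6)
}
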