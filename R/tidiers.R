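#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a QTL scan profile
#'
#' @param x A `qtl_scan` from [scan_qtl()].
#' @param ... Unused.
#' @return The profile as a plain tibble with `trait` and `env` columns.
#' @method tidy qtl_scan
#' @export
tidy.qtl_scan <- function(x, ...) {
  out <- as_tibble(x)
  mutate(out, trait = attr(x, "trait"), env = attr(x, "env"), .before = 1)
}

#' @rdname tidy.qtl_scan
#' @method glance qtl_scan
#' @export
glance.qtl_scan <- function(x, ...) {
  i <- which.max(x$lod)
  tibble(
    trait = attr(x, "trait"), env = attr(x, "env"), n = attr(x, "n"),
    n_points = nrow(x), max_lod = x$lod[i], peak_chrom = x$chrom[i],
    peak_bin = x$bin_id[i], peak_bp = x$pos_bp[i]
  )
}

#' Tidy ANOVA variance components
#'
#' @param x A `variance_components` from [anova_components()].
#' @param ... Unused.
#' @return One row per component: `component`, `variance`, `fraction` (share
#'   of line-mean phenotypic variance).
#' @method tidy variance_components
#' @export
tidy.variance_components <- function(x, ...) {
  frac <- variance_partition(x)
  tibble(
    component = c("genotype", "gxe", "error"),
    variance = c(x$genotype, x$gxe, x$error),
    fraction = c(frac$genotype, frac$gxe, frac$residual)
  )
}

#' @rdname tidy.variance_components
#' @method glance variance_components
#' @export
glance.variance_components <- function(x, ...) {
  tibble(
    trait = x$trait, n_lines = x$n_lines, n_env = x$n_env, n_rep = x$n_rep,
    heritability = heritability(x)
  )
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation LOD threshold: %.3f (alpha %.2f, %d permutations; effective %.3f with floor %.1f)\n",
    x$threshold, x$alpha, x$n_perm, x$effective, x$lod_floor
  ))
  invisible(x)
}
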