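#' Forward simulation of a selfed RIL population
#'
#' `breed_ril_population()` breeds recombinant inbred lines by single-seed
#' descent from a biparental F1: each generation one offspring is produced by
#' two independent meioses of the current individual. Crossovers per
#' chromosome are Poisson with mean `length_cm / 100` (no interference) and
#' crossover positions are uniform on the genetic scale, mapped to base pairs
#' through a linear cM-bp relation. After `n_selfing` generations the expected
#' residual heterozygous genome fraction is `2^-n_selfing` and the expected
#' junction count per line approaches twice the map length in Morgans.
#'
#' Segments are reported half-open `(start_bp, end_bp]`; the first segment of
#' each chromosome starts at 0 and the last ends at the chromosome length, so
#' segment lengths are `end_bp - start_bp`.
#'
#' @param spec A [genome_spec()].
#' @param n_rils Number of lines to breed (default 314).
#' @param n_selfing Number of selfing generations after the F1 (default 10,
#'   i.e. F11 lines).
#' @param seed Optional integer seed. Per-line substreams are derived from it
#'   so individual lines are reproducible.
#' @return A tibble with columns `ril`, `chrom`, `start_bp`, `end_bp`,
#'   `founder` (`"A"`, `"B"` or `"H"`), class `ril_mosaic`.
#' @examples
#' spec <- genome_spec(c(1e7, 8e6), c(90, 70), n_snps = 100)
#' moz <- breed_ril_population(spec, n_rils = 5, seed = 1)
#' mosaic_stats(moz)
#' @export
breed_ril_population <- function(spec, n_rils = 314, n_selfing = 10,
                                 seed = NULL) {
  assert_genome_spec(spec)
  if (n_rils < 1) abort("`n_rils` must be >= 1")
  if (n_selfing < 0) abort("`n_selfing` must be >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  ril_seeds <- sample.int(.Machine$integer.max - 1L, n_rils)
  ids <- ril_ids(n_rils)

  per_ril <- map(seq_len(n_rils), function(i) {
    withr::with_seed(ril_seeds[i], {
      map(seq_len(nrow(spec)), function(ci) {
        breed_one_chrom(spec$length_bp[ci], spec$length_cm[ci], n_selfing)
      })
    })
  })

  rows <- map2(per_ril, ids, function(chroms, id) {
    segs <- map2(chroms, spec$chrom, function(m, ch) {
      tibble(
        chrom = ch,
        start_bp = c(0, head(m$ends, -1)),
        end_bp = m$ends,
        founder = c("A", "B", "H")[m$geno]
      )
    })
    mutate(list_rbind(segs), ril = id, .before = 1)
  })
  out <- list_rbind(rows)
  class(out) <- c("ril_mosaic", class(out))
  out
}

ril_ids <- function(n) sprintf("RIL%0*d", max(3L, nchar(n)), seq_len(n))

# One chromosome of one line, bred by single-seed descent.
# Haplotypes are lists (ends, fnd) of segment end positions and founder ids.
breed_one_chrom <- function(L_bp, L_cm, n_selfing) {
  h1 <- list(ends = L_bp, fnd = 1L)
  h2 <- list(ends = L_bp, fnd = 2L)
  if (n_selfing > 0) {
    for (g in seq_len(n_selfing)) {
      g1 <- meiosis(h1, h2, L_bp, L_cm)
      g2 <- meiosis(h1, h2, L_bp, L_cm)
      h1 <- g1
      h2 <- g2
    }
  }
  hap_merge(h1, h2)
}

# A single gamete: Poisson(L_cm/100) crossovers, uniform on the genetic scale
# (linear cM-bp relation), alternating between the two parental haplotypes.
meiosis <- function(h1, h2, L_bp, L_cm) {
  nco <- rpois(1L, L_cm / 100)
  first <- sample.int(2L, 1L)
  if (nco == 0L) {
    return(if (first == 1L) h1 else h2)
  }
  x <- sort(runif(nco, 0, L_bp))
  cuts <- sort(unique(c(h1$ends, h2$ends, x)))
  active <- (first - 1L + findInterval(cuts, x, left.open = TRUE)) %% 2L
  f1 <- h1$fnd[findInterval(cuts, h1$ends, left.open = TRUE) + 1L]
  f2 <- h2$fnd[findInterval(cuts, h2$ends, left.open = TRUE) + 1L]
  f <- ifelse(active == 0L, f1, f2)
  keep <- c(f[-length(f)] != f[-1L], TRUE)
  list(ends = cuts[keep], fnd = f[keep])
}

# Diplotype -> genotype mosaic (1 = AA, 2 = BB, 3 = het).
hap_merge <- function(h1, h2) {
  cuts <- sort(unique(c(h1$ends, h2$ends)))
  f1 <- h1$fnd[findInterval(cuts, h1$ends, left.open = TRUE) + 1L]
  f2 <- h2$fnd[findInterval(cuts, h2$ends, left.open = TRUE) + 1L]
  g <- ifelse(f1 == f2, f1, 3L)
  keep <- c(g[-length(g)] != g[-1L], TRUE)
  list(ends = cuts[keep], geno = g[keep])
}

#' Simulate one gamete from a pair of parental haplotypes
#'
#' Exposes the meiosis model used by [breed_ril_population()]: the crossover
#' count is Poisson with mean `map_length_cm / 100`, crossover positions are
#' uniform on the genetic scale and mapped linearly to base pairs, and the
#' gamete alternates between the two haplotypes at each crossover.
#'
#' @param haplotypes A tibble with columns `hap` (1 or 2), `start_bp`,
#'   `end_bp`, `founder`; each haplotype must tile `(0, length_bp]`.
#' @param map_length_cm Chromosome map length in cM (> 0).
#' @param length_bp Chromosome physical length.
#' @param seed Optional integer seed.
#' @return A tibble `start_bp`, `end_bp`, `founder` tiling the chromosome.
#' @examples
#' haps <- tibble::tibble(
#'   hap = c(1, 2), start_bp = 0, end_bp = 1e6, founder = c("A", "B")
#' )
#' simulate_gamete(haps, map_length_cm = 150, length_bp = 1e6, seed = 1)
#' @export
simulate_gamete <- function(haplotypes, map_length_cm, length_bp,
                            seed = NULL) {
  if (map_length_cm <= 0) abort("`map_length_cm` must be > 0")
  if (!is.null(seed)) withr::local_seed(seed)
  hs <- map(1:2, function(k) {
    h <- arrange(filter(haplotypes, .data$hap == k), .data$start_bp)
    if (nrow(h) == 0 || abs(tail(h$end_bp, 1) - length_bp) > 1e-9) {
      abort("each haplotype must tile the chromosome up to `length_bp`")
    }
    list(ends = h$end_bp, fnd = match(h$founder, c("A", "B", "H")))
  })
  g <- meiosis(hs[[1]], hs[[2]], length_bp, map_length_cm)
  tibble(
    start_bp = c(0, head(g$ends, -1)),
    end_bp = g$ends,
    founder = c("A", "B", "H")[g$fnd]
  )
}

#' Per-line junction counts and heterozygosity of a simulated population
#'
#' @param mosaics A `ril_mosaic` tibble from [breed_ril_population()].
#' @return A tibble with one row per line: `ril`, `n_junctions` (boundaries
#'   between adjacent segments of different founder, summed over
#'   chromosomes), `het_fraction` (fraction of the genome heterozygous).
#' @export
mosaic_stats <- function(mosaics) {
  mosaics %>%
    mutate(len = .data$end_bp - .data$start_bp) %>%
    group_by(.data$ril, .data$chrom) %>%
    summarise(
      junc = n() - 1L,
      het_len = sum(.data$len[.data$founder == "H"]),
      len = sum(.data$len),
      .groups = "drop"
    ) %>%
    group_by(.data$ril) %>%
    summarise(
      n_junctions = sum(.data$junc),
      het_fraction = sum(.data$het_len) / sum(.data$len),
      .groups = "drop"
    )
}

# founder/genotype code of each line at given positions on one chromosome;
# returns integers 1 (A), 2 (B), 3 (H)
mosaic_codes_at <- function(seg, pos) {
  idx <- findInterval(pos, seg$end_bp, left.open = TRUE) + 1L
  match(seg$founder[idx], c("A", "B", "H"))
}

#' GBS-like sparse observation of a simulated population
#'
#' Each segregating SNP of each line is observed independently with
#' probability `observe_rate` (low-coverage GBS sees only a few percent of
#' the segregating sites per line). An observed call is the founder allele at
#' that position, flipped to the other parent's allele with probability
#' `allele_error_rate`; heterozygous segments emit either allele with
#' probability 1/2 (a single low-coverage read cannot reveal a het).
#' Unobserved entries are `"N"`.
#'
#' @param mosaics A `ril_mosaic` tibble.
#' @param spec The [genome_spec()] carrying SNP positions.
#' @param observe_rate Per-SNP, per-line observation probability in `[0, 1]`.
#' @param allele_error_rate Allele flip probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A wide SNP matrix tibble: `snp_id`, `chrom`, `pos`, then one
#'   character column per line with calls in `A/B/N`.
#' @export
observe_gbs <- function(mosaics, spec, observe_rate = 0.05,
                        allele_error_rate = 0.01, seed = NULL) {
  assert_genome_spec(spec)
  if (observe_rate < 0 || observe_rate > 1 ||
      allele_error_rate < 0 || allele_error_rate > 1) {
    abort("rates must lie in [0, 1]")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  rils <- unique(mosaics$ril)
  by_ril <- split(mosaics, factor(mosaics$ril, levels = rils))
  n_tot <- sum(lengths(spec$snp_pos))

  cols <- map(by_ril, function(m) {
    by_chrom <- split(m, factor(m$chrom, levels = spec$chrom))
    calls <- map2(by_chrom, spec$snp_pos, function(seg, pos) {
      g <- mosaic_codes_at(seg, pos)
      allele <- g
      het <- g == 3L
      if (any(het)) allele[het] <- sample.int(2L, sum(het), replace = TRUE)
      if (allele_error_rate > 0) {
        flip <- runif(length(pos)) < allele_error_rate
        allele[flip] <- 3L - allele[flip]
      }
      out <- c("A", "B")[allele]
      out[runif(length(pos)) >= observe_rate] <- "N"
      out
    })
    unlist(calls, use.names = FALSE)
  })
  names(cols) <- rils

  base <- tibble(
    snp_id = sprintf("snp%0*d", max(5L, nchar(n_tot)), seq_len(n_tot)),
    chrom = rep(spec$chrom, lengths(spec$snp_pos)),
    pos = unlist(spec$snp_pos, use.names = FALSE)
  )
  bind_cols(base, as_tibble(cols))
}

#' Specify the genetic architecture of simulated traits
#'
#' Bundles the planted QTL (position and additive effect, with positive
#' effects meaning the B/Qi319 allele increases the trait) with the trait
#' model used by [simulate_phenotypes()]:
#' `y(line, env, rep) = mean + env_offset + sum(a_q * x_q) + gxe + resid`,
#' where `x_q` is -1/0/+1 for the A-homozygous / heterozygous / B-homozygous
#' genotype at the QTL.
#'
#' @param qtl Tibble with columns `trait`, `chrom`, `pos_bp`, `add`.
#' @param trait_means Named numeric vector of grand means per trait.
#' @param env_offsets Matrix (traits x environments, rownames = traits) of
#'   environment offsets; the number of columns sets the number of
#'   environments.
#' @param gxe_sd,resid_sd Named numeric vectors: SD of the line-by-environment
#'   interaction deviate and of the replicate-level residual, per trait.
#' @param n_rep Replicates per environment (default 2).
#' @return A list of class `qtl_truth`.
#' @seealso [default_qtl_truth()]
#' @export
qtl_truth <- function(qtl, trait_means, env_offsets, gxe_sd, resid_sd,
                      n_rep = 2) {
  traits <- names(trait_means)
  stopifnot(
    all(qtl$trait %in% traits),
    all(rownames(env_offsets) == traits),
    all(traits %in% names(gxe_sd)), all(traits %in% names(resid_sd)),
    n_rep >= 1, ncol(env_offsets) >= 1, all(is.finite(qtl$add))
  )
  structure(
    list(
      qtl = as_tibble(qtl), trait_means = trait_means,
      env_offsets = env_offsets, gxe_sd = gxe_sd, resid_sd = resid_sd,
      n_env = ncol(env_offsets), n_rep = n_rep
    ),
    class = "qtl_truth"
  )
}

#' Default trait architecture for the maize-like simulation
#'
#' Three plant-architecture traits measured in three environments with two
#' replicates: plant height (PH, cm), ear height (EH, cm) and internode
#' number (IN). Grand means and environment offsets follow the published
#' Ye478 x Qi319 trait table; planted QTL include a pleiotropic region on
#' chromosome 10 affecting all three traits, and effect sizes are chosen so
#' the line-mean broad-sense heritabilities land near the reported 0.8-0.95
#' range.
#'
#' @param spec The [genome_spec()] the positions must fit (default
#'   [maize_genome_spec()] layout, 10 chromosomes).
#' @return A `qtl_truth` object.
#' @export
default_qtl_truth <- function(spec = maize_genome_spec()) {
  assert_genome_spec(spec)
  qtl <- tibble(
    trait = c("PH", "PH", "PH", "EH", "EH", "IN", "IN"),
    chrom = c("chr1", "chr2", "chr10", "chr1", "chr10", "chr8", "chr10"),
    pos_bp = c(165e6, 197e6, 83e6, 95e6, 87e6, 110e6, 87e6),
    add = c(6, 5, 8, 5, 5, 0.5, 0.45)
  )
  means <- c(PH = 209.1, EH = 78.5, IN = 15.3)
  offs <- rbind(
    PH = c(-8.2, 8.5, -0.3),
    EH = c(1.6, -0.9, -0.7),
    IN = c(-0.6, 0.3, 0.3)
  )
  colnames(offs) <- paste0("E", 1:3)
  qtl_truth(
    qtl, means, offs,
    gxe_sd = c(PH = 2.5, EH = 2.0, IN = 0.35),
    resid_sd = c(PH = 8.0, EH = 7.5, IN = 0.7),
    n_rep = 2
  )
}

#' Simulate replicated multi-environment phenotypes
#'
#' @param mosaics A `ril_mosaic` tibble.
#' @param truth A [qtl_truth()] object; every planted QTL must lie on a
#'   chromosome present in `mosaics`.
#' @param seed Optional integer seed.
#' @return A tibble `ril`, `env`, `rep`, then one numeric column per trait.
#' @export
simulate_phenotypes <- function(mosaics, truth, seed = NULL) {
  stopifnot(inherits(truth, "qtl_truth"))
  if (!all(truth$qtl$chrom %in% mosaics$chrom)) {
    abort("planted QTL reference chromosomes absent from the mosaics")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  rils <- unique(mosaics$ril)
  n <- length(rils)
  e <- truth$n_env
  r <- truth$n_rep
  envs <- colnames(truth$env_offsets) %||% paste0("E", seq_len(e))

  # +1/0/-1 coding of every line at every planted QTL
  xq <- map_dbl_matrix(mosaics, truth$qtl, rils)

  grid <- tidyr::expand_grid(ril = rils, env = envs, rep = seq_len(r))
  traits <- names(truth$trait_means)
  vals <- map(traits, function(tr) {
    rows <- which(truth$qtl$trait == tr)
    gen <- if (length(rows)) {
      as.vector(xq[, rows, drop = FALSE] %*% truth$qtl$add[rows])
    } else {
      rep(0, n)
    }
    gxe <- matrix(rnorm(n * e, 0, truth$gxe_sd[[tr]]), n, e,
                  dimnames = list(rils, envs))
    mu <- truth$trait_means[[tr]] +
      truth$env_offsets[tr, grid$env] +
      gen[match(grid$ril, rils)] +
      gxe[cbind(match(grid$ril, rils), match(grid$env, envs))]
    mu + rnorm(nrow(grid), 0, truth$resid_sd[[tr]])
  })
  names(vals) <- traits
  bind_cols(grid, as_tibble(vals))
}

# lines x QTL matrix of -1/0/+1 codings at the planted QTL positions
map_dbl_matrix <- function(mosaics, qtl, rils) {
  by_ril <- split(mosaics, factor(mosaics$ril, levels = rils))
  out <- matrix(0, length(rils), nrow(qtl))
  for (q in seq_len(nrow(qtl))) {
    codes <- map_int(by_ril, function(m) {
      seg <- m[m$chrom == qtl$chrom[q], ]
      mosaic_codes_at(seg, qtl$pos_bp[q])
    })
    out[, q] <- c(-1, 1, 0)[codes]
  }
  rownames(out) <- rils
  out
}
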