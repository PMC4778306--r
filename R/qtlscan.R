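#' Genotype expectations at bins and pseudomarkers
#'
#' Converts bin genotypes to the numeric coding used by the regression scan:
#' -1 for the A (Ye478) homozygote, +1 for the B (Qi319) homozygote, 0 for
#' heterozygotes. Missing genotypes, and pseudomarkers inserted every
#' `step_cm` between bins, get the conditional expectation of the coding
#' given the nearest flanking homozygous bins under the selfed-RIL Markov
#' model: cM gaps are inverted through [kosambi_inv()] and expanded to RIL
#' recombination frequencies with [ril_expand()]. Heterozygous flanks are
#' treated as uninformative; a line with no homozygous calls on a chromosome
#' codes to 0 there.
#'
#' @param bins A `bin_map` tibble from [build_bins()].
#' @param gmap The matching `genetic_map` from [build_genetic_map()].
#' @param step_cm Pseudomarker spacing in cM; 0 scans markers only
#'   (default 1).
#' @return A list of class `qtl_coding`: `points` (tibble: `point`, `bin_id`,
#'   `chrom`, `pos_cm`, `pos_bp`, `start_bp`, `end_bp`, `is_bin`) and
#'   `coding` (lines x points numeric matrix).
#' @export
genotype_expectations <- function(bins, gmap, step_cm = 1) {
  if (step_cm < 0) abort("`step_cm` must be >= 0")
  rils <- bin_call_cols(bins)
  stopifnot(identical(bins$bin_id, gmap$bin_id))

  per_chrom <- map(unique(bins$chrom), function(ch) {
    bi <- which(bins$chrom == ch)
    cm <- gmap$pos_cm[bi]
    mid <- (bins$start_bp[bi] + bins$end_bp[bi]) / 2
    pts <- tibble(
      bin_id = bins$bin_id[bi], chrom = ch, pos_cm = cm, pos_bp = mid,
      start_bp = bins$start_bp[bi], end_bp = bins$end_bp[bi], is_bin = TRUE
    )
    if (step_cm > 0 && length(bi) >= 2 && max(cm) > 0) {
      grid <- setdiff(seq(0, max(cm), by = step_cm), cm)
      grid <- grid[grid > min(cm) & grid < max(cm)]
      if (length(grid)) {
        pb <- stats::approx(cm, mid, xout = grid, ties = "ordered")$y
        pts <- bind_rows(pts, tibble(
          bin_id = NA_character_, chrom = ch, pos_cm = grid, pos_bp = pb,
          start_bp = NA_real_, end_bp = NA_real_, is_bin = FALSE
        ))
      }
    }
    arrange(pts, .data$pos_cm, .data$pos_bp)
  })
  points <- list_rbind(per_chrom)
  points <- mutate(points, point = row_number(), .before = 1)

  coding <- matrix(0, length(rils), nrow(points),
                   dimnames = list(rils, points$point))
  for (ch in unique(points$chrom)) {
    pidx <- which(points$chrom == ch)
    pcm <- points$pos_cm[pidx]
    bin_rows <- which(bins$chrom == ch)
    bcm <- gmap$pos_cm[bin_rows]
    geno <- as.matrix(bins[bin_rows, rils, drop = FALSE])
    obs <- matrix(c(-1, 1, 0)[match(geno, c("A", "B", "H"))], nrow(geno))
    at_bin <- match(round(pcm, 9), round(bcm, 9))  # point -> bin row or NA
    for (k in seq_along(rils)) {
      x <- obs[, k]
      hom <- which(!is.na(x) & x != 0)
      vals <- numeric(length(pidx))
      if (length(hom) > 0) {
        hcm <- bcm[hom]
        hx <- x[hom]
        li <- findInterval(pcm, hcm)
        ri <- length(hom) - findInterval(-pcm, rev(-hcm)) + 1L
        vals <- cond_expectation(pcm, hcm, hx, li, ri)
      }
      known <- !is.na(at_bin) & !is.na(x[pmax(at_bin, 1L)])
      vals[known] <- x[at_bin[known]]
      coding[k, pidx] <- vals
    }
  }
  structure(list(points = points, coding = coding), class = "qtl_coding")
}

# E[coding | nearest left/right homozygous flanks] under the RIL Markov model.
# li/ri index the flanks (0 / >length = absent).
cond_expectation <- function(pcm, hcm, hx, li, ri) {
  n <- length(pcm)
  kh <- length(hcm)
  has_l <- li >= 1
  has_r <- ri <= kh
  RL <- rep(NA_real_, n)
  RR <- rep(NA_real_, n)
  RL[has_l] <- ril_expand(kosambi_inv(pcm[has_l] - hcm[li[has_l]]))
  RR[has_r] <- ril_expand(kosambi_inv(hcm[ri[has_r]] - pcm[has_r]))
  xl <- ifelse(has_l, hx[pmax(li, 1L)], 0)
  xr <- ifelse(has_r, hx[pmin(ri, kh)], 0)
  # P(target = A | flank) style factors; coding A = -1, B = +1
  pa <- ifelse(has_l, ifelse(xl < 0, 1 - RL, RL), 1) *
    ifelse(has_r, ifelse(xr < 0, 1 - RR, RR), 1)
  pb <- ifelse(has_l, ifelse(xl > 0, 1 - RL, RL), 1) *
    ifelse(has_r, ifelse(xr > 0, 1 - RR, RR), 1)
  out <- (pb - pa) / (pa + pb)
  out[!has_l & !has_r] <- 0
  out
}

#' Single-QTL regression scan
#'
#' At every evaluation point the phenotype is regressed on the genotype
#' expectation (Haley-Knott style): `LOD = (n/2) * log10(RSS0 / RSS1)`, the
#' additive effect is the slope (half the difference between homozygote
#' classes, positive when the B/Qi319 allele increases the trait), and
#' `PVE = 100 * (1 - RSS1 / RSS0)`.
#'
#' @param coding A `qtl_coding` from [genotype_expectations()].
#' @param y Phenotypes: a numeric vector named by line, or a tibble with
#'   columns `ril` and `value` (one row per line, e.g. environment line
#'   means).
#' @param trait,env Optional labels stored with the profile.
#' @return A tibble of class `qtl_scan`: the `points` table plus `lod`,
#'   `effect`, `pve`, with attributes `n`, `trait`, `env`.
#' @export
scan_qtl <- function(coding, y, trait = NA_character_, env = NA_character_) {
  stopifnot(inherits(coding, "qtl_coding"))
  if (is.data.frame(y)) y <- setNames(y$value, y$ril)
  ids <- intersect(rownames(coding$coding), names(y)[is.finite(y)])
  n <- length(ids)
  if (n < 10) abort("need at least 10 non-missing phenotypes")
  yv <- y[ids]
  if (var(yv) == 0) abort("phenotype has zero variance")
  X <- coding$coding[ids, , drop = FALSE]
  yc <- yv - mean(yv)
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2)
  sxy <- drop(crossprod(xc, yc))
  rss0 <- sum(yc^2)
  ok <- sxx > 1e-12
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  rss1 <- ifelse(ok, rss0 - sxy^2 / sxx, rss0)
  out <- mutate(coding$points,
    lod = unname((n / 2) * log10(rss0 / rss1)),
    effect = unname(beta),
    pve = unname(100 * (1 - rss1 / rss0))
  )
  structure(out, n = n, trait = trait, env = env,
            class = c("qtl_scan", class(out)))
}

#' Genome-wide permutation LOD threshold
#'
#' Phenotypes are permuted across lines `n_perm` times (one shared
#' permutation per replicate across all evaluation points), the genome-wide
#' maximum LOD is recorded for each, and the threshold is the empirical
#' `1 - alpha` quantile. The effective declaration threshold is the larger of
#' the permutation threshold and `lod_floor` (3.5 by default).
#'
#' @inheritParams scan_qtl
#' @param n_perm Number of permutations (default 1000, minimum 100).
#' @param alpha Genome-wide error rate (default 0.05).
#' @param lod_floor Minimum LOD to declare a QTL (default 3.5).
#' @param seed Optional integer seed.
#' @return A list of class `perm_threshold`: `threshold`, `effective`,
#'   `max_lods`, `n_perm`, `alpha`, `lod_floor`.
#' @export
permutation_threshold <- function(coding, y, n_perm = 1000, alpha = 0.05,
                                  lod_floor = 3.5, seed = NULL) {
  stopifnot(inherits(coding, "qtl_coding"))
  if (n_perm < 100) abort("`n_perm` must be >= 100")
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.data.frame(y)) y <- setNames(y$value, y$ril)
  ids <- intersect(rownames(coding$coding), names(y)[is.finite(y)])
  n <- length(ids)
  yv <- y[ids]
  X <- coding$coding[ids, , drop = FALSE]
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2)
  keep <- sxx > 1e-12
  xs <- sweep(xc[, keep, drop = FALSE], 2, sqrt(sxx[keep]), "/")
  P <- vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
  Y <- matrix(yv[P], n, n_perm)
  Yc <- sweep(Y, 2, colMeans(Y))
  syy <- colSums(Yc^2)
  Ys <- sweep(Yc, 2, sqrt(syy), "/")
  r2 <- crossprod(xs, Ys)^2                     # points x perms
  max_lods <- apply(-(n / 2) * log10(1 - pmin(r2, 1 - 1e-12)), 2, max)
  thr <- unname(quantile(max_lods, 1 - alpha))
  structure(
    list(threshold = thr, effective = max(thr, lod_floor),
         max_lods = max_lods, n_perm = n_perm, alpha = alpha,
         lod_floor = lod_floor),
    class = "perm_threshold"
  )
}

#' 1.5-LOD support interval around a peak
#'
#' The maximal contiguous run of evaluation points around the peak whose LOD
#' stays within `drop` of the peak LOD, reported with the flanking bin
#' markers and their outer physical coordinates.
#'
#' @param scan A `qtl_scan` tibble.
#' @param peak_point Value of the `point` column at the peak.
#' @param drop LOD drop defining the interval (default 1.5).
#' @return A one-row tibble: peak location, LOD, and the interval as point
#'   range, flanking bin ids, and `ci_start_bp` / `ci_end_bp`.
#' @export
support_interval <- function(scan, peak_point, drop = 1.5) {
  i <- which(scan$point == peak_point)
  stopifnot(length(i) == 1)
  ch <- scan$chrom[i]
  rows <- which(scan$chrom == ch)
  lod <- scan$lod[rows]
  j <- match(i, rows)
  keep <- lod >= scan$lod[i] - drop
  lo <- j
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- j
  while (hi < length(rows) && keep[hi + 1]) hi <- hi + 1
  seg <- scan[rows[lo:hi], , drop = FALSE]
  bins <- seg[seg$is_bin, , drop = FALSE]
  # CI endpoints may be pseudomarkers; flank with the nearest bins just outside
  all_bins <- scan[rows, , drop = FALSE]
  all_bins <- all_bins[all_bins$is_bin, , drop = FALSE]
  left <- all_bins[all_bins$pos_cm <= seg$pos_cm[1], ]
  right <- all_bins[all_bins$pos_cm >= seg$pos_cm[nrow(seg)], ]
  left_bin <- if (nrow(left)) left[nrow(left), ] else all_bins[1, ]
  right_bin <- if (nrow(right)) right[1, ] else all_bins[nrow(all_bins), ]
  peak_bin <- scan$bin_id[i]
  if (is.na(peak_bin)) {
    # pseudomarker peak: report the nearest bin marker
    j2 <- which.min(abs(all_bins$pos_cm - scan$pos_cm[i]))
    peak_bin <- all_bins$bin_id[j2]
  }
  tibble(
    chrom = ch,
    peak_point = peak_point,
    peak_bin = peak_bin,
    peak_cm = scan$pos_cm[i],
    peak_bp = scan$pos_bp[i],
    lod = scan$lod[i],
    pve = scan$pve[i],
    effect = scan$effect[i],
    flank_left = left_bin$bin_id,
    flank_right = right_bin$bin_id,
    ci_start_bp = left_bin$start_bp,
    ci_end_bp = right_bin$end_bp
  )
}

# peaks of all contiguous above-threshold segments of one scan
scan_peaks <- function(scan, threshold, drop = 1.5) {
  rows <- list()
  for (ch in unique(scan$chrom)) {
    sub <- scan[scan$chrom == ch, , drop = FALSE]
    above <- sub$lod >= threshold
    if (!any(above)) next
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values)) {
      seg <- sub[starts[k]:ends[k], , drop = FALSE]
      best <- which(seg$lod == max(seg$lod))
      best <- best[which.min(seg$pos_bp[best])]   # tie -> lower bp
      rows[[length(rows) + 1]] <-
        support_interval(scan, seg$point[best], drop)
    }
  }
  if (!length(rows)) return(NULL)
  list_rbind(rows)
}

#' Collect QTL from scans across traits and environments
#'
#' Each contiguous above-threshold region of each scan yields one peak with
#' its support interval; peaks of the same trait on the same chromosome with
#' overlapping intervals across environments are merged into one named QTL
#' carrying the environment tags and the mean LOD / PVE / additive effect of
#' its members (the convention used for multi-environment QTL tables).
#'
#' @param scans A list of `qtl_scan` objects (each labelled with `trait` and
#'   `env` at [scan_qtl()] time).
#' @param threshold Declaration threshold(s): a single LOD or a vector
#'   recycled along `scans` (e.g. per-environment permutation thresholds).
#' @param drop LOD drop for support intervals (default 1.5).
#' @return A tibble of class `qtl_result`: `qtl`, `trait`, `envs`, `n_env`,
#'   `chrom`, `peak_bin`, `flank_left`, `flank_right`, `ci_start_bp`,
#'   `ci_end_bp`, `length_mb`, `lod`, `pve`, `add`.
#' @export
summarize_qtl <- function(scans, threshold = 3.5, drop = 1.5) {
  threshold <- rep_len(threshold, length(scans))
  peaks <- map2(scans, threshold, function(s, thr) {
    p <- scan_peaks(s, thr, drop)
    if (is.null(p)) return(NULL)
    mutate(p, trait = attr(s, "trait"), env = attr(s, "env"), .before = 1)
  })
  peaks <- list_rbind(peaks[!vapply(peaks, is.null, logical(1))])

  # within one scan, overlapping above-threshold segments are one QTL: keep
  # the strongest peak so that the cross-environment means below average one
  # value per environment
  if (!is.null(peaks) && nrow(peaks) > 1) {
    peaks <- peaks %>%
      group_by(.data$trait, .data$env, .data$chrom) %>%
      arrange(.data$ci_start_bp, .by_group = TRUE) %>%
      mutate(seg = cumsum(
        c(TRUE, tail(.data$ci_start_bp, -1) >
            head(cummax(.data$ci_end_bp), -1))
      )) %>%
      group_by(.data$trait, .data$env, .data$chrom, .data$seg) %>%
      slice_max(.data$lod, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      select(-"seg")
  }
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(structure(
      tibble(
        qtl = character(), trait = character(), envs = character(),
        n_env = integer(), chrom = character(), peak_bin = character(),
        flank_left = character(), flank_right = character(),
        ci_start_bp = numeric(), ci_end_bp = numeric(),
        length_mb = numeric(), lod = numeric(), pve = numeric(),
        add = numeric()
      ),
      class = c("qtl_result", "tbl_df", "tbl", "data.frame")
    ))
  }

  merged <- peaks %>%
    group_by(.data$trait, .data$chrom) %>%
    arrange(.data$ci_start_bp, .by_group = TRUE) %>%
    mutate(group = cumsum(
      c(TRUE, tail(.data$ci_start_bp, -1) >
          head(cummax(.data$ci_end_bp), -1))
    )) %>%
    group_by(.data$trait, .data$chrom, .data$group) %>%
    summarise(
      envs = paste(sort(unique(.data$env)), collapse = ","),
      n_env = length(unique(.data$env)),
      peak_bin = .data$peak_bin[which.max(.data$lod)],
      flank_left = .data$flank_left[which.min(.data$ci_start_bp)],
      flank_right = .data$flank_right[which.max(.data$ci_end_bp)],
      ci_start_bp = min(.data$ci_start_bp),
      ci_end_bp = max(.data$ci_end_bp),
      lod = mean(.data$lod),
      pve = mean(.data$pve),
      add = mean(.data$effect),
      .groups = "drop"
    ) %>%
    mutate(length_mb = (.data$ci_end_bp - .data$ci_start_bp) / 1e6)

  merged <- merged %>%
    group_by(.data$trait, .data$chrom) %>%
    arrange(.data$ci_start_bp, .by_group = TRUE) %>%
    mutate(
      qtl = paste0(
        "q", .data$trait, chrom_number(.data$chrom),
        if (n() > 1) paste0("-", row_number()) else ""
      )
    ) %>%
    ungroup() %>%
    arrange(.data$trait, .data$chrom, .data$ci_start_bp) %>%
    select("qtl", "trait", "envs", "n_env", "chrom", "peak_bin",
           "flank_left", "flank_right", "ci_start_bp", "ci_end_bp",
           "length_mb", "lod", "pve", "add")
  structure(merged, class = c("qtl_result", class(merged)))
}

chrom_number <- function(chrom) {
  num <- gsub("\\D", "", chrom)
  ifelse(num == "", chrom, num)
}

#' Stable QTL: detected in at least `min_env` environments
#'
#' @param results A `qtl_result` tibble from [summarize_qtl()].
#' @param min_env Minimum number of environments (default 2).
#' @return The stable subset of `results`.
#' @export
find_stable_qtl <- function(results, min_env = 2) {
  filter(results, .data$n_env >= min_env)
}

#' Integrate QTL of different traits into pleiotropic regions
#'
#' On each chromosome, QTL whose support intervals overlap are chained
#' (union-chaining: a QTL joins a chain if its interval overlaps the chain's
#' running union); chains containing at least two distinct traits become
#' pleiotropic QTL whose interval is the union of the member intervals.
#'
#' @param results A `qtl_result` tibble.
#' @return A tibble of class `pqtl_result`: `pqtl`, `chrom`, `start_bp`,
#'   `end_bp`, `length_mb`, `n_qtl`, `n_traits`, `members` (comma-joined
#'   QTL names), `traits`.
#' @export
integrate_pleiotropic <- function(results) {
  if (nrow(results) == 0) {
    return(tibble(
      pqtl = character(), chrom = character(), start_bp = numeric(),
      end_bp = numeric(), length_mb = numeric(), n_qtl = integer(),
      n_traits = integer(), members = character(), traits = character()
    ))
  }
  chains <- results %>%
    group_by(.data$chrom) %>%
    arrange(.data$ci_start_bp, .by_group = TRUE) %>%
    mutate(chain = cumsum(
      c(TRUE, tail(.data$ci_start_bp, -1) >
          head(cummax(.data$ci_end_bp), -1))
    )) %>%
    group_by(.data$chrom, .data$chain) %>%
    summarise(
      start_bp = min(.data$ci_start_bp),
      end_bp = max(.data$ci_end_bp),
      n_qtl = n(),
      n_traits = length(unique(.data$trait)),
      members = paste(.data$qtl, collapse = ","),
      traits = paste(sort(unique(.data$trait)), collapse = ","),
      .groups = "drop"
    ) %>%
    filter(.data$n_traits >= 2) %>%
    mutate(length_mb = (.data$end_bp - .data$start_bp) / 1e6)
  out <- chains %>%
    group_by(.data$chrom) %>%
    mutate(pqtl = paste0(
      "pQTL", chrom_number(.data$chrom),
      if (n() > 1) paste0("-", row_number()) else ""
    )) %>%
    ungroup() %>%
    select("pqtl", "chrom", "start_bp", "end_bp", "length_mb",
           "n_qtl", "n_traits", "members", "traits")
  structure(out, class = c("pqtl_result", class(out)))
}
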