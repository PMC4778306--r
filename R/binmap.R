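#' Build population-level recombination bins on a fixed physical grid
#'
#' The genome is tiled with `bin_unit` intervals (100 Kb by default; the last
#' interval of a chromosome may be truncated). A grid interval is a boundary
#' interval when at least one line has a breakpoint uncertainty interval
#' overlapping it; maximal runs of consecutive intervals free of recombination
#' in the entire population form one bin. Boundary intervals are attached to
#' the bin starting at them (right attachment), so every bin except the first
#' of a chromosome starts at a recombination event. Each line's genotype
#' within a bin is the label of the genotype block covering the majority of
#' the bin's base pairs (`"N"` when the line has no called blocks on the
#' chromosome). Short heterozygous blocks sandwiched between opposite
#' homozygous blocks — the transitional slivers the window rule produces at
#' every clean junction — are collapsed to a point junction at their midpoint
#' before genotypes are assigned, so a recombinant line reads A then B across
#' the boundary rather than A, H, B.
#'
#' @param blocks A blocks tibble from [call_genotype_blocks()].
#' @param spec The [genome_spec()] (chromosome lengths).
#' @param bin_unit Grid unit in bp (default 1e5).
#' @param breakpoints Optional precomputed [extract_breakpoints()] result.
#' @return A wide bin-map tibble of class `bin_map`: `bin_id`, `chrom`,
#'   `start_bp`, `end_bp` (half-open `[start, end)`, 0-based starts), then
#'   one genotype column per line.
#' @export
build_bins <- function(blocks, spec, bin_unit = 1e5, breakpoints = NULL) {
  assert_genome_spec(spec)
  if (bin_unit <= 0) abort("`bin_unit` must be > 0")
  bp <- breakpoints %||% extract_breakpoints(blocks)
  bp <- bp$breakpoints

  per_chrom <- map(seq_len(nrow(spec)), function(ci) {
    ch <- spec$chrom[ci]
    L <- spec$length_bp[ci]
    m <- ceiling(L / bin_unit)
    boundary <- logical(m)
    cbp <- bp[bp$chrom == ch, , drop = FALSE]
    if (nrow(cbp) > 0) {
      # each breakpoint recombines the grid interval containing its point
      # estimate (the midpoint of its uncertainty interval); marking the
      # whole uncertainty interval would flag nearly every interval at GBS
      # sparsity and dissolve the bins
      mid <- (cbp$left_bp + cbp$right_bp) / 2
      boundary[pmax(1L, pmin(m, floor(mid / bin_unit) + 1L))] <- TRUE
    }
    start_new <- boundary
    start_new[1] <- TRUE
    idx <- cumsum(start_new)
    starts <- (which(start_new) - 1) * bin_unit
    ends <- c(starts[-1], L)
    tibble(chrom = ch, start_bp = starts, end_bp = pmin(ends, L))
  })
  bins <- list_rbind(per_chrom)
  bins <- mutate(bins,
    bin_id = sprintf("mk%0*d", max(4L, nchar(nrow(bins))), row_number()),
    .before = 1
  )

  geno <- bin_genotypes(bins, blocks, bp, spec)
  out <- bind_cols(bins, geno)
  class(out) <- c("bin_map", class(out))
  out
}

# per-line majority-bp genotype of every bin
bin_genotypes <- function(bins, blocks, bp, spec) {
  rils <- unique(blocks$ril)
  labs <- c("A", "B", "H")
  cols <- map(rils, function(id) {
    out <- rep("N", nrow(bins))
    for (ci in seq_len(nrow(spec))) {
      ch <- spec$chrom[ci]
      L <- spec$length_bp[ci]
      rows <- which(bins$chrom == ch)
      blk <- blocks[blocks$ril == id & blocks$chrom == ch, , drop = FALSE]
      if (nrow(blk) == 0 || length(rows) == 0) next
      rb <- bp[bp$ril == id & bp$chrom == ch, , drop = FALSE]
      seg <- collapse_transitional_het(
        c(0, (rb$left_bp + rb$right_bp) / 2, L), blk$label
      )
      cuts <- seg$cuts
      blk <- tibble(label = seg$labels)
      acc <- matrix(0, length(rows), 3L)
      s <- bins$start_bp[rows]
      e <- bins$end_bp[rows]
      for (j in seq_len(nrow(blk))) {
        ov <- pmin(e, cuts[j + 1]) - pmax(s, cuts[j])
        lab <- match(blk$label[j], labs)
        pos <- ov > 0
        acc[pos, lab] <- acc[pos, lab] + ov[pos]
      }
      out[rows] <- labs[max.col(acc, ties.method = "first")]
    }
    out
  })
  names(cols) <- rils
  as_tibble(cols)
}

# The 11-of-15 window rule always produces a short heterozygous run where a
# line's genotype flips between opposite homozygotes: the windows straddling
# the junction favour neither parent. In an F11 line (residual heterozygosity
# ~ 2^-10) such an A|H|B sliver is breakpoint uncertainty, not genotype, so
# for bin-genotype assignment it is collapsed to a single junction at its
# physical midpoint. H blocks flanked by same-label homozygous blocks (or at
# chromosome ends) are kept as genuine heterozygous calls.
collapse_transitional_het <- function(cuts, labels) {
  k <- length(labels)
  if (k >= 3) {
    repeat {
      j <- which(labels[-c(1, k)] == "H" &
                   labels[-c(k - 1, k)] != labels[-c(1, 2)] &
                   labels[-c(k - 1, k)] != "H" &
                   labels[-c(1, 2)] != "H") + 1L
      if (!length(j)) break
      j <- j[1]
      mid <- (cuts[j] + cuts[j + 1]) / 2
      cuts <- c(cuts[seq_len(j - 1)], mid, cuts[seq(j + 2, k + 1)])
      labels <- labels[-j]
      k <- length(labels)
      if (k < 3) break
    }
  }
  list(cuts = cuts, labels = labels)
}

bin_call_cols <- function(bins) {
  setdiff(names(bins), c("bin_id", "chrom", "start_bp", "end_bp"))
}

#' Summary statistics of a bin map
#'
#' @param bins A `bin_map` tibble from [build_bins()].
#' @param hist_breaks_mb Histogram bin edges for the length distribution, in
#'   Mb (the last edge is open-ended).
#' @return A list: `summary` (one-row tibble: bin count, mean / median length,
#'   fraction under 0.5 Mb, number over 10 Mb, missing-genotype rate),
#'   `histogram` (length-class counts) and `long_bins` (the rows over 10 Mb).
#' @export
bin_stats <- function(bins, hist_breaks_mb = c(0, 0.5, 1, 5, 10, Inf)) {
  if (nrow(bins) == 0) abort("empty bin list")
  len <- bins$end_bp - bins$start_bp
  geno <- as.matrix(bins[bin_call_cols(bins)])
  hist <- tibble(
    length_class = cut(len / 1e6, hist_breaks_mb, right = FALSE),
    len = len
  ) %>% count(.data$length_class, name = "n_bins")
  list(
    summary = tibble(
      n_bins = nrow(bins),
      mean_length_bp = mean(len),
      median_length_bp = median(len),
      frac_under_0.5mb = mean(len < 5e5),
      n_over_10mb = sum(len > 1e7),
      missing_rate = mean(geno == "N")
    ),
    histogram = hist,
    long_bins = bins[len > 1e7, c("bin_id", "chrom", "start_bp", "end_bp")]
  )
}

#' Observed recombination frequency between two marker genotype vectors
#'
#' Counts mismatches among lines that are homozygous and non-missing at both
#' markers; heterozygous or missing lines are uninformative.
#'
#' @param g_i,g_j Character genotype vectors (`A/B/H/N`) of equal length.
#' @return A one-row tibble: `rhat`, `n_informative`, `n_mismatch`.
#' @export
estimate_rf <- function(g_i, g_j) {
  if (length(g_i) != length(g_j)) abort("genotype vectors differ in length")
  inf <- g_i %in% c("A", "B") & g_j %in% c("A", "B")
  if (!any(inf)) abort("no informative pairs: recombination frequency undefined")
  mism <- sum(g_i[inf] != g_j[inf])
  tibble(rhat = mism / sum(inf), n_informative = sum(inf), n_mismatch = mism)
}

#' Estimate the genetic map of a bin map
#'
#' Adjacent-bin distances are estimated pairwise: the observed RIL
#' recombination frequency (mismatches among doubly homozygous lines) is
#' corrected for selfed-RIL map expansion with [ril_correct()] and converted
#' to cM with [kosambi()]. Pairs with no informative lines get distance 0 and
#' are flagged (`undefined = TRUE`) with a warning.
#'
#' @param bins A `bin_map` tibble.
#' @param rmax Clamp on the observed recombination frequency (default 0.49).
#' @return A tibble of class `genetic_map`: `bin_id`, `chrom`, `start_bp`,
#'   `end_bp`, `pos_cm` (cumulative within chromosome), `rhat`, `r`, `d_cm`
#'   (distance to the previous marker), `n_informative`, `undefined`.
#' @export
build_genetic_map <- function(bins, rmax = 0.49) {
  rils <- bin_call_cols(bins)
  per_chrom <- map(unique(bins$chrom), function(ch) {
    sub <- bins[bins$chrom == ch, , drop = FALSE]
    m <- nrow(sub)
    geno <- as.matrix(sub[rils])
    x <- matrix(match(geno, c("A", "B")), m)   # NA for H/N
    if (m > 1) {
      a <- x[-m, , drop = FALSE]
      b <- x[-1, , drop = FALSE]
      inf <- !is.na(a) & !is.na(b)
      mism <- inf & (a != b)
      n_inf <- rowSums(inf)
      rhat <- ifelse(n_inf > 0, rowSums(mism) / n_inf, NA_real_)
    } else {
      n_inf <- integer(0)
      rhat <- numeric(0)
    }
    undefined <- is.na(rhat)
    r <- ifelse(undefined, NA_real_, ril_correct(pmin(rhat, rmax), rmax))
    d <- ifelse(undefined, 0, kosambi(ifelse(undefined, 0, r)))
    tibble(
      bin_id = sub$bin_id, chrom = ch,
      start_bp = sub$start_bp, end_bp = sub$end_bp,
      pos_cm = cumsum(c(0, d)),
      rhat = c(NA, rhat), r = c(NA, r), d_cm = c(NA, d),
      n_informative = c(NA, n_inf), undefined = c(NA, undefined)
    )
  })
  out <- list_rbind(per_chrom)
  n_undef <- sum(out$undefined, na.rm = TRUE)
  if (n_undef > 0) {
    warn(sprintf(
      "%d adjacent-marker interval(s) had no informative lines; treated as 0-cM map gaps",
      n_undef
    ))
  }
  class(out) <- c("genetic_map", class(out))
  out
}

#' Per-chromosome map summary (marker counts, lengths, gaps)
#'
#' @param gmap A `genetic_map` tibble from [build_genetic_map()].
#' @param gap_cm Gap-reporting threshold in cM (default 5).
#' @return A tibble with one row per chromosome plus a `Total` row:
#'   `n_markers`, `phys_mb`, `length_cm`, `avg_spacing_cm`
#'   (`length_cm / n_markers`), `n_gaps_ge` (adjacent intervals at or above
#'   `gap_cm`), `max_gap_cm`.
#' @export
map_summary <- function(gmap, gap_cm = 5) {
  per <- gmap %>%
    group_by(.data$chrom) %>%
    summarise(
      n_markers = n(),
      phys_mb = sum(.data$end_bp - .data$start_bp) / 1e6,
      length_cm = max(.data$pos_cm),
      n_gaps_ge = sum(.data$d_cm >= gap_cm, na.rm = TRUE),
      max_gap_cm = max(.data$d_cm, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(avg_spacing_cm = .data$length_cm / .data$n_markers)
  tot <- tibble(
    chrom = "Total",
    n_markers = sum(per$n_markers),
    phys_mb = sum(per$phys_mb),
    length_cm = sum(per$length_cm),
    n_gaps_ge = sum(per$n_gaps_ge),
    max_gap_cm = max(per$max_gap_cm),
    avg_spacing_cm = sum(per$length_cm) / sum(per$n_markers)
  )
  bind_rows(per, tot) %>%
    select("chrom", "n_markers", "phys_mb", "length_cm",
           "avg_spacing_cm", "n_gaps_ge", "max_gap_cm")
}

#' Agreement between genetic (cM) and physical (bp) marker order
#'
#' Maps built by [build_genetic_map()] are collinear by construction; for
#' externally loaded maps this flags order violations (adjacent pairs whose
#' physical order contradicts the map order).
#'
#' @param gmap A `genetic_map`-shaped tibble (needs `chrom`, `pos_cm`,
#'   `start_bp`), rows in map order.
#' @return A tibble per chromosome: `n_markers`, `n_violations`, `agreement`
#'   (1 minus the violation fraction among adjacent pairs).
#' @export
collinearity_check <- function(gmap) {
  gmap %>%
    group_by(.data$chrom) %>%
    arrange(.data$pos_cm, .by_group = TRUE) %>%
    summarise(
      n_markers = n(),
      n_violations = sum(diff(.data$start_bp) < 0),
      agreement = if (n() > 1) {
        1 - sum(diff(.data$start_bp) < 0) / (n() - 1)
      } else {
        1
      },
      .groups = "drop"
    )
}
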