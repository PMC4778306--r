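#' Filter SNPs for segregation distortion
#'
#' In a biparental RIL population every marker should segregate 1:1 between
#' the two homozygous classes. Each SNP is tested with the 1-df chi-square
#' statistic `(nA - nB)^2 / (nA + nB)` on the homozygous call counts (no
#' continuity correction); SNPs with `p < alpha` are removed as distorted, and
#' SNPs with no informative (A/B) calls at all are removed as uninformative.
#'
#' @param snp A wide SNP matrix tibble (`snp_id`, `chrom`, `pos`, one call
#'   column per line with values in `A/B/H/N`), e.g. from [observe_gbs()] or
#'   [read_snp_tsv()].
#' @param alpha Removal significance level (default 0.001).
#' @return A list with `snp` (the retained rows), `tests` (per-SNP `n_a`,
#'   `n_b`, `chisq`, `p`, `status`), and `report` (one-row input / removed /
#'   retained counts).
#' @examples
#' spec <- genome_spec(1e7, 90, n_snps = 50)
#' moz <- breed_ril_population(spec, n_rils = 40, seed = 1)
#' snp <- observe_gbs(moz, spec, observe_rate = 1, seed = 2)
#' filter_segregation(snp)$report
#' @export
filter_segregation <- function(snp, alpha = 0.001) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1)")
  if (nrow(snp) == 0) abort("SNP matrix has no SNPs")
  calls <- as.matrix(snp[snp_call_cols(snp)])
  n_a <- rowSums(calls == "A")
  n_b <- rowSums(calls == "B")
  n_inf <- n_a + n_b
  chisq <- ifelse(n_inf > 0, (n_a - n_b)^2 / n_inf, NA_real_)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  status <- case_when(
    n_inf == 0 ~ "uninformative",
    p < alpha ~ "distorted",
    TRUE ~ "retained"
  )
  tests <- tibble(
    snp_id = snp$snp_id, chrom = snp$chrom, pos = snp$pos,
    n_a = n_a, n_b = n_b, chisq = chisq, p = p, status = status
  )
  list(
    snp = snp[status == "retained", , drop = FALSE],
    tests = tests,
    report = tibble(
      n_input = nrow(snp),
      n_distorted = sum(status == "distorted"),
      n_uninformative = sum(status == "uninformative"),
      n_retained = sum(status == "retained"),
      alpha = alpha
    )
  )
}

snp_call_cols <- function(snp) {
  setdiff(names(snp), c("snp_id", "chrom", "pos"))
}

#' Sliding-window genotype calls along one chromosome of one line
#'
#' Windows of `window` informative SNPs (het and missing calls are excluded
#' from the counts) slide one SNP at a time. A window is labelled homozygous
#' for the parent contributing at least `hom_threshold` of its SNPs, and
#' heterozygous otherwise. When fewer than `window` informative SNPs are
#' available a single truncated window is used with the supermajority
#' threshold rescaled to `ceiling(hom_threshold / window * n)`.
#'
#' @param calls Character vector of calls (`A/B/H/N`) ordered by position.
#' @param window,step,hom_threshold Window size, slide step, and homozygosity
#'   count threshold (defaults 15 / 1 / 11).
#' @return A tibble with one row per window: `win`, `i_from`, `i_to` (indices
#'   into the informative subset), `snp_from`, `snp_to` (indices into
#'   `calls`), `n_a`, `n_b`, `label`. The informative indices and the window
#'   size are carried in attributes `informative` and `window` for
#'   [merge_blocks()].
#' @export
call_windows <- function(calls, window = 15, step = 1, hom_threshold = 11) {
  if (!all(calls %in% CALL_LEVELS)) abort("calls must be in {A, B, H, N}")
  if (window < hom_threshold || hom_threshold < ceiling(window / 2) + 1) {
    abort("need window >= hom_threshold >= ceiling(window/2) + 1")
  }
  if (step < 1) abort("`step` must be >= 1")
  inf_idx <- which(calls %in% c("A", "B"))
  n <- length(inf_idx)
  empty <- tibble(
    win = integer(), i_from = integer(), i_to = integer(),
    snp_from = integer(), snp_to = integer(),
    n_a = integer(), n_b = integer(), label = character()
  )
  if (n == 0) {
    return(structure(empty, informative = inf_idx, window = window))
  }
  is_a <- calls[inf_idx] == "A"
  if (n < window) {
    th <- ceiling(hom_threshold / window * n)
    from <- 1L
    to <- n
  } else {
    from <- seq.int(1L, n - window + 1L, by = step)
    to <- from + window - 1L
    th <- hom_threshold
  }
  ca <- c(0L, cumsum(is_a))
  n_a <- ca[to + 1L] - ca[from]
  n_b <- (to - from + 1L) - n_a
  label <- ifelse(n_a >= th, "A", ifelse(n_b >= th, "B", "H"))
  out <- tibble(
    win = seq_along(from), i_from = from, i_to = to,
    snp_from = inf_idx[from], snp_to = inf_idx[to],
    n_a = n_a, n_b = n_b, label = label
  )
  structure(out, informative = inf_idx, window = window)
}

#' Merge equal-label windows into genotype blocks
#'
#' Maximal runs of windows with the same label become blocks. Where the label
#' run changes, adjacent runs share `window - 1` SNPs; the block boundary is
#' cut at the midpoint of that overlap zone, so the supporting SNP ranges of
#' consecutive blocks partition the informative SNPs. The exact placement
#' within the overlap is an interpretation (the sliding-window literature does
#' not fix it); the uncertainty interval reported downstream spans the SNPs
#' flanking the cut.
#'
#' @param windows A window tibble from [call_windows()] (its `informative`
#'   and `window` attributes are required).
#' @param positions Base-pair positions of all SNPs in the call vector the
#'   windows were computed from.
#' @return A tibble with one row per block: `label`, `i_first`, `i_last`
#'   (informative indices), `n_snps`, `start_bp`, `end_bp` (positions of the
#'   first and last supporting SNP).
#' @export
merge_blocks <- function(windows, positions) {
  inf_idx <- attr(windows, "informative")
  w <- attr(windows, "window")
  if (is.null(inf_idx) || is.null(w)) {
    abort("`windows` must come from call_windows()")
  }
  if (nrow(windows) == 0) {
    return(tibble(
      label = character(), i_first = integer(), i_last = integer(),
      n_snps = integer(), start_bp = numeric(), end_bp = numeric()
    ))
  }
  runs <- rle(windows$label)
  ke <- cumsum(runs$lengths)            # last window of each run
  n <- max(windows$i_to)
  cut <- c(0L, pmin(windows$i_to[ke[-length(ke)]] - w + floor(w / 2), n), n)
  # cut[j] is the last informative SNP of block j-1; runs shorter than the
  # overlap can produce non-increasing cuts, so enforce monotonicity
  cut <- cummax(cut)
  first <- cut[-length(cut)] + 1L
  last <- cut[-1]
  keep <- last >= first
  tibble(
    label = runs$values[keep],
    i_first = first[keep], i_last = last[keep],
    n_snps = last[keep] - first[keep] + 1L,
    start_bp = positions[inf_idx[first[keep]]],
    end_bp = positions[inf_idx[last[keep]]]
  )
}

#' Call genotype blocks for every line of a population
#'
#' Runs [call_windows()] and [merge_blocks()] over every line x chromosome of
#' a (filtered) SNP matrix.
#'
#' @inheritParams filter_segregation
#' @inheritParams call_windows
#' @param min_block_windows Optional smoothing: blocks supported by fewer
#'   than this many windows are absorbed into their longer neighbour before
#'   breakpoint extraction (default 1 = no smoothing, the literal
#'   window-merging rule).
#' @return A blocks tibble: `ril`, `chrom`, `label`, `i_first`, `i_last`,
#'   `n_snps`, `start_bp`, `end_bp`, ordered within line and chromosome.
#' @export
call_genotype_blocks <- function(snp, window = 15, step = 1,
                                 hom_threshold = 11, min_block_windows = 1) {
  rils <- snp_call_cols(snp)
  chroms <- unique(snp$chrom)
  per_chrom <- map(chroms, function(ch) {
    sub <- snp[snp$chrom == ch, , drop = FALSE]
    pos <- sub$pos
    rows <- map(rils, function(id) {
      wins <- call_windows(sub[[id]], window, step, hom_threshold)
      if (min_block_windows > 1 && nrow(wins) > 0) {
        wins$label <- smooth_window_labels(wins$label, min_block_windows)
        attr(wins, "informative") <- attr(wins, "informative") %||%
          which(sub[[id]] %in% c("A", "B"))
      }
      blk <- merge_blocks(wins, pos)
      if (nrow(blk) == 0) return(NULL)
      mutate(blk, ril = id, chrom = ch, .before = 1)
    })
    list_rbind(rows[!vapply(rows, is.null, logical(1))])
  })
  list_rbind(per_chrom) %>% arrange(.data$ril, .data$chrom, .data$i_first)
}

# absorb label runs shorter than `min_run` windows into the longer neighbour
smooth_window_labels <- function(labels, min_run) {
  repeat {
    runs <- rle(labels)
    if (length(runs$lengths) <= 1) return(labels)
    short <- which(runs$lengths < min_run)
    if (length(short) == 0) return(labels)
    i <- short[which.min(runs$lengths[short])]
    left_len <- if (i > 1) runs$lengths[i - 1] else -1L
    right_len <- if (i < length(runs$lengths)) runs$lengths[i + 1] else -1L
    runs$values[i] <- if (left_len >= right_len) {
      runs$values[i - 1]
    } else {
      runs$values[i + 1]
    }
    labels <- inverse.rle(runs)
  }
}

#' Extract recombination breakpoints from genotype blocks
#'
#' Every adjacent block pair within a line and chromosome implies one
#' breakpoint; its uncertainty interval runs from the last supporting SNP of
#' the left block to the first supporting SNP of the right block.
#'
#' @param blocks A blocks tibble from [call_genotype_blocks()].
#' @return A list: `breakpoints` (`ril`, `chrom`, `left_bp`, `right_bp`,
#'   `left_label`, `right_label`), `per_ril` counts, `n_total`, and
#'   `mean_per_ril` (total / number of lines).
#' @export
extract_breakpoints <- function(blocks) {
  bp <- blocks %>%
    group_by(.data$ril, .data$chrom) %>%
    arrange(.data$i_first, .by_group = TRUE) %>%
    reframe(
      left_bp = head(.data$end_bp, -1),
      right_bp = tail(.data$start_bp, -1),
      left_label = head(.data$label, -1),
      right_label = tail(.data$label, -1)
    )
  rils <- unique(blocks$ril)
  per_ril <- bp %>%
    count(.data$ril, name = "n_breakpoints") %>%
    tidyr::complete(ril = rils, fill = list(n_breakpoints = 0L))
  list(
    breakpoints = bp,
    per_ril = per_ril,
    n_total = nrow(bp),
    mean_per_ril = nrow(bp) / length(rils)
  )
}
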