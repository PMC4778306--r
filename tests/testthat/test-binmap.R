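test_that("Kosambi map function and its inverse round-trip", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.2 / 0.8))
  expect_equal(round(kosambi(0.1), 3), 10.137)
  expect_error(kosambi(0.5), "0.5")
  expect_error(kosambi(-0.01), "0.5")
  r <- seq(0, 0.49, by = 0.007)
  expect_lt(max(abs(kosambi_inv(kosambi(r)) - r)), 1e-10)
  expect_true(all(diff(kosambi(r)) > 0))
})

test_that("Haldane-Waddington RIL correction matches the closed form", {
  expect_equal(ril_correct(0), 0)
  expect_equal(ril_correct(0.2), 0.125)
  # free-recombination fixed point (clamp relaxed)
  expect_equal(ril_correct(0.5, rmax = 0.5), 0.4999, tolerance = 1e-3)
  expect_error(ril_correct(-0.1), ">= 0")
  R <- seq(0, 0.45, by = 0.009)
  expect_lt(max(abs(ril_expand(ril_correct(R, rmax = 0.5)) - R)), 1e-10)
})

test_that("estimate_rf counts mismatches among doubly homozygous lines", {
  g <- rep(c("A", "B"), 150)
  expect_equal(estimate_rf(g, g)$rhat, 0)

  g2 <- g
  g2[seq_len(20) * 2] <- "H"          # 20 het -> uninformative
  g2[41:50] <- ifelse(g[41:50] == "A", "B", "A")   # 10 mismatches
  out <- estimate_rf(g, g2)
  expect_equal(out$n_informative, 280)
  expect_equal(out$n_mismatch, 10)
  expect_equal(out$rhat, 10 / 280)

  flipped <- ifelse(g == "A", "B", "A")
  expect_equal(estimate_rf(g, flipped)$rhat, 1)

  expect_error(estimate_rf(g, rep("N", 300)), "informative")
  expect_error(estimate_rf(g, g[-1]), "length")
})

test_that("bins are cut exactly at recombined grid intervals", {
  spec <- genome_spec(c(2e6, 1.5e6), c(90, 70), n_snps = c(10, 10))
  # no breakpoints: one bin per chromosome
  blocks0 <- tibble(
    ril = "RIL001", chrom = c("chr1", "chr2"), label = "A",
    i_first = 1L, i_last = 10L, n_snps = 10L,
    start_bp = 1e5, end_bp = c(1.9e6, 1.4e6)
  )
  bins0 <- build_bins(blocks0, spec)
  expect_equal(nrow(bins0), 2)
  expect_equal(bins0$start_bp, c(0, 0))
  expect_equal(bins0$end_bp, c(2e6, 1.5e6))
  expect_equal(bins0$RIL001, c("A", "A"))

  # one line recombines inside grid interval 8 of chr1 (0.7-0.8 Mb)
  blocks1 <- bind_rows(
    tibble(ril = "RIL002", chrom = "chr1",
           label = c("A", "B"), i_first = c(1L, 6L), i_last = c(5L, 10L),
           n_snps = 5L, start_bp = c(1e5, 7.8e5), end_bp = c(7.2e5, 1.9e6)),
    blocks0
  )
  bins1 <- build_bins(blocks1, spec)
  chr1 <- bins1[bins1$chrom == "chr1", ]
  expect_equal(nrow(chr1), 2)
  expect_equal(chr1$end_bp[1], 7e5)   # split at the start of interval 8
  expect_equal(chr1$start_bp[2], 7e5)
  expect_equal(chr1$RIL002, c("A", "B"))
  expect_equal(chr1$RIL001, c("A", "A"))

  # brute-force grid scan oracle: an interval is recombinant iff it
  # contains a breakpoint midpoint
  bp <- extract_breakpoints(blocks1)$breakpoints
  unit <- 1e5
  for (ci in 1:2) {
    ch <- spec$chrom[ci]
    m <- ceiling(spec$length_bp[ci] / unit)
    mids <- (bp$left_bp[bp$chrom == ch] + bp$right_bp[bp$chrom == ch]) / 2
    rec <- vapply(seq_len(m), function(k) {
      lo <- (k - 1) * unit
      hi <- min(k * unit, spec$length_bp[ci])
      any(mids >= lo & mids < hi)
    }, logical(1))
    expected_cuts <- unique(c(0, (which(rec) - 1) * unit))
    got <- bins1$start_bp[bins1$chrom == ch]
    expect_equal(sort(got), sort(expected_cuts))
  }

  expect_error(build_bins(blocks1, spec, bin_unit = 0), "bin_unit")
})

test_that("bin statistics match a direct recount", {
  spec <- genome_spec(4e5, 50, n_snps = 8)
  blocks <- tibble(
    ril = c("RIL001", "RIL001"), chrom = "chr1", label = c("A", "B"),
    i_first = c(1L, 5L), i_last = c(4L, 8L), n_snps = 4L,
    start_bp = c(5e4, 1.35e5), end_bp = c(1.15e5, 3.5e5)
  )
  bins <- build_bins(blocks, spec)   # 100 Kb + 300 Kb
  st <- bin_stats(bins)
  expect_equal(st$summary$n_bins, 2)
  expect_equal(st$summary$mean_length_bp, 2e5)
  expect_equal(st$summary$median_length_bp, 2e5)
  expect_equal(st$summary$frac_under_0.5mb, 1)
  expect_equal(st$summary$n_over_10mb, 0)
  expect_error(bin_stats(bins[0, ]), "empty")

  # seeded population: summary equals a naive recount of the same tibble
  spec2 <- small_spec()
  moz <- breed_ril_population(spec2, n_rils = 40, n_selfing = 10, seed = 31)
  snp <- observe_gbs(moz, spec2, observe_rate = 0.8,
                     allele_error_rate = 0.005, seed = 32)
  bins2 <- build_bins(call_genotype_blocks(filter_segregation(snp)$snp),
                      spec2)
  st2 <- bin_stats(bins2)
  len <- bins2$end_bp - bins2$start_bp
  expect_equal(st2$summary$mean_length_bp, mean(len))
  expect_equal(st2$summary$frac_under_0.5mb, mean(len < 5e5))
  geno <- as.matrix(bins2[setdiff(
    names(bins2), c("bin_id", "chrom", "start_bp", "end_bp")
  )])
  expect_equal(st2$summary$missing_rate, mean(geno == "N"))
})

test_that("bins tile chromosomes and respect within-bin consistency", {
  spec <- small_spec()
  moz <- breed_ril_population(spec, n_rils = 60, n_selfing = 10, seed = 33)
  snp <- observe_gbs(moz, spec, observe_rate = 0.9,
                     allele_error_rate = 0.01, seed = 34)
  blocks <- call_genotype_blocks(filter_segregation(snp)$snp)
  bps <- extract_breakpoints(blocks)
  bins <- build_bins(blocks, spec, breakpoints = bps)
  for (ci in seq_len(3)) {
    sub <- bins[bins$chrom == spec$chrom[ci], ]
    expect_equal(sub$start_bp[1], 0)
    expect_equal(tail(sub$end_bp, 1), spec$length_bp[ci])
    expect_equal(sub$start_bp[-1], head(sub$end_bp, -1))
    expect_true(all(sub$start_bp %% 1e5 == 0))
  }
  # every breakpoint uncertainty interval overlaps the boundary (first grid
  # unit) of some bin on its chromosome
  for (k in seq_len(nrow(bps$breakpoints))) {
    b <- bps$breakpoints[k, ]
    starts <- bins$start_bp[bins$chrom == b$chrom]
    first_units_lo <- starts
    first_units_hi <- starts + 1e5
    expect_true(any(b$left_bp < first_units_hi & b$right_bp > first_units_lo))
  }
})

test_that("the genetic map recovers the simulated map length", {
  # three bins with zero recombination -> 0 cM
  spec0 <- genome_spec(4e5, 50, n_snps = 9)
  blocks0 <- tibble(
    ril = rep(sprintf("RIL%03d", 1:20), each = 1), chrom = "chr1",
    label = rep(c("A", "B"), 10), i_first = 1L, i_last = 9L, n_snps = 9L,
    start_bp = 5e4, end_bp = 3.6e5
  )
  bins0 <- build_bins(blocks0, spec0)
  gmap0 <- build_genetic_map(bins0)
  expect_equal(max(gmap0$pos_cm), 0)

  # error-free fully observed population: chromosome lengths within 10 %
  spec <- genome_spec(c(3e7, 2e7), c(110, 90), n_snps = c(3000, 2000))
  moz <- breed_ril_population(spec, n_rils = 250, n_selfing = 10, seed = 35)
  snp <- observe_gbs(moz, spec, observe_rate = 1, allele_error_rate = 0,
                     seed = 36)
  bins <- build_bins(call_genotype_blocks(snp), spec)
  gmap <- build_genetic_map(bins)
  ms <- map_summary(gmap)
  est <- ms$length_cm[match(spec$chrom, ms$chrom)]
  expect_true(all(abs(est - spec$length_cm) / spec$length_cm < 0.10))
  # kosambi-of-corrected-rhat is monotone over the observed range
  ok <- !is.na(gmap$rhat)
  expect_true(all(gmap$d_cm[ok] >= 0))
  expect_equal(ms$n_markers[ms$chrom == "Total"], nrow(bins))
})

test_that("collinearity is perfect by construction and flags injected swaps", {
  gmap <- tibble(
    chrom = "chr1", pos_cm = c(0, 1, 2, 3, 4),
    start_bp = c(0, 1e6, 2e6, 3e6, 4e6)
  )
  chk <- collinearity_check(gmap)
  expect_equal(chk$agreement, 1)
  expect_equal(chk$n_violations, 0)

  swapped <- gmap
  swapped$start_bp <- swapped$start_bp[c(1, 4, 3, 2, 5)]
  chk2 <- collinearity_check(swapped)
  # oracle: count descents among adjacent physical positions in map order
  expect_equal(chk2$n_violations, sum(diff(swapped$start_bp) < 0))
  expect_equal(chk2$n_violations, 2)
  expect_lt(chk2$agreement, 1)
})
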