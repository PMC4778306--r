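# a tiny hand-made bin map: 5 bins on one chromosome, 12 lines
toy_bins <- function() {
  geno <- tribble(
    ~mk1, ~mk2, ~mk3, ~mk4, ~mk5,
    "A", "A", "A", "A", "A",
    "A", "A", "A", "B", "B",
    "B", "B", "B", "B", "B",
    "B", "B", "A", "A", "A",
    "A", "A", "N", "A", "A",
    "B", "N", "B", "B", "B",
    "A", "A", "H", "A", "A",
    "B", "B", "B", "B", "B",
    "A", "A", "A", "A", "A",
    "B", "B", "B", "A", "A",
    "A", "B", "B", "B", "B",
    "B", "B", "B", "B", "N"
  )
  ids <- sprintf("RIL%03d", 1:12)
  base <- tibble(
    bin_id = sprintf("mk%d", 1:5), chrom = "chr1",
    start_bp = (0:4) * 1e6, end_bp = (1:5) * 1e6
  )
  cols <- as_tibble(setNames(as.list(as.data.frame(t(as.matrix(geno)))), ids))
  structure(bind_cols(base, cols), class = c("bin_map", "tbl_df", "tbl",
                                             "data.frame"))
}

toy_map <- function(bins) {
  structure(
    tibble(
      bin_id = bins$bin_id, chrom = "chr1",
      start_bp = bins$start_bp, end_bp = bins$end_bp,
      pos_cm = c(0, 5, 10, 15, 20),
      rhat = NA, r = NA, d_cm = NA, n_informative = NA, undefined = NA
    ),
    class = c("genetic_map", "tbl_df", "tbl", "data.frame")
  )
}

test_that("genotype expectations code observed bins and impute missing ones", {
  bins <- toy_bins()
  cod <- genotype_expectations(bins, toy_map(bins), step_cm = 0)
  X <- cod$coding
  expect_equal(dim(X), c(12, 5))
  expect_equal(X["RIL001", ], setNames(rep(-1, 5), 1:5))
  expect_equal(unname(X["RIL003", 1]), 1)
  expect_equal(unname(X["RIL007", 3]), 0)    # observed het codes 0
  # missing genotype midway between A-hom and B-hom flanks -> 0 by symmetry
  bins2 <- bins
  bins2$RIL005 <- c("A", "N", "N", "N", "B")
  cod2 <- genotype_expectations(bins2, toy_map(bins), step_cm = 0)
  expect_equal(unname(cod2$coding["RIL005", 3]), 0, tolerance = 1e-12)
  # imputed values interpolate monotonically between opposite flanks
  expect_lt(cod2$coding["RIL005", 2], 0)
  expect_gt(cod2$coding["RIL005", 4], 0)

  # A-hom flanks at r = 0.1 on each side: enumeration oracle on the
  # two-locus selfed-RIL table gives E = -(pa - pb)/(pa + pb), pa = (1-R)^2
  d <- kosambi(0.1)
  bins3 <- bins[, 1:6]   # one line is enough
  bins3$RIL001 <- c("A", "N", "A", "A", "A")
  gmap3 <- toy_map(bins)
  gmap3$pos_cm <- c(0, d, 2 * d, 2 * d + 5, 2 * d + 10)
  cod3 <- genotype_expectations(bins3, gmap3, step_cm = 0)
  R <- 2 * 0.1 / (1 + 2 * 0.1)
  oracle <- -((1 - R)^2 - R^2) / ((1 - R)^2 + R^2)
  expect_equal(unname(cod3$coding["RIL001", 2]), oracle, tolerance = 1e-10)
  expect_lt(oracle, -0.9)
})

test_that("pseudomarkers are inserted on the cM grid", {
  bins <- toy_bins()
  cod <- genotype_expectations(bins, toy_map(bins), step_cm = 1)
  expect_equal(sum(cod$points$is_bin), 5)
  expect_equal(nrow(cod$points), 21)   # 0..20 cM inclusive on the 1-cM grid
  expect_true(all(diff(cod$points$pos_cm) > 0))
  expect_false(any(is.na(cod$coding)))
})

test_that("the regression scan matches the closed-form oracle to 1e-8", {
  bins <- toy_bins()
  cod <- genotype_expectations(bins, toy_map(bins), step_cm = 0)
  # fixed 12-line toy phenotype
  y <- setNames(
    c(10.2, 11.1, 14.3, 12.0, 10.5, 13.8, 10.9, 14.1, 9.8, 13.0, 12.6, 14.4),
    sprintf("RIL%03d", 1:12)
  )
  sc <- scan_qtl(cod, y, trait = "PH", env = "E1")
  for (j in 1:5) {
    o <- oracle_lod(cod$coding[, j], y)
    expect_equal(sc$lod[j], o$lod, tolerance = 1e-8)
    expect_equal(sc$effect[j], o$beta, tolerance = 1e-8)
    expect_equal(sc$pve[j], o$pve, tolerance = 1e-8)
  }
  expect_true(all(sc$lod >= 0))

  # constant coding column -> LOD 0
  bins0 <- bins
  for (id in sprintf("RIL%03d", 1:12)) bins0[[id]][1] <- "A"
  cod0 <- genotype_expectations(bins0, toy_map(bins), step_cm = 0)
  sc0 <- scan_qtl(cod0, y)
  expect_equal(sc0$lod[1], 0)

  expect_error(scan_qtl(cod, y[1:5]), "10")
  expect_error(scan_qtl(cod, setNames(rep(1, 12), names(y))), "variance")
})

test_that("permutation thresholds are deterministic and floor at 3.5", {
  bins <- toy_bins()
  cod <- genotype_expectations(bins, toy_map(bins), step_cm = 0)
  y <- setNames(rnorm(12, 10, 2), sprintf("RIL%03d", 1:12))
  t1 <- permutation_threshold(cod, y, n_perm = 200, seed = 7)
  t2 <- permutation_threshold(cod, y, n_perm = 200, seed = 7)
  expect_identical(t1$max_lods, t2$max_lods)
  expect_identical(t1$threshold, t2$threshold)
  expect_equal(t1$effective, max(t1$threshold, 3.5))
  expect_equal(t1$n_perm, 200)
  expect_error(permutation_threshold(cod, y, n_perm = 50), "100")
})

test_that("support intervals implement the LOD-drop rule", {
  sc <- fake_scan(c(1, 5, 1))
  ci <- support_interval(sc, peak_point = 2, drop = 1.5)
  expect_equal(ci$peak_point, 2)
  expect_equal(ci$flank_left, "mk0002")
  expect_equal(ci$flank_right, "mk0002")

  # hand-evaluated drop rule on a 6-point profile: peak 5.0 at point 3,
  # the contiguous run with LOD >= 3.5 is points 2..4
  sc2 <- fake_scan(c(2.0, 3.9, 5.0, 4.1, 3.2, 1.0))
  ci2 <- support_interval(sc2, peak_point = 3, drop = 1.5)
  expect_equal(ci2$flank_left, "mk0002")
  expect_equal(ci2$flank_right, "mk0004")
  expect_equal(ci2$ci_start_bp, 1e6)
  expect_equal(ci2$ci_end_bp, 4e6)
  # a deeper drop widens the interval to points 2..5
  ci3 <- support_interval(sc2, peak_point = 3, drop = 2.0)
  expect_equal(ci3$flank_right, "mk0005")
})

test_that("QTL summaries merge environments by interval overlap", {
  expect_equal(nrow(summarize_qtl(list(fake_scan(rep(1, 8))), 3.5)), 0)

  s1 <- fake_scan(c(1, 4, 6, 4, 1, 1, 1, 1), env = "E1")
  s2 <- fake_scan(c(1, 1, 4, 6, 4, 1, 1, 1), env = "E2")
  s3 <- fake_scan(c(1, 1, 1, 1, 1, 1, 6, 4), env = "E3")
  res <- summarize_qtl(list(s1, s2, s3), 3.5)
  expect_s3_class(res, "qtl_result")
  expect_equal(nrow(res), 2)
  merged <- res[res$n_env == 2, ]
  expect_equal(merged$envs, "E1,E2")
  expect_equal(merged$lod, 6)
  expect_equal(merged$qtl, "qPH1-1")
  # union of the member 1.5-LOD intervals (each is its lone peak point)
  expect_equal(merged$ci_start_bp, 2e6)
  expect_equal(merged$ci_end_bp, 4e6)
  single <- res[res$n_env == 1, ]
  expect_equal(single$envs, "E3")
  expect_equal(single$qtl, "qPH1-2")

  stable <- find_stable_qtl(res)
  expect_equal(stable$qtl, "qPH1-1")
  expect_equal(nrow(find_stable_qtl(res, min_env = 3)), 0)
})

test_that("planting a positive Qi319 effect yields a positive ADD", {
  bins <- toy_bins()
  cod <- genotype_expectations(bins, toy_map(bins), step_cm = 0)
  x <- cod$coding[, 3]
  withr::with_seed(17, {
    y <- setNames(10 + 2 * x + rnorm(12, 0, 0.5),
                  rownames(cod$coding))
  })
  sc <- scan_qtl(cod, y)
  expect_gt(sc$effect[3], 0)
  expect_equal(sc$effect[3], oracle_lod(x, y)$beta, tolerance = 1e-8)
})

test_that("pleiotropic integration chains overlapping intervals", {
  res <- tibble(
    qtl = c("qPH1", "qEH1", "qIN2"),
    trait = c("PH", "EH", "IN"),
    chrom = c("chr1", "chr1", "chr2"),
    ci_start_bp = c(10e6, 14e6, 10e6),
    ci_end_bp = c(15e6, 22e6, 15e6)
  )
  p <- integrate_pleiotropic(res)
  expect_equal(nrow(p), 1)
  expect_equal(p$pqtl, "pQTL1")
  expect_equal(p$start_bp, 10e6)
  expect_equal(p$end_bp, 22e6)
  expect_equal(p$n_qtl, 2)

  # QTL on different chromosomes never merge
  res2 <- res[c(1, 3), ]
  expect_equal(nrow(integrate_pleiotropic(res2)), 0)

  # same chromosome, same trait only: not pleiotropic
  res3 <- res[1:2, ]
  res3$trait <- "PH"
  expect_equal(nrow(integrate_pleiotropic(res3)), 0)
})
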