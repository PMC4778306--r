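#' Configure the simulate -> filter -> call -> bin -> map -> scan pipeline
#'
#' Collects every stage parameter in one validated list. Defaults follow the
#' published protocol where one exists: 15-SNP windows sliding by 1 with an
#' 11-count homozygosity threshold, chi-square filter at p < 0.001, 100-Kb
#' bin grid, 1000 permutations at alpha 0.05 with a 3.5 LOD floor and
#' 1.5-LOD support intervals, 314 F11 lines.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Root seed; stage seeds are derived from it.
#' @param spec [genome_spec()] used when simulating.
#' @param truth [qtl_truth()] used when simulating phenotypes.
#' @param n_rils,n_selfing Population size and selfing generations.
#' @param observe_rate,allele_error_rate GBS observation model.
#' @param window,step,hom_threshold Sliding-window caller parameters.
#' @param alpha_seg Segregation-distortion removal level.
#' @param min_block_windows Optional block smoothing (1 = off).
#' @param bin_unit Bin grid unit in bp.
#' @param rmax Observed recombination frequency clamp.
#' @param n_perm,alpha_qtl,lod_floor,lod_drop,step_cm Scan parameters.
#' @param snp_file,pheno_file Optional external inputs (TSV / CSV as written
#'   by [write_snp_tsv()] / [write_phenotypes()]); when given, simulation is
#'   skipped.
#' @param verbose Log stage markers to stderr.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("rilqtl_run_"), seed = 1,
                            spec = maize_genome_spec(),
                            truth = default_qtl_truth(spec),
                            n_rils = 314, n_selfing = 10,
                            observe_rate = 0.05, allele_error_rate = 0.01,
                            window = 15, step = 1, hom_threshold = 11,
                            alpha_seg = 0.001, min_block_windows = 1,
                            bin_unit = 1e5, rmax = 0.49,
                            n_perm = 1000, alpha_qtl = 0.05,
                            lod_floor = 3.5, lod_drop = 1.5, step_cm = 1,
                            snp_file = NULL, pheno_file = NULL,
                            verbose = TRUE) {
  cfg <- as.list(environment())
  assert_genome_spec(cfg$spec)
  stopifnot(
    inherits(cfg$truth, "qtl_truth"), cfg$n_rils >= 1, cfg$n_selfing >= 0,
    cfg$bin_unit > 0, cfg$n_perm >= 100, cfg$lod_drop > 0
  )
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' Scalar parameters are taken verbatim; the genome is rebuilt from the
#' `genome` block (`chrom`, `length_bp`, `length_cm`, `n_snps` arrays) and
#' the trait model from the `qtl`, `trait_means`, `env_offsets`, `gxe_sd`,
#' `resid_sd`, `n_rep` blocks when present. Unknown keys are rejected.
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(pipeline_config)), c("spec", "truth"))
  extra <- setdiff(names(raw),
                   c(known, "genome", "qtl", "trait_means", "env_offsets",
                     "gxe_sd", "resid_sd", "n_rep"))
  if (length(extra)) {
    abort(paste("unknown config keys:", paste(extra, collapse = ", ")))
  }
  args <- raw[intersect(names(raw), known)]
  if (!is.null(raw$genome)) {
    g <- raw$genome
    args$spec <- genome_spec(g$length_bp, g$length_cm,
                             n_snps = g$n_snps %||% 1000,
                             chrom = g$chrom)
  }
  spec <- args$spec %||% maize_genome_spec()
  if (!is.null(raw$qtl)) {
    offs <- do.call(rbind, raw$env_offsets)
    args$truth <- qtl_truth(
      as_tibble(raw$qtl),
      trait_means = unlist(raw$trait_means),
      env_offsets = offs,
      gxe_sd = unlist(raw$gxe_sd), resid_sd = unlist(raw$resid_sd),
      n_rep = raw$n_rep %||% 2
    )
  }
  do.call(pipeline_config, args)
}

stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 997 + k * 101) %% (.Machine$integer.max - 1) + 1)
}

#' Run the full pipeline
#'
#' Simulates (or loads) a SNP matrix and phenotypes, filters distorted SNPs,
#' calls genotype blocks and breakpoints, builds the bin map and the genetic
#' map, computes trait statistics and heritability, scans every trait in
#' every environment with permutation thresholds, and integrates stable and
#' pleiotropic QTL. All tables are written to `config$out_dir` as TSV/CSV
#' together with a JSON run manifest; re-running with the same config is
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate object (`snp`, `filter`,
#'   `blocks`, `breakpoints`, `bins`, `gmap`, `map_summary`, `pheno`,
#'   `trait_stats`, `heritability`, `scans`, `thresholds`, `qtl`, `stable`,
#'   `pqtl`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (cfg$verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  out <- list()

  # --- simulate / load -------------------------------------------------
  if (is.null(cfg$snp_file)) {
    say("simulate", "breeding %d lines, %d selfing generations",
        cfg$n_rils, cfg$n_selfing)
    moz <- breed_ril_population(cfg$spec, cfg$n_rils, cfg$n_selfing,
                                seed = stage_seed(cfg$seed, 1))
    snp <- observe_gbs(moz, cfg$spec, cfg$observe_rate,
                       cfg$allele_error_rate, seed = stage_seed(cfg$seed, 2))
    pheno <- simulate_phenotypes(moz, cfg$truth,
                                 seed = stage_seed(cfg$seed, 3))
    out$mosaics <- moz
    write_phenotypes(pheno, file.path(cfg$out_dir, "phenotypes.csv"))
    write_snp_tsv(snp, file.path(cfg$out_dir, "snp_matrix.tsv"))
  } else {
    say("load", "reading %s", cfg$snp_file)
    if (!file.exists(cfg$snp_file)) {
      abort(sprintf("[load] SNP file not found: %s", cfg$snp_file))
    }
    snp <- read_snp_tsv(cfg$snp_file)
    if (is.null(cfg$pheno_file)) {
      abort("[scan] phenotype file required when loading external SNPs")
    }
    if (!file.exists(cfg$pheno_file)) {
      abort(sprintf("[scan] phenotype file not found: %s", cfg$pheno_file))
    }
    pheno <- read_phenotypes(cfg$pheno_file)
  }
  out$snp <- snp
  out$pheno <- pheno

  # --- filter ----------------------------------------------------------
  flt <- filter_segregation(snp, cfg$alpha_seg)
  say("filter", "%d SNPs in, %d distorted, %d uninformative, %d retained",
      flt$report$n_input, flt$report$n_distorted,
      flt$report$n_uninformative, flt$report$n_retained)
  readr::write_tsv(flt$report, file.path(cfg$out_dir, "filter_report.tsv"))
  out$filter <- flt

  # --- call blocks and breakpoints ------------------------------------
  blocks <- call_genotype_blocks(flt$snp, cfg$window, cfg$step,
                                 cfg$hom_threshold, cfg$min_block_windows)
  bps <- extract_breakpoints(blocks)
  say("callbins", "%d blocks, %d breakpoints (%.2f per line)",
      nrow(blocks), bps$n_total, bps$mean_per_ril)
  readr::write_tsv(blocks, file.path(cfg$out_dir, "blocks.tsv"))
  readr::write_tsv(bps$breakpoints, file.path(cfg$out_dir, "breakpoints.tsv"))
  out$blocks <- blocks
  out$breakpoints <- bps

  # --- bins and genetic map -------------------------------------------
  bins <- build_bins(blocks, cfg$spec, cfg$bin_unit, breakpoints = bps)
  stats <- bin_stats(bins)
  say("binmap", "%d bins, mean length %.0f Kb",
      stats$summary$n_bins, stats$summary$mean_length_bp / 1e3)
  readr::write_tsv(bins, file.path(cfg$out_dir, "bin_map.tsv"))
  readr::write_tsv(stats$summary, file.path(cfg$out_dir, "bin_stats.tsv"))
  gmap <- build_genetic_map(bins, cfg$rmax)
  msum <- map_summary(gmap)
  say("map", "total %.2f cM over %d markers",
      msum$length_cm[msum$chrom == "Total"],
      msum$n_markers[msum$chrom == "Total"])
  readr::write_tsv(gmap, file.path(cfg$out_dir, "genetic_map.tsv"))
  readr::write_tsv(msum, file.path(cfg$out_dir, "map_summary.tsv"))
  out$bins <- bins
  out$bin_stats <- stats
  out$gmap <- gmap
  out$map_summary <- msum

  # --- phenotype statistics -------------------------------------------
  traits <- pheno_trait_cols(pheno)
  tstats <- descriptive_stats(pheno)
  herit <- list_rbind(map(traits, function(tr) {
    vc <- anova_components(pheno, tr)
    tibble(trait = tr, v_genotype = vc$genotype, v_gxe = vc$gxe,
           v_error = vc$error, heritability = heritability(vc))
  }))
  say("pheno", "heritabilities: %s",
      paste(sprintf("%s %.2f", herit$trait, herit$heritability),
            collapse = ", "))
  readr::write_tsv(tstats, file.path(cfg$out_dir, "trait_stats.tsv"))
  readr::write_tsv(herit, file.path(cfg$out_dir, "heritability.tsv"))
  out$trait_stats <- tstats
  out$heritability <- herit

  # --- QTL scans -------------------------------------------------------
  coding <- genotype_expectations(bins, gmap, cfg$step_cm)
  lm_ <- line_means(pheno)
  envs <- sort(unique(lm_$env))
  scans <- list()
  thresholds <- list()
  k <- 0
  for (tr in traits) {
    for (ev in envs) {
      k <- k + 1
      y <- lm_ %>% filter(.data$env == ev) %>%
        transmute(ril = .data$ril, value = .data[[tr]])
      sc <- scan_qtl(coding, y, trait = tr, env = ev)
      th <- permutation_threshold(coding, y, cfg$n_perm, cfg$alpha_qtl,
                                  cfg$lod_floor,
                                  seed = stage_seed(cfg$seed, 10 + k))
      say("scan", "%s %s: max LOD %.2f, threshold %.2f",
          tr, ev, max(sc$lod), th$effective)
      scans[[paste(tr, ev, sep = ":")]] <- sc
      thresholds[[paste(tr, ev, sep = ":")]] <- th
    }
  }
  qtl <- summarize_qtl(scans, map_dbl(thresholds, "effective"),
                       drop = cfg$lod_drop)
  stable <- find_stable_qtl(qtl)
  pqtl <- integrate_pleiotropic(qtl)
  say("report", "%d QTL, %d stable, %d pleiotropic regions",
      nrow(qtl), nrow(stable), nrow(pqtl))
  readr::write_tsv(qtl, file.path(cfg$out_dir, "qtl.tsv"))
  readr::write_tsv(stable, file.path(cfg$out_dir, "qtl_stable.tsv"))
  readr::write_tsv(pqtl, file.path(cfg$out_dir, "pqtl.tsv"))
  out$scans <- scans
  out$thresholds <- thresholds
  out$qtl <- qtl
  out$stable <- stable
  out$pqtl <- pqtl

  # --- manifest --------------------------------------------------------
  params <- cfg[setdiff(names(cfg), c("spec", "truth", "verbose"))]
  manifest <- list(
    package = "rilqtl",
    version = as.character(utils::packageVersion("rilqtl")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = params,
    genome = list(chrom = cfg$spec$chrom, length_bp = cfg$spec$length_bp,
                  length_cm = cfg$spec$length_cm, n_snps = cfg$spec$n_snps),
    parameter_hash = rlang::hash(list(params, cfg$spec$length_bp,
                                      cfg$spec$length_cm, cfg$spec$n_snps)),
    n_qtl = nrow(qtl), n_stable = nrow(stable), n_pqtl = nrow(pqtl)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
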