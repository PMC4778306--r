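#' Line means per environment
#'
#' Averages replicates within line x environment, the scale on which QTL
#' scans and correlations operate.
#'
#' @param pheno A phenotype tibble (`ril`, `env`, `rep`, one column per
#'   trait), e.g. from [simulate_phenotypes()] or [read_phenotypes()].
#' @return A tibble `ril`, `env`, one mean column per trait.
#' @export
line_means <- function(pheno) {
  pheno %>%
    group_by(.data$ril, .data$env) %>%
    summarise(across(-"rep", \(x) mean(x, na.rm = TRUE)), .groups = "drop")
}

pheno_trait_cols <- function(pheno) {
  setdiff(names(pheno), c("ril", "env", "rep"))
}

#' Descriptive statistics per trait and environment
#'
#' Computed on line means within each environment: range, mean, SD, skewness
#' (third standardized sample moment), excess kurtosis, and the coefficient
#' of variation `CV = 100 * SD / mean`. Zero-variance or zero-mean cases
#' yield `NA` for the undefined statistics.
#'
#' @inheritParams line_means
#' @return A tibble with one row per trait x environment: `trait`, `env`,
#'   `n`, `min`, `max`, `mean`, `sd`, `skewness`, `kurtosis`, `cv`.
#' @export
descriptive_stats <- function(pheno) {
  lm_ <- line_means(pheno)
  lm_ %>%
    tidyr::pivot_longer(all_of(pheno_trait_cols(pheno)),
                        names_to = "trait", values_to = "value") %>%
    filter(is.finite(.data$value)) %>%
    group_by(.data$trait, .data$env) %>%
    summarise(
      n = n(),
      min = min(.data$value),
      max = max(.data$value),
      mean = mean(.data$value),
      sd = sd(.data$value),
      skewness = moment_skewness(.data$value),
      kurtosis = moment_kurtosis(.data$value),
      .groups = "drop"
    ) %>%
    mutate(cv = ifelse(.data$mean != 0, 100 * .data$sd / abs(.data$mean),
                       NA_real_))
}

moment_skewness <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  n <- length(x)
  if (n < 3) return(NA_real_)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NA_real_)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' ANOVA variance components for a balanced multi-environment trial
#'
#' Method-of-moments estimates from the two-way genotype x environment ANOVA
#' with replication (genotype and interaction random): with `e` environments
#' and `r` replicates, `error = MS_error`,
#' `gxe = (MS_gxe - MS_error) / r`, `genotype = (MS_g - MS_gxe) / (e * r)`.
#' Negative estimates are clamped to zero with a warning. Unbalanced designs
#' are rejected.
#'
#' @inheritParams line_means
#' @param trait Name of the trait column to analyse.
#' @return A list of class `variance_components`: `genotype`, `gxe`, `error`,
#'   `n_env`, `n_rep`, `n_lines`, and the raw `mean_squares`.
#' @export
anova_components <- function(pheno, trait) {
  if (!trait %in% names(pheno)) abort(sprintf("unknown trait '%s'", trait))
  d <- pheno[is.finite(pheno[[trait]]), c("ril", "env", "rep", trait)]
  counts <- count(d, .data$ril, .data$env)
  if (length(unique(counts$n)) != 1 ||
      nrow(counts) != length(unique(d$ril)) * length(unique(d$env))) {
    abort("design is unbalanced; variance components need a balanced trial")
  }
  r <- counts$n[1]
  e <- length(unique(d$env))
  if (r < 2) abort("need at least 2 replicates to separate error from G x E")
  fit <- lm(d[[trait]] ~ factor(d$ril) * factor(d$env))
  tab <- anova(fit)
  ms <- setNames(tab$`Mean Sq`, rownames(tab))
  ms_g <- ms[["factor(d$ril)"]]
  ms_ge <- ms[["factor(d$ril):factor(d$env)"]]
  ms_err <- ms[["Residuals"]]
  comp <- c(
    genotype = (ms_g - ms_ge) / (e * r),
    gxe = (ms_ge - ms_err) / r,
    error = ms_err
  )
  if (any(comp < 0)) {
    warn("negative variance component estimate(s) clamped to zero")
    comp <- pmax(comp, 0)
  }
  structure(
    list(
      genotype = unname(comp["genotype"]), gxe = unname(comp["gxe"]),
      error = unname(comp["error"]), n_env = e, n_rep = r,
      n_lines = length(unique(d$ril)),
      mean_squares = c(genotype = ms_g, gxe = ms_ge, error = ms_err),
      trait = trait
    ),
    class = "variance_components"
  )
}

#' Broad-sense heritability on the multi-environment line-mean basis
#'
#' `H2 = V_g / (V_g + V_gxe / e + V_error / (e * r))`: the fraction of
#' line-mean phenotypic variance attributable to genetic variance.
#'
#' @param components A `variance_components` object from
#'   [anova_components()], or a list/vector with `genotype`, `gxe`, `error`,
#'   `n_env`, `n_rep`.
#' @return Heritability as a fraction in `[0, 1]`.
#' @examples
#' heritability(list(genotype = 4, gxe = 2, error = 6, n_env = 3, n_rep = 2))
#' @export
heritability <- function(components) {
  v <- components
  denom <- v$genotype + v$gxe / v$n_env + v$error / (v$n_env * v$n_rep)
  if (denom == 0) abort("all variance components are zero; H2 undefined")
  v$genotype / denom
}

#' Fractions of line-mean phenotypic variance by factor
#'
#' Partitions the line-mean variance `V_g + V_gxe/e + V_error/(e*r)` into its
#' genotype, genotype-by-environment, and residual shares; the genotype share
#' equals the broad-sense heritability.
#'
#' @inheritParams heritability
#' @return A one-row tibble: `genotype`, `gxe`, `residual` (summing to 1).
#' @export
variance_partition <- function(components) {
  v <- components
  parts <- c(
    genotype = v$genotype,
    gxe = v$gxe / v$n_env,
    residual = v$error / (v$n_env * v$n_rep)
  )
  if (sum(parts) == 0) abort("all variance components are zero")
  as_tibble(as.list(parts / sum(parts)))
}

#' Spearman rank correlations between traits
#'
#' Rank correlations between line means for every trait pair, within each
#' environment and pooled across environments (mean of line means), with
#' mid-ranked ties and asymptotic p-values.
#'
#' @inheritParams line_means
#' @return A tibble: `env` (`"pooled"` or environment id), `trait1`,
#'   `trait2`, `rho`, `p_value`, `n`.
#' @export
trait_correlations <- function(pheno) {
  lm_ <- line_means(pheno)
  traits <- pheno_trait_cols(pheno)
  if (length(unique(lm_$ril)) < 5) abort("need at least 5 lines")
  pooled <- lm_ %>%
    group_by(.data$ril) %>%
    summarise(across(all_of(traits), mean), .groups = "drop") %>%
    mutate(env = "pooled")
  sets <- bind_rows(mutate(lm_, env = .data$env), pooled)
  pairs <- utils::combn(traits, 2, simplify = FALSE)
  out <- sets %>%
    group_by(.data$env) %>%
    group_modify(function(d, key) {
      list_rbind(map(pairs, function(pr) {
        x <- d[[pr[1]]]
        y <- d[[pr[2]]]
        ok <- is.finite(x) & is.finite(y)
        if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
          return(tibble(trait1 = pr[1], trait2 = pr[2], rho = NA_real_,
                        p_value = NA_real_, n = sum(ok)))
        }
        ct <- suppressWarnings(
          cor.test(x[ok], y[ok], method = "spearman", exact = FALSE)
        )
        tibble(trait1 = pr[1], trait2 = pr[2],
               rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
      }))
    }) %>%
    ungroup()
  out
}
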