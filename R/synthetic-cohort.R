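# Synthetic cohort generator.
#
# Individual-level biobank data of the kind this pipeline analyzes are
# access-restricted, so every downstream stage is exercised on generated
# cohorts that emulate the study's data structure: log-normal metabolite peak
# areas with covariate effects, knockout effects injected on the log scale in
# SD units of the residual noise, left-censoring of each metabolite below a
# detection quantile (missing = below LOD), covariate missingness, and
# stratified EHR case rates with a configurable common odds ratio. Every
# injected effect is stored in a truth record so recovery tests can serve as
# the acceptance surface for stages with no externally printed numbers.

#' Specify a synthetic pLoF variant
#'
#' @param variant_id,gene identifiers.
#' @param n_homozygous,n_heterozygous carrier counts to inject.
#' @param maf minor allele frequency in \[0, 0.5\].
#' @param loftee `"HC"`, `"LC"` or `"none"`.
#' @param pathogenic logical pathogenicity flag.
#' @param in_omim,in_open_targets,drug_target logical gene-list memberships.
#' @param affected_metabolites data.frame with columns `metabolite_id`,
#'   `beta` (signed effect on homozygous carriers, in SD units of the
#'   residual noise), or `NULL` for no effect.
#' @return a `variant_spec` list.
#' @export
variant_spec <- function(variant_id, gene, n_homozygous = 0L,
                         n_heterozygous = 0L, maf = 0.01, loftee = "HC",
                         pathogenic = FALSE, in_omim = TRUE,
                         in_open_targets = FALSE, drug_target = FALSE,
                         affected_metabolites = NULL) {
  stopifnot(maf >= 0, maf <= 0.5, n_homozygous >= 0, n_heterozygous >= 0,
            loftee %in% c("HC", "LC", "none"))
  if (!is.null(affected_metabolites)) {
    stopifnot(is.data.frame(affected_metabolites),
              all(c("metabolite_id", "beta") %in% names(affected_metabolites)),
              all(is.finite(affected_metabolites$beta)))
  }
  structure(list(variant_id = variant_id, gene = gene,
                 n_homozygous = as.integer(n_homozygous),
                 n_heterozygous = as.integer(n_heterozygous),
                 maf = maf, loftee = loftee, pathogenic = pathogenic,
                 in_omim = in_omim, in_open_targets = in_open_targets,
                 drug_target = drug_target,
                 affected_metabolites = affected_metabolites),
            class = "variant_spec")
}

#' Configure a synthetic cohort
#'
#' @param n_samples total cohort size.
#' @param n_controls number of designated non-carrier controls
#'   (`<= n_samples`).
#' @param n_metabolites number of metabolite columns.
#' @param variants list of [variant_spec()] objects.
#' @param covariate_effects named list: metabolite ID -> list(covariate =
#'   name, slope = effect in SD units per SD of the covariate), or `NULL`.
#' @param lod_quantile per-metabolite left-censoring quantile in \[0, 1).
#' @param covariate_missing_rates named numeric vector of missing-data rates
#'   for `bmi`, `smoking`, `education`, `season` (all in \[0, 1\]).
#' @param ehr_specs data.frame with columns `variant_id`, `icd10_category`,
#'   `common_odds_ratio` (> 0), `baseline_rate`, or `NULL`.
#' @param het_effect_fraction fraction of the homozygous effect applied to
#'   heterozygous carriers (default 0.5).
#' @param factor_share fraction of residual noise variance shared through
#'   latent sample factors, emulating the strong inter-metabolite correlation
#'   of real panels (default 0.35; set 0 for independent metabolites).
#' @param n_factors number of latent factors (default `ceiling(m / 10)`).
#' @param seed integer RNG seed.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 981L, n_controls = 258L,
                          n_metabolites = 100L, variants = list(),
                          covariate_effects = NULL, lod_quantile = 0.05,
                          covariate_missing_rates = c(bmi = 0.2, smoking = 0.3,
                                                      education = 0.25,
                                                      season = 0.1),
                          ehr_specs = NULL, het_effect_fraction = 0.5,
                          factor_share = 0.35,
                          n_factors = ceiling(n_metabolites / 10),
                          seed = 1L) {
  stopifnot(n_controls <= n_samples, lod_quantile >= 0, lod_quantile < 1,
            factor_share >= 0, factor_share < 1,
            all(covariate_missing_rates >= 0 & covariate_missing_rates <= 1))
  if (!is.null(ehr_specs)) {
    stopifnot(all(ehr_specs$common_odds_ratio > 0),
              all(ehr_specs$baseline_rate >= 0 & ehr_specs$baseline_rate <= 1))
  }
  for (v in variants) {
    if (v$n_homozygous + v$n_heterozygous > n_samples) {
      stop("variant '", v$variant_id, "': n_homozygous + n_heterozygous (",
           v$n_homozygous + v$n_heterozygous, ") exceeds n_samples (",
           n_samples, ")")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_controls = as.integer(n_controls),
                 n_metabolites = as.integer(n_metabolites),
                 variants = variants, covariate_effects = covariate_effects,
                 lod_quantile = lod_quantile,
                 covariate_missing_rates = covariate_missing_rates,
                 ehr_specs = ehr_specs,
                 het_effect_fraction = het_effect_fraction,
                 factor_share = factor_share,
                 n_factors = as.integer(n_factors),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Shared-variance noise: metabolite panels are strongly correlated (a few
# hundred principal components explain most of the variance of >1000
# metabolites), so the residual noise mixes per-metabolite white noise with a
# small set of latent sample factors. Total noise variance stays 1 so the
# injected knockout effects remain in SD units.
.correlated_noise <- function(n, m, factor_share, n_factors) {
  eps <- matrix(stats::rnorm(n * m), nrow = n)
  if (factor_share <= 0 || n_factors == 0L) return(eps)
  f <- matrix(stats::rnorm(n * n_factors), nrow = n)
  load <- matrix(stats::rnorm(n_factors * m), nrow = n_factors)
  load <- sweep(load, 2, sqrt(colSums(load^2)), `/`)   # unit-variance mix
  sqrt(1 - factor_share) * eps + sqrt(factor_share) * (f %*% load)
}

# centered, unit-scale numeric version of a latent covariate vector
.scale_covariate <- function(x) {
  if (is.numeric(x)) as.numeric(scale(x)) else {
    z <- as.integer(factor(x))
    as.numeric(scale(z))
  }
}

#' Generate a synthetic cohort bundle
#'
#' Deterministic for a fixed seed. Metabolite peak areas are
#' `exp(baseline + covariate effects + variant effect + N(0, 1) noise)`;
#' values below each metabolite's `lod_quantile` are set missing. EHR case
#' indicators are drawn per sex x age stratum with stratum-varying baseline
#' log-odds so that the conditional (common) odds ratio between knockouts and
#' everyone else equals the configured value. Covariate effects act on the
#' latent (fully observed) covariates; missingness is injected afterwards
#' into the reported phenotype table only.
#'
#' @param config a [cohort_config()].
#' @return a `komet_cohort` list: `phenotypes`, `genotypes` (dosage matrix),
#'   `annotations`, `abundance`, `ehr`, `control_ids`, `gene_lists`, `truth`
#'   (injected metabolite effects and EHR odds ratios), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n <- config$n_samples
  ids <- sprintf("S%05d", seq_len(n))
  # latent phenotypes (fully observed; used for generation)
  latent <- data.frame(
    sample_id = ids,
    age = stats::runif(n, 18, 90),
    sex = sample(c("F", "M"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  for (k in 1:10) latent[[paste0("pc", k)]] <- stats::rnorm(n)
  latent$bmi <- stats::rnorm(n, 27, 4)
  latent$smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                           prob = c(0.5, 0.3, 0.2))
  latent$education <- sample(c("basic", "secondary", "higher"), n,
                             replace = TRUE)
  latent$season <- sample(c("winter", "spring", "summer", "autumn"), n,
                          replace = TRUE)

  # carrier assignment: controls never carry anything
  control_ids <- sort(sample(ids, config$n_controls))
  pool <- setdiff(ids, control_ids)
  geno <- matrix(0L, nrow = n, ncol = length(config$variants),
                 dimnames = list(ids, vapply(config$variants, `[[`, "",
                                             "variant_id")))
  for (v in config$variants) {
    need <- v$n_homozygous + v$n_heterozygous
    if (need > length(pool)) {
      stop("variant '", v$variant_id, "': not enough non-control samples (",
           length(pool), ") for ", need, " carriers")
    }
    picked <- sample(pool, need)
    geno[picked[seq_len(v$n_homozygous)], v$variant_id] <- 2L
    if (v$n_heterozygous > 0L) {
      geno[picked[v$n_homozygous + seq_len(v$n_heterozygous)],
           v$variant_id] <- 1L
    }
  }

  annotations <- do.call(rbind, lapply(seq_along(config$variants), function(i) {
    v <- config$variants[[i]]
    data.frame(variant_id = v$variant_id, gene = v$gene, chrom = "1",
               pos = 1000L * i, loftee = v$loftee, maf = v$maf,
               pathogenic = v$pathogenic, stringsAsFactors = FALSE)
  }))
  if (is.null(annotations)) {
    annotations <- data.frame(variant_id = character(), gene = character(),
                              chrom = character(), pos = integer(),
                              loftee = character(), maf = numeric(),
                              pathogenic = logical(), stringsAsFactors = FALSE)
  }

  # metabolites on the log scale: baseline + covariate effects + KO effect + noise
  met_ids <- sprintf("M%04d", seq_len(config$n_metabolites))
  logm <- .correlated_noise(n, config$n_metabolites, config$factor_share,
                            config$n_factors)
  dimnames(logm) <- list(ids, met_ids)
  baseline <- stats::runif(config$n_metabolites, 9, 13)
  logm <- sweep(logm, 2, baseline, `+`)
  if (!is.null(config$covariate_effects)) {
    for (mid in names(config$covariate_effects)) {
      eff <- config$covariate_effects[[mid]]
      logm[, mid] <- logm[, mid] +
        eff$slope * .scale_covariate(latent[[eff$covariate]])
    }
  }
  truth_effects <- list()
  for (v in config$variants) {
    if (is.null(v$affected_metabolites)) next
    hom <- rownames(geno)[geno[, v$variant_id] == 2L]
    het <- rownames(geno)[geno[, v$variant_id] == 1L]
    for (r in seq_len(nrow(v$affected_metabolites))) {
      mid <- v$affected_metabolites$metabolite_id[r]
      beta <- v$affected_metabolites$beta[r]
      logm[hom, mid] <- logm[hom, mid] + beta
      logm[het, mid] <- logm[het, mid] + beta * config$het_effect_fraction
      truth_effects[[length(truth_effects) + 1L]] <- data.frame(
        variant_id = v$variant_id, gene = v$gene, metabolite_id = mid,
        beta = beta, n_ko = length(hom), stringsAsFactors = FALSE)
    }
  }
  abundance <- exp(logm)
  if (config$lod_quantile > 0) {
    for (j in seq_len(ncol(abundance))) {
      lod <- stats::quantile(abundance[, j], config$lod_quantile, names = FALSE)
      abundance[abundance[, j] < lod, j] <- NA_real_
    }
  }

  # EHR: stratum-varying baseline log-odds; configured common OR for KOs
  age_bin <- cut(latent$age, breaks = seq(18, 98, by = 10), right = FALSE,
                 include.lowest = TRUE)
  ehr_rows <- list()
  if (!is.null(config$ehr_specs) && nrow(config$ehr_specs) > 0L) {
    for (r in seq_len(nrow(config$ehr_specs))) {
      spec <- config$ehr_specs[r, ]
      ko <- ids %in% rownames(geno)[geno[, spec$variant_id] == 2L]
      base_lo <- stats::qlogis(spec$baseline_rate) +
        0.3 * as.numeric(scale(as.integer(age_bin))) +
        0.2 * (latent$sex == "M")
      p <- stats::plogis(base_lo + log(spec$common_odds_ratio) * ko)
      case <- stats::runif(n) < p
      if (any(case)) {
        sub <- sprintf("%s.%d", spec$icd10_category,
                       sample(0:9, sum(case), replace = TRUE))
        ehr_rows[[length(ehr_rows) + 1L]] <- data.frame(
          sample_id = rep(ids[case], each = 2L),
          icd10_code = rep(sub, each = 2L), stringsAsFactors = FALSE)
      }
      # single (non-recurrent) events so the >=2 rule is exercised
      single <- !case & stats::runif(n) < spec$baseline_rate / 2
      if (any(single)) {
        ehr_rows[[length(ehr_rows) + 1L]] <- data.frame(
          sample_id = ids[single],
          icd10_code = sprintf("%s.%d", spec$icd10_category,
                               sample(0:9, sum(single), replace = TRUE)),
          stringsAsFactors = FALSE)
      }
    }
  }
  ehr <- if (length(ehr_rows)) do.call(rbind, ehr_rows) else
    data.frame(sample_id = character(), icd10_code = character(),
               stringsAsFactors = FALSE)
  rownames(ehr) <- NULL

  # reported phenotypes: inject covariate missingness
  phenotypes <- latent
  for (cv in names(config$covariate_missing_rates)) {
    rate <- config$covariate_missing_rates[[cv]]
    if (rate > 0) phenotypes[[cv]][stats::runif(n) < rate] <- NA
  }

  gene_lists <- list(
    omim = sort(unique(vapply(Filter(function(v) v$in_omim, config$variants),
                              `[[`, "", "gene"))),
    open_targets = sort(unique(vapply(Filter(function(v) v$in_open_targets,
                                             config$variants), `[[`, "", "gene"))),
    drug_targets = sort(unique(vapply(Filter(function(v) v$drug_target,
                                             config$variants), `[[`, "", "gene"))))

  truth <- list(
    metabolite_effects = if (length(truth_effects))
      do.call(rbind, truth_effects) else
        data.frame(variant_id = character(), gene = character(),
                   metabolite_id = character(), beta = numeric(),
                   n_ko = integer(), stringsAsFactors = FALSE),
    ehr_specs = config$ehr_specs)

  structure(list(phenotypes = phenotypes, genotypes = geno,
                 annotations = annotations, abundance = abundance, ehr = ehr,
                 control_ids = control_ids, gene_lists = gene_lists,
                 truth = truth, config = config),
            class = "komet_cohort")
}
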