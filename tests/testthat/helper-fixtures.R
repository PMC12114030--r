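# Shared fixture builders and independent oracles.

# Exhaustive one-sided rank-sum p by enumerating all C(N, n1) carrier rank
# assignments (independent of the package's dynamic program).
enum_wilcoxon_p <- function(carrier, control, greater = TRUE) {
  r <- rank(c(carrier, control))
  n1 <- length(carrier)
  w_obs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(length(r), n1)
  ws <- colSums(matrix(r[subsets], nrow = n1))
  if (greater) mean(ws >= w_obs - 1e-9) else mean(ws <= w_obs + 1e-9)
}

# A small cohort with one strong injected knockout effect plus null variants.
demo_cohort <- function(seed = 7, n_samples = 400, n_metabolites = 20,
                        beta = 5, n_ko = 6, lod_quantile = 0.05, ...) {
  vs <- list(
    variant_spec("v1", "GENE1", n_homozygous = n_ko, maf = 0.01,
                 affected_metabolites = data.frame(metabolite_id = "M0001",
                                                   beta = beta)),
    variant_spec("v2", "GENE2", n_homozygous = 3, n_heterozygous = 4,
                 maf = 0.005))
  cfg <- cohort_config(n_samples = n_samples, n_controls = 258,
                       n_metabolites = n_metabolites, variants = vs,
                       lod_quantile = lod_quantile, seed = seed, ...)
  generate_cohort(cfg)
}

# Quietly run the full preprocessing chain.
quiet_preprocess <- function(abundance, phenotypes, ...) {
  suppressMessages(suppressWarnings(
    preprocess_metabolites(abundance, phenotypes, ...)))
}

# Random 2x2 stratum with nonzero margins.
random_stratum <- function(max_n = 12) {
  repeat {
    tab <- matrix(rpois(4, 3) + c(0, 1, 0, 1), 2)
    if (all(rowSums(tab) > 0) && sum(tab[, 1]) > 0 && sum(tab) <= 4 * max_n)
      return(tab)
  }
}
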