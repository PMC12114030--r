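# EHR case definitions, stratification, the conditional exact test and the
# CMLE common odds ratio, each against an independent oracle.

test_that("recurrent case definition aggregates to the 3-character category", {
  ids <- c("s1", "s2", "s3", "s4")
  ev <- data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s3"),
    icd10_code = c("E79.8", "E79.8", "E79.9", "E79.8", "E79.9"),
    stringsAsFactors = FALSE)
  ct <- recurrent_case_table(ev, ids)
  expect_true(ct["s1", "E79"])    # same full code twice
  expect_false(ct["s2", "E79"])   # single event
  expect_true(ct["s3", "E79"])    # two different codes, same category
  expect_false(ct["s4", "E79"])
  # alternative count-then-aggregate reading differs for s3
  ct2 <- recurrent_case_table(ev, ids, category_level = FALSE)
  expect_true(ct2["s1", "E79"])
  expect_false(ct2["s3", "E79"])
  # malformed codes are skipped with a warning; lowercase/dots normalized
  ev_bad <- rbind(ev, data.frame(sample_id = c("s4", "s4", "s4"),
                                 icd10_code = c("9X", "e11.0", "E11.9")))
  expect_warning(ct3 <- recurrent_case_table(ev_bad, ids), "malformed")
  expect_true(ct3["s4", "E11"])
  expect_error(recurrent_case_table(
    data.frame(sample_id = "zz", icd10_code = "E79.8"), ids), "zz")
})

test_that("exclusions keep categories with >=5 cases and variants with >=2 knockouts", {
  ct <- matrix(FALSE, 20, 2, dimnames = list(sprintf("s%d", 1:20), c("A01", "B02")))
  ct[1:5, "A01"] <- TRUE
  ct[1:4, "B02"] <- TRUE
  cs <- list(v1 = list(hom = c("s1", "s2"), het = character()),
             v2 = list(hom = "s1", het = c("s2", "s3")))
  ex <- suppressMessages(apply_exclusions(ct, cs))
  expect_identical(ex$categories, "A01")
  expect_identical(ex$variants, "v1")
})

test_that("strata cross-tabulation matches brute force and conserves counts", {
  set.seed(20)
  n <- 200
  ph <- data.frame(sample_id = sprintf("s%03d", 1:n),
                   age = runif(n, 18, 88),
                   sex = sample(c("F", "M"), n, TRUE),
                   stringsAsFactors = FALSE)
  ko <- sample(ph$sample_id, 30)
  ctl <- setdiff(ph$sample_id, ko)
  case <- setNames(runif(n) < 0.2, ph$sample_id)
  strata <- build_strata(case, ko, ctl, ph, age_bin_years = 10)
  # conservation: cells sum to samples in non-dropped strata
  expect_lte(sum(unlist(strata)), n)
  # brute force: recount each stratum independently
  bin <- cut(ph$age, seq(18, max(ph$age) + 10, 10), right = FALSE,
             include.lowest = TRUE)
  key <- paste(ph$sex, bin, sep = ".")
  names(key) <- ph$sample_id
  for (s in names(strata)) {
    in_s <- names(key)[key == s]
    expect_identical(strata[[s]]["KO", "case"],
                     sum(in_s %in% ko & case[in_s]), label = s)
    expect_identical(strata[[s]]["control", "noncase"],
                     sum(in_s %in% ctl & !case[in_s]))
  }
  # one sex, one age bin -> exactly one stratum
  ph1 <- ph; ph1$sex <- "F"; ph1$age <- 25
  expect_length(build_strata(case, ko, ctl, ph1), 1L)
})

test_that("single-stratum conditional exact test equals Fisher's two-sided test", {
  set.seed(21)
  for (i in 1:20) {
    tab <- random_stratum()
    expect_equal(conditional_exact_test(list(a = tab))$p.value,
                 fisher.test(tab)$p.value, tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
  }
})

test_that("multi-stratum null distribution matches exhaustive enumeration", {
  set.seed(22)
  for (rep in 1:5) {
    strata <- replicate(3, random_stratum(5), simplify = FALSE)
    res <- conditional_exact_test(strata)
    expect_equal(sum(res$null$prob), 1, tolerance = 1e-12)
    # exhaustive: enumerate every margin-consistent table triple
    sup <- lapply(strata, komet:::.stratum_support)
    grid <- expand.grid(lapply(sup, function(s) s$x))
    lp <- rowSums(mapply(function(k) sup[[k]]$logd[match(grid[[k]], sup[[k]]$x)],
                         seq_along(sup)))
    t_all <- rowSums(grid)
    p_obs <- sum(exp(lp[t_all == res$t_obs]))
    p_enum <- sum(exp(lp)[vapply(t_all, function(t)
      sum(exp(lp[t_all == t])), numeric(1)) <= p_obs * (1 + 1e-7)])
    expect_equal(res$p.value, p_enum, tolerance = 1e-10)
  }
})

test_that("conditional test and CMLE agree with mantelhaen.test(exact = TRUE)", {
  set.seed(23)
  for (i in 1:8) {
    strata <- replicate(sample(2:3, 1), random_stratum(), simplify = FALSE)
    arr <- array(0, c(2, 2, length(strata)))
    for (k in seq_along(strata)) arr[, , k] <- strata[[k]]
    mh <- mantelhaen.test(arr, exact = TRUE)
    expect_equal(conditional_exact_test(strata)$p.value, mh$p.value,
                 tolerance = 1e-9)
    est <- cmle_common_or(strata)
    if (!est$boundary && is.finite(mh$estimate)) {
      expect_equal(est$psi, unname(mh$estimate), tolerance = 1e-3)
    }
  }
})

test_that("CMLE matches a brute-force likelihood grid for a single stratum", {
  tab <- matrix(c(2, 8, 1, 9), 2, byrow = TRUE)
  est <- cmle_common_or(list(tab))
  # grid maximization of the noncentral hypergeometric likelihood
  s <- komet:::.stratum_support(tab)
  loglik <- function(psi) {
    lw <- s$logd + s$x * log(psi)
    lw[match(s$a_obs, s$x)] - log(sum(exp(lw - max(lw)))) - max(lw)
  }
  grid <- exp(seq(log(0.01), log(100), length.out = 20000))
  psi_grid <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  expect_equal(est$psi, psi_grid, tolerance = 1e-3)
})

test_that("expected T is strictly increasing in psi and boundaries yield 0 / Inf", {
  set.seed(24)
  strata <- replicate(3, random_stratum(), simplify = FALSE)
  sup <- lapply(strata, komet:::.stratum_support)
  lps <- seq(-3, 3, length.out = 25)
  et <- vapply(lps, function(lp) komet:::.expected_t(lp, sup), numeric(1))
  expect_true(all(diff(et) > 0))
  # boundary: observed T at the minimum of its range
  tab0 <- matrix(c(0, 5, 3, 7), 2, byrow = TRUE)
  expect_identical(cmle_common_or(list(tab0))$psi, 0)
  tabI <- matrix(c(3, 2, 0, 10), 2, byrow = TRUE)
  expect_identical(cmle_common_or(list(tabI))$psi, Inf)
})

test_that("null CMLE is centred at 1 over replicates", {
  set.seed(25)
  psis <- vapply(1:100, function(i) {
    strata <- replicate(3, {
      a <- rbinom(1, 15, 0.3); c <- rbinom(1, 40, 0.3)
      matrix(c(a, 15 - a, c, 40 - c), 2, byrow = TRUE)
    }, simplify = FALSE)
    log(cmle_common_or(strata)$psi)
  }, numeric(1))
  psis <- psis[is.finite(psis)]
  se <- sd(psis) / sqrt(length(psis))
  expect_lt(abs(mean(psis)), 3 * se)
})

test_that("adding a stratum with a zero margin changes neither p nor psi", {
  tabs <- list(matrix(c(3, 7, 2, 18), 2, byrow = TRUE),
               matrix(c(2, 5, 4, 20), 2, byrow = TRUE))
  zero <- matrix(c(0, 0, 0, 10), 2, byrow = TRUE)  # no KOs, no cases
  expect_equal(conditional_exact_test(tabs)$p.value,
               conditional_exact_test(c(tabs, list(zero)))$p.value,
               tolerance = 1e-12)
  expect_equal(cmle_common_or(tabs)$psi,
               cmle_common_or(c(tabs, list(zero)))$psi, tolerance = 1e-9)
  # no informative stratum at all
  res <- conditional_exact_test(list(zero))
  expect_identical(res$p.value, 1)
})

test_that("disease_scan derives its threshold from surviving counts and ranks an injected OR first", {
  vs <- list(variant_spec("v1", "G1", n_homozygous = 60),
             variant_spec("v2", "G2", n_homozygous = 40))
  cfg <- cohort_config(
    n_samples = 3000, n_controls = 2500, n_metabolites = 2, variants = vs,
    ehr_specs = data.frame(
      variant_id = c("v1", "v2"),
      icd10_category = c("E79", "J45"),
      common_odds_ratio = c(20, 1),
      baseline_rate = c(0.05, 0.2)),
    seed = 26)
  b <- generate_cohort(cfg)
  ct <- recurrent_case_table(b$ehr, b$phenotypes$sample_id)
  cs <- carrier_sets_from_genotypes(b$genotypes)
  ds <- suppressMessages(disease_scan(ct, cs, b$control_ids, b$phenotypes))
  expect_equal(attr(ds, "threshold"),
               0.05 / (ncol(ct[, colSums(ct) >= 5, drop = FALSE]) * 2))
  top <- ds[1, ]
  expect_identical(paste(top$variant_id, top$category), "v1 E79")
  expect_gt(top$cmle_or, 5)
})
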