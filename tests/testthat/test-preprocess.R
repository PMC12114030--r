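# Missingness filter, log transform and the two-stage covariate adjustment.

make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  ph <- data.frame(sample_id = sprintf("S%04d", 1:n),
                   age = runif(n, 18, 90),
                   sex = sample(c("F", "M"), n, TRUE),
                   stringsAsFactors = FALSE)
  for (k in 1:10) ph[[paste0("pc", k)]] <- rnorm(n)
  ph$bmi <- rnorm(n, 27, 4)
  ph$smoking <- sample(c("never", "former", "current"), n, TRUE)
  ph$education <- sample(c("basic", "secondary", "higher"), n, TRUE)
  ph$season <- sample(c("winter", "spring", "summer", "autumn"), n, TRUE)
  ph
}

test_that("missingness filter uses a strict inequality at the threshold", {
  n <- 981
  m <- matrix(exp(rnorm(n * 3)), n, 3,
              dimnames = list(sprintf("S%04d", 1:n), c("keep1", "drop1", "edge")))
  m[1:933, "drop1"] <- NA   # 95.1% > 95% -> removed
  m[1:931, "edge"] <- NA    # 94.9% -> kept
  out <- suppressMessages(filter_by_missingness(m, 0.95))
  expect_setequal(colnames(out), c("keep1", "edge"))
  expect_identical(attr(out, "removed"), "drop1")
  expect_identical(nrow(out), as.integer(n))  # samples untouched
  expect_error(filter_by_missingness(m, 1.2), "max_missing")
})

test_that("log transform is elementwise, preserves missingness, rejects non-positive values", {
  m <- matrix(c(1, exp(1), NA, 4), 2, 2,
              dimnames = list(c("a", "b"), c("m1", "m2")))
  lt <- log_transform(m)
  expect_equal(lt["a", "m1"], 0)
  expect_equal(lt["b", "m1"], 1)
  expect_true(is.na(lt["a", "m2"]))
  m["a", "m1"] <- 0
  expect_error(log_transform(m), "sample 'a', metabolite 'm1'")
})

test_that("stage-1 residuals match a textbook hat-matrix computation on a 20x13 design", {
  ph <- make_pheno(20, seed = 3)
  set.seed(4)
  y <- matrix(rnorm(20 * 2) + 5, 20, 2,
              dimnames = list(ph$sample_id, c("m1", "m2")))
  r <- stage1_residualize(y, ph)
  X <- cbind(1, ph$age, as.numeric(ph$sex == "M"),
             as.matrix(ph[paste0("pc", 1:10)]))
  H <- X %*% solve(crossprod(X)) %*% t(X)
  r_oracle <- (diag(20) - H) %*% y
  expect_lt(max(abs(r - r_oracle)), 1e-10)
  # residuals orthogonal to every regressor
  expect_lt(max(abs(crossprod(X, r))), 1e-6 * 20)
})

test_that("stage-1 removes covariate signal and maps constants to zero", {
  ph <- make_pheno(500, seed = 5)
  set.seed(6)
  y <- matrix(NA_real_, 500, 2, dimnames = list(ph$sample_id, c("agey", "const")))
  y[, "agey"] <- 2 * ph$age + rnorm(500)
  y[, "const"] <- 7
  r <- stage1_residualize(y, ph)
  expect_lt(abs(cor(r[, "agey"], ph$age)), 0.05)
  expect_lt(max(abs(r[, "const"])), 1e-10)
})

test_that("covariate selection has power for a real BMI effect and rejects one-level factors", {
  ph <- make_pheno(500, seed = 7)
  set.seed(8)
  y <- matrix(0.5 * scale(ph$bmi) + rnorm(500), 500, 1,
              dimnames = list(ph$sample_id, "m1"))
  r <- stage1_residualize(y, ph)
  sel <- select_covariates(r, ph)
  expect_true("bmi" %in% sel$m1)

  ph1 <- ph
  ph1$season <- "winter"
  expect_warning(sel1 <- select_covariates(r, ph1), "single observed level")
  expect_false("season" %in% sel1$m1)
})

test_that("null covariates are selected at roughly the test level", {
  set.seed(9)
  hits <- 0L
  n_reps <- 400
  ph <- make_pheno(60, seed = 10)
  for (i in seq_len(n_reps)) {
    y <- matrix(rnorm(60), 60, 1, dimnames = list(ph$sample_id, "m1"))
    r <- stage1_residualize(y, ph)
    sel <- select_covariates(r, ph, alpha = 0.05)
    hits <- hits + ("bmi" %in% sel$m1)
  }
  rate <- hits / n_reps
  se <- sqrt(0.05 * 0.95 / n_reps)
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("stage 2 with empty selection equals z-scored stage-1 residuals", {
  ph <- make_pheno(100, seed = 11)
  set.seed(12)
  y <- matrix(rnorm(300) + 8, 100, 3,
              dimnames = list(ph$sample_id, paste0("m", 1:3)))
  sel <- setNames(rep(list(character()), 3), colnames(y))
  r2 <- stage2_residualize(y, ph, sel)
  r1 <- stage1_residualize(y, ph)
  z1 <- apply(r1, 2, function(v) (v - mean(v)) / sd(v))
  expect_lt(max(abs(r2 - z1)), 1e-10)
})

test_that("stage-2 missingness is the union of metabolite and selected-covariate missingness", {
  ph <- make_pheno(200, seed = 13)
  set.seed(14)
  ph$bmi[sample(200, 20)] <- NA
  y <- matrix(rnorm(200) + 9, 200, 1, dimnames = list(ph$sample_id, "m1"))
  y[sample(200, 15), 1] <- NA
  r2 <- stage2_residualize(y, ph, list(m1 = "bmi"))
  expect_identical(is.na(r2[, 1]), is.na(y[, 1]) | is.na(ph$bmi))
})

test_that("normalized residuals have mean 0 and SD 1 to 1e-8; residualization is idempotent", {
  b <- demo_cohort(seed = 15)
  pr <- quiet_preprocess(b$abundance, b$phenotypes)
  r <- pr$residuals
  mu <- apply(r, 2, function(v) mean(v, na.rm = TRUE))
  sg <- apply(r, 2, function(v) sd(v, na.rm = TRUE))
  expect_lt(max(abs(mu)), 1e-8)
  expect_lt(max(abs(sg - 1)), 1e-8)
  # no imputation: missingness can only grow
  expect_true(all(is.na(r) | !is.na(b$abundance[rownames(r), colnames(r)])))
  # idempotence: residualizing the residuals changes nothing
  sel <- attr(r, "selected_covariates")
  r_again <- suppressWarnings(stage2_residualize(r, b$phenotypes, sel))
  expect_lt(max(abs(r_again - r), na.rm = TRUE), 1e-10)
})

test_that("full two-stage run recovers a null covariate relationship", {
  # generating model has a BMI effect on M0002; after adjustment the
  # residual-vs-covariate slope must be statistically null
  b <- demo_cohort(seed = 16, n_samples = 500,
                   covariate_effects = list(M0002 = list(covariate = "bmi",
                                                         slope = 0.5)))
  pr <- quiet_preprocess(b$abundance, b$phenotypes)
  expect_true("bmi" %in% pr$selected_covariates$M0002)
  r <- pr$residuals[, "M0002"]
  use <- !is.na(r) & !is.na(b$phenotypes$bmi)
  fit <- summary(lm(r[use] ~ b$phenotypes$bmi[use]))$coefficients
  expect_lt(abs(fit[2, 1]), 2 * fit[2, 2])
})
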