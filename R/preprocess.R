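# Metabolite preprocessing: missingness filter, log transform, and the
# two-stage covariate adjustment producing normalized residual values.
#
# Stage 1 regresses each log metabolite on the always-observed covariates
# (age, sex, 10 genotype PCs). Candidate covariates with substantial
# missingness (BMI, smoking, education, sampling season) are then tested
# marginally against the stage-1 residuals; stage 2 refits each metabolite
# from the log values on the base covariates plus only its significantly
# associated candidates, so samples are dropped only for covariates that
# matter for that metabolite. Residuals are z-scored per metabolite.

.BASE_COVARIATES <- c("age", "sex", paste0("pc", 1:10))
.CANDIDATE_COVARIATES <- c("bmi", "smoking", "education", "season")

#' Drop metabolites that are almost never detected
#'
#' Metabolites missing (below the limit of detection) in more than
#' `max_missing` of the samples carry too little signal to test and are
#' removed. The comparison is strict: a metabolite missing in exactly the
#' threshold fraction is kept.
#'
#' @param abundance numeric matrix samples x metabolites, `NA` = below LOD.
#' @param max_missing maximum tolerated missing fraction, in \[0, 1\].
#' @return the filtered matrix; removed metabolite IDs are attached as
#'   attribute `"removed"` and reported via `message()`.
#' @export
filter_by_missingness <- function(abundance, max_missing = 0.95) {
  if (!is.numeric(max_missing) || max_missing < 0 || max_missing > 1) {
    stop("max_missing must be in [0, 1]")
  }
  if (nrow(abundance) == 0L || ncol(abundance) == 0L) stop("abundance matrix is empty")
  frac <- colMeans(is.na(abundance))
  drop <- frac > max_missing
  removed <- colnames(abundance)[drop]
  if (length(removed)) {
    message(length(removed), " metabolite(s) removed for missingness > ",
            max_missing, "; ", sum(!drop), " retained")
  }
  out <- abundance[, !drop, drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Natural-log transform of a peak-area matrix
#'
#' @param abundance numeric matrix of positive peak areas, `NA` = missing.
#' @return elementwise `log(abundance)`; missing stays missing.
#' @export
log_transform <- function(abundance) {
  bad <- which(!is.na(abundance) & abundance <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("non-positive abundance value at sample '",
         rownames(abundance)[bad[1, 1]], "', metabolite '",
         colnames(abundance)[bad[1, 2]], "'")
  }
  log(abundance)
}

# Build the base design matrix (intercept, age, sex indicator, 10 PCs) from a
# phenotype table, dropping constant columns with a warning (rank deficiency).
.base_design <- function(phenotypes) {
  need <- .BASE_COVARIATES
  missing_cols <- setdiff(need, names(phenotypes))
  if (length(missing_cols)) stop("phenotype table lacks column(s): ",
                                 paste(missing_cols, collapse = ", "))
  if (anyNA(phenotypes[need])) {
    stop("stage-1 covariates (age, sex, pc1..pc10) must be fully observed")
  }
  X <- cbind(`(Intercept)` = 1,
             age = phenotypes$age,
             sexM = as.numeric(phenotypes$sex == "M"),
             as.matrix(phenotypes[paste0("pc", 1:10)]))
  const <- apply(X[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warning("constant covariate column(s) dropped from design: ",
            paste(names(const)[const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  X
}

# OLS residuals of y on X over rows `use`; positions outside `use` are NA.
.ols_residuals <- function(y, X, use) {
  r <- rep(NA_real_, length(y))
  if (sum(use) < ncol(X) + 2L) return(NULL)
  fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
  r[use] <- fit$residuals
  r
}

#' Stage-1 residualization on always-observed covariates
#'
#' Regresses each log-transformed metabolite on intercept + age + sex +
#' pc1..pc10 by OLS over the samples where that metabolite is present, and
#' returns the residuals (unnormalized). Missingness is preserved.
#'
#' @param log_abundance numeric matrix samples x metabolites (log scale),
#'   rownames = sample IDs matching `phenotypes$sample_id`.
#' @param phenotypes phenotype data.frame (see package vignette for schema).
#' @return residual matrix with the same dimensions and dimnames.
#' @export
stage1_residualize <- function(log_abundance, phenotypes) {
  phenotypes <- phenotypes[match(rownames(log_abundance), phenotypes$sample_id), ]
  X <- .base_design(phenotypes)
  out <- log_abundance
  for (j in seq_len(ncol(log_abundance))) {
    y <- log_abundance[, j]
    use <- !is.na(y)
    r <- .ols_residuals(y, X, use)
    if (is.null(r)) {
      warning("metabolite '", colnames(log_abundance)[j],
              "' skipped: too few observed samples")
      out[, j] <- NA_real_
    } else out[, j] <- r
  }
  out
}

#' Select per-metabolite candidate covariates by marginal tests
#'
#' Each candidate covariate is tested marginally against each metabolite's
#' stage-1 residuals over the samples where the candidate is observed: simple
#' linear regression for BMI (slope t-test), one-way ANOVA for the
#' categorical candidates (smoking, education, season). A candidate is
#' selected when its p-value is below `alpha`.
#'
#' @param stage1_residuals matrix from [stage1_residualize()].
#' @param phenotypes phenotype data.frame.
#' @param alpha selection level (default 0.05).
#' @return named list: metabolite ID -> character vector of selected
#'   covariates (possibly empty).
#' @export
select_covariates <- function(stage1_residuals, phenotypes, alpha = 0.05) {
  phenotypes <- phenotypes[match(rownames(stage1_residuals), phenotypes$sample_id), ]
  candidates <- intersect(.CANDIDATE_COVARIATES, names(phenotypes))
  out <- vector("list", ncol(stage1_residuals))
  names(out) <- colnames(stage1_residuals)
  for (j in seq_len(ncol(stage1_residuals))) {
    r <- stage1_residuals[, j]
    sel <- character()
    for (cv in candidates) {
      x <- phenotypes[[cv]]
      use <- !is.na(r) & !is.na(x)
      if (sum(use) < 4L) next
      p <- if (cv == "bmi") {
        fit <- stats::lm(r[use] ~ x[use])
        cf <- summary(fit)$coefficients
        if (nrow(cf) < 2L) next
        cf[2, 4]
      } else {
        f <- factor(x[use])
        if (nlevels(f) < 2L) {
          warning("candidate '", cv, "' has a single observed level for metabolite '",
                  colnames(stage1_residuals)[j], "'; excluded")
          next
        }
        stats::anova(stats::lm(r[use] ~ f))[["Pr(>F)"]][1]
      }
      if (!is.na(p) && p < alpha) sel <- c(sel, cv)
    }
    out[[j]] <- sel
  }
  out
}

#' Stage-2 refit with selected covariates and z-scoring
#'
#' Refits each log metabolite by OLS on the base covariates plus its selected
#' candidates, over samples where the metabolite and all its selected
#' covariates are observed; residuals are standardized to mean 0, SD 1.
#' Entries excluded from the fit are missing in the output, so the
#' missingness pattern of the result contains that of the input (no
#' imputation).
#'
#' @param log_abundance numeric matrix (log scale).
#' @param phenotypes phenotype data.frame.
#' @param selected named list from [select_covariates()], covering every
#'   metabolite column.
#' @return normalized residual matrix (attribute `"selected_covariates"`
#'   carries the selection map).
#' @export
stage2_residualize <- function(log_abundance, phenotypes, selected) {
  missing_sel <- setdiff(colnames(log_abundance), names(selected))
  if (length(missing_sel)) stop("selection map lacks metabolite(s): ",
                                paste(utils::head(missing_sel, 5), collapse = ", "))
  phenotypes <- phenotypes[match(rownames(log_abundance), phenotypes$sample_id), ]
  Xbase <- .base_design(phenotypes)
  out <- log_abundance
  for (j in seq_len(ncol(log_abundance))) {
    mid <- colnames(log_abundance)[j]
    y <- log_abundance[, j]
    sel <- selected[[mid]]
    X <- Xbase
    use <- !is.na(y)
    for (cv in sel) {
      x <- phenotypes[[cv]]
      use <- use & !is.na(x)
    }
    for (cv in sel) {
      x <- phenotypes[[cv]]
      if (cv == "bmi") {
        X <- cbind(X, bmi = x)
      } else {
        f <- factor(x[use])
        if (nlevels(f) < 2L) next
        mm <- matrix(0, nrow = nrow(X), ncol = nlevels(f) - 1L)
        colnames(mm) <- paste0(cv, levels(f)[-1])
        mm[use, ] <- stats::model.matrix(~ f)[, -1, drop = FALSE]
        X <- cbind(X, mm)
      }
    }
    if (sum(use) < ncol(X) + 2L) {
      warning("metabolite '", mid, "' skipped in stage 2: too few usable samples")
      out[, j] <- NA_real_
      next
    }
    fit <- stats::lm.fit(X[use, , drop = FALSE], y[use])
    r <- fit$residuals
    s <- stats::sd(r)
    if (is.na(s) || s == 0) {
      out[, j] <- NA_real_
      out[use, j] <- 0
    } else {
      out[, j] <- NA_real_
      out[use, j] <- (r - mean(r)) / s
    }
  }
  attr(out, "selected_covariates") <- selected
  out
}

#' Full two-stage preprocessing of a raw abundance matrix
#'
#' Convenience wrapper: missingness filter, natural-log transform, stage-1
#' residualization, marginal covariate selection, stage-2 refit with
#' z-scoring.
#'
#' @inheritParams filter_by_missingness
#' @inheritParams select_covariates
#' @param phenotypes phenotype data.frame.
#' @return list with `residuals` (normalized residual matrix),
#'   `selected_covariates`, `removed_metabolites`.
#' @export
preprocess_metabolites <- function(abundance, phenotypes, max_missing = 0.95,
                                   alpha = 0.05) {
  filtered <- filter_by_missingness(abundance, max_missing)
  logm <- log_transform(filtered)
  s1 <- stage1_residualize(logm, phenotypes)
  sel <- select_covariates(s1, phenotypes, alpha)
  resid <- stage2_residualize(logm, phenotypes, sel)
  list(residuals = resid, selected_covariates = sel,
       removed_metabolites = attr(filtered, "removed"))
}
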