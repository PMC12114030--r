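# Variant-metabolite association scan: effective-test Bonferroni threshold,
# 3-SD outlier counts, below-LOD missingness test, and the scan orchestrator.

#' Effective number of tests from principal components of the residual matrix
#'
#' Metabolite levels are strongly correlated, so Bonferroni correction on the
#' raw metabolite count is conservative. The effective number of tests is the
#' smallest number of principal components explaining at least
#' `variance_fraction` of the total variance of the normalized residual
#' matrix. Missing entries are replaced by 0 for this computation only (the
#' column mean, since residual columns are centered), leaving the remaining
#' missingness pattern untouched.
#'
#' @param residuals numeric matrix, samples x metabolites, `NA` allowed.
#' @param variance_fraction fraction of total variance to cover, in (0, 1].
#' @return integer count of components.
#' @export
effective_tests <- function(residuals, variance_fraction = 0.90) {
  if (!is.numeric(variance_fraction) || length(variance_fraction) != 1 ||
      variance_fraction <= 0 || variance_fraction > 1) {
    stop("variance_fraction must be in (0, 1]")
  }
  if (nrow(residuals) < 2L || ncol(residuals) < 2L) {
    stop("need at least 2 samples and 2 metabolites")
  }
  x <- residuals
  x[is.na(x)] <- 0
  d <- svd(x, nu = 0, nv = 0)$d
  share <- d^2 / sum(d^2)
  # small relative slack so variance_fraction = 1 returns the numerical rank
  k <- which(cumsum(share) >= variance_fraction * (1 - 1e-9))[1]
  as.integer(k)
}

#' Bonferroni threshold over effective tests and variants
#'
#' The study-wise significance threshold is `alpha / (m_eff * n_variants)`,
#' where `m_eff` is the effective number of metabolite tests (see
#' [effective_tests()]) and `n_variants` the number of variants scanned. No
#' rounding is applied internally.
#'
#' @param alpha study-wise type I error level.
#' @param m_eff effective number of metabolite tests.
#' @param n_variants number of variants tested.
#' @return An object of class `threshold_spec`: list with `alpha`, `m_eff`,
#'   `n_variants`, `threshold`.
#' @examples
#' significance_threshold(0.05, 368, 152)$threshold  # 8.94e-7
#' @export
significance_threshold <- function(alpha, m_eff, n_variants) {
  if (any(c(alpha, m_eff, n_variants) <= 0)) stop("all arguments must be positive")
  structure(
    list(alpha = alpha, m_eff = m_eff, n_variants = n_variants,
         threshold = alpha / (m_eff * n_variants)),
    class = "threshold_spec"
  )
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("Study-wise threshold: %g / %d / %d = %.3g (reported %.0e)\n",
              x$alpha, as.integer(x$m_eff), as.integer(x$n_variants),
              x$threshold, x$threshold))
  invisible(x)
}

#' Count carriers lying outside 3 control standard deviations
#'
#' @param carrier_residuals numeric vector of carrier residual values (`NA`
#'   dropped).
#' @param control_residuals numeric vector of control residual values (`NA`
#'   dropped); must be nonempty.
#' @return integer count of carriers with `|value - mean(controls)| >
#'   3 * sd(controls)`.
#' @export
count_3sd_outliers <- function(carrier_residuals, control_residuals) {
  ctl <- control_residuals[!is.na(control_residuals)]
  car <- carrier_residuals[!is.na(carrier_residuals)]
  if (length(ctl) == 0L) stop("control group is empty")
  m <- mean(ctl)
  s <- stats::sd(ctl)
  if (is.na(s) || s == 0) {
    warning("control SD is zero; counting all carriers distinct from the control value")
    return(sum(car != m))
  }
  sum(abs(car - m) > 3 * s)
}

#' One-sided Fisher exact test for below-LOD missingness enrichment
#'
#' Missing metabolite measurements are interpreted as concentrations below
#' the platform's limit of detection, making missingness itself informative:
#' a knockout abolishing the producing enzyme can push a metabolite below LOD
#' in every carrier. Tests the 2x2 table (missing/detected x KO/other) for
#' higher missingness in knockouts, using the exact hypergeometric tail.
#'
#' @param ko_detected logical vector: `TRUE` where the metabolite was detected
#'   in a knockout sample.
#' @param other_detected logical vector for the remaining samples.
#' @return one-sided p-value (exact).
#' @examples
#' # all 10 KOs missing, 61 of 971 others missing: p ~ 2e-12
#' missingness_test(rep(FALSE, 10), rep(c(FALSE, TRUE), c(61, 910)))
#' @export
missingness_test <- function(ko_detected, other_detected) {
  if (length(ko_detected) == 0L || length(other_detected) == 0L) {
    stop("both groups must be nonempty")
  }
  a <- sum(!ko_detected)                       # KO missing
  n_ko <- length(ko_detected)
  miss_total <- a + sum(!other_detected)
  det_total <- length(ko_detected) + length(other_detected) - miss_total
  if (miss_total == 0L || det_total == 0L) return(1)
  # P(X >= a), X ~ Hypergeometric(miss_total, det_total, n_ko)
  stats::phyper(a - 1, miss_total, det_total, n_ko, lower.tail = FALSE)
}

#' Scan all variant-metabolite pairs for knockout-associated outliers
#'
#' For each (variant, metabolite) pair, compares carrier and control residual
#' values with the exact one-sided Wilcoxon rank-sum test in the direction of
#' the observed shift, counts 3-SD carrier outliers, and flags significance
#' against a study-wise threshold. Samples missing a metabolite are excluded
#' pair-wise (no imputation). Missingness tests are emitted for every pair
#' where at least one group has a missing value.
#'
#' Null rank-sum distributions are cached per (carrier, control) group-size
#' pair for tie-free columns, so large scans do not recompute the dynamic
#' program per metabolite.
#'
#' @param residuals numeric matrix samples x metabolites with rownames =
#'   sample IDs; `NA` = missing.
#' @param carriers data.frame with columns `variant_id`, `gene`, `sample_id`
#'   listing the carrier (knockout) samples per variant.
#' @param control_ids character vector of control sample IDs (disjoint from
#'   all carrier sets).
#' @param threshold either a `threshold_spec` or a bare numeric p-value
#'   threshold.
#' @param alternative passed to [exact_wilcoxon_one_sided()]; default
#'   `"auto"` (one-sided in the direction of the shift).
#' @return list with `associations` (data.frame sorted by p: gene, variant_id,
#'   metabolite_id, n_controls, n_carriers, n_outliers_3sd, direction,
#'   p_value, significant) and `missingness` (data.frame: variant_id,
#'   metabolite_id, ko_missing, ko_total, other_missing, other_total,
#'   p_value).
#' @export
run_association_scan <- function(residuals, carriers, control_ids, threshold,
                                 alternative = "auto") {
  thr <- if (inherits(threshold, "threshold_spec")) threshold$threshold else threshold
  stopifnot(is.numeric(thr), thr > 0, thr <= 1)
  samp <- rownames(residuals)
  unknown <- setdiff(unique(c(carriers$sample_id, control_ids)), samp)
  if (length(unknown) > 0L) {
    stop("unknown sample ID(s) in carrier/control sets: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  overlap <- intersect(carriers$sample_id, control_ids)
  if (length(overlap) > 0L) {
    stop("control IDs overlap carrier sets: ", paste(utils::head(overlap, 5), collapse = ", "))
  }

  variant_ids <- unique(carriers$variant_id)
  genes <- carriers$gene[match(variant_ids, carriers$variant_id)]
  tail_cache <- new.env(parent = emptyenv())
  assoc <- vector("list", length(variant_ids) * ncol(residuals))
  missrec <- list()
  k <- 0L

  for (vi in seq_along(variant_ids)) {
    v <- variant_ids[vi]
    ko_ids <- unique(carriers$sample_id[carriers$variant_id == v])
    ko_rows <- match(ko_ids, samp)
    ctl_rows <- match(control_ids, samp)
    for (j in seq_len(ncol(residuals))) {
      ko <- residuals[ko_rows, j]
      ctl <- residuals[ctl_rows, j]
      ko_ok <- ko[!is.na(ko)]
      ctl_ok <- ctl[!is.na(ctl)]
      if (anyNA(ko) || anyNA(ctl)) {
        missrec[[length(missrec) + 1L]] <- data.frame(
          variant_id = v, metabolite_id = colnames(residuals)[j],
          ko_missing = sum(is.na(ko)), ko_total = length(ko),
          other_missing = sum(is.na(ctl)), other_total = length(ctl),
          p_value = missingness_test(!is.na(ko), !is.na(ctl)),
          stringsAsFactors = FALSE)
      }
      if (length(ko_ok) == 0L || length(ctl_ok) == 0L) next
      res <- .cached_wilcoxon(ko_ok, ctl_ok, alternative, tail_cache)
      k <- k + 1L
      assoc[[k]] <- data.frame(
        gene = genes[vi], variant_id = v,
        metabolite_id = colnames(residuals)[j],
        n_controls = length(ctl_ok), n_carriers = length(ko_ok),
        n_outliers_3sd = count_3sd_outliers(ko_ok, ctl_ok),
        direction = res$direction, p_value = res$p.value,
        stringsAsFactors = FALSE)
    }
  }
  assoc <- do.call(rbind, assoc[seq_len(k)])
  if (is.null(assoc)) {
    assoc <- data.frame(gene = character(), variant_id = character(),
                        metabolite_id = character(), n_controls = integer(),
                        n_carriers = integer(), n_outliers_3sd = integer(),
                        direction = character(), p_value = numeric(),
                        significant = logical(), stringsAsFactors = FALSE)
  } else {
    assoc$significant <- assoc$p_value < thr
    assoc <- assoc[order(assoc$p_value, assoc$gene, assoc$metabolite_id), , drop = FALSE]
    rownames(assoc) <- NULL
  }
  miss <- if (length(missrec)) do.call(rbind, missrec) else
    data.frame(variant_id = character(), metabolite_id = character(),
               ko_missing = integer(), ko_total = integer(),
               other_missing = integer(), other_total = integer(),
               p_value = numeric(), stringsAsFactors = FALSE)
  rownames(miss) <- NULL
  list(associations = assoc, missingness = miss)
}

# Exact one-sided test with per-(n1, n2) caching of the tie-free null tail
# CDF. Falls back to the general midrank DP when ties are present.
.cached_wilcoxon <- function(ko, ctl, alternative, cache) {
  n1 <- length(ko); n2 <- length(ctl)
  r <- rank(c(ko, ctl))
  if (anyDuplicated(c(ko, ctl)) > 0L) {
    return(exact_wilcoxon_one_sided(ko, ctl, alternative))
  }
  key <- paste0(n1, "_", n2)
  tail <- cache[[key]]
  if (is.null(tail)) {
    counts <- .ranksum_null_counts(seq_len(n1 + n2), n1)
    total <- sum(counts)
    # upper[s+1] = P(W >= s) on the single-rank scale (sums 0..max)
    tail <- list(upper = rev(cumsum(rev(counts))) / total,
                 lower = cumsum(counts) / total)
    cache[[key]] <- tail
  }
  w <- sum(r[seq_len(n1)])             # integer: no ties
  e_w <- n1 * (n1 + n2 + 1) / 2
  pick_greater <- switch(alternative,
                         greater = TRUE, less = FALSE,
                         auto = w >= e_w, two.sided = NA)
  if (alternative == "two.sided") {
    p <- min(1, 2 * min(tail$upper[w + 1L], tail$lower[w + 1L]))
    dir <- if (w >= e_w) "+" else "-"
  } else if (pick_greater) {
    p <- tail$upper[w + 1L]; dir <- "+"
  } else {
    p <- tail$lower[w + 1L]; dir <- "-"
  }
  list(p.value = p, direction = dir, statistic = w, n_carriers = n1, n_controls = n2)
}
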