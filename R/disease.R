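# Variant-disease association from EHR diagnoses: recurrent-diagnosis case
# definitions, sex x age stratification, the conditional exact test given
# strata margins, and the conditional maximum-likelihood common odds ratio.
#
# The exact machinery: under the null (common odds ratio 1), each stratum's
# knockout-case count a_k given its margins is central hypergeometric, so the
# null distribution of T = sum_k a_k is the convolution of per-stratum
# hypergeometrics. The support of T is tiny (few knockouts), making the exact
# convolution cheap. The common odds ratio psi is estimated by conditional
# maximum likelihood: the product of noncentral (Fisher) hypergeometric
# likelihoods is maximized where E_psi[T] equals the observed T, a strictly
# increasing function of psi, solved by bracketed root search on log(psi).

#' Build recurrent-diagnosis case flags per ICD-10 category
#'
#' A sample is a case for a 3-character ICD-10 category when its medical
#' history holds at least two diagnosis events whose codes fall in that
#' category (recurrence is counted at the category level, after stripping the
#' dot and uppercasing). Codes without three leading characters matching an
#' ICD-10 pattern are skipped with a warning.
#'
#' @param events data.frame with columns `sample_id`, `icd10_code` (one row
#'   per recorded diagnosis occurrence).
#' @param sample_ids character vector of all cohort sample IDs.
#' @param min_events recurrence threshold (default 2).
#' @param category_level if `TRUE` (default) recurrence is counted within the
#'   3-character category; if `FALSE`, within the full code, then aggregated.
#' @return logical matrix samples x categories (`TRUE` = case).
#' @export
recurrent_case_table <- function(events, sample_ids, min_events = 2L,
                                 category_level = TRUE) {
  unknown <- setdiff(events$sample_id, sample_ids)
  if (length(unknown)) stop("event sample(s) not in cohort: ",
                            paste(utils::head(unknown, 5), collapse = ", "))
  code <- toupper(gsub(".", "", events$icd10_code, fixed = TRUE))
  ok <- grepl("^[A-Z][0-9]{2}", code)
  if (any(!ok)) {
    warning(sum(!ok), " event row(s) with malformed ICD-10 code skipped")
  }
  events <- events[ok, , drop = FALSE]
  cat3 <- substr(code[ok], 1L, 3L)
  if (nrow(events) == 0L) {
    return(matrix(FALSE, nrow = length(sample_ids), ncol = 0,
                  dimnames = list(sample_ids, character())))
  }
  if (category_level) {
    counts <- table(events$sample_id, cat3)
    hit <- counts >= min_events
  } else {
    # alternative reading: a sample is a case for a category when some FULL
    # code within it recurs >= min_events times
    full <- code[ok]
    rec <- table(events$sample_id, full) >= min_events
    cats_of_code <- substr(colnames(rec), 1L, 3L)
    hit <- vapply(split(seq_len(ncol(rec)), cats_of_code),
                  function(ix) rowSums(rec[, ix, drop = FALSE]) > 0,
                  logical(nrow(rec)))
    if (is.null(dim(hit))) hit <- matrix(hit, nrow = nrow(rec),
                                         dimnames = list(rownames(rec), unique(cats_of_code)))
    else rownames(hit) <- rownames(rec)
  }
  categories <- sort(unique(cat3))
  out <- matrix(FALSE, nrow = length(sample_ids), ncol = length(categories),
                dimnames = list(sample_ids, categories))
  out[rownames(hit), colnames(hit)] <- hit
  out
}

#' Apply case-count and knockout-count exclusions
#'
#' @param case_table logical matrix from [recurrent_case_table()].
#' @param carrier_sets named list (variant -> list(hom, het)).
#' @param min_cases categories with fewer cases are excluded (default 5).
#' @param min_ko variants with fewer knockouts are excluded (default 2).
#' @return list with `categories`, `variants` (surviving IDs) and the counts.
#' @export
apply_exclusions <- function(case_table, carrier_sets, min_cases = 5L,
                             min_ko = 2L) {
  n_cases <- colSums(case_table)
  cats <- colnames(case_table)[n_cases >= min_cases]
  n_ko <- vapply(carrier_sets, function(cs) length(unique(cs$hom)), integer(1))
  vars <- names(carrier_sets)[n_ko >= min_ko]
  message(length(cats), " diagnosis categories and ", length(vars),
          " variants survive exclusions")
  list(categories = cats, variants = vars,
       n_categories = length(cats), n_variants = length(vars))
}

#' Stratify a knockout-vs-control case comparison by sex and age group
#'
#' @param case_flags named logical vector (sample -> case status for one
#'   category).
#' @param ko_ids,control_ids sample ID vectors (disjoint).
#' @param phenotypes phenotype data.frame covering all listed samples.
#' @param age_bin_years age bin width in years (bins start at 18).
#' @return named list of 2x2 integer matrices, rows (KO, control), columns
#'   (case, noncase); strata lacking a KO or a control are dropped (they
#'   carry no conditional information).
#' @export
build_strata <- function(case_flags, ko_ids, control_ids, phenotypes,
                         age_bin_years = 10) {
  ids <- c(ko_ids, control_ids)
  ph <- phenotypes[match(ids, phenotypes$sample_id), ]
  if (anyNA(ph$sample_id)) stop("phenotypes do not cover all samples")
  breaks <- seq(18, max(ph$age, na.rm = TRUE) + age_bin_years, by = age_bin_years)
  bin <- cut(ph$age, breaks = breaks, right = FALSE, include.lowest = TRUE)
  stratum <- interaction(ph$sex, bin, drop = TRUE)
  is_ko <- ids %in% ko_ids
  case <- as.logical(case_flags[ids])
  out <- list()
  for (s in levels(stratum)) {
    in_s <- stratum == s
    if (!any(in_s & is_ko) || !any(in_s & !is_ko)) next
    tab <- matrix(c(sum(in_s & is_ko & case), sum(in_s & is_ko & !case),
                    sum(in_s & !is_ko & case), sum(in_s & !is_ko & !case)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("KO", "control"), c("case", "noncase")))
    out[[s]] <- tab
  }
  out
}

# Per-stratum conditional support and log central-hypergeometric weights.
# Margins: m1 = KO total, m2 = control total, t = case total.
.stratum_support <- function(tab) {
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); t <- sum(tab[, 1])
  lo <- max(0L, t - m2); hi <- min(t, m1)
  x <- lo:hi
  list(x = x, logd = stats::dhyper(x, m1, m2, t, log = TRUE),
       a_obs = tab[1, 1], lo = lo, hi = hi)
}

# Exact null distribution of T = sum_k a_k by convolution.
.null_distribution <- function(strata) {
  sup <- lapply(strata, .stratum_support)
  dist <- c(1)           # probability over T offset by `base`
  base <- 0L
  for (s in sup) {
    p <- exp(s$logd - max(s$logd)); p <- p / sum(p)
    new <- rep(0, length(dist) + length(s$x) - 1L)
    for (i in seq_along(s$x)) {
      idx <- seq_along(dist) + (i - 1L)
      new[idx] <- new[idx] + dist * p[i]
    }
    dist <- new
    base <- base + s$lo
  }
  list(support = base + seq_along(dist) - 1L, prob = dist,
       t_obs = sum(vapply(sup, `[[`, numeric(1), "a_obs")),
       t_min = sum(vapply(sup, `[[`, numeric(1), "lo")),
       t_max = sum(vapply(sup, `[[`, numeric(1), "hi")))
}

#' Conditional exact test for a stratified 2x2 association
#'
#' Exact test of no association between knockout status and case status
#' given every stratum's margins. The null distribution of the summed
#' knockout-case count is computed by exact convolution of central
#' hypergeometrics; the two-sided p-value sums the probabilities of all
#' outcomes no more probable than the observed one (the probability-mass
#' rule, matching Fisher's exact two-sided test in the single-stratum case).
#'
#' @param strata list of 2x2 matrices from [build_strata()].
#' @param alternative `"two.sided"` (default), `"greater"` (higher case rate
#'   in knockouts) or `"less"`.
#' @return list with `p.value`, `t_obs`, and the exact `null` distribution
#'   (`support`, `prob`).
#' @export
conditional_exact_test <- function(strata,
                                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  strata <- Filter(function(tab) {
    s <- .stratum_support(tab); s$hi > s$lo
  }, strata)
  if (length(strata) == 0L) {
    return(list(p.value = 1, t_obs = NA_integer_,
                null = list(support = integer(), prob = numeric()),
                note = "no informative stratum"))
  }
  nd <- .null_distribution(strata)
  p_obs <- nd$prob[match(nd$t_obs, nd$support)]
  p <- switch(alternative,
    two.sided = sum(nd$prob[nd$prob <= p_obs * (1 + 1e-7)]),
    greater = sum(nd$prob[nd$support >= nd$t_obs]),
    less = sum(nd$prob[nd$support <= nd$t_obs]))
  list(p.value = min(1, p), t_obs = nd$t_obs,
       null = list(support = nd$support, prob = nd$prob))
}

# E_psi[T] on the log-psi scale: strictly increasing in psi.
.expected_t <- function(log_psi, sup) {
  sum(vapply(sup, function(s) {
    lw <- s$logd + s$x * log_psi
    w <- exp(lw - max(lw))
    sum(s$x * w) / sum(w)
  }, numeric(1)))
}

#' Conditional maximum-likelihood estimate of the common odds ratio
#'
#' Maximizes the product of per-stratum noncentral (Fisher) hypergeometric
#' likelihoods conditional on all margins. The maximizer solves
#' `E_psi[T] = T_obs`; since the expectation is strictly increasing in psi,
#' the root is unique and found by bracketed search on `log(psi)`. When the
#' observed T sits on the boundary of its attainable range the estimate is 0
#' or `Inf` and is flagged.
#'
#' @param strata list of 2x2 matrices from [build_strata()].
#' @param tol root-finding tolerance on `log(psi)` (default 1e-8).
#' @return list with `psi`, `t_obs`, `boundary` flag.
#' @export
cmle_common_or <- function(strata, tol = 1e-8) {
  sup <- lapply(strata, .stratum_support)
  sup <- Filter(function(s) s$hi > s$lo, sup)
  t_obs <- sum(vapply(lapply(strata, .stratum_support), `[[`, numeric(1), "a_obs"))
  if (length(sup) == 0L) stop("no informative stratum: common odds ratio undefined")
  t_fixed <- t_obs - sum(vapply(sup, `[[`, numeric(1), "a_obs"))
  t_inf <- t_obs - t_fixed  # observed T over informative strata
  t_min <- sum(vapply(sup, `[[`, numeric(1), "lo"))
  t_max <- sum(vapply(sup, `[[`, numeric(1), "hi"))
  if (t_inf <= t_min) return(list(psi = 0, t_obs = t_obs, boundary = TRUE))
  if (t_inf >= t_max) return(list(psi = Inf, t_obs = t_obs, boundary = TRUE))
  root <- stats::uniroot(function(lp) .expected_t(lp, sup) - t_inf,
                         interval = c(-50, 50), tol = tol)$root
  list(psi = exp(root), t_obs = t_obs, boundary = FALSE)
}

#' Scan variant-diagnosis pairs with the stratified conditional exact test
#'
#' Applies the case-count and knockout-count exclusions, derives the
#' Bonferroni threshold from the surviving counts, and for each surviving
#' (variant, category) pair builds sex x age strata, runs the conditional
#' exact test, and estimates the common odds ratio.
#'
#' @param case_table logical matrix from [recurrent_case_table()].
#' @param carrier_sets named list (variant -> list(hom, het)).
#' @param control_ids control sample IDs.
#' @param phenotypes phenotype data.frame.
#' @param alpha study-wise level (default 0.05).
#' @param min_cases,min_ko exclusion thresholds (defaults 5 and 2).
#' @param age_bin_years age stratum width (default 10).
#' @param alternative sidedness of the exact test (default two-sided).
#' @return data.frame (variant_id, category, n_cases, cmle_or, p_value,
#'   significant) sorted by p, with attributes `threshold` and `nominal`
#'   (the p <= 0.05 subset).
#' @export
disease_scan <- function(case_table, carrier_sets, control_ids, phenotypes,
                         alpha = 0.05, min_cases = 5L, min_ko = 2L,
                         age_bin_years = 10, alternative = "two.sided") {
  excl <- apply_exclusions(case_table, carrier_sets, min_cases, min_ko)
  if (excl$n_categories == 0L || excl$n_variants == 0L) {
    out <- data.frame(variant_id = character(), category = character(),
                      n_cases = integer(), cmle_or = numeric(),
                      p_value = numeric(), significant = logical())
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  threshold <- alpha / (excl$n_categories * excl$n_variants)
  rows <- list()
  for (v in excl$variants) {
    ko_ids <- setdiff(unique(carrier_sets[[v]]$hom), control_ids)
    for (cc in excl$categories) {
      strata <- build_strata(case_table[, cc], ko_ids, control_ids,
                             phenotypes, age_bin_years)
      if (length(strata) == 0L) next
      tst <- conditional_exact_test(strata, alternative)
      est <- tryCatch(cmle_common_or(strata),
                      error = function(e) list(psi = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v, category = cc,
        n_cases = sum(case_table[, cc]),
        cmle_or = est$psi, p_value = tst$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), category = character(),
               n_cases = integer(), cmle_or = numeric(), p_value = numeric())
  out$significant <- out$p_value < threshold
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "nominal") <- out[out$p_value <= 0.05, , drop = FALSE]
  out
}
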