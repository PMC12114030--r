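# Simulation-based power analysis of the exact one-sided Wilcoxon test under
# extreme group imbalance: controls drawn N(0, 1), knockouts N(beta, 1).
#
# With continuous data ties occur with probability zero, so the exact null
# tail of the carrier rank sum depends only on the group sizes. The null tail
# CDF is therefore precomputed once per (n_ko, n_controls) and each simulated
# trial reduces to comparing the carrier rank sum against the critical value
# -- the identical rejection rule that exact_wilcoxon_one_sided() applies
# (direction "+", known by construction); the equivalence is asserted in the
# test suite.

#' Empirical power of the exact one-sided Wilcoxon test
#'
#' For every combination of effect size `beta` (SD units) and knockout group
#' size, simulates `n_trials` datasets with `n_controls` controls from
#' N(0, 1) and the knockouts from N(beta, 1), applies the exact one-sided
#' rank-sum test toward higher knockout values, and records the fraction of
#' trials rejecting at `threshold`. Cells where even complete separation
#' cannot reach the threshold (`minimal_p >= threshold`) are reported as
#' power 0 without simulation and flagged.
#'
#' @param betas vector of location shifts in SD units (nonempty).
#' @param ko_sizes vector of knockout group sizes (each >= 1).
#' @param n_controls number of controls (default 258).
#' @param n_trials Monte-Carlo trials per cell (default 10000).
#' @param threshold study-wise significance threshold (default
#'   0.05 / 368 / 152).
#' @param seed integer RNG seed.
#' @return `power_grid` object: list with the grid parameters, the `power`
#'   matrix (rows = betas, cols = ko_sizes), and `attainable` flags.
#' @export
simulate_power <- function(betas, ko_sizes, n_controls = 258,
                           n_trials = 10000, threshold = 0.05 / 368 / 152,
                           seed = 1L) {
  if (length(betas) == 0L || length(ko_sizes) == 0L) {
    stop("betas and ko_sizes must be nonempty")
  }
  stopifnot(n_controls >= 1, all(ko_sizes >= 1), threshold > 0, threshold < 1,
            n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  power <- matrix(NA_real_, nrow = length(betas), ncol = length(ko_sizes),
                  dimnames = list(beta = as.character(betas),
                                  n_ko = as.character(ko_sizes)))
  attainable <- rep(TRUE, length(ko_sizes))
  crit <- rep(NA_integer_, length(ko_sizes))
  for (k in seq_along(ko_sizes)) {
    n1 <- ko_sizes[k]
    if (minimal_p(n1, n_controls) >= threshold) {
      attainable[k] <- FALSE
      power[, k] <- 0
      next
    }
    counts <- .ranksum_null_counts(seq_len(n1 + n_controls), n1)
    upper <- rev(cumsum(rev(counts))) / sum(counts)  # P(W >= s), s = 0..max
    crit[k] <- min(which(upper < threshold)) - 1L    # smallest rejecting W
  }
  for (b in seq_along(betas)) {
    for (k in seq_along(ko_sizes)) {
      if (!attainable[k]) next
      n1 <- ko_sizes[k]
      w_min <- n1 * (n1 + 1) / 2
      rejects <- 0L
      for (trial in seq_len(n_trials)) {
        ctl <- sort.int(stats::rnorm(n_controls))
        ko <- stats::rnorm(n1, mean = betas[b])
        w <- w_min + sum(findInterval(ko, ctl))  # carrier rank sum (no ties a.s.)
        if (w >= crit[k]) rejects <- rejects + 1L
      }
      power[b, k] <- rejects / n_trials
    }
  }
  structure(list(betas = betas, ko_sizes = ko_sizes, n_controls = n_controls,
                 n_trials = n_trials, threshold = threshold, seed = seed,
                 power = power, attainable = attainable, critical = crit),
            class = "power_grid")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Tabulate and plot a power grid
#'
#' @param grid a `power_grid` from [simulate_power()].
#' @param tsv_file optional path: write the long-format table as TSV.
#' @param plot_file optional path: write the heatmap as PNG.
#' @return list with `table` (long data.frame: beta, n_ko, power, attainable)
#'   and `plot` (a ggplot heatmap annotating the >= 80% power region).
#' @export
power_report <- function(grid, tsv_file = NULL, plot_file = NULL) {
  stopifnot(inherits(grid, "power_grid"))
  tab <- expand.grid(beta = grid$betas, n_ko = grid$ko_sizes,
                     KEEP.OUT.ATTRS = FALSE)
  tab$power <- as.vector(grid$power)
  tab$attainable <- rep(grid$attainable, each = length(grid$betas))
  if (!is.null(tsv_file)) {
    utils::write.table(tab, tsv_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = factor(n_ko), y = factor(beta),
                                         fill = power)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(power >= 0.80, ">=80%", "")),
                       size = 2.5) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "knockout group size", y = expression(beta ~ "(SD units)"),
                  fill = "power",
                  title = sprintf("Exact one-sided Wilcoxon power, %d controls, p < %.2g",
                                  grid$n_controls, grid$threshold)) +
    ggplot2::theme_minimal()
  if (!is.null(plot_file)) {
    ggplot2::ggsave(plot_file, p, width = 7, height = 5, dpi = 150)
  }
  list(table = tab, plot = p)
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf("Power grid: %d controls, %d trials/cell, threshold %.3g\n",
              x$n_controls, x$n_trials, x$threshold))
  print(round(x$power, 3))
  invisible(x)
}
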