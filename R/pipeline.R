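# End-to-end orchestration from a single YAML config: selection ->
# preprocessing -> metabolite association scan -> (optional) power grid ->
# EHR disease scan, with a count ledger logged at every filtering step.

#' Annotate association records with drug-target and OMIM columns
#'
#' Left-joins by gene symbol; genes absent from the lists get blank
#' annotations. Duplicate genes in the OMIM map: last entry wins, with a
#' warning.
#'
#' @param records association data.frame with a `gene` column.
#' @param drug_genes character vector of drug-target gene symbols.
#' @param omim_map data.frame with columns `gene`, `disorder` (or a character
#'   vector of genes, in which case the disorder text is blank).
#' @param strategy_map optional named vector gene -> strategy label.
#' @return `records` with `drug_target` (logical), `omim_disorder`
#'   (character) and `strategy` columns appended.
#' @export
annotate_report <- function(records, drug_genes = character(),
                            omim_map = NULL, strategy_map = NULL) {
  if (is.character(omim_map)) {
    omim_map <- data.frame(gene = omim_map, disorder = "",
                           stringsAsFactors = FALSE)
  }
  if (!is.null(omim_map) && anyDuplicated(omim_map$gene)) {
    warning("duplicate gene(s) in OMIM map; last entry wins")
    omim_map <- omim_map[!duplicated(omim_map$gene, fromLast = TRUE), ]
  }
  records$drug_target <- records$gene %in% drug_genes
  records$omim_disorder <- if (is.null(omim_map)) "" else {
    d <- omim_map$disorder[match(records$gene, omim_map$gene)]
    ifelse(is.na(d), "", d)
  }
  records$strategy <- if (is.null(strategy_map)) NA_character_ else
    unname(strategy_map[records$gene])
  records
}

.log_line <- function(log_con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the full knockout-metabolite pipeline from a config
#'
#' Stages: carrier-set construction, Strategy 1/2 selection, metabolite
#' preprocessing, effective-test threshold derivation, exact Wilcoxon
#' association scan with missingness tests, optional power grid, and the EHR
#' disease scan. One TSV is written per stage plus a combined annotated
#' report sorted by metabolite name; a run log records every filter's
#' input/output counts and the derived thresholds. Any stage failure aborts
#' with the stage name, removing partial outputs.
#'
#' @param config a list or a path to a YAML file with components `inputs`
#'   (paths: phenotypes, genotypes, variants, abundance, ehr, controls,
#'   omim_genes, open_targets_genes, drug_target_genes, disease_genes
#'   optional), `thresholds` (alpha, max_missing, variance_fraction,
#'   age_bin), `seed`, `output_dir`, `run_power` (logical).
#' @return list with `associations`, `missingness`, `report`, `disease`,
#'   `threshold`, `m_eff`, invisibly; files under `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: '", config, "'")
    config <- yaml::read_yaml(config)
  }
  inp <- config$inputs
  thr <- config$thresholds
  alpha <- thr$alpha %||% 0.05
  max_missing <- thr$max_missing %||% 0.95
  variance_fraction <- thr$variance_fraction %||% 0.90
  age_bin <- thr$age_bin %||% 10
  outdir <- config$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  log_path <- file.path(outdir, "run.log")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con), add = TRUE)

  emit <- function(df, name) {
    path <- file.path(outdir, name)
    .write_tsv(df, path)
    written <<- c(written, path)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- load inputs -----------------------------------------------------
  dat <- run_stage("load", {
    for (f in unlist(inp)) if (!file.exists(f)) stop("input file not found: '", f, "'")
    geno <- if (grepl("\\.vcf$", inp$genotypes)) read_genotypes_vcf(inp$genotypes)
            else { g <- read_matrix_tsv(inp$genotypes); storage.mode(g) <- "integer"; g }
    list(phenotypes = .read_tsv(inp$phenotypes),
         genotypes = geno,
         annotations = .read_tsv(inp$variants),
         abundance = read_matrix_tsv(inp$abundance),
         ehr = .read_tsv(inp$ehr, colClasses = "character"),
         control_ids = readLines(inp$controls),
         omim = readLines(inp$omim_genes),
         open_targets = readLines(inp$open_targets_genes),
         drug_targets = readLines(inp$drug_target_genes),
         disease_genes = if (!is.null(inp$disease_genes))
           readLines(inp$disease_genes) else character())
  })
  .log_line(log_con, "loaded ", nrow(dat$phenotypes), " samples, ",
            ncol(dat$genotypes), " variants, ", ncol(dat$abundance),
            " metabolites, ", nrow(dat$ehr), " EHR events")

  # --- selection -------------------------------------------------------
  sel <- run_stage("select", {
    cs <- carrier_sets_from_genotypes(dat$genotypes)
    s1 <- select_strategy1(dat$annotations, cs, dat$omim, dat$open_targets)
    s2 <- select_strategy2(dat$annotations, cs, dat$disease_genes)
    list(carrier_sets = cs, s1 = s1, s2 = s2)
  })
  .log_line(log_con, "Strategy 1: ", nrow(sel$s1), "/", nrow(dat$annotations),
            " variants selected; Strategy 2: ", nrow(sel$s2), " genes")
  emit(sel$s1, "selected_strategy1.tsv")
  emit(sel$s2, "selected_strategy2.tsv")

  # --- preprocess ------------------------------------------------------
  prep <- run_stage("preprocess",
                    preprocess_metabolites(dat$abundance, dat$phenotypes,
                                           max_missing = max_missing,
                                           alpha = alpha))
  .log_line(log_con, length(prep$removed_metabolites),
            " metabolites removed by missingness filter; ",
            ncol(prep$residuals), " retained")

  # --- associate -------------------------------------------------------
  scan <- run_stage("associate", {
    # Strategy-1 variants scanned on homozygous knockouts; qualifying
    # variants of Strategy-2 genes on heterozygous carriers
    carr <- list()
    for (i in seq_len(nrow(sel$s1))) {
      v <- sel$s1$variant_id[i]
      hom <- sel$carrier_sets[[v]]$hom
      if (length(hom)) carr[[length(carr) + 1L]] <- data.frame(
        variant_id = v, gene = sel$s1$gene[i], sample_id = hom,
        strategy = "1", stringsAsFactors = FALSE)
    }
    for (g in sel$s2$gene) {
      q <- dat$annotations$maf <= 0.001 &
        (dat$annotations$pathogenic | dat$annotations$loftee == "HC") &
        dat$annotations$gene == g
      for (v in dat$annotations$variant_id[q]) {
        het <- setdiff(sel$carrier_sets[[v]]$het, dat$control_ids)
        if (length(het)) carr[[length(carr) + 1L]] <- data.frame(
          variant_id = v, gene = g, sample_id = het, strategy = "2",
          stringsAsFactors = FALSE)
      }
    }
    carriers <- do.call(rbind, carr)
    if (is.null(carriers)) stop("no variants selected for association scan")
    n_var <- length(unique(carriers$variant_id))
    m_eff <- effective_tests(prep$residuals, variance_fraction)
    tspec <- significance_threshold(alpha, m_eff, n_var)
    res <- run_association_scan(prep$residuals, carriers, dat$control_ids, tspec)
    list(res = res, tspec = tspec, m_eff = m_eff,
         strategy_map = stats::setNames(carriers$strategy, carriers$gene))
  })
  .log_line(log_con, "effective tests: ", scan$m_eff, "; scan threshold ",
            format(scan$tspec$threshold, digits = 3), "; ",
            sum(scan$res$associations$significant), " significant of ",
            nrow(scan$res$associations), " pairs")
  emit(scan$res$associations, "associations.tsv")
  emit(scan$res$missingness, "missingness_tests.tsv")

  report <- annotate_report(scan$res$associations[scan$res$associations$significant, ,
                                                  drop = FALSE],
                            drug_genes = dat$drug_targets,
                            omim_map = dat$omim,
                            strategy_map = scan$strategy_map)
  report <- report[order(report$metabolite_id), , drop = FALSE]
  emit(report, "report.tsv")

  # --- power (optional) ------------------------------------------------
  if (isTRUE(config$run_power)) {
    grid <- run_stage("power",
                      simulate_power(betas = config$power$betas %||% seq(0.5, 5, 0.5),
                                     ko_sizes = config$power$ko_sizes %||% 1:10,
                                     n_controls = length(dat$control_ids),
                                     n_trials = config$power$n_trials %||% 10000,
                                     threshold = scan$tspec$threshold,
                                     seed = (config$seed %||% 1L) + 1L))
    power_report(grid, tsv_file = file.path(outdir, "power.tsv"),
                 plot_file = file.path(outdir, "power.png"))
    .log_line(log_con, "power grid written")
  }

  # --- disease scan ----------------------------------------------------
  disease <- run_stage("ehr-scan", {
    case_tab <- recurrent_case_table(dat$ehr, dat$phenotypes$sample_id)
    disease_scan(case_tab, sel$carrier_sets, dat$control_ids, dat$phenotypes,
                 alpha = alpha, age_bin_years = age_bin)
  })
  .log_line(log_con, nrow(disease), " variant-diagnosis pairs tested; ",
            sum(disease$significant), " significant at ",
            format(attr(disease, "threshold"), digits = 3))
  emit(disease, "disease_associations.tsv")

  invisible(list(associations = scan$res$associations,
                 missingness = scan$res$missingness,
                 report = report, disease = disease,
                 threshold = scan$tspec, m_eff = scan$m_eff,
                 selected_strategy1 = sel$s1, selected_strategy2 = sel$s2,
                 log = log_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
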