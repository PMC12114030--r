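# Fixture reading/writing: TSV tables with header rows, matrix TSV (first
# column sample_id, empty cell = missing), and an optional minimal VCF v4.2
# genotype representation (GT-only, diploid, "./." = missing call; read back
# through vcfR).

.write_tsv <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

.read_tsv <- function(path, ...) {
  if (!file.exists(path)) stop("input file not found: '", path, "'")
  utils::read.delim(path, sep = "\t", na.strings = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

#' Write an abundance (or residual) matrix as TSV
#'
#' First column `sample_id`, one column per metabolite, empty cell = missing.
#' @param mat numeric matrix with sample rownames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#' @param path input path.
#' @return numeric matrix with sample rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  m
}

#' Write a dosage matrix as a minimal VCF v4.2
#'
#' GT-only, diploid; dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`, `NA` -> `./.`.
#'
#' @param genotypes integer dosage matrix samples x variants.
#' @param annotations data.frame with `variant_id`, `chrom`, `pos`.
#' @param path output path.
#' @export
write_genotypes_vcf <- function(genotypes, annotations, path) {
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  ann <- annotations[match(colnames(genotypes), annotations$variant_id), ]
  body <- vapply(seq_len(ncol(genotypes)), function(j) {
    d <- genotypes[, j]
    gt <- ifelse(is.na(d), "./.", gt_map[as.character(d)])
    paste(c(ann$chrom[j], ann$pos[j], colnames(genotypes)[j], "A", "T", ".",
            "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  ok <- tryCatch({
    writeLines(c(header, body), path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a minimal GT-only VCF back to a dosage matrix
#' @param path VCF path.
#' @return integer dosage matrix samples x variants.
#' @export
read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("input file not found: '", path, "'")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(s) {
    if (is.na(s) || s %in% c("./.", ".|.", ".")) return(NA_integer_)
    sum(as.integer(strsplit(gsub("\\|", "/", s), "/", fixed = FALSE)[[1]]) > 0L)
  }
  d <- apply(gt, c(1, 2), count_alt)
  out <- t(d)
  storage.mode(out) <- "integer"
  out
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Emits `phenotypes.tsv`, `genotypes.tsv` (dosage) or `genotypes.vcf`,
#' `variants.tsv`, `abundance.tsv`, `ehr.tsv`, `controls.txt`, gene lists,
#' and the truth record (`truth_metabolite_effects.tsv`, `truth_ehr.tsv`).
#'
#' @param bundle a `komet_cohort` from [generate_cohort()].
#' @param directory output directory (created if absent).
#' @param genotype_format `"tsv"` (dosage matrix) or `"vcf"`.
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(bundle, directory, genotype_format = c("tsv", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  stopifnot(inherits(bundle, "komet_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(directory, f)
  .write_tsv(bundle$phenotypes, fp("phenotypes.tsv"))
  if (genotype_format == "tsv") {
    write_matrix_tsv(bundle$genotypes, fp("genotypes.tsv"))
  } else {
    write_genotypes_vcf(bundle$genotypes, bundle$annotations,
                        fp("genotypes.vcf"))
  }
  .write_tsv(bundle$annotations, fp("variants.tsv"))
  write_matrix_tsv(bundle$abundance, fp("abundance.tsv"))
  .write_tsv(bundle$ehr, fp("ehr.tsv"))
  writeLines(bundle$control_ids, fp("controls.txt"))
  writeLines(bundle$gene_lists$omim, fp("omim_genes.txt"))
  writeLines(bundle$gene_lists$open_targets, fp("open_targets_genes.txt"))
  writeLines(bundle$gene_lists$drug_targets, fp("drug_target_genes.txt"))
  .write_tsv(bundle$truth$metabolite_effects, fp("truth_metabolite_effects.tsv"))
  if (!is.null(bundle$truth$ehr_specs)) {
    .write_tsv(bundle$truth$ehr_specs, fp("truth_ehr.tsv"))
  }
  invisible(directory)
}

#' Read a fixture directory back into a cohort bundle
#'
#' @param directory path written by [write_fixture()].
#' @return list mirroring the `komet_cohort` structure (without `config`).
#' @export
read_fixture <- function(directory) {
  fp <- function(f) file.path(directory, f)
  geno <- if (file.exists(fp("genotypes.tsv"))) {
    g <- read_matrix_tsv(fp("genotypes.tsv"))
    storage.mode(g) <- "integer"
    g
  } else {
    read_genotypes_vcf(fp("genotypes.vcf"))
  }
  abundance <- read_matrix_tsv(fp("abundance.tsv"))
  truth_ehr <- if (file.exists(fp("truth_ehr.tsv"))) .read_tsv(fp("truth_ehr.tsv")) else NULL
  list(phenotypes = .read_tsv(fp("phenotypes.tsv")),
       genotypes = geno,
       annotations = .read_tsv(fp("variants.tsv")),
       abundance = abundance,
       ehr = .read_tsv(fp("ehr.tsv"), colClasses = "character"),
       control_ids = readLines(fp("controls.txt")),
       gene_lists = list(omim = readLines(fp("omim_genes.txt")),
                         open_targets = readLines(fp("open_targets_genes.txt")),
                         drug_targets = readLines(fp("drug_target_genes.txt"))),
       truth = list(metabolite_effects = .read_tsv(fp("truth_metabolite_effects.tsv")),
                    ehr_specs = truth_ehr))
}
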