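# Gene/variant selection strategies on annotated variant tables.
#
# Strategy 1 targets complete human knockouts: high-confidence pLoF variants
# at MAF < 2% with at least two homozygous carriers, restricted to genes with
# a known disease or target annotation (OMIM or Open Targets, union).
# Strategy 2 targets disease genes with enough heterozygous carriers of very
# rare (MAF <= 0.1%) pathogenic or HC pLoF variants to test.

#' Build carrier sets from a dosage matrix
#'
#' @param genotypes integer matrix samples x variants with dosages 0/1/2
#'   (`NA` = missing call); rownames = sample IDs, colnames = variant IDs.
#' @return named list: variant ID -> list(`hom` = homozygous sample IDs,
#'   `het` = heterozygous sample IDs).
#' @export
carrier_sets_from_genotypes <- function(genotypes) {
  out <- lapply(seq_len(ncol(genotypes)), function(j) {
    d <- genotypes[, j]
    list(hom = rownames(genotypes)[!is.na(d) & d == 2],
         het = rownames(genotypes)[!is.na(d) & d == 1])
  })
  names(out) <- colnames(genotypes)
  out
}

.check_carriers <- function(annotations, carrier_sets) {
  miss <- setdiff(annotations$variant_id, names(carrier_sets))
  if (length(miss)) {
    stop("variant(s) missing from carrier sets: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
}

#' Strategy 1: complete-knockout variants in annotated disease genes
#'
#' Selects variants with LOFTEE high-confidence pLoF annotation, minor allele
#' frequency strictly below `maf_max`, at least `min_ko` homozygous carriers,
#' and a gene present in the union of the OMIM and Open Targets lists.
#'
#' @param annotations data.frame with columns `variant_id`, `gene`, `loftee`
#'   (`"HC"`, `"LC"`, `"none"`), `maf`, `pathogenic`.
#' @param carrier_sets named list from [carrier_sets_from_genotypes()].
#' @param omim_genes,open_targets_genes character vectors of gene symbols.
#' @param maf_max strict MAF upper bound (default 0.02).
#' @param min_ko minimum number of homozygous carriers (default 2).
#' @return the selected annotation rows, ordered by gene then variant ID,
#'   with an `n_ko` column appended.
#' @export
select_strategy1 <- function(annotations, carrier_sets, omim_genes,
                             open_targets_genes, maf_max = 0.02, min_ko = 2L) {
  .check_carriers(annotations, carrier_sets)
  n_ko <- vapply(carrier_sets[annotations$variant_id],
                 function(cs) length(unique(cs$hom)), integer(1))
  keep <- annotations$loftee == "HC" &
    annotations$maf < maf_max &
    n_ko >= min_ko &
    annotations$gene %in% union(omim_genes, open_targets_genes)
  out <- annotations[keep, , drop = FALSE]
  out$n_ko <- n_ko[keep]
  out <- out[order(out$gene, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strategy 2: disease genes with enough rare heterozygous carriers
#'
#' Per gene in `disease_genes`, pools the distinct heterozygous carriers over
#' that gene's variants with MAF <= `maf_max` and (pathogenic OR LOFTEE HC),
#' and keeps genes whose pooled distinct carrier count is at least
#' `min_carriers`.
#'
#' @inheritParams select_strategy1
#' @param disease_genes character vector of candidate disease gene symbols.
#' @param maf_max inclusive MAF upper bound (default 0.001).
#' @param min_carriers minimum pooled distinct heterozygous carriers
#'   (default 10).
#' @return data.frame with columns `gene`, `n_het_carriers` for selected
#'   genes, ordered by gene.
#' @export
select_strategy2 <- function(annotations, carrier_sets, disease_genes,
                             maf_max = 0.001, min_carriers = 10L) {
  .check_carriers(annotations, carrier_sets)
  if (length(disease_genes) == 0L) {
    message("empty disease gene list: Strategy 2 selects nothing")
    return(data.frame(gene = character(), n_het_carriers = integer(),
                      stringsAsFactors = FALSE))
  }
  qual <- annotations$maf <= maf_max &
    (annotations$pathogenic | annotations$loftee == "HC")
  rows <- lapply(sort(unique(disease_genes)), function(g) {
    vs <- annotations$variant_id[qual & annotations$gene == g]
    carriers <- unique(unlist(lapply(carrier_sets[vs], `[[`, "het"),
                              use.names = FALSE))
    data.frame(gene = g, n_het_carriers = length(carriers),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_het_carriers >= min_carriers, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag candidate compound heterozygotes
#'
#' Samples heterozygous for two or more qualifying (HC pLoF) variants of the
#' same gene may carry no intact gene copy if the variants are in trans.
#' Phase is unknown here, so such samples are reported as candidates only and
#' never promoted to knockouts automatically.
#'
#' @inheritParams select_strategy1
#' @param maf_max MAF cutoff for qualifying variants (default 0.02, strict).
#' @return data.frame `gene`, `sample_id`, `n_variants`.
#' @export
find_compound_het_candidates <- function(annotations, carrier_sets,
                                         maf_max = 0.02) {
  .check_carriers(annotations, carrier_sets)
  qual <- annotations[annotations$loftee == "HC" & annotations$maf < maf_max, ,
                      drop = FALSE]
  rows <- list()
  for (g in unique(qual$gene)) {
    vs <- qual$variant_id[qual$gene == g]
    if (length(vs) < 2L) next
    hets <- unlist(lapply(carrier_sets[vs], `[[`, "het"), use.names = FALSE)
    tab <- table(hets)
    hit <- names(tab)[tab >= 2L]
    if (length(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample_id = hit, n_variants = as.integer(tab[hit]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), sample_id = character(),
                      n_variants = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
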