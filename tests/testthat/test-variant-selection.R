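# Strategy 1/2 selection logic against brute-force predicate evaluation.

make_annotations <- function(n, seed) {
  set.seed(seed)
  data.frame(
    variant_id = sprintf("v%02d", 1:n),
    gene = sprintf("G%02d", sample(1:max(2, n %/% 2), n, TRUE)),
    loftee = sample(c("HC", "LC", "none"), n, TRUE, prob = c(0.5, 0.3, 0.2)),
    maf = signif(runif(n, 0, 0.05), 3),
    pathogenic = runif(n) < 0.3,
    stringsAsFactors = FALSE)
}

make_carriers <- function(ann, seed, pool = sprintf("S%03d", 1:60)) {
  set.seed(seed)
  out <- lapply(ann$variant_id, function(v) {
    nh <- sample(0:4, 1); nz <- sample(0:12, 1)
    picked <- sample(pool, nh + nz)
    list(hom = picked[seq_len(nh)], het = picked[nh + seq_len(nz)])
  })
  names(out) <- ann$variant_id
  out
}

test_that("strategy 1 applies all four predicates with the printed boundaries", {
  ann <- data.frame(
    variant_id = c("a", "b", "c", "d", "e"),
    gene = c("G1", "G1", "G2", "G3", "G4"),
    loftee = c("HC", "HC", "LC", "HC", "HC"),
    maf = c(0.01, 0.01, 0.01, 0.02, 0.01),
    pathogenic = FALSE, stringsAsFactors = FALSE)
  cs <- list(a = list(hom = c("s1", "s2", "s3"), het = character()),
             b = list(hom = "s1", het = c("s2", "s3")),      # 1 KO only
             c = list(hom = c("s1", "s2"), het = character()),
             d = list(hom = c("s1", "s2"), het = character()), # maf not < 0.02
             e = list(hom = c("s1", "s2"), het = character())) # gene in neither list
  sel <- select_strategy1(ann, cs, omim_genes = c("G1", "G3"),
                          open_targets_genes = "G2")
  expect_identical(sel$variant_id, "a")
  expect_identical(sel$n_ko, 3L)
  expect_error(select_strategy1(ann, cs[-1], "G1", "G2"), "missing from carrier sets.*a")
})

test_that("strategy 1 matches brute-force filtering on randomized tables and is order invariant", {
  for (seed in 1:6) {
    ann <- make_annotations(10, seed)
    cs <- make_carriers(ann, seed + 100)
    omim <- unique(ann$gene)[c(1, 3)]
    ot <- unique(ann$gene)[2]
    sel <- select_strategy1(ann, cs, omim, ot)
    # independent re-implementation of the predicate
    keep <- vapply(seq_len(nrow(ann)), function(i) {
      ann$loftee[i] == "HC" && ann$maf[i] < 0.02 &&
        length(cs[[ann$variant_id[i]]]$hom) >= 2 &&
        ann$gene[i] %in% c(omim, ot)
    }, logical(1))
    expect_setequal(sel$variant_id, ann$variant_id[keep])
    # permuting input rows changes nothing
    perm <- sample(nrow(ann))
    sel_p <- select_strategy1(ann[perm, ], cs, omim, ot)
    expect_identical(sel, sel_p)
  }
})

test_that("strategy 1 selection is monotone in the MAF cutoff", {
  ann <- make_annotations(12, 7)
  cs <- make_carriers(ann, 77)
  genes <- unique(ann$gene)
  prev <- character()
  for (cutoff in c(0.005, 0.01, 0.02, 0.05)) {
    cur <- select_strategy1(ann, cs, genes, character(), maf_max = cutoff)$variant_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("strategy 2 pools distinct heterozygous carriers with the printed MAF boundary", {
  ann <- data.frame(
    variant_id = c("a", "b", "c"),
    gene = c("G1", "G1", "G2"),
    loftee = c("HC", "none", "HC"),
    maf = c(0.001, 0.0005, 0.002),
    pathogenic = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE)
  cs <- list(
    a = list(hom = character(), het = sprintf("s%d", 1:6)),
    b = list(hom = character(), het = sprintf("s%d", 5:9)),  # s5, s6 shared
    c = list(hom = character(), het = sprintf("s%d", 1:10)))
  # G1: distinct het carriers over a (HC, maf<=0.001) and b (pathogenic,
  # maf<=0.001) = s1..s9 union = 9 -> below 10 -> excluded
  sel <- select_strategy2(ann, cs, c("G1", "G2"))
  expect_false("G1" %in% sel$gene)
  # G2's only variant has maf 0.002 > 0.1% -> excluded despite 10 carriers
  expect_false("G2" %in% sel$gene)
  # shrink the shared overlap: now G1 reaches exactly 10 distinct carriers
  cs$b$het <- sprintf("s%d", 6:10)
  sel2 <- select_strategy2(ann, cs, c("G1", "G2"))
  expect_identical(sel2$gene, "G1")
  expect_identical(sel2$n_het_carriers, 10L)
  expect_message(empty <- select_strategy2(ann, cs, character()), "empty")
  expect_identical(nrow(empty), 0L)
})

test_that("strategy 2 matches brute-force set arithmetic on randomized tables", {
  for (seed in 11:15) {
    ann <- make_annotations(12, seed)
    ann$maf <- signif(runif(12, 0, 0.002), 3)
    cs <- make_carriers(ann, seed + 200)
    genes <- unique(ann$gene)
    sel <- select_strategy2(ann, cs, genes, min_carriers = 5)
    oracle <- Filter(function(g) {
      vs <- ann$variant_id[ann$gene == g & ann$maf <= 0.001 &
                             (ann$pathogenic | ann$loftee == "HC")]
      length(unique(unlist(lapply(cs[vs], `[[`, "het")))) >= 5
    }, genes)
    expect_setequal(sel$gene, oracle)
  }
})

test_that("compound heterozygote candidates are reported but never promoted", {
  ann <- data.frame(variant_id = c("a", "b"), gene = "G1",
                    loftee = "HC", maf = 0.01, pathogenic = FALSE,
                    stringsAsFactors = FALSE)
  cs <- list(a = list(hom = character(), het = c("s1", "s2")),
             b = list(hom = character(), het = c("s1", "s3")))
  ch <- find_compound_het_candidates(ann, cs)
  expect_identical(ch$sample_id, "s1")
  expect_identical(ch$n_variants, 2L)
  # strategy 1 still sees zero homozygotes for these variants
  expect_identical(nrow(select_strategy1(ann, cs, "G1", character())), 0L)
})
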