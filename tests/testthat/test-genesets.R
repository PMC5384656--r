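# Deleteriousness filter and gene-set characterization.

test_that("nonsynonymous and deleterious rules follow the filter definitions", {
  m <- mk_mut(subject = rep("S", 6), pos = 1:6,
              class = c("SNV", "SNV", "indel", "SNV", "SNV", "SNV"),
              consequence = c("missense", "synonymous", "frameshift",
                              "noncoding", "nonsense", "other"),
              cadd = c(25, 30, NA, NA, 35, NA))
  expect_equal(is_nonsynonymous(m), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))

  ns <- m[is_nonsynonymous(m), ]
  expect_equal(is_deleterious(ns), c(TRUE, TRUE, TRUE))

  edge <- mk_mut(subject = c("S", "S", "S"), pos = 1:3,
                 class = c("SNV", "indel", "SNV"),
                 consequence = c("missense", "frameshift", "missense"),
                 cadd = c(20.0, NA, NA))
  got <- is_deleterious(edge)
  expect_false(got[1])      # CADD exactly 20 fails the strict > rule
  expect_true(got[2])       # frameshift deleterious despite absent CADD
  expect_false(got[3])      # absent CADD on missense -> not deleterious

  syn <- mk_mut(consequence = "synonymous")
  expect_error(is_deleterious(syn), "nonsynonymous")
})

test_that("deleterious filter is monotone in the CADD cutoff", {
  set.seed(21)
  n <- 300
  m <- mk_mut(subject = rep("S", n), pos = 1:n,
              class = ifelse(runif(n) < 0.2, "indel", "SNV"),
              consequence = sample(c("missense", "nonsense", "frameshift"),
                                   n, replace = TRUE),
              cadd = ifelse(runif(n) < 0.1, NA, runif(n, 0, 45)),
              gene = sample(sprintf("G%02d", 1:40), n, replace = TRUE))
  m$consequence[m$variant_class == "SNV" & m$consequence == "frameshift"] <-
    "missense"
  cutoffs <- c(0, 10, 20, 30, 50)
  sets <- lapply(cutoffs, function(cc) which(is_deleterious(m, cc)))
  for (i in seq_along(cutoffs)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
  # at an infinite cutoff only frameshifts remain
  expect_equal(which(is_deleterious(m, Inf)),
               which(m$consequence == "frameshift"))
})

test_that("gene-set extraction deduplicates and tracks missing symbols", {
  m <- mk_mut(subject = rep("S", 4), pos = 1:4, class = "SNV",
              consequence = c("missense", "missense", "nonsense",
                              "synonymous"),
              cadd = c(30, 28, 31, 35), gene = c("ABC1", "ABC1", NA, "DDD"))
  gs <- extract_gene_set(m, "PTB")
  expect_equal(gs$genes, "ABC1")          # two hits in one gene, one member
  expect_equal(gs$n_mutations, 3L)        # synonymous never counted
  expect_equal(gs$n_without_gene, 1L)
  expect_lte(length(gs$genes), gs$n_mutations)

  none <- extract_gene_set(m[m$consequence == "synonymous", ], "empty")
  expect_length(none$genes, 0)
})

test_that("intolerance comparison matches the enumeration oracle", {
  ann <- gene_annotation(sprintf("G%d", 1:7), cnv_intolerance = c(5, 6, 7, 1,
                                                                  2, 3, 4))
  res <- compare_intolerance(c("G1", "G2", "G3"), ann, "cnv")
  expect_equal(res$p_value, oracle_wilcox_p(c(5, 6, 7), c(1, 2, 3, 4)))

  const <- gene_annotation(sprintf("C%d", 1:10), del_intolerance = 2)
  expect_equal(compare_intolerance(c("C1", "C2"), const, "del")$p_value, 1)

  unann <- gene_annotation(c("A", "B", "C"),
                           dup_intolerance = c(NA, NA, 1))
  expect_error(compare_intolerance(c("A", "B"), unann, "dup"), "annotation")
})

test_that("null intolerance p-values are roughly uniform", {
  genes <- sprintf("G%04d", 1:800)
  ps <- vapply(1:60, function(i) {
    ann <- simulate_gene_annotation(genes, seed = 1000 + i)
    set.seed(2000 + i)
    compare_intolerance(sample(genes, 40), ann, "cnv")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("viability composition and enrichment follow their contracts", {
  ann <- gene_annotation(c("L1", "L2", "V1", "U1"),
                         viability = c("lethal", "lethal", "viable",
                                       "unknown"))
  vc <- viability_composition(c("L1", "L2", "V1", "U1"), ann)
  expect_equal(unname(vc$proportions), c(2 / 3, 0, 1 / 3))
  expect_equal(vc$n_unknown, 1L)

  off <- viability_composition(c("X9"), ann)
  expect_false(off$defined)
  expect_true(all(is.na(off$proportions)))

  gonl <- gene_annotation(c("A", "B", "C"), viability = "viable")
  expect_equal(unname(viability_composition(c("A", "B", "C"),
                                            gonl)$proportions),
               c(0, 0, 1))
})

test_that("essentiality enrichment equals hypergeometric enumeration", {
  mk_ann <- function(nlA, nvA, nlB, nvB) {
    gene_annotation(sprintf("G%03d", seq_len(nlA + nvA + nlB + nvB)),
                    viability = rep(c("lethal", "viable", "lethal", "viable"),
                                    c(nlA, nvA, nlB, nvB)))
  }
  ann <- mk_ann(7, 10, 5, 40)
  setA <- sprintf("G%03d", 1:17); setB <- sprintf("G%03d", 18:62)
  res <- viability_enrichment(setA, setB, ann)
  expect_equal(res$p_value,
               oracle_fisher_p(matrix(c(7, 5, 10, 40), 2)))
  expect_equal(res$p_value,
               fisher.test(matrix(c(7, 5, 10, 40), 2))$p.value)

  even <- mk_ann(5, 5, 10, 10)
  res2 <- viability_enrichment(sprintf("G%03d", 1:10), sprintf("G%03d", 11:30),
                               even)
  expect_equal(res2$p_value, 1)

  zero <- mk_ann(0, 10, 0, 40)
  expect_error(viability_enrichment(sprintf("G%03d", 1:10),
                                    sprintf("G%03d", 11:50), zero),
               "lethal margin")
})

test_that("phenotype enrichment matches the closed-form hypergeometric tail", {
  universe <- sprintf("U%02d", 1:20)
  term_map <- data.frame(term = "t1", gene = universe[1:5])
  set <- c(universe[1:4], universe[10])     # overlap 4 of set size 5
  pe <- phenotype_enrichment(set, term_map, universe)
  expect_equal(pe$p_value, oracle_hyper_tail(4, 5, 20, 5))
  expect_equal(pe$p_value,
               sum(choose(5, 4:5) * choose(15, 1:0)) / choose(20, 5))

  # a set equal to one full term has that term as its top hit
  tm2 <- rbind(term_map,
               data.frame(term = "t2", gene = universe[6:15]),
               data.frame(term = "t3", gene = universe[c(1:3, 16:20)]))
  pe2 <- phenotype_enrichment(universe[1:5], tm2, universe)
  expect_equal(pe2$term[1], "t1")
  expect_equal(min(pe2$p_value), pe2$p_value[pe2$term == "t1"])

  # disjoint set -> empty result; empty map -> error
  expect_equal(nrow(phenotype_enrichment("U20", term_map, universe)), 0)
  expect_error(phenotype_enrichment(set, term_map[0, ], universe), "empty")
})

test_that("BH adjustment is monotone and bounded by 1", {
  set.seed(99)
  universe <- sprintf("U%03d", 1:200)
  tm <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(term = sprintf("t%02d", i),
               gene = sample(universe, sample(10:40, 1)))
  }))
  pe <- phenotype_enrichment(sample(universe, 30), tm, universe)
  expect_true(all(pe$fdr <= 1))
  ord <- order(pe$p_value)
  expect_true(all(diff(pe$fdr[ord]) >= -1e-12))
  expect_equal(pe$fdr, p.adjust(pe$p_value, "BH"))
})
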