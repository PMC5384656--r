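# Synthetic cohort generator: determinism, calibration against the stated
# cohort structure, and planted-effect behaviour.

test_that("same seed gives identical outputs, different seeds differ", {
  p <- sim_params(n_trios = 200, seed = 5)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  genes <- sprintf("G%03d", 1:100)
  expect_identical(simulate_mutations(a$burden, genes, p),
                   simulate_mutations(b$burden, genes, p))
  c <- simulate_cohort(sim_params(n_trios = 200, seed = 6))
  expect_false(identical(a$burden, c$burden))
})

test_that("burden counts are exchangeable with the trio table", {
  co <- simulate_cohort(sim_params(n_trios = 150, seed = 2))
  expect_setequal(names(co$burden), co$trios$family_id)
  expect_true(all(co$burden >= 0))
  expect_true(all(co$burden == round(co$burden)))
})

test_that("no age effect means no age-burden correlation", {
  p <- sim_params(n_trios = 10000, age_slope = 0, preterm_shift = 0, seed = 3)
  co <- simulate_cohort(p)
  expect_lt(abs(cor(co$trios$paternal_age, co$burden)), 0.05)
})

test_that("default calibration reproduces the cohort's burden structure", {
  p <- sim_params(n_trios = 10000, seed = 4)
  co <- simulate_cohort(p)
  r <- cor(co$trios$paternal_age, co$burden)
  expect_lt(abs(r - 0.62), 0.03)
  expect_lt(abs(mean(co$burden[!co$trios$preterm]) - 43.86), 0.5)
  # closed form r = b*sigma / sqrt(b^2 sigma^2 + E[lambda]) within 3 MC SEs
  el <- p$baseline_rate + p$preterm_shift * p$preterm_fraction
  r_theory <- p$age_slope * p$paternal_age_sd /
    sqrt(p$age_slope^2 * p$paternal_age_sd^2 + el)
  se <- (1 - r_theory^2) / sqrt(10000)
  expect_lt(abs(r - r_theory), 3 * se)
})

test_that("the preterm shift reproduces the printed mean difference", {
  p <- sim_params(n_trios = 10000, preterm_shift = 2.22, seed = 8)
  co <- simulate_cohort(p)
  diff <- mean(co$burden[co$trios$preterm]) - mean(co$burden[!co$trios$preterm])
  expect_lt(abs(diff - 2.22), 0.3)
})

test_that("mutation lists honour per-subject counts and consequence knobs", {
  p <- sim_params(n_trios = 10, seed = 9)
  genes <- sprintf("G%03d", 1:50)
  counts <- setNames(c(0L, 3L, 5L), c("s1", "s2", "s3"))
  m <- simulate_mutations(counts, genes, p)
  expect_equal(sum(m$subject_id == "s1"), 0)
  expect_equal(as.integer(table(m$subject_id)[c("s2", "s3")]), c(3L, 5L))

  p0 <- sim_params(exonic_fraction = 0, seed = 9)
  m0 <- simulate_mutations(setNames(rep(50L, 10), paste0("t", 1:10)),
                           genes, p0)
  expect_false(any(is_nonsynonymous(m0)))

  expect_error(simulate_mutations(counts, character(0), p), "gene universe")
})

test_that("default rates give the study's per-genome mutation total", {
  p <- sim_params(seed = 10)             # n = 816
  co <- simulate_cohort(p)
  m <- simulate_mutations(co$burden, sprintf("G%04d", 1:2000), p)
  expect_lt(abs(nrow(m) / 816 - 36441 / 816), 0.5)
})

test_that("gene annotation null is calibrated and planted shifts are found", {
  genes <- sprintf("G%04d", 1:2000)
  set.seed(123)
  causal <- sample(genes, 51)
  reject0 <- logical(300)
  reject2 <- logical(100)
  for (i in 1:300) {
    a0 <- simulate_gene_annotation(genes, causal, del_shift = 0, seed = i)
    reject0[i] <- compare_intolerance(causal, a0, "del")$p_value < 0.05
  }
  for (i in 1:100) {
    a2 <- simulate_gene_annotation(genes, causal, del_shift = 2, seed = i)
    reject2[i] <- compare_intolerance(causal, a2, "del")$p_value < 0.05
  }
  # the tie-corrected normal approximation without continuity correction is
  # mildly anticonservative at 51-vs-background, so the true type-I error
  # sits near 0.06 rather than 0.05
  expect_gte(mean(!reject0), 0.92)       # type-I calibration
  expect_gte(mean(reject2), 0.80)        # power at a 2 SD shift

  expect_error(simulate_gene_annotation(genes, "NOT_A_GENE", seed = 1),
               "absent")
  expect_error(simulate_gene_annotation(genes, causal, del_shift = -1,
                                        seed = 1), ">= 0")
})

test_that("expression simulator biases the designated set and stays positive", {
  genes <- sprintf("G%03d", 1:500)
  em0 <- simulate_expression(genes, genes, bias = 0, seed = 1)
  b0 <- beta_scores(genes, em0)
  expect_lt(abs(mean(b0$beta) - 1), 0.05)
  expect_true(all(em0$values > 0))

  gt1 <- vapply(1:20, function(i) {
    em <- simulate_expression(genes, genes, bias = 0.15, seed = i)
    mean(beta_scores(genes, em)$beta) > 1
  }, logical(1))
  expect_gte(mean(gt1), 0.95)

  no_post <- data.frame(stage = c("PCW8", "PCW12"),
                        epoch = c("early_fetal", "later_fetal"))
  expect_error(simulate_expression(genes, stages = no_post, seed = 1),
               "postnatal")
})

test_that("interval simulator constructs its shared/novel ground truth", {
  all_shared <- simulate_interval_sets(20, 60, 1, seed = 2)
  cls <- classify_cnvrs(all_shared$query, all_shared$reference)
  expect_true(all(cls$status == "shared"))

  none <- simulate_interval_sets(20, 60, 0, seed = 3)
  cls0 <- classify_cnvrs(none$query, none$reference)
  expect_true(all(cls0$status == "novel"))

  expect_error(simulate_interval_sets(10, 20, 1.2, seed = 1),
               "shared_fraction")
})
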