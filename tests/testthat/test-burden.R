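# Burden computation and the four burden inference strategies.

mk_trios <- function(n, ga = NULL, pat = NULL, mat = NULL, seed = 1) {
  set.seed(seed)
  trio_table(sprintf("T%04d", 1:n),
             if (is.null(pat)) round(runif(n, 25, 45), 1) else pat,
             if (is.null(mat)) round(runif(n, 22, 42), 1) else mat,
             if (is.null(ga)) round(runif(n, 28, 42), 1) else ga)
}

test_that("burden counts autosomal mutations only, zero-filling subjects", {
  tr <- mk_trios(3)
  m <- mk_mut(subject = rep(tr$family_id[1], 3), chrom = c("chr1", "22", "X"),
              pos = c(1, 2, 3))
  b <- count_burden(m, tr)
  expect_equal(unname(b), c(2L, 0L, 0L))     # X excluded, others zero
  expect_equal(names(b), tr$family_id)

  empty <- m[0, ]
  expect_equal(unname(count_burden(empty, tr)), c(0L, 0L, 0L))

  orphan <- mk_mut(subject = "GHOST", chrom = "1", pos = 5)
  expect_error(count_burden(orphan, tr), "GHOST")
})

test_that("rank-sum comparison matches its stated conventions", {
  # complete separation: U of the first group is 0
  sep <- compare_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(sep$statistic, 0)
  # total ties: p = 1
  tied <- compare_groups(rep(5, 6), rep(c("a", "b"), each = 3))
  expect_equal(tied$p_value, 1)
  # tiny untied groups: exact two-sided p = 2/6
  ex <- compare_groups(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(ex$p_value, 1 / 3)
  expect_match(ex$method, "exact")
})

test_that("rank-sum p agrees with enumeration and with stats::wilcox.test", {
  set.seed(31)
  for (rep in 1:10) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    mine <- compare_groups(c(x, y), rep(c("x", "y"), c(n1, n2)))
    expect_equal(mine$p_value, oracle_wilcox_p(x, y))
    expect_equal(mine$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
  # large-sample approximation vs stats (no continuity correction)
  x <- rnorm(40); y <- rnorm(35) + 0.4
  mine <- compare_groups(c(x, y), rep(c("x", "y"), c(40, 35)))
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(mine$p_value, ref$p.value)
})

test_that("rank-sum p is label-symmetric and exact ~ approx for n >= 10", {
  set.seed(77)
  for (rep in 1:20) {
    vals <- rnorm(12)
    labs <- sample(rep(c("g1", "g2"), c(5, 7)))
    a <- compare_groups(vals, labs)$p_value
    b <- compare_groups(vals, factor(labs, levels = c("g2", "g1")))$p_value
    expect_equal(a, b)
  }
  # without a continuity correction the normal approximation sits within
  # ~0.04 of exact at sizes 10-12 and within 0.02 from ~15 up
  for (rep in 1:10) {
    x <- rnorm(11); y <- rnorm(12) + runif(1, -1, 1)
    vals <- c(x, y); labs <- rep(c("x", "y"), c(11, 12))
    pe <- compare_groups(vals, labs, exact = TRUE)$p_value
    pa <- compare_groups(vals, labs, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.04)
  }
  for (rep in 1:10) {
    x <- rnorm(15); y <- rnorm(16) + runif(1, -1, 1)
    vals <- c(x, y); labs <- rep(c("x", "y"), c(15, 16))
    pe <- compare_groups(vals, labs, exact = TRUE)$p_value
    pa <- compare_groups(vals, labs, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("logistic regression recovers null and planted burden effects", {
  p <- sim_params(n_trios = 10000, preterm_shift = 0, seed = 12)
  co <- simulate_cohort(p)
  fit0 <- fit_preterm_logistic(co$trios, co$burden)
  expect_lt(abs(fit0$coefficients[["burden"]]), 0.05)

  # scale invariance of z-scoring: duplicating the data changes nothing
  tr2 <- co$trios; tr2$family_id <- paste0(tr2$family_id, "b")
  both <- rbind(co$trios, tr2)
  b2 <- setNames(c(co$burden, co$burden), both$family_id)
  fit2 <- fit_preterm_logistic(both, b2)
  expect_equal(fit2$coefficients, fit0$coefficients, tolerance = 1e-4)

  small <- mk_trios(12, ga = c(rep(33, 2), rep(40, 10)))
  expect_error(fit_preterm_logistic(small, setNames(rpois(12, 40),
                                                    small$family_id)),
               ">= 10")
})

test_that("residualization matches closed-form OLS and preserves ranks", {
  # counts exactly linear in age: all residuals zero
  age <- c(20, 30, 40, 50)
  expect_equal(residualize_burden(2 * age + 5, age), rep(0, 4))

  # hand-computed OLS: slope 0.7, intercept 19.5
  res <- residualize_burden(c(40, 45, 47), c(30, 35, 40))
  expect_equal(res, c(-0.5, 1, -0.5))
  expect_lt(abs(sum(res)), 1e-9 * 3)

  # slope-0 data: residuals are centered counts, same rank-sum p as raw
  set.seed(5)
  counts <- rpois(60, 40)
  age <- rep(35, 60) + rnorm(60)
  labs <- rep(c("a", "b"), 30)
  res2 <- residualize_burden(counts, age)
  p_raw <- compare_groups(counts, labs)$p_value
  # adding any multiple of age to the counts is absorbed by the fit
  res3 <- residualize_burden(counts + 3.7 * age, age)
  expect_equal(compare_groups(res3, labs)$p_value,
               compare_groups(res2, labs)$p_value)

  expect_error(residualize_burden(c(1, 2, 3), c(30, 30, 30)), "variance")
})

test_that("extreme-load subset uses the quantile-with-ties rule", {
  b <- setNames(sample(1:100), sprintf("s%03d", 1:100))
  expect_length(extreme_load_subset(b, 0.05), 5)

  all_equal <- setNames(rep(7, 20), sprintf("s%02d", 1:20))
  expect_length(extreme_load_subset(all_equal, 0.05), 20)

  big <- setNames(1:816, sprintf("s%03d", 1:816))
  top <- extreme_load_subset(big, 0.05)
  expect_length(top, 41)                       # ceil(0.05 * 816)
  expect_equal(min(big[top]), 776)
})

test_that("replication-timing context is a base-weighted window mean", {
  track <- replication_timing_track("1", 0, 1e6, 0.7)
  m <- mk_mut(chrom = "1", pos = 5000)
  expect_equal(timing_context(m, track), 0.7)

  # half the window on 0.2, half on 0.8 around the 0-based center 4999
  track2 <- replication_timing_track(c("1", "1"), c(0, 4999), c(4999, 1e6),
                                     c(0.2, 0.8))
  expect_equal(timing_context(m, track2), 0.5)

  # 600 bp of 1.0, 400 bp of 0.0
  track3 <- replication_timing_track(c("1", "1"), c(4499, 5099),
                                     c(5099, 5499), c(1, 0))
  expect_equal(timing_context(m, track3), 0.6)

  # no covered base -> NA
  far <- replication_timing_track("2", 0, 100, 0.5)
  expect_true(is.na(timing_context(m, far)))

  expect_error(timing_context(m, track, window = 999), "even")
})

test_that("gestational-age stratification tests bins against term births", {
  p <- sim_params(n_trios = 4000, preterm_shift = 8, seed = 13)
  co <- simulate_cohort(p)
  s <- stratified_burden(co$trios, co$burden)
  expect_equal(s$bin, c("[32,37)", "[20,32)"))
  # uniform shift: both bins move in the same direction (U above its mean)
  term_n <- sum(co$trios$gestational_age >= 37)
  expect_true(all(s$statistic > s$n * term_n / 2))
  expect_true(all(s$p_value < 0.05))

  tiny <- mk_trios(30, ga = c(rep(40, 28), 33, 30.5))
  b <- setNames(rpois(30, 40), tiny$family_id)
  s2 <- stratified_burden(tiny, b, bins = list(c(32, 37), c(22, 31)))
  expect_true(all(s2$underpowered))
  empty_bin <- stratified_burden(tiny, b, bins = list(c(20, 22)))
  expect_true(is.na(empty_bin$p_value))

  expect_error(stratified_burden(tiny, b, bins = list(c(35, 38))), "term")
})
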