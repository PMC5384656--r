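# Independent brute-force oracles, kept deliberately naive: they enumerate or
# scan per base, and never call the package code paths they check.

# Two-sided rank-sum p by enumeration over all C(n1+n2, n1) label assignments:
# probability of a rank-sum at least as far from its null mean as observed.
oracle_wilcox_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  EW <- n1 * (length(pooled) + 1) / 2
  idx <- utils::combn(length(pooled), n1)
  Ws <- apply(idx, 2, function(j) sum(r[j]))
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(Ws - EW) >= abs(W_obs - EW) - eps),
         greater = mean(Ws >= W_obs - eps),
         less = mean(Ws <= W_obs + eps))
}

# Per-base bitmap coverage of a query interval by a reference interval set
# (same chromosome/type assumed filtered by the caller).
oracle_coverage <- function(q_start, q_end, ref_starts, ref_ends) {
  bases <- rep(FALSE, q_end - q_start)
  for (i in seq_along(ref_starts)) {
    lo <- max(q_start, ref_starts[i])
    hi <- min(q_end, ref_ends[i])
    if (lo < hi) bases[(lo - q_start + 1):(hi - q_start)] <- TRUE
  }
  mean(bases)
}

# Per-base union length of an interval set on one chromosome.
oracle_union_length <- function(starts, ends, chrom_size) {
  bases <- rep(FALSE, chrom_size)
  for (i in seq_along(starts)) {
    bases[(starts[i] + 1):ends[i]] <- TRUE
  }
  sum(bases)
}

# Two-sided Fisher exact p by summation over all 2x2 tables with the observed
# margins, including every table whose hypergeometric probability does not
# exceed the observed one.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Upper hypergeometric tail: P(overlap >= k) drawing n from a universe of N
# containing K term genes.
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Small mutation-table builder for tests.
mk_mut <- function(subject = "S1", chrom = "1", pos = 1000, ref = "A",
                   alt = "T", class = "SNV", consequence = "other",
                   cadd = NA_real_, gene = NA_character_,
                   origin = "unknown") {
  mutation_table(subject, chrom, pos, ref, alt, class, consequence, cadd,
                 gene, origin)
}
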