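# Wilcoxon rank-sum (Mann-Whitney) comparison. Implemented here rather than
# delegated so the exact small-sample path, midrank tie handling and the
# absence of a continuity correction are pinned down; tests cross-check it
# against brute-force enumeration and stats::wilcox.test.

# Exact two-sided p with ties: probability, over all C(n1+n2, n1) equally
# likely label assignments, of a rank-sum deviating from its null mean by at
# least the observed deviation. For untied data this equals the classical
# doubled-tail Mann-Whitney p.
exact_enumeration_p <- function(ranks, n1, alternative) {
  n <- length(ranks)
  W_obs <- sum(ranks[seq_len(n1)])
  EW <- n1 * (n + 1) / 2
  idx <- combn(n, n1)
  Ws <- colSums(matrix(ranks[idx], nrow = n1))
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(Ws - EW) >= abs(W_obs - EW) - eps),
         greater = mean(Ws >= W_obs - eps),
         less = mean(Ws <= W_obs + eps))
}

wilcox_ranksum <- function(x, y, alternative = c("two.sided", "greater",
                                                 "less"), exact = NULL) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("NA values in group comparison")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2             # Mann-Whitney U of group 1
  has_ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- n1 <= 12 && n2 <= 12
  if (exact && has_ties && n > 20) exact <- FALSE  # enumeration too large
  if (exact) {
    if (has_ties) {
      p <- exact_enumeration_p(r, n1, alternative)
      method <- "wilcoxon rank-sum (exact, enumeration)"
    } else {
      lo <- stats::pwilcox(U, n1, n2)
      hi <- stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      p <- switch(alternative,
                  two.sided = min(1, 2 * min(lo, hi)),
                  greater = hi,
                  less = lo)
      method <- "wilcoxon rank-sum (exact)"
    }
  } else {
    mu <- n1 * n2 / 2
    tie_counts <- table(pooled)
    tie_term <- sum(tie_counts^3 - tie_counts)
    v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (v <= 0) {
      p <- 1                              # all observations tied
    } else {
      z <- (U - mu) / sqrt(v)             # no continuity correction
      p <- switch(alternative,
                  two.sided = min(1, 2 * pnorm(-abs(z))),
                  greater = pnorm(z, lower.tail = FALSE),
                  less = pnorm(z))
    }
    method <- "wilcoxon rank-sum (normal, tie-corrected)"
  }
  test_result(method, statistic = U, p_value = p, n_group1 = n1,
              n_group2 = n2)
}

#' Compare two groups by the Wilcoxon rank-sum test
#'
#' Two-sided by default. Uses exact inference when both groups have at most 12
#' observations (the exact Mann-Whitney distribution for untied data,
#' enumeration over label assignments when ties are present and the total
#' group size allows it), and otherwise the tie-corrected normal approximation
#' on midranks with no continuity correction. The reported statistic is the
#' Mann-Whitney U of the first group; complete separation with the first group
#' lowest gives U = 0.
#'
#' @param values numeric vector of per-subject values.
#' @param labels vector with exactly two distinct values; the first group is
#'   the first level (factor order, or order of first appearance).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`, stated
#'   for the first group.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact path;
#'   default `NULL` chooses by group size.
#' @return a [test_result()] of class `dnm_test`.
#' @export
compare_groups <- function(values, labels, alternative = "two.sided",
                           exact = NULL) {
  if (length(values) != length(labels)) {
    stop("values and labels must have the same length")
  }
  f <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = unique(labels))
  if (nlevels(f) != 2) {
    stop("need exactly two groups, got ", nlevels(f), ": ",
         paste(levels(f), collapse = ", "))
  }
  g1 <- values[f == levels(f)[1]]
  g2 <- values[f == levels(f)[2]]
  if (!length(g1) || !length(g2)) {
    stop("group '", levels(f)[which(!c(length(g1), length(g2)))],
         "' is empty")
  }
  res <- wilcox_ranksum(g1, g2, alternative = alternative, exact = exact)
  res$extra$group1 <- levels(f)[1]
  res$extra$group2 <- levels(f)[2]
  res
}
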