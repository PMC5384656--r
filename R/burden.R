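# Per-genome burden and the four burden inference strategies: raw group
# comparison, z-scored logistic regression, age residualization, and the
# extreme-load subset; plus replication-timing context and gestational-age
# stratification.

#' Count autosomal de novo mutations per subject
#'
#' Only mutations on chromosomes 1-22 are counted. Subjects with no mutations
#' get a count of zero; mutations whose `subject_id` is absent from the trio
#' table are an error.
#'
#' @param mutations mutation data.frame (see [read_mutations()]).
#' @param trios trio data.frame (see [read_trios()]).
#' @return named integer vector of counts, one per trio, in trio-table order.
#' @export
count_burden <- function(mutations, trios) {
  ids <- trios$family_id
  orphans <- setdiff(unique(mutations$subject_id), ids)
  if (length(orphans)) {
    stop("mutation subject_id(s) absent from trio table: ",
         paste(orphans, collapse = ", "))
  }
  auto <- mutations[norm_chrom(mutations$chrom) %in% AUTOSOMES, , drop = FALSE]
  tab <- table(factor(auto$subject_id, levels = ids))
  setNames(as.integer(tab), ids)
}

#' Pearson correlation of burden with an age covariate
#'
#' Computed on raw (unstandardized) values; the share of burden variance
#' explained is reported as r squared.
#'
#' @param burden numeric burden per subject.
#' @param age matching numeric ages.
#' @return list with elements `r` and `r_squared`.
#' @export
burden_age_correlation <- function(burden, age) {
  if (length(burden) != length(age)) stop("length mismatch")
  r <- cor(age, burden)
  list(r = r, r_squared = r^2)
}

#' Logistic regression of preterm status on ages and burden
#'
#' Fits `preterm ~ z(paternal_age) + z(maternal_age) + z(burden)` by maximum
#' likelihood (IRLS, tolerance 1e-8, max 100 iterations). All three predictors
#' are z-score normalized; the standardization constants are recorded so the
#' coefficients are per-SD log-odds. Per-term Wald p-values are reported.
#'
#' @param trios trio data.frame.
#' @param burden named burden vector aligned with `trios$family_id`.
#' @return object of class `preterm_logistic` with elements `coefficients`,
#'   `p_values`, `standardization`, `n_preterm`, `n_term`, `fit`.
#' @export
fit_preterm_logistic <- function(trios, burden) {
  burden <- align_burden(burden, trios)
  n_pre <- sum(trios$preterm); n_term <- sum(!trios$preterm)
  if (n_pre < 10 || n_term < 10) {
    stop("need >= 10 subjects in each outcome class (got ", n_pre, " preterm, ",
         n_term, " term)")
  }
  zs <- function(v) (v - mean(v)) / sd(v)
  dat <- data.frame(preterm = trios$preterm,
                    paternal_age = zs(trios$paternal_age),
                    maternal_age = zs(trios$maternal_age),
                    burden = zs(burden))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(preterm ~ paternal_age + maternal_age + burden, data = dat,
        family = binomial(), control = glm.control(epsilon = 1e-8,
                                                   maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) stop("logistic regression did not converge")
  if (sep_warn || any(abs(coef(fit)) > 15)) {
    stop("logistic regression unstable: (quasi-)complete separation suspected")
  }
  sm <- summary(fit)$coefficients
  std <- data.frame(
    predictor = c("paternal_age", "maternal_age", "burden"),
    mean = c(mean(trios$paternal_age), mean(trios$maternal_age), mean(burden)),
    sd = c(sd(trios$paternal_age), sd(trios$maternal_age), sd(burden)))
  structure(list(coefficients = coef(fit), p_values = sm[, "Pr(>|z|)"],
                 standardization = std, n_preterm = n_pre, n_term = n_term,
                 fit = fit),
            class = "preterm_logistic")
}

#' @export
print.preterm_logistic <- function(x, ...) {
  cat("Logistic regression: preterm ~ z(paternal_age) + z(maternal_age) +",
      "z(burden)\n")
  cat("  n =", x$n_preterm, "preterm /", x$n_term, "term\n")
  out <- data.frame(coefficient = round(x$coefficients, 4),
                    p_value = signif(x$p_values, 3))
  print(out)
  invisible(x)
}

#' @export
coef.preterm_logistic <- function(object, ...) object$coefficients

align_burden <- function(burden, trios) {
  if (!is.null(names(burden))) {
    missing <- setdiff(trios$family_id, names(burden))
    if (length(missing)) {
      stop("burden missing for subject(s): ", paste(missing, collapse = ", "))
    }
    burden <- burden[trios$family_id]
  } else if (length(burden) != nrow(trios)) {
    stop("unnamed burden vector must match the trio table length")
  }
  unname(burden)
}

#' Residualize burden on an age covariate
#'
#' Ordinary least-squares fit of burden on age; returns
#' `burden - (intercept + slope * age)`. The residuals carry the paternal- (or
#' maternal-) age-corrected mutation load and sum to zero up to numerical
#' tolerance.
#'
#' @param burden numeric burden per subject (>= 3 subjects).
#' @param age matching age values with nonzero variance.
#' @return numeric residuals (named like `burden` if it was named).
#' @export
residualize_burden <- function(burden, age) {
  if (length(burden) != length(age)) stop("length mismatch")
  if (length(burden) < 3) stop("need at least 3 subjects")
  if (var(age) == 0) stop("age variance is zero; cannot residualize")
  res <- unname(residuals(lm(burden ~ age)))
  names(res) <- names(burden)
  res
}

#' Subjects with extreme mutation load
#'
#' The top `fraction` of subjects by burden: everyone whose burden is at least
#' the (1 - fraction) empirical quantile, computed as the
#' `ceiling(fraction * n)`-th largest value. Ties at the threshold are all
#' included, so the set size is at least `ceiling(fraction * n)`.
#'
#' @param burden named burden vector.
#' @param fraction top fraction to keep, in (0, 1); default 0.05.
#' @return character vector of subject ids (or integer indices if `burden` is
#'   unnamed).
#' @export
extreme_load_subset <- function(burden, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(burden)
  k <- ceiling(fraction * n)
  thr <- sort(burden, decreasing = TRUE)[k]
  sel <- which(burden >= thr)
  if (is.null(names(burden))) sel else names(burden)[sel]
}

#' Mean replication timing around each mutation
#'
#' For each mutation, takes a window of `window` bp centered on the (0-based)
#' mutation locus, `[c - window/2, c + window/2)`, and averages the
#' piecewise-constant timing track over it, weighting each segment by the
#' number of window bases it covers. Mutations whose window covers no
#' annotated base get `NA`.
#'
#' @param mutations mutation data.frame.
#' @param track timing track (see [replication_timing_track()]).
#' @param window window width in bp, even and positive (default 1000).
#' @return numeric vector, one mean timing value (or `NA`) per mutation row.
#' @export
timing_context <- function(mutations, track, window = 1000) {
  if (window <= 0 || window %% 2 != 0) stop("window must be even and > 0")
  half <- window / 2
  centers <- mutations$pos - 1          # 1-based position -> 0-based locus
  chroms <- norm_chrom(mutations$chrom)
  out <- rep(NA_real_, nrow(mutations))
  for (ch in unique(chroms)) {
    seg <- track[track$chrom == ch, , drop = FALSE]
    if (!nrow(seg)) next
    idx <- which(chroms == ch)
    for (i in idx) {
      ws <- centers[i] - half
      we <- centers[i] + half
      cov <- pmax(0, pmin(we, seg$end) - pmax(ws, seg$start))
      tot <- sum(cov)
      if (tot > 0) out[i] <- sum(cov * seg$value) / tot
    }
  }
  out
}

#' Burden comparison stratified by gestational-age bin
#'
#' Compares each preterm gestational-age bin `[lo, hi)` (all `hi` <= the term
#' cutoff) against the term group (gestational age >= 37 weeks). Bins with
#' fewer than 5 subjects are flagged underpowered but still tested; empty bins
#' are reported with `NA` p-values.
#'
#' @param trios trio data.frame.
#' @param burden named burden vector.
#' @param bins list of `c(lo, hi)` gestational-age intervals in weeks,
#'   disjoint and entirely below 37.
#' @param term_cutoff term threshold in weeks (default 37).
#' @return data.frame with one row per bin: bin label, n, underpowered flag,
#'   U statistic and p-value.
#' @export
stratified_burden <- function(trios, burden, bins = list(c(32, 37), c(20, 32)),
                              term_cutoff = 37) {
  burden <- align_burden(burden, trios)
  for (b in bins) {
    if (length(b) != 2 || b[1] >= b[2]) stop("each bin must be c(lo, hi), lo < hi")
    if (b[2] > term_cutoff) {
      stop("bin [", b[1], ", ", b[2], ") overlaps the term range (>= ",
           term_cutoff, " weeks)")
    }
  }
  ga <- trios$gestational_age
  term_vals <- burden[ga >= term_cutoff]
  if (!length(term_vals)) stop("no term subjects (gestational age >= ",
                               term_cutoff, ")")
  rows <- lapply(bins, function(b) {
    inbin <- ga >= b[1] & ga < b[2]
    n <- sum(inbin)
    lab <- sprintf("[%g,%g)", b[1], b[2])
    if (n == 0) {
      return(data.frame(bin = lab, n = 0L, underpowered = TRUE,
                        statistic = NA_real_, p_value = NA_real_))
    }
    tst <- wilcox_ranksum(burden[inbin], term_vals)
    data.frame(bin = lab, n = n, underpowered = n < 5,
               statistic = tst$statistic, p_value = tst$p_value)
  })
  do.call(rbind, rows)
}
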