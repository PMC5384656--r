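# Developmental expression: per-gene normalization across stages, gene-set
# trajectories (mean +/- SEM per stage), and the expression-propensity fold
# change beta = mean(early fetal) / mean(postnatal), computed on raw values.

#' Normalize expression across developmental stages
#'
#' Per-gene z-score across stages (sample SD, n-1 denominator) by default, or
#' per-gene min-max scaling. Genes with zero cross-stage variance are set to
#' all-zero and recorded in the `flagged_genes` attribute. Normalization is
#' for trajectory plots only; the propensity fold change uses raw values.
#'
#' @param em an [expression_matrix()].
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return a normalized `expression_matrix` with attribute `flagged_genes`.
#' @export
normalize_stages <- function(em, method = c("zscore", "minmax")) {
  stopifnot(inherits(em, "expression_matrix"))
  method <- match.arg(method)
  v <- em$values
  if (ncol(v) < 2) stop("need at least 2 stages to normalize")
  rng <- apply(v, 1, function(x) diff(range(x)))
  flat <- rng == 0
  out <- v
  if (method == "zscore") {
    mu <- rowMeans(v)
    sdv <- apply(v, 1, sd)
    out[!flat, ] <- (v[!flat, , drop = FALSE] - mu[!flat]) / sdv[!flat]
  } else {
    mn <- apply(v, 1, min)
    out[!flat, ] <- (v[!flat, , drop = FALSE] - mn[!flat]) / rng[!flat]
  }
  out[flat, ] <- 0
  # z-scores are signed, so bypass the nonnegativity check of the constructor
  res <- structure(list(values = out, epochs = em$epochs),
                   class = "expression_matrix")
  attr(res, "flagged_genes") <- rownames(v)[flat]
  attr(res, "normalized") <- method
  res
}

#' Stage-wise trajectory of a gene set
#'
#' Mean and standard error of the mean (SD / sqrt(n)) per stage over the set
#' genes present in the (normalized) matrix.
#'
#' @param set a `gene_set` or symbol vector (>= 2 genes present required, or
#'   the SEM is undefined).
#' @param em an `expression_matrix`, typically from [normalize_stages()].
#' @return data.frame (stage, epoch, mean, sem, n_genes).
#' @export
trajectory <- function(set, em) {
  stopifnot(inherits(em, "expression_matrix"))
  sg <- intersect(set_genes(set), rownames(em$values))
  if (length(sg) < 2) {
    stop("need at least 2 set genes present in the matrix (got ",
         length(sg), ")")
  }
  sub <- em$values[sg, , drop = FALSE]
  data.frame(stage = colnames(sub), epoch = em$epochs,
             mean = colMeans(sub),
             sem = apply(sub, 2, sd) / sqrt(nrow(sub)),
             n_genes = nrow(sub), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Expression propensity fold change for one gene
#'
#' beta = mean raw expression over the early-fetal stages / mean raw
#' expression over the postnatal stages. beta > 1 indicates early-fetal-biased
#' expression. Undefined (`NA`) when the postnatal mean is zero.
#'
#' @param gene gene symbol (must be present in the matrix).
#' @param em a raw (unnormalized) `expression_matrix`.
#' @param early,postnatal stage labels of the two epochs; default to the
#'   matrix's epoch tags.
#' @return list with `gene` and `beta`.
#' @export
beta_score <- function(gene, em, early = epoch_stages(em, "early_fetal"),
                       postnatal = epoch_stages(em, "postnatal")) {
  stopifnot(inherits(em, "expression_matrix"))
  if (!is.null(attr(em, "normalized"))) {
    stop("beta_score must be computed on raw (unnormalized) values")
  }
  gene <- norm_gene(gene)
  if (!gene %in% rownames(em$values)) {
    stop("gene not in expression matrix: ", gene)
  }
  if (!length(early) || !length(postnatal)) {
    stop("both epochs must be nonempty")
  }
  row <- em$values[gene, ]
  num <- mean(row[early])
  den <- mean(row[postnatal])
  beta <- if (den == 0) NA_real_ else num / den
  list(gene = gene, beta = beta)
}

#' Expression propensity fold changes for a gene set
#'
#' Vectorized [beta_score()] over the set genes present in the matrix. Genes
#' with a zero postnatal mean are excluded and counted.
#'
#' @inheritParams beta_score
#' @param set a `gene_set` or symbol vector.
#' @return data.frame (gene, beta) of defined scores, with attributes
#'   `n_undefined` (zero postnatal mean) and `n_absent` (not in matrix).
#' @export
beta_scores <- function(set, em, early = epoch_stages(em, "early_fetal"),
                        postnatal = epoch_stages(em, "postnatal")) {
  sg <- set_genes(set)
  present <- intersect(sg, rownames(em$values))
  betas <- vapply(present, function(g) {
    beta_score(g, em, early = early, postnatal = postnatal)$beta
  }, numeric(1))
  defined <- !is.na(betas)
  out <- data.frame(gene = present[defined], beta = unname(betas[defined]),
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(!defined)
  attr(out, "n_absent") <- length(sg) - length(present)
  out
}

#' Compare expression propensity between two gene sets
#'
#' Two-sided Wilcoxon rank-sum test of per-gene beta values between two sets,
#' with each group's median beta and fraction of genes with beta > 1 reported
#' alongside.
#'
#' @param beta_a,beta_b numeric beta vectors or data.frames from
#'   [beta_scores()].
#' @param alternative test sidedness for the first set (default two-sided).
#' @return a `dnm_test`; `extra` carries `median_a`, `median_b`,
#'   `frac_gt1_a`, `frac_gt1_b`.
#' @export
compare_beta <- function(beta_a, beta_b, alternative = "two.sided") {
  get_beta <- function(b) {
    v <- if (is.data.frame(b)) b$beta else as.numeric(b)
    v <- v[!is.na(v)]
    if (!length(v)) stop("a beta group is empty")
    v
  }
  a <- get_beta(beta_a); b <- get_beta(beta_b)
  res <- wilcox_ranksum(a, b, alternative = alternative)
  res$method <- paste0(res$method, " [beta]")
  res$extra <- c(res$extra,
                 list(median_a = median(a), median_b = median(b),
                      frac_gt1_a = mean(a > 1), frac_gt1_b = mean(b > 1)))
  res
}
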