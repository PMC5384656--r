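# Synthetic cohort generator. The defaults are the study's stated world:
# 816 trios with 292 preterm, parental ages 33.5 +/- 5.8 (paternal) and
# 31.4 +/- 4.9 (maternal) years, Poisson burden with a term mean of 43.86
# mutations, a preterm shift of 2.22 (46.08 - 43.86), a paternal-age slope
# solved so that cor(paternal age, burden) = 0.62, ~1 coding mutation per 50,
# and ~80% paternal origin. Randomness is a single seeded stream per
# generator; sub-streams derive from the global seed by fixed offsets
# (cohort +0, mutations +1, annotation +2, expression +3, intervals +4,
# gene coordinates +5).

# hg19-scale autosome lengths (Mb), used as a toy coordinate map.
TOY_AUTOSOME_MB <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135,
                     134, 115, 107, 103, 90, 81, 78, 59, 63, 48, 51)

#' Solve the paternal-age slope from a target burden correlation
#'
#' Under the burden model `count ~ Poisson(a + b (age - mu) + delta preterm)`
#' with `age ~ N(mu, sigma^2)`, the population correlation between age and
#' count is `r = b sigma / sqrt(b^2 sigma^2 + E[lambda])`. Inverting for `b`:
#' `b = sqrt(E[lambda] r^2 / (1 - r^2)) / sigma`.
#'
#' @param r target Pearson correlation (default 0.62).
#' @param baseline_rate term-birth mean burden `a` (default 43.86).
#' @param preterm_shift additive preterm increment `delta` (default 2.22).
#' @param preterm_fraction cohort preterm fraction (default 292/816).
#' @param paternal_age_sd paternal-age SD in years (default 5.8).
#' @return slope `b` in mutations per year of paternal age.
#' @export
solve_age_slope <- function(r = 0.62, baseline_rate = 43.86,
                            preterm_shift = 46.08 - 43.86,
                            preterm_fraction = 292 / 816,
                            paternal_age_sd = 5.8) {
  if (r <= 0 || r >= 1) stop("r must be in (0, 1)")
  mean_lambda <- baseline_rate + preterm_shift * preterm_fraction
  sqrt(mean_lambda * r^2 / (1 - r^2)) / paternal_age_sd
}

#' Simulation parameters
#'
#' All defaults are calibrated to the study cohort; see the package vignette
#' for the provenance of each value.
#'
#' @param n_trios number of families (default 816).
#' @param preterm_fraction probability a birth is preterm (default 292/816).
#' @param paternal_age_mean,paternal_age_sd paternal age distribution, years
#'   (defaults 33.5, 5.8; normal truncated below at 18).
#' @param maternal_age_mean,maternal_age_sd maternal age distribution, years
#'   (defaults 31.4, 4.9).
#' @param maternal_corr correlation between parental ages (default 0.7; a free
#'   realism choice, not an observed value).
#' @param baseline_rate `a`, expected burden for a term birth at the mean
#'   paternal age (default 43.86).
#' @param age_slope `b`, mutations per year of paternal age; default solved
#'   from r = 0.62 via [solve_age_slope()].
#' @param preterm_shift `delta`, additive preterm burden increment (default
#'   46.08 - 43.86 = 2.22).
#' @param exonic_fraction probability a mutation receives a coding consequence
#'   (default 1/50).
#' @param consequence_split distribution of coding consequences (missense,
#'   nonsense, frameshift, synonymous).
#' @param cadd_gt20_fraction fraction of missense/nonsense mutations drawn
#'   with CADD phred > 20 (default 0.21, so that with frameshifts the
#'   deleterious share of nonsynonymous mutations is ~0.32, matching 51/169
#'   and 112/339).
#' @param indel_fraction probability a noncoding mutation is an indel (default
#'   648/36441; frameshifts are always indels).
#' @param paternal_origin_fraction probability a mutation is paternal in
#'   origin (default 0.80).
#' @param ga_term_mean,ga_term_sd,ga_preterm_mean,ga_preterm_sd gestational
#'   age mixture components in weeks (term mode 39.1, preterm mode 33.1).
#' @param ga_min lower clamp on gestational age (default 22.7 weeks).
#' @param seed global seed; generator sub-streams use fixed offsets from it.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_trios = 816, preterm_fraction = 292 / 816,
                       paternal_age_mean = 33.5, paternal_age_sd = 5.8,
                       maternal_age_mean = 31.4, maternal_age_sd = 4.9,
                       maternal_corr = 0.7,
                       baseline_rate = 43.86,
                       age_slope = NULL,
                       preterm_shift = 46.08 - 43.86,
                       exonic_fraction = 1 / 50,
                       consequence_split = c(missense = 0.55, nonsense = 0.07,
                                             frameshift = 0.10,
                                             synonymous = 0.28),
                       cadd_gt20_fraction = 0.21,
                       indel_fraction = 648 / 36441,
                       paternal_origin_fraction = 0.80,
                       ga_term_mean = 39.1, ga_term_sd = 1.2,
                       ga_preterm_mean = 33.1, ga_preterm_sd = 2.9,
                       ga_min = 22.7, seed = 1) {
  if (is.null(age_slope)) {
    age_slope <- solve_age_slope(0.62, baseline_rate, preterm_shift,
                                 preterm_fraction, paternal_age_sd)
  }
  p <- list(n_trios = as.integer(n_trios),
            preterm_fraction = preterm_fraction,
            paternal_age_mean = paternal_age_mean,
            paternal_age_sd = paternal_age_sd,
            maternal_age_mean = maternal_age_mean,
            maternal_age_sd = maternal_age_sd,
            maternal_corr = maternal_corr,
            baseline_rate = baseline_rate, age_slope = age_slope,
            preterm_shift = preterm_shift,
            exonic_fraction = exonic_fraction,
            consequence_split = consequence_split / sum(consequence_split),
            cadd_gt20_fraction = cadd_gt20_fraction,
            indel_fraction = indel_fraction,
            paternal_origin_fraction = paternal_origin_fraction,
            ga_term_mean = ga_term_mean, ga_term_sd = ga_term_sd,
            ga_preterm_mean = ga_preterm_mean, ga_preterm_sd = ga_preterm_sd,
            ga_min = ga_min, seed = as.integer(seed))
  probs <- c(p$preterm_fraction, p$exonic_fraction, p$cadd_gt20_fraction,
             p$indel_fraction, p$paternal_origin_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (p$baseline_rate <= 0) stop("baseline_rate must be positive")
  if (p$n_trios < 1) stop("n_trios must be >= 1")
  structure(p, class = "sim_params")
}

# normal truncated below at `lower`, by resampling (negligible at 2.7 SD)
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Simulate a trio cohort with per-genome mutation burden
#'
#' Paternal ages are normal (truncated at 18 years), maternal ages correlated
#' normal; gestational age is a two-component mixture (term mode 39.1 weeks,
#' preterm mode 33.1, clamped to at least 22.7 and split at 37). The burden is
#' Poisson with rate `a + b (paternal_age - mean) + delta * preterm`, floored
#' at 1. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @return list with `trios` (trio data.frame) and `burden` (named integer
#'   vector).
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_trios
  pat <- rnorm_trunc(n, params$paternal_age_mean, params$paternal_age_sd, 18)
  z <- (pat - params$paternal_age_mean) / params$paternal_age_sd
  mat <- params$maternal_age_mean +
    params$maternal_age_sd * (params$maternal_corr * z +
                                sqrt(1 - params$maternal_corr^2) * rnorm(n))
  mat <- pmax(mat, 16)
  preterm <- runif(n) < params$preterm_fraction
  ga <- numeric(n)
  ga[preterm] <- rnorm(sum(preterm), params$ga_preterm_mean,
                       params$ga_preterm_sd)
  ga[!preterm] <- rnorm(sum(!preterm), params$ga_term_mean, params$ga_term_sd)
  ga[preterm] <- pmin(pmax(ga[preterm], params$ga_min), 36.9)
  ga[!preterm] <- pmin(pmax(ga[!preterm], 37), 43)
  lambda <- params$baseline_rate +
    params$age_slope * (pat - params$paternal_age_mean) +
    params$preterm_shift * preterm
  if (any(lambda <= 0)) {
    stop("Poisson rate <= 0 for some subject; decrease age_slope or ",
         "increase baseline_rate")
  }
  lambda <- pmax(lambda, 1)
  counts <- rpois(n, lambda)
  ids <- sprintf("F%04d", seq_len(n))
  trios <- trio_table(ids, round(pat, 1), round(mat, 1), round(ga, 1))
  list(trios = trios, burden = setNames(counts, ids))
}

#' Simulate per-subject de novo mutation lists
#'
#' Draws exactly `counts[s]` mutations for each subject: positions uniform on
#' a toy autosome map, coding consequences with probability `exonic_fraction`
#' (split per `consequence_split`), CADD phred for missense/nonsense from a
#' two-component mixture with a `cadd_gt20_fraction` chance of exceeding 20,
#' parental origin Bernoulli(`paternal_origin_fraction`). When `preterm` and
#' `causal_genes` are supplied, deleterious-class mutations of preterm
#' subjects hit a causal gene with probability `causal_prob`, planting the
#' gene-set signal the downstream characterization looks for.
#'
#' @param counts named integer vector of per-subject burden (from
#'   [simulate_cohort()]).
#' @param genes gene universe (symbols) for coding mutations.
#' @param params a [sim_params()]; the RNG sub-stream is `seed + 1`.
#' @param preterm optional named logical vector (per subject).
#' @param causal_genes optional subset of `genes` to enrich among deleterious
#'   preterm mutations.
#' @param causal_prob probability a deleterious preterm mutation hits a causal
#'   gene (default 0.5).
#' @return mutation data.frame.
#' @export
simulate_mutations <- function(counts, genes, params = sim_params(),
                               preterm = NULL, causal_genes = character(),
                               causal_prob = 0.5) {
  stopifnot(inherits(params, "sim_params"))
  genes <- norm_gene(genes)
  if (params$exonic_fraction > 0 && !length(genes)) {
    stop("empty gene universe with exonic_fraction > 0")
  }
  if (length(causal_genes) && !all(causal_genes %in% genes)) {
    stop("causal genes absent from the universe: ",
         paste(setdiff(causal_genes, genes), collapse = ", "))
  }
  set.seed(params$seed + 1L)
  total <- sum(counts)
  if (total == 0) {
    return(mutation_table(character(0), character(0), integer(0),
                          character(0), character(0), character(0)))
  }
  subject <- rep(names(counts), counts)
  chrom_len <- TOY_AUTOSOME_MB * 1e6
  chrom <- sample(AUTOSOMES, total, replace = TRUE,
                  prob = chrom_len / sum(chrom_len))
  pos <- floor(runif(total) * chrom_len[match(chrom, AUTOSOMES)]) + 1
  coding <- runif(total) < params$exonic_fraction
  consequence <- rep("noncoding", total)
  if (any(coding)) {
    consequence[coding] <- sample(names(params$consequence_split),
                                  sum(coding), replace = TRUE,
                                  prob = params$consequence_split)
  }
  # CADD only for substitutions with a deleteriousness question to answer
  cadd <- rep(NA_real_, total)
  mn <- consequence %in% c("missense", "nonsense")
  if (any(mn)) {
    high <- runif(sum(mn)) < params$cadd_gt20_fraction
    cadd[mn] <- ifelse(high, 20 + rgamma(sum(mn), shape = 2, scale = 4),
                       runif(sum(mn), 0, 20))
  }
  gene <- rep(NA_character_, total)
  if (any(coding)) {
    gene[coding] <- sample(genes, sum(coding), replace = TRUE)
  }
  if (length(causal_genes) && !is.null(preterm)) {
    deleterious <- consequence == "frameshift" | (!is.na(cadd) & cadd > 20)
    target <- deleterious & preterm[subject] &
      runif(total) < causal_prob
    if (any(target)) {
      gene[target] <- sample(causal_genes, sum(target), replace = TRUE)
    }
  }
  is_indel <- consequence == "frameshift" |
    (consequence == "noncoding" & runif(total) < params$indel_fraction)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  ins <- is_indel & runif(total) < 0.5
  alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
  del <- is_indel & !ins
  ref[del] <- paste0(alt[del], sample(bases, sum(del), replace = TRUE))
  origin <- ifelse(runif(total) < params$paternal_origin_fraction,
                   "paternal", "maternal")
  mutation_table(subject_id = subject, chrom = chrom, pos = pos,
                 ref = ref, alt = alt,
                 variant_class = ifelse(is_indel, "indel", "SNV"),
                 consequence = consequence, cadd_phred = cadd,
                 gene = gene, parental_origin = origin)
}

#' Simulate a gene annotation table with a planted causal shift
#'
#' Background intolerance scores are standard normal (deletion and duplication
#' intolerance correlated at 0.5, as seen genome-wide; the overall CNV score
#' is their standardized sum). Causal genes receive an additive
#' `del_shift`-SD location shift on deletion intolerance only, which
#' propagates attenuated into the CNV score and leaves duplication intolerance
#' unshifted. Viability classes are multinomial with background proportions
#' from the knockout screen (410 lethal / 198 subviable / 1143 viable among
#' 1751 scored genes), an elevated lethal odds (`lethal_odds`) for causal
#' genes, and a `known_fraction` of genes scored at all.
#'
#' @param genes gene universe.
#' @param causal_genes subset of `genes` carrying the planted effects.
#' @param del_shift deletion-intolerance shift in SD units (>= 0).
#' @param lethal_odds multiplier on the lethal-class odds for causal genes
#'   (>= 0).
#' @param known_fraction fraction of genes with a known viability class.
#' @param seed RNG seed (bundle uses global seed + 2).
#' @return gene annotation data.frame.
#' @export
simulate_gene_annotation <- function(genes, causal_genes = character(),
                                     del_shift = 1.0, lethal_odds = 3,
                                     known_fraction = 0.3, seed = 1) {
  genes <- norm_gene(genes)
  if (!all(causal_genes %in% genes)) {
    stop("causal genes absent from the universe: ",
         paste(setdiff(causal_genes, genes), collapse = ", "))
  }
  if (del_shift < 0 || lethal_odds < 0) stop("effect sizes must be >= 0")
  set.seed(seed)
  n <- length(genes)
  causal <- genes %in% causal_genes
  rho <- 0.5
  dup <- rnorm(n)
  del <- rho * dup + sqrt(1 - rho^2) * rnorm(n)
  del[causal] <- del[causal] + del_shift
  cnv <- (del + dup) / sqrt(2 * (1 + rho))
  base_probs <- c(lethal = 410, subviable = 198, viable = 1143) / 1751
  causal_probs <- base_probs * c(lethal_odds, 1, 1)
  causal_probs <- causal_probs / sum(causal_probs)
  viability <- rep("unknown", n)
  known <- runif(n) < known_fraction
  draw <- function(k, probs) {
    sample(c("lethal", "subviable", "viable"), k, replace = TRUE, prob = probs)
  }
  viability[known & !causal] <- draw(sum(known & !causal), base_probs)
  viability[known & causal] <- draw(sum(known & causal), causal_probs)
  gene_annotation(genes, cnv_intolerance = cnv, del_intolerance = del,
                  dup_intolerance = dup, viability = viability)
}

#' Default developmental stage table
#'
#' Nine neocortical stages: three early-fetal (PCW 8-10, 12, 13), three
#' later-fetal (PCW 16, 17-22, 25-26) and three postnatal (months 4, 10, 12).
#' @return data.frame with columns `stage`, `epoch`.
#' @export
default_stages <- function() {
  data.frame(
    stage = c("PCW8-10", "PCW12", "PCW13", "PCW16", "PCW17-22", "PCW25-26",
              "4mo", "10mo", "12mo"),
    epoch = rep(c("early_fetal", "later_fetal", "postnatal"), each = 3),
    stringsAsFactors = FALSE)
}

#' Simulate a staged expression matrix
#'
#' Log-normal expression with a per-gene base level; genes in `biased_set` get
#' an expected log-expression decreasing linearly across the stage order
#' (strength `bias` per stage step), others are flat. All values are positive.
#'
#' @param genes gene universe (matrix rows).
#' @param biased_set genes with early-fetal-biased (monotone decreasing)
#'   expected expression.
#' @param stages stage table as from [default_stages()]; must contain a
#'   postnatal epoch (the propensity denominator).
#' @param bias log-scale decrease per stage step for biased genes (default
#'   0.15, giving beta ~ exp(0.9) ~ 2.5 across the default 9 stages).
#' @param noise_sd log-scale noise SD (default 0.3).
#' @param seed RNG seed (bundle uses global seed + 3).
#' @return an [expression_matrix()].
#' @export
simulate_expression <- function(genes, biased_set = character(),
                                stages = default_stages(), bias = 0.15,
                                noise_sd = 0.3, seed = 1) {
  genes <- norm_gene(genes)
  if (!any(stages$epoch == "postnatal")) {
    stop("no postnatal stage defined; expression propensity undefined")
  }
  if (bias < 0) stop("bias must be >= 0")
  set.seed(seed)
  n <- length(genes)
  k <- nrow(stages)
  base <- rnorm(n, mean = 2, sd = 1)
  slope <- ifelse(genes %in% norm_gene(biased_set), -bias, 0)
  logv <- outer(base, rep(1, k)) +
    outer(slope, seq_len(k) - 1) +
    matrix(rnorm(n * k, sd = noise_sd), n, k)
  vals <- exp(logv)
  dimnames(vals) <- list(genes, stages$stage)
  expression_matrix(vals, stages$epoch)
}

#' Simulate query/reference interval collections with known novelty truth
#'
#' Query regions are placed in disjoint slots of a toy genome; each "shared"
#' query is constructed so that 85-100% of its span is covered by reference
#' records (two pieces, exercising the union), each "novel" query so that
#' 10-70% is covered. Extra reference records are placed away from every
#' query. The construction guarantees the 80%-coverage classifier reproduces
#' the truth labels exactly.
#'
#' @param n_query number of query regions (default 74).
#' @param n_reference total reference records (default 500; at least the
#'   number needed to cover the shared queries).
#' @param shared_fraction fraction of queries constructed as shared, in
#'   `[0, 1]` (default 64/74).
#' @param seed RNG seed (bundle uses global seed + 4).
#' @param svtype interval type for the whole collection.
#' @return list with `query`, `reference` (interval data.frames) and `truth`
#'   (query data.frame plus a `status` column).
#' @export
simulate_interval_sets <- function(n_query = 74, n_reference = 500,
                                   shared_fraction = 64 / 74, seed = 1,
                                   svtype = "deletion") {
  if (shared_fraction < 0 || shared_fraction > 1) {
    stop("shared_fraction must be in [0, 1]")
  }
  set.seed(seed)
  n_shared <- round(shared_fraction * n_query)
  status <- rep(c("shared", "novel"), c(n_shared, n_query - n_shared))
  status <- sample(status)                     # shuffle label order
  slot <- 2e6
  chrom_len <- TOY_AUTOSOME_MB * 1e6
  slots_per_chrom <- floor(chrom_len / slot) - 1
  # slot index i -> (chrom, offset), round-robin over autosomes
  place <- function(i) {
    ch <- ((i - 1) %% 22) + 1
    row <- ((i - 1) %/% 22) %% slots_per_chrom[ch]
    c(ch, row * slot)
  }
  qs <- t(vapply(seq_len(n_query), place, numeric(2)))
  L <- floor(runif(n_query, 5e4, 5e5))
  start <- qs[, 2] + floor(runif(n_query, 1e4, 5e5))
  query <- genomic_intervals(AUTOSOMES[qs[, 1]], start, start + L, svtype)
  ref_rows <- list()
  for (i in seq_len(n_query)) {
    s <- query$start[i]; e <- query$end[i]; len <- e - s
    if (status[i] == "shared") {
      covered <- ceiling(runif(1, 0.85, 1.0) * len)
      c1 <- floor(covered / 2); c2 <- covered - c1
      ref_rows[[length(ref_rows) + 1]] <-
        data.frame(chrom = query$chrom[i],
                   start = c(s, e - c2), end = c(s + c1, e))
    } else {
      covered <- floor(runif(1, 0.10, 0.70) * len)
      if (covered > 0) {
        ref_rows[[length(ref_rows) + 1]] <-
          data.frame(chrom = query$chrom[i], start = s, end = s + covered)
      }
    }
  }
  used <- sum(vapply(ref_rows, nrow, 0L))
  n_extra <- max(0, n_reference - used)
  if (n_extra > 0) {
    idx <- n_query + seq_len(n_extra)
    es <- t(vapply(idx, place, numeric(2)))
    el <- floor(runif(n_extra, 1e4, 4e5))
    est <- es[, 2] + floor(runif(n_extra, 1e4, 5e5))
    ref_rows[[length(ref_rows) + 1]] <-
      data.frame(chrom = AUTOSOMES[es[, 1]], start = est, end = est + el)
  }
  ref <- do.call(rbind, ref_rows)
  reference <- genomic_intervals(ref$chrom, ref$start, ref$end, svtype)
  truth <- query
  truth$status <- status
  list(query = query, reference = reference, truth = truth)
}

#' Place genes inside query regions
#'
#' Tiles `per_region` genes inside each region so that downstream
#' gene-in-region extraction has known ground truth. Symbols are taken from
#' `gene_pool` in order.
#'
#' @param regions interval data.frame.
#' @param gene_pool symbols to assign (needs `per_region * nrow(regions)`).
#' @param per_region genes per region (default 2).
#' @param seed RNG seed (bundle uses global seed + 5).
#' @return gene coordinate data.frame (gene, chrom, start, end).
#' @export
simulate_gene_coords <- function(regions, gene_pool, per_region = 2,
                                 seed = 1) {
  need <- per_region * nrow(regions)
  if (length(gene_pool) < need) {
    stop("gene_pool too small: need ", need, " symbols")
  }
  set.seed(seed)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$start[i]; e <- regions$end[i]
    w <- floor((e - s) / per_region)
    gs <- s + (seq_len(per_region) - 1) * w
    glen <- pmax(1000, floor(w * runif(per_region, 0.2, 0.6)))
    data.frame(gene = gene_pool[(i - 1) * per_region + seq_len(per_region)],
               chrom = regions$chrom[i], start = gs,
               end = pmin(gs + glen, e), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a binary outcome from a planted burden log-odds
#'
#' Draws preterm status from `logit(p) = intercept + beta * z(burden)`,
#' ignoring ages, for logistic-regression parameter-recovery checks.
#'
#' @param burden numeric burden vector.
#' @param beta planted log-odds per SD of burden.
#' @param intercept log-odds intercept (default `qlogis(0.35)`).
#' @param seed RNG seed.
#' @return logical outcome vector.
#' @export
simulate_logistic_outcome <- function(burden, beta, intercept =
                                        stats::qlogis(0.35), seed = 1) {
  set.seed(seed)
  z <- (burden - mean(burden)) / sd(burden)
  runif(length(burden)) < stats::plogis(intercept + beta * z)
}

#' Simulate the full synthetic analysis bundle
#'
#' Generates everything the pipeline consumes: a trio cohort with burden, the
#' per-subject mutation table, a gene annotation with a causal set planted
#' (the genes deleterious preterm mutations preferentially hit), a phenotype
#' term map in which one term collects causal genes, a staged expression
#' matrix biased towards early-fetal expression for the causal and
#' novel-region genes, and deletion/duplication interval collections with
#' known novelty truth (64/74 deletions shared, 56/57 duplications shared).
#'
#' @param params a [sim_params()].
#' @param n_genes gene universe size (default 2000).
#' @param n_causal causal gene-set size (default 51).
#' @param dir if non-NULL, write the bundle as TSV/BED files plus params.json
#'   into this directory.
#' @return list with all simulated objects (and `paths` when written).
#' @export
simulate_bundle <- function(params = sim_params(), n_genes = 2000,
                            n_causal = 51, dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  universe <- sprintf("GENE%04d", seq_len(n_genes))
  set.seed(params$seed + 10L)
  causal <- sort(sample(universe, n_causal))
  cohort <- simulate_cohort(params)
  mutations <- simulate_mutations(cohort$burden, universe, params,
                                  preterm = setNames(cohort$trios$preterm,
                                                     cohort$trios$family_id),
                                  causal_genes = causal)
  annotation <- simulate_gene_annotation(universe, causal,
                                         seed = params$seed + 2L)
  # one term gathering most causal genes, plus unrelated terms
  set.seed(params$seed + 6L)
  term_map <- rbind(
    data.frame(term = "abnormal_nervous_system_development",
               gene = c(sample(causal, ceiling(n_causal * 0.6)),
                        sample(setdiff(universe, causal), 80)),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(1:5, function(i) {
      data.frame(term = sprintf("background_term_%d", i),
                 gene = sample(universe, 100), stringsAsFactors = FALSE)
    })))
  dels <- simulate_interval_sets(74, 400, 64 / 74, seed = params$seed + 4L,
                                 svtype = "deletion")
  dups <- simulate_interval_sets(57, 300, 56 / 57, seed = params$seed + 7L,
                                 svtype = "duplication")
  query <- rbind(dels$query, dups$query)
  reference <- rbind(dels$reference, dups$reference)
  truth <- rbind(dels$truth, dups$truth)
  cnv_pool <- sprintf("CNVGENE%04d", seq_len(2 * nrow(dels$query)))
  gene_coords <- simulate_gene_coords(dels$query, cnv_pool,
                                      seed = params$seed + 5L)
  novel_genes <- genes_in_regions(dels$truth[dels$truth$status == "novel", ],
                                  gene_coords, "novel")$genes
  expr_universe <- c(universe, cnv_pool)
  expression <- simulate_expression(expr_universe,
                                    biased_set = c(causal, novel_genes),
                                    seed = params$seed + 3L)
  bundle <- list(params = params, universe = universe, causal = causal,
                 trios = cohort$trios, burden = cohort$burden,
                 mutations = mutations, annotation = annotation,
                 term_map = term_map, expression = expression,
                 query = query, reference = reference, truth = truth,
                 gene_coords = gene_coords)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      trios = write_trios(cohort$trios, file.path(dir, "trios.tsv")),
      mutations = write_mutations(mutations, file.path(dir, "mutations.tsv")),
      genes = write_gene_annotations(annotation, file.path(dir, "genes.tsv")),
      terms = write_term_map(term_map, file.path(dir, "terms.tsv")),
      expression = write_expression(expression,
                                    file.path(dir, "expression.tsv")),
      query_bed = write_intervals(query, file.path(dir, "query.bed")),
      reference_bed = write_intervals(reference,
                                      file.path(dir, "reference.bed")),
      gene_coords = write_gene_coords(gene_coords,
                                      file.path(dir, "gene_coords.tsv")),
      truth = {
        write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        file.path(dir, "truth.tsv")
      })
    jsonlite::write_json(unclass(params), file.path(dir, "params.json"),
                         auto_unbox = TRUE, digits = NA)
    bundle$paths <- paths
  }
  bundle
}
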