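# End-to-end orchestration: burden -> gene sets -> CNV novelty -> expression
# propensity, over real inputs or the synthetic bundle, producing a single
# machine-readable run summary.

test_to_list <- function(t) {
  if (is.null(t)) return(NULL)
  list(method = t$method, statistic = t$statistic, p_value = t$p_value,
       n_group1 = t$n_group1, n_group2 = t$n_group2,
       extra = t$extra)
}

#' Run the full analysis pipeline
#'
#' Executes every stage for which inputs are available and records the rest as
#' skipped. With `config$simulate = TRUE` all inputs come from
#' [simulate_bundle()] at `config$seed`; mixing `simulate` with real input
#' paths is a contradiction and errors before execution. Analysis stages are
#' deterministic given inputs; randomness enters only through the simulator,
#' so re-running with the same seed yields an identical summary.
#'
#' @param config a [load_config()] configuration (or named list of overrides).
#' @return object of class `run_summary`: a nested list with the parameter
#'   echo, every test result, gene-set sizes and classification counts.
#' @export
run_all <- function(config = load_config()) {
  if (!inherits(config, "ptbdnm_config")) {
    config <- load_config(overrides = config)
  }
  path_keys <- c("trios", "mutations", "genes", "terms", "expression",
                 "query_bed", "reference_bed", "gene_coords", "timing")
  given <- path_keys[!is.na(unlist(config[path_keys]))]
  if (config$simulate && length(given)) {
    stop("contradictory config: simulate = true together with input path(s) ",
         paste(given, collapse = ", "))
  }
  inputs <- list()
  if (config$simulate) {
    bundle <- simulate_bundle(sim_params(seed = config$seed))
    inputs <- bundle[c("trios", "mutations", "annotation", "term_map",
                       "expression", "query", "reference", "gene_coords")]
    names(inputs) <- c("trios", "mutations", "genes", "terms", "expression",
                       "query_bed", "reference_bed", "gene_coords")
  } else {
    readers <- list(trios = function(p) read_trios(p, config$preterm_cutoff),
                    mutations = read_mutations,
                    genes = read_gene_annotations, terms = read_term_map,
                    expression = read_expression,
                    query_bed = read_intervals,
                    reference_bed = read_intervals,
                    gene_coords = read_gene_coords,
                    timing = read_timing_track)
    for (k in names(readers)) {
      if (!is.na(config[[k]])) inputs[[k]] <- readers[[k]](config[[k]])
    }
  }
  has <- function(...) all(c(...) %in% names(inputs))
  summary <- list(
    package = "ptbdnm",
    version = as.character(packageVersion("ptbdnm")),
    seed = config$seed,
    simulate = config$simulate,
    thresholds = list(preterm_cutoff = config$preterm_cutoff,
                      cadd_cutoff = config$cadd_cutoff,
                      coverage_threshold = config$coverage_threshold,
                      window = config$window,
                      top_load_fraction = config$top_load_fraction,
                      normalization = config$normalization),
    stages = list())

  ## --- burden stage -------------------------------------------------------
  if (has("trios", "mutations")) {
    trios <- inputs$trios
    burden <- count_burden(inputs$mutations, trios)
    grp <- ifelse(trios$preterm, "preterm", "term")
    corr <- burden_age_correlation(burden, trios$paternal_age)
    logit <- fit_preterm_logistic(trios, burden)
    res_pat <- residualize_burden(burden, trios$paternal_age)
    res_mat <- residualize_burden(burden, trios$maternal_age)
    extreme <- extreme_load_subset(burden, config$top_load_fraction)
    ext <- trios[trios$family_id %in% extreme, ]
    ext_grp <- ifelse(ext$preterm, "preterm", "term")
    extreme_tests <- if (length(unique(ext_grp)) == 2) {
      list(paternal_age = test_to_list(
             compare_groups(ext$paternal_age, ext_grp)),
           maternal_age = test_to_list(
             compare_groups(ext$maternal_age, ext_grp)))
    } else NULL
    timing <- NULL
    if (has("timing")) {
      tvals <- timing_context(inputs$mutations, inputs$timing, config$window)
      tgrp <- trios$preterm[match(inputs$mutations$subject_id,
                                  trios$family_id)]
      keep <- !is.na(tvals)
      timing <- test_to_list(compare_groups(
        tvals[keep], ifelse(tgrp[keep], "preterm", "term")))
    }
    summary$stages$burden <- list(
      status = "run",
      n_subjects = nrow(trios), n_preterm = sum(trios$preterm),
      n_term = sum(!trios$preterm),
      mean_burden_term = mean(burden[!trios$preterm]),
      mean_burden_preterm = mean(burden[trios$preterm]),
      paternal_age_r = corr$r, paternal_age_r_squared = corr$r_squared,
      raw_comparison = test_to_list(compare_groups(burden, grp)),
      residual_paternal_comparison = test_to_list(
        compare_groups(res_pat, grp)),
      residual_maternal_comparison = test_to_list(
        compare_groups(res_mat, grp)),
      logistic = list(coefficients = as.list(logit$coefficients),
                      p_values = as.list(logit$p_values)),
      extreme_load = list(n = length(extreme),
                          fraction = config$top_load_fraction,
                          age_tests = extreme_tests),
      stratified = {
        s <- stratified_burden(trios, burden,
                               term_cutoff = config$preterm_cutoff)
        lapply(seq_len(nrow(s)), function(i) as.list(s[i, ]))
      },
      timing_comparison = timing)
  } else {
    summary$stages$burden <- list(status = "skipped",
                                  reason = "missing trios or mutations")
  }

  ## --- gene-set stage -----------------------------------------------------
  sets <- NULL
  if (has("trios", "mutations")) {
    trios <- inputs$trios
    mt <- inputs$mutations
    pre_ids <- trios$family_id[trios$preterm]
    sets <- list(
      PTB = extract_gene_set(mt[mt$subject_id %in% pre_ids, ], "PTB",
                             config$cadd_cutoff),
      term = extract_gene_set(mt[!(mt$subject_id %in% pre_ids), ], "term",
                              config$cadd_cutoff))
  }
  if (!is.null(sets) && has("genes")) {
    ann <- inputs$genes
    intoler <- lapply(sets, function(s) {
      lapply(c(cnv = "cnv", del = "del", dup = "dup"), function(sc) {
        test_to_list(tryCatch(compare_intolerance(s, ann, sc),
                              error = function(e) NULL))
      })
    })
    pairwise <- test_to_list(tryCatch(
      compare_intolerance(sets$PTB, ann, "cnv", background = sets$term),
      error = function(e) NULL))
    viab <- lapply(sets, viability_composition, annotation = ann)
    viab_enr <- test_to_list(tryCatch(
      viability_enrichment(sets$PTB, sets$term, ann),
      error = function(e) NULL))
    pheno <- NULL
    if (has("terms")) {
      pe <- phenotype_enrichment(sets$PTB, inputs$terms,
                                 universe = ann$gene)
      pheno <- lapply(seq_len(nrow(pe)), function(i) as.list(pe[i, ]))
    }
    summary$stages$genesets <- list(
      status = "run",
      set_sizes = lapply(sets, function(s) length(s$genes)),
      deleterious_mutations = lapply(sets, function(s) s$n_mutations),
      nonsynonymous_mutations = lapply(sets, function(s) s$n_nonsynonymous),
      intolerance = intoler, intolerance_ptb_vs_term = pairwise,
      viability = viab, viability_enrichment = viab_enr,
      phenotype_enrichment = pheno)
  } else {
    summary$stages$genesets <- list(status = "skipped",
                                    reason = "missing mutations or genes")
  }

  ## --- CNV novelty stage --------------------------------------------------
  novel_genes <- shared_genes <- NULL
  if (has("query_bed", "reference_bed")) {
    cls <- classify_cnvrs(inputs$query_bed, inputs$reference_bed,
                          config$coverage_threshold)
    counts <- attr(cls, "counts")
    if (has("gene_coords")) {
      novel_genes <- genes_in_regions(cls[cls$status == "novel", ],
                                      inputs$gene_coords, "novel")
      shared_genes <- genes_in_regions(cls[cls$status == "shared", ],
                                       inputs$gene_coords, "shared")
    }
    summary$stages$cnv <- list(
      status = "run",
      counts = lapply(rownames(counts), function(tp) {
        list(svtype = tp, shared = unname(counts[tp, "shared"]),
             novel = unname(counts[tp, "novel"]))
      }),
      novel_region_genes = if (!is.null(novel_genes)) novel_genes$genes)
  } else {
    summary$stages$cnv <- list(status = "skipped",
                               reason = "missing query or reference intervals")
  }

  ## --- expression stage ---------------------------------------------------
  if (has("expression") && !is.null(sets)) {
    em <- inputs$expression
    norm <- normalize_stages(em, config$normalization)
    trajectories <- lapply(sets, function(s) {
      tr <- tryCatch(trajectory(s, norm), error = function(e) NULL)
      if (is.null(tr)) return(NULL)
      lapply(seq_len(nrow(tr)), function(i) as.list(tr[i, ]))
    })
    beta_cmp <- NULL
    if (!is.null(novel_genes) && length(novel_genes$genes) &&
        length(shared_genes$genes)) {
      bn <- beta_scores(novel_genes, em)
      bs <- beta_scores(shared_genes, em)
      if (nrow(bn) && nrow(bs)) {
        beta_cmp <- test_to_list(compare_beta(bn, bs))
      }
    } else {
      ba <- beta_scores(sets$PTB, em)
      bb <- beta_scores(sets$term, em)
      if (nrow(ba) && nrow(bb)) beta_cmp <- test_to_list(compare_beta(ba, bb))
    }
    summary$stages$expression <- list(
      status = "run", normalization = config$normalization,
      trajectories = trajectories,
      beta_comparison = beta_cmp)
  } else {
    summary$stages$expression <- list(status = "skipped",
                                      reason = "missing expression matrix")
  }
  structure(summary, class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("ptbdnm run summary (seed ", x$seed, ")\n", sep = "")
  for (st in names(x$stages)) {
    s <- x$stages[[st]]
    cat("  ", st, ": ", s$status, sep = "")
    if (st == "burden" && s$status == "run") {
      cat(sprintf(" | mean burden term %.2f / preterm %.2f, p = %.3g",
                  s$mean_burden_term, s$mean_burden_preterm,
                  s$raw_comparison$p_value))
    }
    if (st == "genesets" && s$status == "run") {
      cat(sprintf(" | %d PTB / %d term genes", s$set_sizes$PTB,
                  s$set_sizes$term))
    }
    cat("\n")
  }
  invisible(x)
}

#' Serialize a run summary to JSON
#'
#' @param summary a `run_summary`.
#' @param path output path, or `NULL` to return the JSON string.
#' @return the path (invisibly) or the JSON string.
#' @export
write_run_summary <- function(summary, path = NULL) {
  js <- jsonlite::toJSON(unclass(summary), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
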