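# Deleteriousness filtering and gene-set characterization: CNV-intolerance
# contrasts, mouse-knockout viability composition and enrichment, and
# phenotype-term over-representation with BH-FDR.

#' Is a mutation nonsynonymous?
#'
#' Nonsynonymous means missense, nonsense or frameshift.
#'
#' @param mutations mutation data.frame (or a character vector of consequence
#'   labels).
#' @return logical vector.
#' @export
is_nonsynonymous <- function(mutations) {
  cons <- if (is.data.frame(mutations)) mutations$consequence else mutations
  cons %in% NONSYNONYMOUS
}

#' Is a nonsynonymous mutation deleterious?
#'
#' Frameshift indels are automatically deleterious, regardless of (typically
#' absent) CADD scores. Missense and nonsense mutations are deleterious iff
#' their CADD phred score is strictly greater than `cadd_cutoff`; a missing
#' CADD score on a non-frameshift mutation is conservatively not deleterious.
#' Calling this on a mutation that is not nonsynonymous is an error.
#'
#' @param mutations mutation data.frame rows, all nonsynonymous.
#' @param cadd_cutoff CADD phred threshold (default 20, strict `>`).
#' @return logical vector.
#' @export
is_deleterious <- function(mutations, cadd_cutoff = 20) {
  if (!all(is_nonsynonymous(mutations))) {
    stop("is_deleterious is defined only for nonsynonymous mutations ",
         "(missense, nonsense, frameshift)")
  }
  cons <- mutations$consequence
  cadd <- mutations$cadd_phred
  cons == "frameshift" | (!is.na(cadd) & cadd > cadd_cutoff)
}

#' Extract the gene set hit by deleterious mutations
#'
#' Filters to nonsynonymous mutations, applies the CADD deleteriousness rule,
#' and collects the unique gene symbols. Deleterious mutations lacking a gene
#' symbol are counted but contribute no gene, so the set size never exceeds
#' the passing mutation count (two hits in one gene collapse to one member).
#'
#' @param mutations mutation data.frame for one cohort.
#' @param label cohort label (e.g. "PTB", "term", "GoNL").
#' @param cadd_cutoff CADD phred threshold (default 20).
#' @return object of class `gene_set`: list with `label`, `genes`,
#'   `n_mutations` (deleterious mutations), `n_nonsynonymous`,
#'   `n_without_gene`.
#' @export
extract_gene_set <- function(mutations, label, cadd_cutoff = 20) {
  ns <- mutations[is_nonsynonymous(mutations), , drop = FALSE]
  del <- ns[is_deleterious(ns, cadd_cutoff), , drop = FALSE]
  genes <- unique(del$gene[!is.na(del$gene)])
  structure(list(label = as.character(label), genes = sort(genes),
                 n_mutations = nrow(del), n_nonsynonymous = nrow(ns),
                 n_without_gene = sum(is.na(del$gene))),
            class = "gene_set")
}

#' Build a gene set directly from symbols
#' @param genes character vector of gene symbols.
#' @param label set label.
#' @return a `gene_set` object.
#' @export
gene_set <- function(genes, label) {
  genes <- unique(norm_gene(genes))
  genes <- genes[!is.na(genes)]
  structure(list(label = as.character(label), genes = sort(genes),
                 n_mutations = NA_integer_, n_nonsynonymous = NA_integer_,
                 n_without_gene = 0L),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$label, "': ", length(x$genes), " genes", sep = "")
  if (!is.na(x$n_mutations)) {
    cat(" from", x$n_mutations, "deleterious of", x$n_nonsynonymous,
        "nonsynonymous mutations")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

set_genes <- function(set) {
  if (inherits(set, "gene_set")) set$genes else norm_gene(set)
}

#' Compare intolerance scores of a gene set against a background
#'
#' Two-sided Wilcoxon rank-sum test of the set's intolerance scores against
#' background scores. With the default whole-annotation background, the set's
#' own genes are excluded from the background so the comparison is
#' set-vs-rest. Genes missing the requested score are dropped and counted.
#'
#' @param set a `gene_set` (or character vector of symbols).
#' @param annotation gene annotation data.frame.
#' @param score which intolerance score: `"cnv"`, `"del"` or `"dup"`.
#' @param background `NULL` for genome background (annotation minus set), or a
#'   second gene set / symbol vector.
#' @param alternative test sidedness for the set group (default two-sided).
#' @return a `dnm_test`; `extra` carries group medians and dropped-gene counts.
#' @export
compare_intolerance <- function(set, annotation,
                                score = c("cnv", "del", "dup"),
                                background = NULL,
                                alternative = "two.sided") {
  score <- match.arg(score)
  col <- paste0(score, "_intolerance")
  sg <- set_genes(set)
  ann_genes <- annotation$gene
  svals <- annotation[[col]][match(sg, ann_genes)]
  n_unannotated <- sum(is.na(svals))
  svals <- svals[!is.na(svals)]
  if (length(svals) < 2) {
    stop("fewer than 2 set genes have a ", col, " annotation")
  }
  if (is.null(background)) {
    bmask <- !(ann_genes %in% sg)
    bvals <- annotation[[col]][bmask]
  } else {
    bg <- set_genes(background)
    bvals <- annotation[[col]][match(bg, ann_genes)]
  }
  n_bg_dropped <- sum(is.na(bvals))
  bvals <- bvals[!is.na(bvals)]
  if (!length(bvals)) stop("background has no annotated genes")
  res <- wilcox_ranksum(svals, bvals, alternative = alternative)
  res$method <- paste0(res$method, " [", col, "]")
  res$extra <- c(res$extra,
                 list(median_set = median(svals),
                      median_background = median(bvals),
                      n_set_unannotated = n_unannotated,
                      n_background_unannotated = n_bg_dropped))
  res
}

#' Viability composition of a gene set
#'
#' Proportions of lethal, subviable and viable mouse-ortholog knockouts among
#' the set genes with a known viability class. Unknown genes are counted but
#' excluded from the denominator.
#'
#' @param set a `gene_set` or symbol vector.
#' @param annotation gene annotation data.frame.
#' @return list with `proportions` (named, sums to 1 when any class is known;
#'   all `NA` with `defined = FALSE` otherwise), `counts`, `n_unknown`,
#'   `defined`.
#' @export
viability_composition <- function(set, annotation) {
  sg <- set_genes(set)
  via <- annotation$viability[match(sg, annotation$gene)]
  via[is.na(via)] <- "unknown"
  known <- via[via != "unknown"]
  counts <- table(factor(known, levels = c("lethal", "subviable", "viable")))
  n_known <- length(known)
  props <- if (n_known > 0) as.numeric(counts) / n_known else
    rep(NA_real_, 3)
  list(proportions = setNames(props, names(counts)),
       counts = setNames(as.integer(counts), names(counts)),
       n_unknown = sum(via == "unknown"),
       defined = n_known > 0)
}

#' Essentiality enrichment between two gene sets
#'
#' Fisher's exact test (two-sided) on the 2x2 table of lethal vs viable gene
#' counts in the two sets; subviable and unknown genes are excluded. A margin
#' of the table that is entirely zero is an error.
#'
#' @param setA,setB gene sets (or symbol vectors).
#' @param annotation gene annotation data.frame.
#' @return a `dnm_test` with the odds ratio as statistic; `extra` carries the
#'   2x2 counts.
#' @export
viability_enrichment <- function(setA, setB, annotation) {
  count_lv <- function(set) {
    via <- annotation$viability[match(set_genes(set), annotation$gene)]
    c(lethal = sum(via == "lethal", na.rm = TRUE),
      viable = sum(via == "viable", na.rm = TRUE))
  }
  a <- count_lv(setA); b <- count_lv(setB)
  tab <- rbind(a, b)
  if (sum(tab[, "lethal"]) == 0) stop("degenerate table: lethal margin is zero")
  if (sum(tab[, "viable"]) == 0) stop("degenerate table: viable margin is zero")
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) {
    stop("degenerate table: a set has no lethal-or-viable annotated gene")
  }
  ft <- fisher.test(tab, alternative = "two.sided")
  test_result("fisher exact (lethal vs viable)",
              statistic = unname(ft$estimate), p_value = ft$p.value,
              n_group1 = sum(tab[1, ]), n_group2 = sum(tab[2, ]),
              extra = list(lethal_A = unname(a["lethal"]),
                           viable_A = unname(a["viable"]),
                           lethal_B = unname(b["lethal"]),
                           viable_B = unname(b["viable"])))
}

#' Phenotype-term over-representation with BH-FDR
#'
#' One-sided hypergeometric over-representation test of the gene set against
#' each phenotype term, Benjamini-Hochberg adjusted across the tested terms.
#' Terms with no set overlap are skipped (they cannot be over-represented).
#'
#' @param set a `gene_set` or symbol vector.
#' @param term_map data.frame with columns `term`, `gene`.
#' @param universe background gene universe; defaults to all genes in the map.
#' @return data.frame (term, term_size, set_size, overlap, p_value, fdr)
#'   sorted by p-value; zero rows if the set is disjoint from every term.
#' @export
phenotype_enrichment <- function(set, term_map, universe = NULL) {
  if (!nrow(term_map)) stop("empty term map")
  genes_map <- norm_gene(term_map$gene)
  if (is.null(universe)) universe <- unique(genes_map)
  universe <- unique(norm_gene(universe))
  sg <- intersect(set_genes(set), universe)
  mapped <- setdiff(intersect(set_genes(set), genes_map), universe)
  if (length(mapped)) {
    stop("universe must contain every set gene appearing in the term map")
  }
  N <- length(universe)
  n <- length(sg)
  terms <- split(genes_map, term_map$term)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(unique(terms[[tm]]), universe)
    k <- length(intersect(sg, tg))
    if (k == 0) return(NULL)
    K <- length(tg)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, term_size = K, set_size = n, overlap = k,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term = character(), term_size = integer(),
                      set_size = integer(), overlap = integer(),
                      p_value = numeric(), fdr = numeric()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
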