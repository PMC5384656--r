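# Domain containers: plain data.frames with validating constructors, plus a
# light S3 class for the staged expression matrix and for test results.

#' Normalize chromosome labels
#'
#' Strips an optional "chr" prefix so "chr1" and "1" compare equal. Matching
#' elsewhere in the package is done on the normalized label; the autosome set
#' is "1".."22".
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @export
norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

norm_gene <- function(gene) {
  out <- toupper(trimws(as.character(gene)))
  out[!nzchar(out)] <- NA_character_
  out
}

#' Construct a validated trio table
#'
#' One row per family: parental ages in years, gestational age in weeks, and
#' the derived preterm flag. The preterm flag is always derived as
#' `gestational_age < preterm_cutoff` (strictly), never supplied.
#'
#' @param family_id character vector of family/subject identifiers (unique).
#' @param paternal_age,maternal_age ages in years, must be positive.
#' @param gestational_age gestational age at delivery in weeks; values outside
#'   `[20, 45]` are rejected.
#' @param preterm_cutoff preterm threshold in weeks (default 37; births with
#'   gestational age strictly below it are preterm).
#' @return data.frame with columns `family_id`, `paternal_age`,
#'   `maternal_age`, `gestational_age`, `preterm`.
#' @export
trio_table <- function(family_id, paternal_age, maternal_age, gestational_age,
                       preterm_cutoff = 37) {
  family_id <- as.character(family_id)
  if (anyDuplicated(family_id)) {
    stop("duplicate family_id: ",
         paste(unique(family_id[duplicated(family_id)]), collapse = ", "))
  }
  paternal_age <- as.numeric(paternal_age)
  maternal_age <- as.numeric(maternal_age)
  gestational_age <- as.numeric(gestational_age)
  n <- length(family_id)
  if (length(paternal_age) != n || length(maternal_age) != n ||
      length(gestational_age) != n) {
    stop("trio fields must have equal length")
  }
  if (any(!is.finite(paternal_age)) || any(paternal_age <= 0)) {
    stop("paternal_age must be a positive number for every trio")
  }
  if (any(!is.finite(maternal_age)) || any(maternal_age <= 0)) {
    stop("maternal_age must be a positive number for every trio")
  }
  bad <- !is.finite(gestational_age) | gestational_age < 20 |
    gestational_age > 45
  if (any(bad)) {
    stop("gestational_age outside [20, 45] weeks for: ",
         paste(family_id[bad], collapse = ", "))
  }
  data.frame(family_id = family_id,
             paternal_age = paternal_age,
             maternal_age = maternal_age,
             gestational_age = gestational_age,
             preterm = gestational_age < preterm_cutoff,
             stringsAsFactors = FALSE)
}

#' Construct a validated de novo mutation table
#'
#' One row per variant call. Positions are 1-based (VCF convention). SNVs must
#' have single-base ref and alt; CADD phred scores, when present, must be
#' nonnegative. Unknown consequence labels degrade to `"other"` with a
#' warning so partially annotated inputs remain usable.
#'
#' @param subject_id subject identifiers (matching trio `family_id`).
#' @param chrom chromosome labels ("chr" prefix tolerated).
#' @param pos 1-based positions, integers >= 1.
#' @param ref,alt allele strings.
#' @param variant_class `"SNV"` or `"indel"`.
#' @param consequence one of `r paste(CONSEQUENCES, collapse = ", ")`;
#'   anything else maps to `"other"`.
#' @param cadd_phred nonnegative CADD phred score or `NA`.
#' @param gene gene symbol or `NA`.
#' @param parental_origin `"paternal"`, `"maternal"` or `"unknown"`.
#' @return data.frame with the ten mutation columns.
#' @export
mutation_table <- function(subject_id, chrom, pos, ref, alt, variant_class,
                           consequence = "other", cadd_phred = NA_real_,
                           gene = NA_character_,
                           parental_origin = "unknown") {
  n <- length(subject_id)
  df <- data.frame(subject_id = as.character(subject_id),
                   chrom = norm_chrom(chrom),
                   pos = as.integer(pos),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   variant_class = as.character(variant_class),
                   consequence = rep_len(as.character(consequence), n),
                   cadd_phred = rep_len(as.numeric(cadd_phred), n),
                   gene = norm_gene(rep_len(gene, n)),
                   parental_origin = rep_len(as.character(parental_origin), n),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$pos)) || any(df$pos < 1L)) {
    stop("mutation positions must be integers >= 1 (1-based)")
  }
  cls <- c(SNV = "SNV", snv = "SNV", indel = "indel", INDEL = "indel")
  mapped <- cls[df$variant_class]
  if (anyNA(mapped)) {
    stop("unknown variant_class: ",
         paste(unique(df$variant_class[is.na(mapped)]), collapse = ", "))
  }
  df$variant_class <- unname(mapped)
  snv <- df$variant_class == "SNV"
  bad <- snv & (nchar(df$ref) != 1L | nchar(df$alt) != 1L)
  if (any(bad)) {
    stop("SNV with multi-base alleles at row(s): ",
         paste(which(bad), collapse = ", "))
  }
  unknown <- !(df$consequence %in% CONSEQUENCES) & !is.na(df$consequence)
  if (any(unknown)) {
    warning(sum(unknown), " mutation(s) with unrecognized consequence label ",
            "mapped to 'other': ",
            paste(unique(df$consequence[unknown]), collapse = ", "))
    df$consequence[unknown] <- "other"
  }
  df$consequence[is.na(df$consequence)] <- "other"
  if (any(df$cadd_phred < 0, na.rm = TRUE)) {
    stop("cadd_phred must be nonnegative when present")
  }
  po <- df$parental_origin
  po[is.na(po) | !(po %in% c("paternal", "maternal"))] <- "unknown"
  df$parental_origin <- po
  df
}

#' Construct a validated gene annotation table
#'
#' Per-gene copy-number intolerance scores (overall, deletion-specific and
#' duplication-specific; higher = less tolerated) and the viability class of
#' the homozygous mouse-ortholog knockout.
#'
#' @param gene gene symbols (deduplicated case-insensitively; duplicates error).
#' @param cnv_intolerance,del_intolerance,dup_intolerance unitless scores,
#'   `NA` permitted.
#' @param viability one of `"lethal"`, `"subviable"`, `"viable"`, `"unknown"`.
#' @return data.frame with one row per gene.
#' @export
gene_annotation <- function(gene, cnv_intolerance = NA_real_,
                            del_intolerance = NA_real_,
                            dup_intolerance = NA_real_,
                            viability = "unknown") {
  gene <- norm_gene(gene)
  if (anyNA(gene)) stop("gene symbols must be nonempty")
  if (anyDuplicated(gene)) {
    stop("duplicated gene symbols: ",
         paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  n <- length(gene)
  viability <- rep_len(as.character(viability), n)
  if (!all(viability %in% VIABILITY_CLASSES)) {
    stop("viability must be one of: ",
         paste(VIABILITY_CLASSES, collapse = ", "))
  }
  data.frame(gene = gene,
             cnv_intolerance = rep_len(as.numeric(cnv_intolerance), n),
             del_intolerance = rep_len(as.numeric(del_intolerance), n),
             dup_intolerance = rep_len(as.numeric(dup_intolerance), n),
             viability = viability,
             stringsAsFactors = FALSE)
}

#' Construct a typed genomic interval table
#'
#' Intervals are 0-based half-open `[start, end)` (BED convention) and typed
#' as deletion or duplication.
#'
#' @param chrom chromosome labels.
#' @param start,end 0-based half-open coordinates; `start < end` required.
#' @param svtype `"deletion"` or `"duplication"`.
#' @return data.frame with columns chrom, start, end, svtype.
#' @export
genomic_intervals <- function(chrom, start, end, svtype) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(!is.finite(start)) || any(!is.finite(end)) || any(start < 0)) {
    stop("interval coordinates must be nonnegative numbers")
  }
  bad <- start >= end
  if (any(bad)) {
    stop("interval start >= end at row(s): ", paste(which(bad), collapse = ", "))
  }
  svtype <- as.character(svtype)
  if (!all(svtype %in% c("deletion", "duplication"))) {
    stop("svtype must be 'deletion' or 'duplication'")
  }
  data.frame(chrom = norm_chrom(chrom), start = start, end = end,
             svtype = rep_len(svtype, length(start)),
             stringsAsFactors = FALSE)
}

#' Construct a replication timing track
#'
#' Piecewise-constant genome annotation: non-overlapping, sorted 0-based
#' half-open segments carrying a timing value.
#'
#' @param chrom,start,end segment coordinates (0-based half-open).
#' @param value replication timing value per segment.
#' @return data.frame sorted by chrom and start.
#' @export
replication_timing_track <- function(chrom, start, end, value) {
  df <- data.frame(chrom = norm_chrom(chrom), start = as.numeric(start),
                   end = as.numeric(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop("timing segments must satisfy 0 <= start < end")
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    seg <- df[df$chrom == ch, ]
    if (nrow(seg) > 1 && any(seg$start[-1] < seg$end[-nrow(seg)])) {
      stop("overlapping timing segments on chromosome ", ch)
    }
  }
  rownames(df) <- NULL
  df
}

#' Construct a staged expression matrix
#'
#' A gene-by-stage matrix of nonnegative expression values where each stage
#' column carries a developmental epoch tag: `early_fetal`, `later_fetal` or
#' `postnatal`. Both the early-fetal and postnatal epochs must be nonempty,
#' since the expression-propensity fold change is a ratio of those two epoch
#' means.
#'
#' @param values numeric matrix, genes in rows (rownames = symbols), stages in
#'   columns (colnames = stage labels).
#' @param epochs character vector, one epoch tag per column.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, epochs) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and stage colnames")
  }
  if (length(epochs) != ncol(values)) {
    stop("need one epoch tag per stage column")
  }
  epochs <- as.character(epochs)
  valid <- c("early_fetal", "later_fetal", "postnatal")
  if (!all(epochs %in% valid)) {
    stop("epoch tags must be one of: ", paste(valid, collapse = ", "))
  }
  if (!any(epochs == "early_fetal") || !any(epochs == "postnatal")) {
    stop("both the early_fetal and postnatal epochs must be nonempty")
  }
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  rownames(values) <- norm_gene(rownames(values))
  structure(list(values = values, epochs = epochs), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "stages\n")
  cat("  stages:", paste0(colnames(x$values), " [", x$epochs, "]",
                          collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Stage labels of an epoch
#' @param em an `expression_matrix`.
#' @param epoch epoch tag.
#' @return character vector of stage labels in that epoch.
#' @export
epoch_stages <- function(em, epoch) {
  stopifnot(inherits(em, "expression_matrix"))
  colnames(em$values)[em$epochs == epoch]
}

#' Build a hypothesis-test result record
#'
#' Carrier for every reported test statistic in the pipeline.
#'
#' @param method short method description.
#' @param statistic test statistic.
#' @param p_value p-value in `[0, 1]`.
#' @param n_group1,n_group2 group sizes.
#' @param extra optional named list of auxiliary summaries (medians, counts
#'   dropped, ...).
#' @return object of class `dnm_test`.
#' @export
test_result <- function(method, statistic, p_value, n_group1, n_group2,
                        extra = list()) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value outside [0, 1]")
  }
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value),
                 n_group1 = as.integer(n_group1),
                 n_group2 = as.integer(n_group2), extra = extra),
            class = "dnm_test")
}

#' @export
print.dnm_test <- function(x, ...) {
  cat(x$method, "\n  statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value, digits = 3),
      "  (n1 = ", x$n_group1, ", n2 = ", x$n_group2, ")\n", sep = "")
  if (length(x$extra)) {
    for (k in names(x$extra)) {
      v <- x$extra[[k]]
      if (is.atomic(v) && length(v) == 1) {
        cat("  ", k, " = ", format(v), "\n", sep = "")
      }
    }
  }
  invisible(x)
}
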