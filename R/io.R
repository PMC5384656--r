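# Readers and writers. Tabular inputs are TSV/CSV with a header; interval
# files are headerless BED-like TSV (0-based half-open). All writers emit TSV
# so write-then-read round-trips exactly.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return("\t")
  if (grepl("\t", first)) "\t" else ","
}

read_delim_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, quote = "", comment.char = "",
                   colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  df
}

# Convert a character column to numeric, reporting 1-based data line numbers
# (header = line 0) for values that fail to parse.
num_col <- function(df, col, path, allow_na = FALSE) {
  raw <- df[[col]]
  out <- suppressWarnings(as.numeric(raw))
  blank <- is.na(raw) | !nzchar(trimws(raw)) | toupper(trimws(raw)) == "NA"
  bad <- is.na(out) & !blank
  if (any(bad)) {
    stop("non-numeric value in column '", col, "' of ", basename(path),
         " at data line(s): ", paste(which(bad), collapse = ", "))
  }
  if (!allow_na && any(blank)) {
    stop("missing value in column '", col, "' of ", basename(path),
         " at data line(s): ", paste(which(blank), collapse = ", "))
  }
  out
}

#' Read a trio table
#'
#' Reads a tab- or comma-delimited file with columns `family_id`,
#' `paternal_age`, `maternal_age` and `gestational_age` (weeks), or
#' `gestational_age_days` (days, converted by /7). The preterm flag is always
#' derived from the gestational age, never read from the file.
#'
#' @param path input file.
#' @param preterm_cutoff preterm threshold in weeks (default 37).
#' @return validated trio data.frame (see [trio_table()]).
#' @export
read_trios <- function(path, preterm_cutoff = 37) {
  probe <- read_delim_checked(path, character())
  has_days <- "gestational_age_days" %in% names(probe)
  ga_col <- if (has_days) "gestational_age_days" else "gestational_age"
  df <- read_delim_checked(path, c("family_id", "paternal_age",
                                   "maternal_age", ga_col))
  ga <- num_col(df, ga_col, path)
  if (has_days) ga <- ga / 7
  trio_table(family_id = df$family_id,
             paternal_age = num_col(df, "paternal_age", path),
             maternal_age = num_col(df, "maternal_age", path),
             gestational_age = ga,
             preterm_cutoff = preterm_cutoff)
}

#' Write a trio table
#' @param trios trio data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly. The derived `preterm` column is not written.
#' @export
write_trios <- function(trios, path) {
  write.table(trios[TRIO_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a de novo mutation table
#'
#' Requires `subject_id`, `chrom`, `pos`, `ref`, `alt`, `variant_class`
#' columns; `consequence`, `cadd_phred`, `gene` and `parental_origin` are
#' optional (absent consequence becomes `"other"`, absent CADD becomes `NA`).
#' No filtering happens at read time.
#'
#' @param path input file (TSV or CSV with header).
#' @return validated mutation data.frame (see [mutation_table()]).
#' @export
read_mutations <- function(path) {
  df <- read_delim_checked(path, c("subject_id", "chrom", "pos", "ref", "alt",
                                   "variant_class"))
  n <- nrow(df)
  get_opt <- function(col, default) {
    if (col %in% names(df)) df[[col]] else rep(default, n)
  }
  mutation_table(subject_id = df$subject_id,
                 chrom = df$chrom,
                 pos = num_col(df, "pos", path),
                 ref = df$ref, alt = df$alt,
                 variant_class = df$variant_class,
                 consequence = get_opt("consequence", "other"),
                 cadd_phred = if ("cadd_phred" %in% names(df)) {
                   num_col(df, "cadd_phred", path, allow_na = TRUE)
                 } else rep(NA_real_, n),
                 gene = get_opt("gene", NA_character_),
                 parental_origin = get_opt("parental_origin", "unknown"))
}

#' Write a de novo mutation table
#' @param mutations mutation data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  write.table(mutations[MUTATION_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene annotation table
#'
#' Columns: `gene`, and optionally `cnv_intolerance`, `del_intolerance`,
#' `dup_intolerance`, `viability`.
#'
#' @param path input file.
#' @return validated annotation data.frame (see [gene_annotation()]).
#' @export
read_gene_annotations <- function(path) {
  df <- read_delim_checked(path, "gene")
  n <- nrow(df)
  score <- function(col) {
    if (col %in% names(df)) num_col(df, col, path, allow_na = TRUE)
    else rep(NA_real_, n)
  }
  gene_annotation(gene = df$gene,
                  cnv_intolerance = score("cnv_intolerance"),
                  del_intolerance = score("del_intolerance"),
                  dup_intolerance = score("dup_intolerance"),
                  viability = if ("viability" %in% names(df)) df$viability
                              else rep("unknown", n))
}

#' Write a gene annotation table
#' @param annotation annotation data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(annotation, path) {
  write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a phenotype term-to-gene map
#'
#' Two columns, `term` and `gene`; one row per (term, gene) membership.
#'
#' @param path input file.
#' @return data.frame with columns `term`, `gene`.
#' @export
read_term_map <- function(path) {
  df <- read_delim_checked(path, c("term", "gene"))
  data.frame(term = df$term, gene = norm_gene(df$gene),
             stringsAsFactors = FALSE)
}

#' Write a phenotype term-to-gene map
#' @param term_map data.frame with columns `term`, `gene`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_term_map <- function(term_map, path) {
  write.table(term_map[c("term", "gene")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a staged expression matrix
#'
#' First column `gene`; every other header cell is `stage:epoch`, e.g.
#' `PCW8-10:early_fetal`.
#'
#' @param path input TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path) {
  df <- read_delim_checked(path, "gene")
  stage_cols <- setdiff(names(df), "gene")
  if (!length(stage_cols)) stop("expression file has no stage columns")
  parts <- strsplit(stage_cols, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("expression header cells must be 'stage:epoch'")
  }
  vals <- vapply(stage_cols, function(cl) num_col(df, cl, path),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(df$gene, vapply(parts, `[`, "", 1)))
  expression_matrix(vals, vapply(parts, `[`, "", 2))
}

#' Write a staged expression matrix
#' @param em an `expression_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path) {
  stopifnot(inherits(em, "expression_matrix"))
  hdr <- paste(colnames(em$values), em$epochs, sep = ":")
  out <- data.frame(gene = rownames(em$values), em$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("gene", hdr)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default structural-variant type map
#'
#' Reference collections label deletions as "deletion" or "loss" and
#' duplications as "duplication" or "gain"; this map canonicalizes them.
#' @return named character vector raw label -> canonical svtype.
#' @export
default_svtype_map <- function() {
  c(deletion = "deletion", loss = "deletion",
    duplication = "duplication", gain = "duplication")
}

#' Read a BED-like interval file
#'
#' Headerless, tab-separated, 0-based half-open: chrom, start, end, type.
#' Rows whose type is not in `svtype_map` are dropped; the number dropped is
#' attached as attribute `n_dropped` (with a warning).
#'
#' @param path input BED-like file.
#' @param svtype_map named vector mapping raw type labels to
#'   deletion/duplication (see [default_svtype_map()]).
#' @return interval data.frame (see [genomic_intervals()]).
#' @export
read_intervals <- function(path, svtype_map = default_svtype_map()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "#",
                   colClasses = "character")
  if (ncol(df) < 4) stop("interval file needs 4 columns: chrom start end type")
  names(df)[1:4] <- c("chrom", "start", "end", "type")
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed coordinates in ", basename(path), " at line(s): ",
         paste(which(is.na(start) | is.na(end)), collapse = ", "))
  }
  svtype <- unname(svtype_map[tolower(df$type)])
  keep <- !is.na(svtype)
  n_dropped <- sum(!keep)
  if (n_dropped) {
    warning(n_dropped, " interval(s) with unmapped type dropped: ",
            paste(unique(df$type[!keep]), collapse = ", "))
  }
  bad <- keep & start >= end
  if (any(bad)) {
    stop("interval start >= end in ", basename(path), " at line(s): ",
         paste(which(bad), collapse = ", "))
  }
  out <- genomic_intervals(df$chrom[keep], start[keep], end[keep],
                           svtype[keep])
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write intervals as BED-like TSV
#' @param intervals interval data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  write.table(intervals[c("chrom", "start", "end", "svtype")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a replication timing track
#'
#' Headerless TSV: chrom, start, end, value (0-based half-open segments).
#' @param path input file.
#' @return timing track data.frame (see [replication_timing_track()]).
#' @export
read_timing_track <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("timing track needs 4 columns: chrom start end value")
  replication_timing_track(df[[1]], df[[2]], df[[3]], df[[4]])
}

#' Read a gene coordinate table
#'
#' Columns `gene`, `chrom`, `start`, `end` (0-based half-open), used to assign
#' genes to CNV regions.
#' @param path input file.
#' @return data.frame with normalized gene symbols and chrom labels.
#' @export
read_gene_coords <- function(path) {
  df <- read_delim_checked(path, c("gene", "chrom", "start", "end"))
  start <- num_col(df, "start", path)
  end <- num_col(df, "end", path)
  if (any(start < 0) || any(start >= end)) {
    stop("gene coordinates must satisfy 0 <= start < end")
  }
  data.frame(gene = norm_gene(df$gene), chrom = norm_chrom(df$chrom),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Write a gene coordinate table
#' @param coords data.frame with gene, chrom, start, end.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_coords <- function(coords, path) {
  write.table(coords[c("gene", "chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
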