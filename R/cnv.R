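# CNVR novelty classification against a reference collection (DGV-style).
# "Found in the reference" is read as coverage of the query's bases by the
# union of same-type, same-chromosome reference records, the only reading
# invariant to record order and fragmentation. Interval algebra is delegated
# to IRanges behind data.frame surfaces.

# 0-based half-open data.frame rows -> 1-based closed IRanges
to_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1, end = df$end)
}

#' Merge an interval collection into a disjoint union
#'
#' Unions same-chromosome, same-type intervals: overlapping and touching
#' (`[a,b)`, `[b,c)`) records are merged; output is sorted and pairwise
#' disjoint per chromosome and svtype.
#'
#' @param intervals interval data.frame (see [genomic_intervals()]).
#' @return interval data.frame of the merged union.
#' @export
merge_union <- function(intervals) {
  if (!nrow(intervals)) return(intervals)
  key <- paste(intervals$chrom, intervals$svtype, sep = "\r")
  parts <- lapply(split(intervals, key), function(grp) {
    red <- IRanges::reduce(to_iranges(grp))
    data.frame(chrom = grp$chrom[1],
               start = IRanges::start(red) - 1,
               end = IRanges::end(red),
               svtype = grp$svtype[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$chrom, out$svtype, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of a query interval covered by a reference union
#'
#' Covered query bases divided by query length. The reference should be the
#' pre-merged union for the query's chromosome and svtype (same-chromosome
#' rows of other types are ignored defensively).
#'
#' @param query single-row interval data.frame (or list with chrom, start,
#'   end, svtype).
#' @param reference interval data.frame of the (merged) reference collection.
#' @return coverage fraction in `[0, 1]`.
#' @export
coverage_fraction <- function(query, reference) {
  qlen <- query$end - query$start
  ref <- reference[reference$chrom == query$chrom &
                     reference$svtype == query$svtype, , drop = FALSE]
  if (!nrow(ref)) return(0)
  qi <- IRanges::IRanges(query$start + 1, query$end)
  ri <- IRanges::reduce(to_iranges(ref))
  covered <- sum(IRanges::width(IRanges::intersect(ri, qi)))
  covered / qlen
}

#' Classify CNV regions as shared or novel
#'
#' A query region is shared with the reference collection iff at least
#' `coverage_threshold` (default 0.8) of its bases are covered by the union of
#' same-type reference records; deletion queries are compared only against
#' reference deletions and duplications only against duplications. If the
#' reference has no record of a type present in the queries, all queries of
#' that type are novel (with a warning).
#'
#' @param queries interval data.frame of CNVRs to classify.
#' @param reference interval data.frame of the reference collection (merging
#'   is performed internally).
#' @param coverage_threshold shared iff coverage >= this fraction, in (0, 1].
#' @return data.frame: chrom, start, end, svtype, coverage_fraction, status;
#'   attribute `counts` holds shared/novel tallies per svtype.
#' @export
classify_cnvrs <- function(queries, reference, coverage_threshold = 0.8) {
  if (coverage_threshold <= 0 || coverage_threshold > 1) {
    stop("coverage_threshold must be in (0, 1]")
  }
  ref_union <- merge_union(reference)
  missing_types <- setdiff(unique(queries$svtype), unique(ref_union$svtype))
  if (length(missing_types)) {
    warning("reference has no intervals of type: ",
            paste(missing_types, collapse = ", "),
            "; all such queries are novel")
  }
  cov <- vapply(seq_len(nrow(queries)), function(i) {
    coverage_fraction(queries[i, ], ref_union)
  }, numeric(1))
  out <- queries
  out$coverage_fraction <- cov
  out$status <- ifelse(cov >= coverage_threshold, "shared", "novel")
  counts <- table(svtype = out$svtype, status = factor(out$status,
                                                       c("shared", "novel")))
  attr(out, "counts") <- counts
  out
}

#' Genes overlapping a set of regions
#'
#' A gene belongs to a region set if it overlaps any region by at least 1 bp
#' (half-open coordinates: a gene starting exactly at a region end does not
#' overlap). Genes spanning several regions are included once.
#'
#' @param regions interval data.frame (e.g. the novel rows of
#'   [classify_cnvrs()] output).
#' @param gene_coords data.frame with gene, chrom, start, end (0-based
#'   half-open; see [read_gene_coords()]).
#' @param label label for the resulting gene set.
#' @return a `gene_set`.
#' @export
genes_in_regions <- function(regions, gene_coords, label = "regions") {
  hits <- character(0)
  for (ch in unique(regions$chrom)) {
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    gen <- gene_coords[gene_coords$chrom == ch, , drop = FALSE]
    if (!nrow(gen)) next
    ov <- IRanges::findOverlaps(to_iranges(gen), to_iranges(reg),
                                minoverlap = 1L)
    hits <- c(hits, gen$gene[unique(S4Vectors::queryHits(ov))])
  }
  gene_set(hits, label)
}
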