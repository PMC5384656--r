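# Flat key:value run configuration. Not YAML proper: one `key: value` (or
# `key = value`) pair per line, '#' comments, no nesting. Every threshold the
# pipeline uses is a documented key with a documented default.

config_defaults <- function() {
  list(
    preterm_cutoff = 37,        # weeks; preterm iff gestational age < cutoff
    cadd_cutoff = 20,           # CADD phred; deleterious iff strictly greater
    coverage_threshold = 0.8,   # CNVR shared iff coverage fraction >= this
    window = 1000,              # bp, replication-timing window (even)
    top_load_fraction = 0.05,   # extreme-burden subset size
    normalization = "zscore",   # expression normalization: zscore | minmax
    seed = 1,
    simulate = FALSE,
    out_dir = NA_character_,
    # input paths (NA = stage skipped unless simulate = TRUE)
    trios = NA_character_, mutations = NA_character_,
    genes = NA_character_, terms = NA_character_,
    expression = NA_character_, query_bed = NA_character_,
    reference_bed = NA_character_, gene_coords = NA_character_,
    timing = NA_character_
  )
}

#' Load a run configuration
#'
#' Reads a flat `key: value` file and merges it over the documented defaults.
#' An empty (or absent) file yields all defaults. Unknown keys error, listing
#' the valid ones.
#'
#' Keys and defaults: `preterm_cutoff` (37 weeks), `cadd_cutoff` (20),
#' `coverage_threshold` (0.8, in (0, 1]), `window` (1000 bp),
#' `top_load_fraction` (0.05, in (0, 1)), `normalization`
#' ("zscore" or "minmax"), `seed` (1), `simulate` (false), `out_dir`, and
#' input paths `trios`, `mutations`, `genes`, `terms`, `expression`,
#' `query_bed`, `reference_bed`, `gene_coords`, `timing`.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @param overrides named list applied after the file (same validation).
#' @return named list of configuration values, class `ptbdnm_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$",
                                  ln))[[1]]
      if (length(m) != 3) stop("malformed config line: ", ln)
      kv[[m[2]]] <- trimws(m[3])
    }
  }
  for (k in names(overrides)) kv[[k]] <- overrides[[k]]
  bad <- setdiff(names(kv), names(cfg))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         "; valid keys: ", paste(names(cfg), collapse = ", "))
  }
  numeric_keys <- c("preterm_cutoff", "cadd_cutoff", "coverage_threshold",
                    "window", "top_load_fraction", "seed")
  for (k in names(kv)) {
    v <- kv[[k]]
    if (k %in% numeric_keys) {
      v <- suppressWarnings(as.numeric(v))
      if (is.na(v)) stop("config key '", k, "' must be numeric")
    } else if (k == "simulate") {
      v <- tolower(as.character(v)) %in% c("true", "1", "yes")
    } else {
      v <- as.character(v)
    }
    cfg[[k]] <- v
  }
  if (cfg$coverage_threshold <= 0 || cfg$coverage_threshold > 1) {
    stop("coverage_threshold must be a fraction in (0, 1]")
  }
  if (cfg$top_load_fraction <= 0 || cfg$top_load_fraction >= 1) {
    stop("top_load_fraction must be in (0, 1)")
  }
  if (cfg$window <= 0 || cfg$window %% 2 != 0) {
    stop("window must be a positive even number of base pairs")
  }
  if (!cfg$normalization %in% c("zscore", "minmax")) {
    stop("normalization must be 'zscore' or 'minmax'")
  }
  structure(cfg, class = "ptbdnm_config")
}
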