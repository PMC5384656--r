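# Domain types, readers/writers and run configuration.

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("trio reader derives the preterm flag and converts day units", {
  p <- write_tsv(data.frame(family_id = c("F1", "F2"),
                            paternal_age = c(33.9, 30),
                            maternal_age = c(31.7, 30),
                            gestational_age = c(33.1, 37.0)))
  tr <- read_trios(p)
  expect_equal(tr$preterm, c(TRUE, FALSE))     # 37.0 is not < 37
  expect_equal(tr$gestational_age, c(33.1, 37.0))

  pd <- write_tsv(data.frame(family_id = "F3", paternal_age = 30,
                             maternal_age = 30, gestational_age_days = 259))
  trd <- read_trios(pd)
  expect_equal(trd$gestational_age, 37.0)
  expect_false(trd$preterm)
})

test_that("trio reader rejects malformed input with informative errors", {
  p <- write_tsv(data.frame(family_id = "F1", paternal_age = 33,
                            gestational_age = 39))
  expect_error(read_trios(p), "maternal_age")

  p2 <- write_tsv(data.frame(family_id = c("F1", "F2"),
                             paternal_age = c("33", "abc"),
                             maternal_age = c(30, 30),
                             gestational_age = c(39, 40)))
  expect_error(read_trios(p2), "line.*2")

  p3 <- write_tsv(data.frame(family_id = "F1", paternal_age = 33,
                             maternal_age = 30, gestational_age = 50))
  expect_error(read_trios(p3), "gestational_age")
})

test_that("mutation reader preserves rows and handles optional columns", {
  df <- data.frame(subject_id = c("S1", "S1", "S2"), chrom = c("chr1", "2", "X"),
                   pos = c(100, 200, 300), ref = c("A", "C", "G"),
                   alt = c("T", "G", "A"), variant_class = "SNV")
  m <- read_mutations(write_tsv(df))
  expect_equal(nrow(m), 3)                      # count preservation
  expect_true(all(is.na(m$cadd_phred)))         # cadd column absent -> NA
  expect_true(all(m$consequence == "other"))
  expect_equal(m$parental_origin, rep("unknown", 3))

  df$ref[1] <- "AT"                             # SNV invariant violation
  expect_error(read_mutations(write_tsv(df)), "SNV")

  df$ref[1] <- "A"
  df$consequence <- c("missense", "stop_gained", "synonymous")
  expect_warning(m2 <- read_mutations(write_tsv(df)), "other")
  expect_equal(m2$consequence, c("missense", "other", "synonymous"))
})

test_that("interval reader canonicalizes svtypes and drops unmapped rows", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tloss", "chr1\t300\t400\tduplication",
               "chr2\t10\t20\tinversion"), p)
  expect_warning(iv <- read_intervals(p), "inversion")
  expect_equal(nrow(iv), 2)
  expect_equal(iv$svtype, c("deletion", "duplication"))
  expect_equal(attr(iv, "n_dropped"), 1)

  writeLines("chr1\t200\t100\tloss", p)
  expect_error(read_intervals(p), "start >= end")
})

test_that("write-then-read round-trips every record type exactly", {
  set.seed(42)
  tr <- trio_table(sprintf("F%02d", 1:8), runif(8, 25, 45), runif(8, 22, 40),
                   round(runif(8, 25, 42), 1))
  expect_equal(read_trios(write_trios(tr, tempfile())), tr)

  mt <- mutation_table(c("S1", "S2"), c("1", "chr2"), c(100L, 5000L),
                       c("A", "AT"), c("G", "A"), c("SNV", "indel"),
                       c("missense", "frameshift"), c(25.5, NA),
                       c("BRCA1", NA), c("paternal", "unknown"))
  expect_equal(read_mutations(write_mutations(mt, tempfile())), mt)

  ann <- gene_annotation(c("A1", "B2"), c(0.5, -1.2), c(1.1, 0),
                         c(NA, 2.2), c("lethal", "unknown"))
  expect_equal(read_gene_annotations(write_gene_annotations(ann, tempfile())),
               ann)

  em <- expression_matrix(matrix(c(1, 2, 3, 4), 2, 2,
                                 dimnames = list(c("G1", "G2"),
                                                 c("PCW8", "4mo"))),
                          c("early_fetal", "postnatal"))
  em2 <- read_expression(write_expression(em, tempfile()))
  expect_equal(em2$values, em$values)
  expect_equal(em2$epochs, em$epochs)

  iv <- genomic_intervals(c("1", "2"), c(0, 100), c(50, 400),
                          c("deletion", "duplication"))
  iv2 <- read_intervals(write_intervals(iv, tempfile()))
  expect_equal(iv2[names(iv)], iv, ignore_attr = TRUE)
})

test_that("preterm flag always equals gestational_age < cutoff after reads", {
  set.seed(7)
  ga <- round(runif(50, 22.7, 43), 1)
  tr <- trio_table(sprintf("F%02d", 1:50), rep(30, 50), rep(30, 50), ga)
  back <- read_trios(write_trios(tr, tempfile()))
  expect_equal(back$preterm, back$gestational_age < 37)
})

test_that("configuration defaults, overrides and validation behave", {
  empty <- tempfile()
  writeLines(character(0), empty)
  cfg <- load_config(empty)
  expect_equal(cfg$preterm_cutoff, 37)
  expect_equal(cfg$cadd_cutoff, 20)
  expect_equal(cfg$coverage_threshold, 0.8)
  expect_equal(cfg$window, 1000)
  expect_equal(cfg$top_load_fraction, 0.05)

  f <- tempfile()
  writeLines(c("# comment", "coverage_threshold: 0.9", "seed = 11"), f)
  cfg2 <- load_config(f)
  expect_equal(cfg2$coverage_threshold, 0.9)
  expect_equal(cfg2$seed, 11)

  writeLines("coverage_threshold: 1.5", f)
  expect_error(load_config(f), "coverage_threshold")

  writeLines("not_a_key: 3", f)
  expect_error(load_config(f), "valid keys")
})
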