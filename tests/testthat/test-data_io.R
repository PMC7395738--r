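test_that("expression matrix round-trips through TSV", {
  st <- random_study(3, 2, 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(st, path)
  back <- read_expression_matrix(path, case_ids = st$case_samples,
                                 control_ids = st$control_samples,
                                 study_id = st$study_id)
  expect_equal(back$genes, st$genes)
  expect_equal(back$samples, st$samples)
  expect_equal(unname(back$values), unname(st$values), tolerance = 1e-12)
})

test_that("duplicate gene rows are collapsed by mean and symbols uppercased", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "tp53\t1\t2\t3\t4",
               "TP53\t3\t4\t5\t6",
               "BRCA1\t0\t0\t0\t0"), path)
  st <- read_expression_matrix(path, c("s1", "s2"), c("s3", "s4"), "dup")
  expect_equal(st$genes, c("TP53", "BRCA1"))
  expect_equal(unname(st$values["TP53", ]), c(2, 3, 4, 5))
})

test_that("expression reader enforces its error contracts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "A\t1\t2\t3\t4"), path)
  expect_error(read_expression_matrix(path, c("s1", "s9"), c("s3", "s4")), "s9")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "A\t1\toops"), bad)
  expect_error(read_expression_matrix(bad, "s1", "s2"), "row 1.*column 's2'")
})

test_that("GMT parsing handles terms, duplicates, empties and errors", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\ta\tb\tc",
               "T2\tdesc\td\te\te"), path)
  lib <- read_gmt(path)
  expect_length(lib$terms, 2)
  expect_setequal(lib$terms$T2, c("D", "E"))  # set semantics
  expect_lte(length(lib$universe), 5)

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  lib0 <- read_gmt(empty)
  expect_length(lib0$terms, 0)
  expect_length(lib0$universe, 0)

  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\ta", "T2\tonly_two_fields"), bad)
  expect_error(read_gmt(bad), "line 2")

  blank <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\ta", "T2\tdesc\t\t"), blank)
  expect_warning(libb <- read_gmt(blank), "empty")
  expect_named(libb$terms, "T1")
})

test_that("GMT write/read round-trips", {
  lib <- gene_set_library(list(S1 = c("A", "B"), S2 = c("B", "C", "D")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(lib, path)
  back <- read_gmt(path)
  expect_equal(back$terms, lib$terms)
  expect_setequal(back$universe, lib$universe)
})

test_that("PPI reader deduplicates, drops self-loops, keeps isolated nodes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC"), path)
  net <- read_ppi(path)
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes, c("A", "B", "C"))

  tri <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tC", "C\tA"), tri)
  net_tri <- read_ppi(tri)
  expect_equal(nrow(net_tri$edges), 3)
  expect_length(net_tri$nodes, 3)

  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines("A pp B", sif)
  net_sif <- read_ppi(sif)
  expect_equal(net_sif$edges, data.frame(from = "A", to = "B",
                                         stringsAsFactors = FALSE))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "A\tB\tC\tD"), bad)
  expect_error(read_ppi(bad), "line 2")
})

test_that("PPI networks are always simple and undirected on noisy input", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 30
    syms <- sample(LETTERS[1:8], 2 * n, replace = TRUE)
    net <- ppi_network(matrix(syms, ncol = 2))
    expect_true(all(net$edges$from != net$edges$to))
    expect_true(all(net$edges$from <= net$edges$to))  # canonical order
    expect_false(any(duplicated(paste(net$edges$from, net$edges$to))))
    expect_true(all(c(net$edges$from, net$edges$to) %in% net$nodes))
  }
})

test_that("signature QC rejects shared samples and counts invalid symbols", {
  st <- random_study(100, 3, 3, seed = 5)
  valid <- st$genes[1:97]
  qc <- validate_signature_metadata(st, valid)
  expect_equal(qc$status, "accepted")
  expect_equal(qc$n_dropped, 3)
  expect_setequal(qc$invalid_symbols, st$genes[98:100])
  expect_length(qc$retained_genes, 97)

  clean <- validate_signature_metadata(st, st$genes)
  expect_equal(clean$status, "accepted")
  expect_equal(clean$n_dropped, 0)

  # forge an overlap between classes
  st2 <- st
  st2$control_samples <- c(st2$control_samples, st2$case_samples[2])
  class(st2) <- "ExpressionStudy"
  qc2 <- validate_signature_metadata(st2, st$genes)
  expect_equal(qc2$status, "rejected")
  expect_equal(qc2$overlapping_samples, st$case_samples[2])
})
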