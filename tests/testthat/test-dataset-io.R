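test_that("expression parser reads the documented format", {
  em <- read_expression_matrix(textConnection(tiny_expression()))
  expect_equal(em$probe_ids, c("g1", "g2", "g3"))
  expect_equal(unname(em$symbols), c("GENE1", "GENE2", "GENE3"))
  expect_equal(em$array_names, c("A1", "A2", "A3", "A4"))
  expect_equal(unname(em$values["g1", ]), c(1, 2, 3, 4))
  expect_true(is.na(em$values["g2", "A2"]))   # empty cell = missing
})

test_that("symbol column is optional and auto-detected", {
  txt <- expr_text("ID\tA1\tA2", "g1\t1.0\t2.0", "g2\t2e-1\tNA")
  em <- read_expression_matrix(textConnection(txt))
  expect_null(em$symbols)
  expect_equal(em$array_names, c("A1", "A2"))
  expect_equal(unname(em$values["g2", ]), c(0.2, NA))
  # explicit override: numeric-looking symbols
  txt2 <- expr_text("ID\tS\tA1\tA2", "g1\t12\t1\t2")
  em2 <- read_expression_matrix(textConnection(txt2), has_symbols = TRUE)
  expect_equal(unname(em2$symbols), "12")
})

test_that("expression format errors name the offending line", {
  dup <- expr_text("ID\tA1\tA2", "g1\t1\t2", "g1\t3\t4")
  expect_error(read_expression_matrix(textConnection(dup)), "line 3")
  short <- expr_text("ID\tS\tA1\tA2", "g1\tGENE1\t1.0")
  expect_error(read_expression_matrix(textConnection(short)), "fields")
  bad <- expr_text("ID\tA1\tA2", "g1\t1\tx2")
  expect_error(read_expression_matrix(textConnection(bad)), "non-numeric")
})

test_that("design parser reads rows and defaults to unpaired", {
  d <- read_design_table(textConnection(tiny_labels()))
  expect_false(d$paired)
  expect_equal(d$treatment, c("alpha", "alpha", "control", "control"))
  expect_equal(d$replicate, c(1L, 1L, 1L, 1L))
  expect_equal(d$time, c(0, 4, 0, 4))
  dp <- read_design_table(textConnection(tiny_labels(paired = TRUE)))
  expect_true(dp$paired)
})

test_that("design validation rejects malformed metadata", {
  bad_rep <- expr_text("Array\tA1\tA2", "Treatment\ta\tb",
                       "Replicate\t1.5\t1", "Time\t0\t0")
  expect_error(read_design_table(textConnection(bad_rep)), "integer")
  bad_time <- expr_text("Array\tA1\tA2", "Treatment\ta\tb",
                        "Replicate\t1\t1", "Time\t0\tzz")
  expect_error(read_design_table(textConnection(bad_time)), "time")
  bad_paired <- expr_text("Array\tA1\tA2", "Treatment\ta\tb",
                          "Replicate\t1\t1", "Time\t0\t0",
                          "Paired\tmaybe\t")
  expect_error(read_design_table(textConnection(bad_paired)), "yes")
  dup_triple <- expr_text("Array\tA1\tA2", "Treatment\ta\ta",
                          "Replicate\t1\t1", "Time\t0\t0")
  expect_error(read_design_table(textConnection(dup_triple)), "duplicate")
  mismatch <- expr_text("Array\tA1\tA2\tA3", "Treatment\ta\ta\tb",
                        "Replicate\t1\t2\t3", "Time\t0\t0\t0",
                        "Paired\tyes\t\t")
  expect_error(read_design_table(textConnection(mismatch)),
               "replicate numbers must match")
})

test_that("assembly joins files, logs on request, and checks array names", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "st_dataset")
  prof <- get_profile(ds, "g1", "alpha", 1)
  expect_equal(prof$times, c(0, 4))
  expect_equal(prof$values, c(1, 2))
  # missing cell omitted from profile
  prof2 <- get_profile(ds, "g2", "alpha", 1)
  expect_equal(prof2$times, 0)

  em <- read_expression_matrix(textConnection(
    expr_text("ID\tA1\tA2", "g1\t8\t2")))
  d <- read_design_table(textConnection(
    expr_text("Array\tA1\tA2", "Treatment\ta\ta",
              "Replicate\t1\t1", "Time\t0\t1")))
  ds2 <- assemble_dataset(em, d, apply_log2 = TRUE)
  expect_equal(unname(ds2$values["g1", ]), c(3, 1))   # log2(8), log2(2)

  em0 <- read_expression_matrix(textConnection(
    expr_text("ID\tA1\tA2", "g1\t0\t2")))
  expect_error(assemble_dataset(em0, d, apply_log2 = TRUE), "non-positive")

  d3 <- read_design_table(textConnection(
    expr_text("Array\tA1\tA3", "Treatment\ta\ta",
              "Replicate\t1\t1", "Time\t0\t1")))
  expect_error(assemble_dataset(em, d3), "A2.*A3|A3.*A2")
})

test_that("assembly is invariant to array column order", {
  ds1 <- tiny_dataset()
  reordered <- expr_text(
    "Array\tA3\tA1\tA4\tA2",
    "Treatment\tcontrol\talpha\tcontrol\talpha",
    "Replicate\t1\t1\t1\t1",
    "Time\t0\t0\t4\t4")
  ds2 <- assemble_dataset(
    read_expression_matrix(textConnection(tiny_expression())),
    read_design_table(textConnection(reordered)))
  for (p in ds1$probe_ids) for (trt in ds1$treatments) {
    p1 <- get_profile(ds1, p, trt, 1)
    p2 <- get_profile(ds2, p, trt, 1)
    expect_equal(p1, p2)
  }
})

test_that("write/parse round-trips preserve matrices including missing", {
  em <- read_expression_matrix(textConnection(tiny_expression()))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(em, f)
  em2 <- read_expression_matrix(f)
  expect_equal(em2, em)
  d <- read_design_table(textConnection(tiny_labels(paired = TRUE)))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_design_table(d, f2)
  expect_equal(read_design_table(f2), d)
})

test_that("results TSV writer renders significant digits and rejects empties", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- data.frame(probe = "g1", p_value = 0.123456789)
  write_results_tsv(tab, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_equal(lines[1], "probe\tp_value")
  expect_equal(lines[2], "g1\t0.123457")
  expect_error(write_results_tsv(data.frame(), f), "non-empty")
})

test_that("CRLF line endings and trailing blank lines are tolerated", {
  txt <- paste0(gsub("\n", "\r\n", tiny_expression()), "\r\n\r\n")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, f, sep = "")
  em <- read_expression_matrix(f)
  expect_equal(em$probe_ids, c("g1", "g2", "g3"))
})
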