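test_that("delimited round-trip preserves values, ids and missing mask", {
  set.seed(11)
  v <- matrix(runif(12, -8, -4), nrow = 4,
              dimnames = list(sprintf("CL%02d", 1:4), c("a", "b", "c")))
  v[2, 3] <- NA
  resp <- drug_response_matrix(v)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(resp, path)
  back <- read_matrix(path, "response")
  expect_identical(dimnames(back$values), dimnames(resp$values))
  expect_identical(is.na(back$values), is.na(resp$values))
  expect_equal(back$values, resp$values)

  e <- expression_matrix(matrix(rnorm(12), nrow = 3,
                                dimnames = list(c("p1", "p2", "p3"),
                                                sprintf("CL%02d", 1:4))))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(e, path2)
  back2 <- read_matrix(path2, "expression")
  expect_equal(back2$values, e$values)
})

test_that("missing vocabulary and empty cells are masked, bad cells error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\td1\td2",
               "CL01\t-7.0\t",
               "CL02\tNA\t-6.0",
               "CL03\tn.s.\t-5.5"), path)
  m <- read_matrix(path, "response")
  expect_equal(sum(is.na(m$values)), 3L)
  expect_equal(m$values["CL02", "d2"], -6.0)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\td1", "CL01\t-7.0", "CL02\toops"), bad)
  expect_error(read_matrix(bad, "response"), "CL02")
})

test_that("GCT 1.2 input respects declared dimensions and keeps Description", {
  path <- withr::local_tempfile(fileext = ".gct")
  body <- c("#1.2", "5\t4",
            paste(c("Name", "Description", sprintf("CL%02d", 1:4)),
                  collapse = "\t"))
  set.seed(3)
  for (i in 1:5) {
    body <- c(body, paste(c(sprintf("probe%d", i), sprintf("GENE%d", i),
                            sprintf("%.3f", rnorm(4))), collapse = "\t"))
  }
  writeLines(body, path)
  e <- read_matrix(path, "expression")
  expect_s3_class(e, "expression_matrix")
  expect_equal(dim(e$values), c(5L, 4L))
  expect_equal(e$annotations$symbol, sprintf("GENE%d", 1:5))

  wrong <- withr::local_tempfile(fileext = ".gct")
  writeLines(c(body[1], "6\t4", body[-(1:2)]), wrong)
  expect_error(read_matrix(wrong, "expression"), "declares")
})

test_that("duplicate ids are a hard error naming the duplicate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\td1", "probeA\t1.0", "probeA\t2.0"), path)
  expect_error(read_matrix(path, "expression"), "probeA")
  expect_error(
    drug_response_matrix(matrix(-6, 2, 1,
                                dimnames = list(c("x", "x"), "d"))),
    "duplicate line id: x")
})

test_that("align_lines restricts to shared lines, reports drops, idempotent", {
  resp <- tiny_response(matrix(runif(10, -8, -4), nrow = 5))
  expr <- tiny_expression(matrix(rnorm(8), nrow = 2,
                                 dimnames = list(NULL, sprintf("CL%02d", 2:5))))
  pair <- align_lines(resp, expr)
  expect_equal(line_ids(pair$response), sprintf("CL%02d", 2:5))
  expect_equal(line_ids(pair$expression), sprintf("CL%02d", 2:5))
  expect_equal(pair$dropped$response, "CL01")
  expect_equal(pair$dropped$expression, character(0))

  again <- align_lines(pair$response, pair$expression)
  expect_equal(again$response$values, pair$response$values)
  expect_equal(again$expression$values, pair$expression$values)
  expect_length(unlist(again$dropped), 0L)

  disjoint <- tiny_expression(matrix(rnorm(6), nrow = 2,
                                     dimnames = list(NULL, c("X1", "X2", "X3"))))
  expect_error(align_lines(resp, disjoint), "fewer than 3 shared")
})

test_that("panel means match a direct per-group loop and stay in range", {
  labels <- rep(c("leukemia", "colon", "breast"), length.out = 9)
  set.seed(5)
  v <- matrix(runif(18, -8, -4), nrow = 9)
  v[1, 1] <- NA
  resp <- tiny_response(v, panel_labels = labels)
  out <- summarise_by_panel(resp)
  for (i in seq_len(nrow(out))) {
    lines <- which(labels == out$panel[i])
    vals <- resp$values[lines, out$compound[i]]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      expect_true(is.na(out$mean_log10ic50[i]))
      expect_equal(out$n_lines[i], 0L)
    } else {
      expect_equal(out$mean_log10ic50[i], sum(vals) / length(vals))
      expect_gte(out$mean_log10ic50[i], min(vals))
      expect_lte(out$mean_log10ic50[i], max(vals))
    }
  }
  # two-point mean example and all-missing panel
  r2 <- tiny_response(matrix(c(-7, -6, NA, NA), nrow = 2),
                      panel_labels = c("colon", "colon"))
  s2 <- summarise_by_panel(r2)
  expect_equal(s2$mean_log10ic50[s2$compound == "drug_1"], -6.5)
  expect_true(is.na(s2$mean_log10ic50[s2$compound == "drug_2"]))
  expect_equal(s2$n_lines[s2$compound == "drug_2"], 0L)
})
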