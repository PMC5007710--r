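test_that("perfect correlates head the standard and reverse lists", {
  set.seed(41)
  resp <- tiny_response(matrix(runif(12, -8, -4), nrow = 6,
                               dimnames = list(NULL, c("d1", "d2"))))
  y <- resp$values[, "d1"]
  v <- rbind(mirror = y, anti = -y,
             noise1 = rnorm(6), noise2 = rnorm(6))
  colnames(v) <- line_ids(resp)
  cmp <- run_compare(expression_matrix(v), resp, "d1")
  expect_equal(cmp$table$probe_id[1], "mirror")
  expect_equal(cmp$table$r[1], 1.0)
  expect_equal(cmp$table$rank[1], 1L)
  expect_equal(cmp$standard$probe_id[1], "mirror")
  expect_equal(cmp$reverse$probe_id[1], "anti")
  expect_equal(cmp$reverse$r[1], -1.0)
})

test_that("ranking equals a brute-force correlation-and-sort oracle", {
  set.seed(88)
  for (rep in 1:10) {
    resp <- tiny_response(matrix(runif(6, -8, -4), ncol = 1,
                                 dimnames = list(NULL, "d")))
    v <- matrix(rnorm(30), nrow = 5,
                dimnames = list(sprintf("P%d", 1:5), line_ids(resp)))
    cmp <- run_compare(expression_matrix(v), resp, "d", threshold = 0.3)
    y <- resp$values[, "d"]
    r_oracle <- vapply(rownames(v), function(p) naive_pearson(v[p, ], y),
                       numeric(1))
    ord <- order(-r_oracle, names(r_oracle))
    expect_equal(cmp$table$probe_id, names(r_oracle)[ord])
    expect_equal(cmp$table$r, unname(r_oracle[ord]), tolerance = 1e-12)
    expect_equal(cmp$table$rank, seq_len(5L))
  }
})

test_that("compare coefficients equal the shared kernel applied probe-wise", {
  cfg <- sim_config(n_background = 50, missing_rate = 0.05, seed = 3)
  resp <- suppressWarnings(simulate_response(cfg))
  ex <- simulate_expression(cfg, resp, "withanolide_1")$expression
  cmp <- run_compare(ex, resp, "withanolide_1")
  y <- resp$values[, "withanolide_1"]
  for (i in seq_len(nrow(cmp$table))) {
    k <- pearson_cor(ex$values[cmp$table$probe_id[i], ], y)
    expect_identical(cmp$table$r[i], k$r)
    expect_identical(cmp$table$p[i], k$p)
    expect_identical(cmp$table$n_pairs[i], k$n_pairs)
  }
})

test_that("negating the response swaps standard and reverse lists", {
  set.seed(19)
  resp <- tiny_response(matrix(runif(8, -8, -4), ncol = 1,
                               dimnames = list(NULL, "d")))
  v <- matrix(rnorm(64), nrow = 8,
              dimnames = list(sprintf("P%d", 1:8), line_ids(resp)))
  cmp <- run_compare(expression_matrix(v), resp, "d", threshold = 0.2)
  neg <- drug_response_matrix(-resp$values - 12)  # stay in plausible range
  cmp_neg <- run_compare(expression_matrix(v), neg, "d", threshold = 0.2)
  expect_setequal(cmp_neg$standard$probe_id, cmp$reverse$probe_id)
  expect_setequal(cmp_neg$reverse$probe_id, cmp$standard$probe_id)
  expect_equal(sort(cmp_neg$table$r), sort(-cmp$table$r), tolerance = 1e-12)
})

test_that("unscorable probes are excluded and reported, never scored 0", {
  resp <- tiny_response(matrix(c(-7, -6.5, -6, -5.5), ncol = 1,
                               dimnames = list(NULL, "d")))
  v <- rbind(const = rep(1, 4),
             sparse = c(1, NA, NA, NA),
             ok = c(0.3, -1, 2, 0.5))
  colnames(v) <- line_ids(resp)
  cmp <- run_compare(expression_matrix(v), resp, "d")
  expect_equal(nrow(cmp$table), 1L)
  expect_setequal(cmp$excluded$probe_id, c("const", "sparse"))
  expect_setequal(cmp$excluded$reason,
                  c("constant_input", "insufficient_pairs"))
  # nothing scorable at all is an error
  v2 <- v[c("const", "sparse"), , drop = FALSE]
  expect_error(run_compare(expression_matrix(v2), resp, "d"),
               "no probe passes")
  expect_error(run_compare(expression_matrix(v), resp, "nope"),
               "unknown compound")
})

test_that("filter_candidates is monotone and hits trivial thresholds", {
  set.seed(55)
  resp <- tiny_response(matrix(runif(10, -8, -4), ncol = 1,
                               dimnames = list(NULL, "d")))
  v <- matrix(rnorm(200), nrow = 20,
              dimnames = list(sprintf("P%02d", 1:20), line_ids(resp)))
  cmp <- run_compare(expression_matrix(v), resp, "d", threshold = 0.5)
  at0 <- filter_candidates(cmp, 0)
  expect_setequal(candidate_ids(at0), at0$table$probe_id[at0$table$r != 0])
  expect_true(all(at0$table$list[at0$table$r > 0] == "standard"))
  at05 <- filter_candidates(cmp, 0.5)
  at07 <- filter_candidates(cmp, 0.7)
  expect_true(all(candidate_ids(at07) %in% candidate_ids(at05)))
  expect_true(all(abs(at05$standard$r) > 0.5))
  expect_error(filter_candidates(cmp, 1), "threshold")
  # threshold ~1 impossible bar: empty lists
  at099 <- filter_candidates(cmp, 0.999)
  expect_equal(nrow(at099$standard) + nrow(at099$reverse), 0L)
})

test_that("planted genes are recovered in the correct-signed list", {
  # spot check at one seed; the averaged version lives in the acceptance suite
  cfg <- sim_config(seed = 1234)
  resp <- suppressWarnings(simulate_response(cfg))
  sim <- simulate_expression(cfg, resp, "withanolide_1")
  cmp <- run_compare(sim$expression, resp, "withanolide_1")
  pos <- sim$truth$probe_id[sim$truth$sign == 1]
  neg <- sim$truth$probe_id[sim$truth$sign == -1]
  expect_gte(mean(pos %in% cmp$standard$probe_id), 0.8)
  expect_gte(mean(neg %in% cmp$reverse$probe_id), 0.8)
})
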