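#' COMPARE ranking of probes against a compound's potency profile
#'
#' Ranks every probe by the Pearson correlation of its expression profile
#' across the cell line panel with one compound's log10 IC50 vector,
#' pairwise-complete per probe, using the same kernel as
#' [pearson_cor()]. Positive coefficients are resistance-associated (high
#' expression in lines the compound inhibits least) and form the
#' *standard* list; negative coefficients are sensitivity-associated and
#' form the *reverse* list. Probes with fewer than `min_pairs` complete
#' pairs or constant expression are excluded from the ranking and reported
#' separately rather than scored r = 0, which would distort rank
#' statistics.
#'
#' @param expr an [expression_matrix()].
#' @param response a [drug_response_matrix()]; aligned on the fly via
#'   [align_lines()] when line sets differ.
#' @param compound compound id to rank against.
#' @param threshold |r| cut-off for candidate lists (default 0.6), applied
#'   symmetrically (`r > threshold` or `r < -threshold`).
#' @param min_pairs minimum complete pairs per probe (default 3).
#' @return An object of class `compare_result`: `table` (data frame with
#'   probe_id, symbol, genbank, r, p, n_pairs, rank, list), `standard` and
#'   `reverse` (the candidate sublists, descending / ascending r),
#'   `excluded` (unscored probes and why), plus `compound`, `threshold`,
#'   `min_pairs`.
#' @export
run_compare <- function(expr, response, compound, threshold = 0.6,
                        min_pairs = 3L) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(response, "drug_response_matrix"))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  if (!compound %in% compound_ids(response)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  if (!identical(line_ids(expr), line_ids(response))) {
    pair <- align_lines(response, expr)
    response <- pair$response
    expr <- pair$expression
  }
  y <- response$values[, compound]
  v <- expr$values
  n_probe <- nrow(v)
  r <- p <- rep(NA_real_, n_probe)
  np <- integer(n_probe)
  flag <- rep(NA_character_, n_probe)
  for (i in seq_len(n_probe)) {
    res <- pearson_cor(v[i, ], y, min_pairs = min_pairs)
    r[i] <- res$r
    p[i] <- res$p
    np[i] <- res$n_pairs
    flag[i] <- res$flag
  }
  ids <- rownames(v)
  ann <- expr$annotations[match(ids, expr$annotations$probe_id), ,
                          drop = FALSE]
  scored <- !is.na(r)
  if (!any(scored)) {
    stop("no probe passes min_pairs; COMPARE ranking undefined",
         call. = FALSE)
  }
  tab <- data.frame(probe_id = ids[scored],
                    symbol = ann$symbol[scored],
                    genbank = ann$genbank[scored],
                    r = r[scored], p = p[scored], n_pairs = np[scored],
                    stringsAsFactors = FALSE)
  # descending r, ties broken lexicographically by probe id
  ord <- order(-tab$r, tab$probe_id)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  excluded <- data.frame(probe_id = ids[!scored],
                         reason = flag[!scored],
                         n_pairs = np[!scored],
                         stringsAsFactors = FALSE)
  out <- structure(list(compound = compound, threshold = threshold,
                        min_pairs = as.integer(min_pairs),
                        table = tab, excluded = excluded),
                   class = "compare_result")
  filter_candidates(out, threshold)
}

#' Re-threshold the candidate lists of a COMPARE result
#'
#' Rebuilds the standard/reverse lists at a new |r| cut-off without
#' recomputing correlations. Monotone: a larger threshold always yields a
#' subset of a smaller one's lists.
#'
#' @param result a `compare_result`.
#' @param threshold new |r| cut-off in \[0, 1).
#' @return The `compare_result` with `threshold`, `table$list`, `standard`
#'   and `reverse` updated.
#' @export
filter_candidates <- function(result, threshold) {
  stopifnot(inherits(result, "compare_result"))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1)", call. = FALSE)
  }
  tab <- result$table
  tab$list <- ifelse(tab$r > threshold, "standard",
                     ifelse(tab$r < -threshold, "reverse", "none"))
  std <- tab[tab$list == "standard", , drop = FALSE]
  std <- std[order(-std$r, std$probe_id), , drop = FALSE]
  rev <- tab[tab$list == "reverse", , drop = FALSE]
  rev <- rev[order(rev$r, rev$probe_id), , drop = FALSE]
  rownames(std) <- rownames(rev) <- NULL
  result$threshold <- threshold
  result$table <- tab
  result$standard <- std
  result$reverse <- rev
  result
}

#' Build a COMPARE result from precomputed coefficients
#'
#' Wraps an existing vector of COMPARE coefficients (e.g. a published
#' candidate-gene table) as a `compare_result` so it can be re-thresholded
#' with [filter_candidates()]. p-values and pair counts are unknown and set
#' to `NA`.
#'
#' @param probe_id character vector of probe identifiers (made unique if
#'   duplicated, as published tables sometimes repeat "unknown").
#' @param r numeric vector of correlation coefficients in \[-1, 1\].
#' @param compound compound id the coefficients refer to.
#' @param threshold |r| cut-off for the candidate lists (default 0.6).
#' @return A `compare_result`.
#' @export
compare_from_coefficients <- function(probe_id, r, compound = "",
                                      threshold = 0.6) {
  stopifnot(length(probe_id) == length(r), all(abs(r) <= 1))
  probe_id <- make.unique(as.character(probe_id))
  tab <- data.frame(probe_id = probe_id, symbol = probe_id,
                    genbank = NA_character_, r = as.numeric(r),
                    p = NA_real_, n_pairs = NA_integer_,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r, tab$probe_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  out <- structure(list(compound = compound, threshold = threshold,
                        min_pairs = NA_integer_, table = tab,
                        excluded = data.frame(probe_id = character(),
                                              reason = character(),
                                              n_pairs = integer())),
                   class = "compare_result")
  filter_candidates(out, threshold)
}

#' Candidate probe ids of a COMPARE result
#'
#' @param result a `compare_result`.
#' @return Character vector: standard-list probes followed by reverse-list
#'   probes.
#' @export
candidate_ids <- function(result) {
  stopifnot(inherits(result, "compare_result"))
  c(result$standard$probe_id, result$reverse$probe_id)
}

#' @export
print.compare_result <- function(x, ...) {
  cat(sprintf("compare_result for %s: %d probes ranked (%d excluded), |r| > %.2f\n",
              x$compound, nrow(x$table), nrow(x$excluded), x$threshold))
  cat(sprintf("standard (resistance) list: %d probes; reverse (sensitivity) list: %d probes\n",
              nrow(x$standard), nrow(x$reverse)))
  if (nrow(x$standard)) {
    cat("top standard:\n")
    print(utils::head(x$standard[, c("probe_id", "symbol", "r", "p", "rank")], 5L))
  }
  if (nrow(x$reverse)) {
    cat("top reverse:\n")
    print(utils::head(x$reverse[, c("probe_id", "symbol", "r", "p", "rank")], 5L))
  }
  invisible(x)
}
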