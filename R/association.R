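#' Dichotomize cell lines into sensitive and resistant
#'
#' Splits the panel at a log10 IC50 cut-off: strictly below the cut-off is
#' sensitive, at or above is resistant (equality counts as resistant; the
#' sensitive class is strict), missing response is unclassified and excluded
#' downstream. When no cut-off is given, the median of the non-missing
#' values is used (midpoint convention for even counts).
#'
#' @param response a [drug_response_matrix()].
#' @param compound compound id.
#' @param cutoff optional log10 molar threshold; default: the median.
#' @return An object of class `sensitivity_partition`: `labels` (named
#'   factor with levels sensitive/resistant, `NA` = unclassified),
#'   `cutoff` (the value actually used), `compound`.
#' @export
dichotomize <- function(response, compound, cutoff = NULL) {
  stopifnot(inherits(response, "drug_response_matrix"))
  if (!compound %in% compound_ids(response)) {
    stop("unknown compound: ", compound, call. = FALSE)
  }
  y <- response$values[, compound]
  if (all(is.na(y))) {
    stop("all response values missing for ", compound, call. = FALSE)
  }
  if (is.null(cutoff)) cutoff <- stats::median(y, na.rm = TRUE)
  labels <- factor(ifelse(is.na(y), NA,
                          ifelse(y < cutoff, "sensitive", "resistant")),
                   levels = c("sensitive", "resistant"))
  names(labels) <- names(y)
  structure(list(labels = labels, cutoff = cutoff, compound = compound),
            class = "sensitivity_partition")
}

#' @export
print.sensitivity_partition <- function(x, ...) {
  tab <- table(x$labels, useNA = "ifany")
  cat(sprintf("sensitivity_partition for %s at cutoff %.3g log10 M:\n",
              x$compound, x$cutoff))
  print(tab)
  invisible(x)
}

#' Cluster-by-response contingency counts
#'
#' Tallies classified cell lines shared by a sensitivity partition and a
#' cluster assignment into a k x 2 table (clusters x
#' {sensitive, resistant}). Unclassified lines and lines absent from either
#' input are excluded and reported.
#'
#' @param partition a [dichotomize()] result.
#' @param assignment a [cut_tree()] result.
#' @return An object of class `contingency_table`: integer `counts` (k x
#'   2), `n_classified`, `excluded_lines`, `cutoff`, `compound`.
#' @export
contingency_counts <- function(partition, assignment) {
  stopifnot(inherits(partition, "sensitivity_partition"),
            inherits(assignment, "cluster_assignment"))
  classified <- names(partition$labels)[!is.na(partition$labels)]
  shared <- intersect(classified, names(assignment$labels))
  if (length(shared) == 0L) {
    stop("no classified cell line shared between partition and clustering",
         call. = FALSE)
  }
  excluded <- setdiff(union(names(partition$labels),
                            names(assignment$labels)), shared)
  cl <- factor(assignment$labels[shared], levels = seq_len(assignment$k))
  counts <- table(cluster = cl, response = partition$labels[shared])
  counts <- matrix(as.integer(counts), nrow = assignment$k,
                   dimnames = list(cluster = paste0("cluster", seq_len(assignment$k)),
                                   response = c("sensitive", "resistant")))
  structure(list(counts = counts, n_classified = length(shared),
                 excluded_lines = excluded, cutoff = partition$cutoff,
                 compound = partition$compound),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table: %d classified lines (%d excluded), cutoff %.3g\n",
              x$n_classified, length(x$excluded_lines), x$cutoff))
  print(x$counts)
  invisible(x)
}

#' Chi-squared test of a cluster-by-response table
#'
#' Pearson's chi-squared statistic: expected counts from the row and column
#' margins, statistic = sum (O - E)^2 / E with no continuity correction,
#' upper-tail p-value from the chi-squared distribution with
#' (rows - 1)(cols - 1) degrees of freedom. All-zero rows are dropped with
#' a warning (degrees of freedom adjust accordingly); cells with expected
#' count below 5 are flagged but the plain statistic is still reported —
#' that is the screening convention this analysis follows.
#'
#' @param counts a [contingency_counts()] result or a non-negative integer
#'   matrix.
#' @return An object of class `association_result`: `counts`, `expected`,
#'   `statistic`, `df`, `p_value`, `low_expected` (logical matrix of cells
#'   with E < 5), plus `cutoff`/`compound` when available.
#' @export
chi_square <- function(counts) {
  meta <- list(cutoff = NA_real_, compound = NA_character_)
  if (inherits(counts, "contingency_table")) {
    meta <- counts[c("cutoff", "compound")]
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  zero_row <- rowSums(counts) == 0
  if (any(zero_row)) {
    warning(sum(zero_row), " all-zero row(s) dropped; df adjusted",
            call. = FALSE)
    counts <- counts[!zero_row, , drop = FALSE]
  }
  zero_col <- colSums(counts) == 0
  if (any(zero_col)) {
    warning(sum(zero_col), " all-zero column(s) dropped; df adjusted",
            call. = FALSE)
    counts <- counts[, !zero_col, drop = FALSE]
  }
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop("degenerate table: need at least 2 non-empty rows and columns",
         call. = FALSE)
  }
  n <- sum(counts)
  if (n < 1) stop("empty table", call. = FALSE)
  expected <- outer(rowSums(counts), colSums(counts)) / n
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  p <- stats::pchisq(statistic, df = df, lower.tail = FALSE)
  structure(list(counts = counts, expected = expected,
                 statistic = statistic, df = df, p_value = p,
                 low_expected = expected < 5,
                 cutoff = meta$cutoff, compound = meta$compound),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association_result: chi-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (any(x$low_expected)) {
    cat(sprintf("note: %d cell(s) with expected count < 5\n",
                sum(x$low_expected)))
  }
  print(x$counts)
  invisible(x)
}
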