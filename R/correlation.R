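#' Pairwise-complete Pearson correlation with a t-based p-value
#'
#' The shared correlation kernel of the package: product-moment r over
#' complete observation pairs, two-sided p-value from the t distribution
#' with n - 2 degrees of freedom, and the screening-table significance
#' convention (significant iff p <= 0.05, otherwise reported "n.s.").
#' Pearson rather than rank correlation is used throughout because the
#' inputs (log10 IC50, expression) are interval-scaled, not equidistant
#' ranks.
#'
#' Fewer than `min_pairs` complete pairs, or a constant input, yields a
#' missing result (never r = 0) with the reason in `flag`.
#'
#' @param x,y numeric vectors of equal length; `NA` allowed.
#' @param min_pairs minimum complete pairs required (default 3).
#' @return A list of class `correlation_result` with elements `r`, `p`,
#'   `n_pairs`, `significant`, `flag` (`NA`, `"insufficient_pairs"` or
#'   `"constant_input"`).
#' @export
pearson_cor <- function(x, y, min_pairs = 3L) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_pairs) {
    return(cor_result(NA_real_, NA_real_, n, "insufficient_pairs"))
  }
  xs <- x[ok]
  ys <- y[ok]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    return(cor_result(NA_real_, NA_real_, n, "constant_input"))
  }
  r <- stats::cor(xs, ys)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  cor_result(r, p, n, NA_character_)
}

cor_result <- function(r, p, n, flag) {
  structure(list(r = r, p = p, n_pairs = as.integer(n),
                 significant = isTRUE(p <= 0.05), flag = flag),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (is.na(x$r)) {
    cat(sprintf("correlation_result: missing (%s), n = %d\n",
                x$flag, x$n_pairs))
  } else {
    cat(sprintf("correlation_result: r = %.3f, p = %.3g%s, n = %d\n",
                x$r, x$p, if (!x$significant) " (n.s.)" else "", x$n_pairs))
  }
  invisible(x)
}

#' Cross-resistance matrix of compound potency profiles
#'
#' Correlates the log10 IC50 profiles of every pair of compounds across the
#' cell line panel, pairwise-complete per pair. A pair is called
#' cross-resistant when |r| exceeds the threshold *and* p <= 0.05: cell
#' lines resistant to one compound then tend to resist the other.
#'
#' @param response a [drug_response_matrix()].
#' @param set_a,set_b compound id vectors (default: all compounds for
#'   both, giving the symmetric all-against-all grid).
#' @param threshold |r| cut-off for the cross-resistance call (default
#'   0.6).
#' @param min_pairs minimum complete pairs per cell (default 3).
#' @return An object of class `cross_resistance` with matrices `r`, `p`,
#'   `n_pairs` (set_a x set_b), logical `cross_resistant`, and the
#'   `threshold` used.
#' @export
cross_resistance <- function(response, set_a = NULL, set_b = NULL,
                             threshold = 0.6, min_pairs = 3L) {
  stopifnot(inherits(response, "drug_response_matrix"))
  all_ids <- compound_ids(response)
  if (is.null(set_a)) set_a <- all_ids
  if (is.null(set_b)) set_b <- all_ids
  unknown <- setdiff(c(set_a, set_b), all_ids)
  if (length(unknown)) {
    stop("unknown compound id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  dims <- list(set_a, set_b)
  r <- p <- matrix(NA_real_, length(set_a), length(set_b), dimnames = dims)
  n <- matrix(NA_integer_, length(set_a), length(set_b), dimnames = dims)
  for (a in set_a) {
    for (b in set_b) {
      res <- pearson_cor(response$values[, a], response$values[, b],
                         min_pairs = min_pairs)
      r[a, b] <- res$r
      p[a, b] <- res$p
      n[a, b] <- res$n_pairs
    }
  }
  flag <- !is.na(r) & abs(r) > threshold & !is.na(p) & p <= 0.05
  structure(list(r = r, p = p, n_pairs = n, cross_resistant = flag,
                 threshold = threshold, set_a = set_a, set_b = set_b),
            class = "cross_resistance")
}

#' Long-format view of a cross-resistance grid
#'
#' @param x a `cross_resistance` object.
#' @param ... unused.
#' @return Data frame with columns `compound_a`, `compound_b`, `r`, `p`,
#'   `n_pairs`, `cross_resistant`.
#' @export
as.data.frame.cross_resistance <- function(x, ...) {
  out <- expand.grid(compound_a = x$set_a, compound_b = x$set_b,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$r <- as.vector(x$r)
  out$p <- as.vector(x$p)
  out$n_pairs <- as.vector(x$n_pairs)
  out$cross_resistant <- as.vector(x$cross_resistant)
  out
}

#' Render a cross-resistance grid with "n.s." marks
#'
#' Formats r values to 3 decimals and replaces the p entries of
#' non-significant cells (p > 0.05) by `"n.s."`, the convention of
#' screening cross-resistance tables.
#'
#' @param x a `cross_resistance` object.
#' @return Character matrix of `r / p-or-n.s.` cells.
#' @export
format_cross_resistance <- function(x) {
  stopifnot(inherits(x, "cross_resistance"))
  fmt <- matrix("", nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  for (i in seq_len(nrow(x$r))) {
    for (j in seq_len(ncol(x$r))) {
      if (is.na(x$r[i, j])) {
        fmt[i, j] <- "NA"
      } else {
        ptxt <- if (!is.na(x$p[i, j]) && x$p[i, j] <= 0.05) {
          sprintf("%.3g", x$p[i, j])
        } else {
          "n.s."
        }
        fmt[i, j] <- sprintf("%.3f / %s", x$r[i, j], ptxt)
      }
    }
  }
  fmt
}

#' @export
print.cross_resistance <- function(x, ...) {
  cat(sprintf("cross_resistance: %d x %d compound pairs, |r| > %.2f & p <= 0.05 flagged\n",
              length(x$set_a), length(x$set_b), x$threshold))
  cat(sprintf("flagged cross-resistant: %d cells\n", sum(x$cross_resistant)))
  print(utils::head(format_cross_resistance(x),
                    n = min(8L, length(x$set_a))))
  invisible(x)
}
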