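#' Z-standardize the variables of a matrix
#'
#' Transforms each variable (row by default, matching the probes-by-lines
#' orientation of an expression submatrix) to mean 0 and variance 1 over
#' its non-missing entries, using the sample (n - 1) standard deviation.
#' Missing entries stay missing.
#'
#' @param x numeric matrix, possibly with `NA`.
#' @param margin 1 to standardize rows (default), 2 for columns.
#' @return Matrix of the same shape.
#' @export
standardize_matrix <- function(x, margin = 1L) {
  stopifnot(is.matrix(x), margin %in% c(1L, 2L))
  if (margin == 2L) return(t(standardize_matrix(t(x), 1L)))
  nm <- rownames(x)
  for (i in seq_len(nrow(x))) {
    v <- x[i, ]
    ok <- !is.na(v)
    if (sum(ok) < 2L) {
      stop("variable ", if (is.null(nm)) i else nm[i],
           " has fewer than 2 non-missing values", call. = FALSE)
    }
    s <- stats::sd(v[ok])
    if (s == 0) {
      stop("constant variable: ", if (is.null(nm)) i else nm[i],
           call. = FALSE)
    }
    x[i, ok] <- (v[ok] - mean(v[ok])) / s
  }
  x
}

#' Pairwise-available Euclidean distance between object profiles
#'
#' Euclidean distance over the coordinates both objects observe, rescaled
#' by `sqrt(m / m_shared)` where m is the total number of coordinates:
#' missing values are omitted and the magnitude corrected for the number
#' of data points actually available, degrading to the plain Euclidean
#' distance when nothing is missing. This is the rescaling
#' `stats::dist(method = "euclidean")` applies, which this function wraps.
#' Pairs sharing no coordinate get a missing distance, with a warning.
#'
#' @param x numeric matrix, rows = objects.
#' @return A `dist` object.
#' @export
profile_dist <- function(x) {
  stopifnot(is.matrix(x))
  d <- stats::dist(x, method = "euclidean")
  if (anyNA(d)) {
    warning("some object pairs share no non-missing coordinate; ",
            "their distance is missing", call. = FALSE)
  }
  d
}

#' Complete-linkage agglomerative clustering
#'
#' Agglomerates objects bottom-up with the complete-linkage rule: the
#' distance between two clusters is the maximum pairwise distance between
#' their members, so merge heights never decrease. Ties are broken
#' deterministically: among equal-distance merge candidates the pair whose
#' clusters contain the smallest (first, second) original object indices
#' merges first.
#'
#' @param x a numeric matrix (objects x variables; distances computed with
#'   [profile_dist()]) or a `dist` object.
#' @return An object of class `linkage_tree`: `merge` (hclust-style (n-1) x
#'   2 matrix, negative entries = leaves), `height`, `labels`,
#'   `method = "complete"`.
#' @export
complete_linkage <- function(x) {
  if (inherits(x, "dist")) {
    D <- as.matrix(x)
  } else {
    stopifnot(is.matrix(x))
    D <- as.matrix(profile_dist(x))
  }
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 objects", call. = FALSE)
  diag(D) <- NA_real_
  off <- D[upper.tri(D)]
  if (anyNA(off)) {
    stop("missing pairwise distance; impute values or remove the ",
         "offending rows before clustering", call. = FALSE)
  }
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- rep(TRUE, n)
  node <- -seq_len(n)     # hclust coding: negative = singleton leaf
  rep_min <- seq_len(n)   # smallest original member index per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  work <- D
  work[lower.tri(work, diag = TRUE)] <- NA_real_
  for (s in seq_len(n - 1L)) {
    dmin <- min(work, na.rm = TRUE)
    cand <- which(work == dmin, arr.ind = TRUE)
    # deterministic tie rule: lexicographically smallest
    # (min member index, max member index)
    key1 <- pmin(rep_min[cand[, 1L]], rep_min[cand[, 2L]])
    key2 <- pmax(rep_min[cand[, 1L]], rep_min[cand[, 2L]])
    pick <- order(key1, key2)[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]
    if (rep_min[j] < rep_min[i]) { tmp <- i; i <- j; j <- tmp }
    merge[s, ] <- c(node[i], node[j])
    height[s] <- dmin
    # Lance-Williams update for complete linkage: max of the two distances
    for (k in which(active)) {
      if (k == i || k == j) next
      dnew <- max(D[k, i], D[k, j])
      D[k, i] <- D[i, k] <- dnew
      work[min(k, i), max(k, i)] <- dnew
    }
    active[j] <- FALSE
    work[j, ] <- NA_real_
    work[, j] <- NA_real_
    node[i] <- s
    rep_min[i] <- min(rep_min[i], rep_min[j])
  }
  structure(list(merge = merge, height = height, labels = labels,
                 method = "complete"),
            class = "linkage_tree")
}

#' Convert a linkage tree to a base-R hclust object
#'
#' @param x a `linkage_tree`.
#' @param ... unused.
#' @return An `hclust` object (usable with [stats::cutree()], `plot()`,
#'   [ape::as.phylo()]).
#' @export
as.hclust.linkage_tree <- function(x, ...) {
  n <- length(x$labels)
  leaf_order <- function(node) {
    if (node < 0L) return(-node)
    c(leaf_order(x$merge[node, 1L]), leaf_order(x$merge[node, 2L]))
  }
  structure(list(merge = x$merge, height = x$height,
                 order = leaf_order(n - 1L), labels = x$labels,
                 method = x$method, dist.method = "euclidean",
                 call = match.call()),
            class = "hclust")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("linkage_tree (%s linkage): %d leaves, merge heights %.3g .. %.3g\n",
              x$method, length(x$labels), min(x$height), max(x$height)))
  invisible(x)
}

#' @export
plot.linkage_tree <- function(x, ...) {
  plot(as.hclust(x), ...)
}

#' Cut a linkage tree into k flat clusters
#'
#' Removes the k - 1 highest merges; clusters are numbered by order of
#' first leaf appearance in the input object order.
#'
#' @param tree a `linkage_tree`.
#' @param k number of clusters, between 1 and the leaf count.
#' @return An object of class `cluster_assignment`: `labels` (named integer
#'   vector in 1..k), `k`, `cut_height` (height of the lowest removed
#'   merge; `Inf` for k = 1).
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "linkage_tree"))
  n <- length(tree$labels)
  if (k < 1L || k > n) stop("k must lie in [1, ", n, "]", call. = FALSE)
  raw <- stats::cutree(as.hclust(tree), k = k)
  labels <- match(raw, unique(raw))  # number by first appearance
  names(labels) <- tree$labels
  cut_height <- if (k == 1L) Inf else tree$height[n - k + 1L]
  structure(list(labels = labels, k = as.integer(k),
                 cut_height = cut_height),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d leaves in %d clusters (sizes: %s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels, x$k), collapse = ", ")))
  invisible(x)
}

#' Export a linkage tree as Newick
#'
#' Branch lengths derive from merge heights via [ape::as.phylo()].
#'
#' @param tree a `linkage_tree`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "linkage_tree"))
  phy <- ape::as.phylo(as.hclust(tree))
  ape::write.tree(phy, file = path)
  invisible(path)
}
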