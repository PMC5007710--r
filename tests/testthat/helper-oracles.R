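# Independent oracles: deliberately naive implementations (explicit sums and
# loops, recomputation from scratch) kept free of the package's code paths.

# product-moment correlation over complete pairs, written out as sums
naive_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  sx <- 0; sy <- 0
  for (i in seq_len(n)) { sx <- sx + x[i]; sy <- sy + y[i] }
  mx <- sx / n; my <- sy / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# complete-linkage agglomeration recomputing every cluster-pair distance
# from the original matrix at every step (no Lance-Williams shortcut),
# with the same deterministic tie rule as the package: among equal-distance
# candidates merge the pair with the smallest (first, second) member indices.
brute_linkage <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  codes <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(members)) {
      for (b in seq_along(members)) {
        if (b <= a) next
        d_ab <- max(D[members[[a]], members[[b]], drop = FALSE])
        key <- c(d_ab,
                 min(members[[a]][1L], members[[b]][1L]),
                 max(members[[a]][1L], members[[b]][1L]))
        if (is.null(best) ||
            key[1L] < best$key[1L] - 1e-15 ||
            (abs(key[1L] - best$key[1L]) <= 1e-15 &&
             (key[2L] < best$key[2L] ||
              (key[2L] == best$key[2L] && key[3L] < best$key[3L])))) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    a <- best$a; b <- best$b
    if (members[[b]][1L] < members[[a]][1L]) { tmp <- a; a <- b; b <- tmp }
    merge[s, ] <- c(codes[a], codes[b])
    height[s] <- best$key[1L]
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    codes[a] <- s
    members[[b]] <- NULL
    codes <- codes[-b]
  }
  list(merge = merge, height = height)
}

# chi-squared statistic cell by cell with margins computed by loops
chi2_oracle <- function(counts) {
  counts <- as.matrix(counts)
  nr <- nrow(counts); nc <- ncol(counts)
  rs <- numeric(nr); cs <- numeric(nc); tot <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rs[i] <- rs[i] + counts[i, j]
    cs[j] <- cs[j] + counts[i, j]
    tot <- tot + counts[i, j]
  }
  stat <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    e <- rs[i] * cs[j] / tot
    stat <- stat + (counts[i, j] - e)^2 / e
  }
  stat
}

# small labelled response / expression fixtures
tiny_response <- function(values, panel_labels = NULL) {
  v <- as.matrix(values)
  if (is.null(rownames(v))) rownames(v) <- sprintf("CL%02d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("drug_%d", seq_len(ncol(v)))
  panel <- if (!is.null(panel_labels)) {
    cell_line_panel(rownames(v), panel_labels)
  }
  drug_response_matrix(v, panel = panel)
}

tiny_expression <- function(values) {
  v <- as.matrix(values)
  if (is.null(rownames(v))) rownames(v) <- sprintf("P%03d", seq_len(nrow(v)))
  if (is.null(colnames(v))) colnames(v) <- sprintf("CL%02d", seq_len(ncol(v)))
  expression_matrix(v)
}

# random distance matrix on n objects; integer-valued grids force ties
random_dist <- function(n, tied = FALSE) {
  if (tied) {
    x <- matrix(sample(0:3, n * 2, replace = TRUE), nrow = n)
  } else {
    x <- matrix(stats::rnorm(n * 3), nrow = n)
  }
  rownames(x) <- sprintf("O%02d", seq_len(n))
  stats::dist(x)
}
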