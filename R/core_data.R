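#' Cell line panel annotation
#'
#' Pairs each cell line identifier with the tumor-type panel it belongs to
#' (the NCI-60 screen spans 9 tumor types: leukemia, colon, breast, CNS,
#' lung, melanoma, ovarian, renal, prostate).
#'
#' @param line_ids character vector of unique, non-empty cell line
#'   identifiers.
#' @param panel_labels character vector of tumor-type labels, one per line.
#' @return A data frame of class `cell_line_panel` with columns `line_id`
#'   and `panel`.
#' @export
cell_line_panel <- function(line_ids, panel_labels) {
  line_ids <- as.character(line_ids)
  panel_labels <- as.character(panel_labels)
  if (length(line_ids) == 0L) {
    stop("panel needs at least one cell line", call. = FALSE)
  }
  if (anyDuplicated(line_ids)) {
    stop("duplicate line id: ", line_ids[duplicated(line_ids)][1L],
         call. = FALSE)
  }
  if (any(!nzchar(line_ids))) stop("empty line id", call. = FALSE)
  if (length(panel_labels) != length(line_ids)) {
    stop("every line needs exactly one panel label", call. = FALSE)
  }
  structure(data.frame(line_id = line_ids, panel = panel_labels,
                       stringsAsFactors = FALSE),
            class = c("cell_line_panel", "data.frame"))
}

#' Drug response matrix (log10 IC50)
#'
#' Cell lines by compounds grid of log10 IC50 values in log10 molar units
#' (more negative = more potent). `NA` entries mark missing screen results.
#' Values outside \[-10, -2\] trigger a warning: NCI-style screens dose
#' between 1e-8 and 1e-4 M, so values far outside that window usually mean
#' a unit mix-up.
#'
#' @param values numeric matrix, rows = cell lines (rownames = line ids),
#'   columns = compounds (colnames = compound ids).
#' @param panel optional [cell_line_panel()] covering all rows.
#' @return An object of class `drug_response_matrix` with elements `values`
#'   and `panel`.
#' @export
drug_response_matrix <- function(values, panel = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry line ids as rownames and compound ids as colnames",
         call. = FALSE)
  }
  check_unique_ids(rownames(values), "line")
  check_unique_ids(colnames(values), "compound")
  if (any(!is.na(values) & !is.finite(values))) {
    stop("non-missing response values must be finite", call. = FALSE)
  }
  rng <- if (all(is.na(values))) c(-6, -6) else range(values, na.rm = TRUE)
  if (rng[1L] < -10 || rng[2L] > -2) {
    warning("log10 IC50 values outside the expected [-10, -2] range; ",
            "check units (log10 molar expected)", call. = FALSE)
  }
  if (!is.null(panel)) {
    if (!inherits(panel, "cell_line_panel")) {
      panel <- cell_line_panel(panel$line_id, panel$panel)
    }
    if (!setequal(panel$line_id, rownames(values))) {
      stop("panel annotation does not cover exactly the matrix lines",
           call. = FALSE)
    }
    panel <- panel[match(rownames(values), panel$line_id), , drop = FALSE]
    rownames(panel) <- NULL
    class(panel) <- c("cell_line_panel", "data.frame")
  }
  structure(list(values = values, panel = panel),
            class = "drug_response_matrix")
}

#' Expression matrix with probe annotations
#'
#' Probes (or genes) by cell lines grid of continuous expression values on
#' the analysis scale, plus per-probe annotations (gene symbol, GenBank
#' accession, clone id) carried as pass-through metadata.
#'
#' @param values numeric matrix, rows = probes (rownames = probe ids),
#'   columns = cell lines (colnames = line ids).
#' @param annotations optional data frame with column `probe_id` and any of
#'   `symbol`, `genbank`, `clone_id`; missing columns are filled with `NA`.
#' @return An object of class `expression_matrix` with elements `values`
#'   and `annotations`.
#' @export
expression_matrix <- function(values, annotations = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry probe ids as rownames and line ids as colnames",
         call. = FALSE)
  }
  check_unique_ids(rownames(values), "probe")
  check_unique_ids(colnames(values), "line")
  if (any(!is.na(values) & !is.finite(values))) {
    stop("non-missing expression values must be finite", call. = FALSE)
  }
  ann <- data.frame(probe_id = rownames(values),
                    symbol = NA_character_,
                    genbank = NA_character_,
                    clone_id = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
    if (is.null(annotations$probe_id)) {
      stop("annotations need a probe_id column", call. = FALSE)
    }
    idx <- match(rownames(values), annotations$probe_id)
    for (col in c("symbol", "genbank", "clone_id")) {
      if (!is.null(annotations[[col]])) {
        ann[[col]] <- as.character(annotations[[col]])[idx]
      }
    }
  }
  rownames(ann) <- NULL
  structure(list(values = values, annotations = ann),
            class = "expression_matrix")
}

check_unique_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop("duplicate ", what, " id: ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("empty ", what, " id", call. = FALSE)
  invisible(ids)
}

#' @export
print.drug_response_matrix <- function(x, ...) {
  cat(sprintf("drug_response_matrix: %d cell lines x %d compounds (%d missing)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  if (!is.null(x$panel)) {
    cat("panels:", paste(unique(x$panel$panel), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d cell lines (%d missing)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Line, compound and probe identifiers
#'
#' @param x a `drug_response_matrix` or `expression_matrix`.
#' @return Character vector of identifiers.
#' @export
line_ids <- function(x) {
  if (inherits(x, "drug_response_matrix")) return(rownames(x$values))
  if (inherits(x, "expression_matrix")) return(colnames(x$values))
  stop("no line ids for this object", call. = FALSE)
}

#' @rdname line_ids
#' @export
compound_ids <- function(x) {
  stopifnot(inherits(x, "drug_response_matrix"))
  colnames(x$values)
}

#' @rdname line_ids
#' @export
probe_ids <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  rownames(x$values)
}

# Tokens accepted as missing in delimited input. Covers spreadsheet exports
# ("", NA, NaN) and the "n.s." marker screening tables print for
# non-significant / unavailable cells. Matched case-insensitively.
missing_tokens <- c("", "na", "nan", "n.s.")

parse_numeric_cells <- function(txt, row_ids, col_ids, path) {
  nr <- length(row_ids)
  nc <- length(col_ids)
  txt <- matrix(trimws(as.matrix(txt)), nrow = nr, ncol = nc)
  txt[is.na(txt)] <- ""  # cells read.delim already coerced to NA
  miss <- tolower(txt) %in% missing_tokens
  vals <- suppressWarnings(as.numeric(txt))
  bad <- matrix(!miss & is.na(vals), nrow = nr, ncol = nc)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 txt[bad][1L], row_ids[ij[1L]], col_ids[ij[2L]], path),
         call. = FALSE)
  }
  vals[miss] <- NA_real_
  matrix(vals, nrow = nr, ncol = nc, dimnames = list(row_ids, col_ids))
}

#' Read a response or expression matrix from delimited text
#'
#' Delimited text (TSV by default, CSV via `sep = ","`) with one header row
#' of column ids and one leading id column. Expression input may instead be
#' GCT 1.2 (`#1.2` version line, dimension line, `Name`/`Description`
#' columns); the `Description` column is kept as the probe symbol
#' annotation. Cells equal to `""`, `NA`, `NaN` or `n.s.`
#' (case-insensitive) are read as missing.
#'
#' @param path file path.
#' @param kind `"response"` for a line x compound log10 IC50 matrix,
#'   `"expression"` for a probe x line matrix.
#' @param sep field separator for delimited input (ignored for GCT).
#' @param panel optional [cell_line_panel()] to attach (response only).
#' @return A [drug_response_matrix()] or [expression_matrix()].
#' @export
read_matrix <- function(path, kind = c("response", "expression"),
                        sep = "\t", panel = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (kind == "expression" && startsWith(first, "#1.2")) {
    return(read_gct(path))
  }
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus data columns in ", path,
                          call. = FALSE)
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  check_unique_ids(row_ids, "row")
  check_unique_ids(col_ids, "column")
  vals <- parse_numeric_cells(df[, -1L, drop = FALSE], row_ids, col_ids, path)
  if (kind == "response") {
    drug_response_matrix(vals, panel = panel)
  } else {
    expression_matrix(vals)
  }
}

read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[1L], "#1.2")) {
    stop("not a GCT 1.2 file: ", path, call. = FALSE)
  }
  dims <- as.integer(strsplit(trimws(lines[2L]), "[\t ]+")[[1L]])
  if (length(dims) < 2L || anyNA(dims)) {
    stop("malformed GCT dimension line in ", path, call. = FALSE)
  }
  df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                          sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("GCT needs Name, Description and sample columns",
                          call. = FALSE)
  if (nrow(df) != dims[1L] || ncol(df) - 2L != dims[2L]) {
    stop(sprintf(
      "GCT declares %d probes x %d samples but file has %d x %d",
      dims[1L], dims[2L], nrow(df), ncol(df) - 2L), call. = FALSE)
  }
  probe_ids <- df[[1L]]
  check_unique_ids(probe_ids, "probe")
  samp_ids <- colnames(df)[-(1:2)]
  check_unique_ids(samp_ids, "line")
  vals <- parse_numeric_cells(df[, -(1:2), drop = FALSE],
                              probe_ids, samp_ids, path)
  expression_matrix(vals, annotations = data.frame(
    probe_id = probe_ids, symbol = df[[2L]], stringsAsFactors = FALSE))
}

#' Write a matrix object as delimited text
#'
#' One header row, leading `id` column; missing values written as `NA`.
#' Reading the file back with [read_matrix()] reproduces values, ids and
#' the missing mask exactly.
#'
#' @param x a `drug_response_matrix` or `expression_matrix`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = "\t") {
  stopifnot(inherits(x, c("drug_response_matrix", "expression_matrix")))
  v <- x$values
  df <- data.frame(id = rownames(v), as.data.frame(v, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a cell line panel annotation table
#'
#' Two-column delimited text: `line_id`, `panel`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return [read_panel()] returns a [cell_line_panel()]; [write_panel()]
#'   returns `path` invisibly.
#' @export
read_panel <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("line_id", "panel") %in% colnames(df))) {
    stop("panel table needs line_id and panel columns", call. = FALSE)
  }
  cell_line_panel(df$line_id, df$panel)
}

#' @rdname read_panel
#' @param panel a [cell_line_panel()].
#' @export
write_panel <- function(panel, path, sep = "\t") {
  utils::write.table(as.data.frame(panel), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Align a response matrix and an expression matrix on shared cell lines
#'
#' Restricts both matrices to the intersection of their line ids, in the
#' response matrix's order, and reports dropped lines. Aligning an
#' already-aligned pair is a no-op.
#'
#' @param response a [drug_response_matrix()].
#' @param expr an [expression_matrix()].
#' @return A list of class `aligned_pair` with elements `response`,
#'   `expression`, and `dropped` (a list of line ids dropped from each
#'   side).
#' @export
align_lines <- function(response, expr) {
  stopifnot(inherits(response, "drug_response_matrix"),
            inherits(expr, "expression_matrix"))
  r_lines <- line_ids(response)
  e_lines <- line_ids(expr)
  shared <- r_lines[r_lines %in% e_lines]
  if (length(shared) < 3L) {
    stop("fewer than 3 shared cell lines between response and expression",
         call. = FALSE)
  }
  dropped <- list(response = setdiff(r_lines, shared),
                  expression = setdiff(e_lines, shared))
  panel <- response$panel
  if (!is.null(panel)) {
    panel <- panel[panel$line_id %in% shared, , drop = FALSE]
    class(panel) <- c("cell_line_panel", "data.frame")
  }
  structure(list(
    response = drug_response_matrix(
      response$values[shared, , drop = FALSE], panel = panel),
    expression = expression_matrix(
      expr$values[, shared, drop = FALSE], annotations = expr$annotations),
    dropped = dropped
  ), class = "aligned_pair")
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("aligned_pair: %d shared cell lines (%d dropped from response, %d from expression)\n",
              nrow(x$response$values),
              length(x$dropped$response), length(x$dropped$expression)))
  invisible(x)
}

#' Mean log10 IC50 per tumor-type panel
#'
#' Arithmetic mean over non-missing values for every (panel, compound)
#' pair, the per-tumor-type potency summary of a screening campaign. Panels
#' with no usable value for a compound get a missing mean, never zero.
#'
#' @param response a [drug_response_matrix()] carrying a panel annotation.
#' @return A data frame with columns `panel`, `compound`,
#'   `mean_log10ic50`, `n_lines` (count of non-missing values behind each
#'   mean).
#' @export
summarise_by_panel <- function(response) {
  stopifnot(inherits(response, "drug_response_matrix"))
  if (is.null(response$panel)) {
    stop("response matrix carries no panel annotation", call. = FALSE)
  }
  panels <- unique(response$panel$panel)
  compounds <- compound_ids(response)
  out <- expand.grid(panel = panels, compound = compounds,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_log10ic50 <- NA_real_
  out$n_lines <- 0L
  for (i in seq_len(nrow(out))) {
    lines <- response$panel$line_id[response$panel$panel == out$panel[i]]
    v <- response$values[lines, out$compound[i]]
    v <- v[!is.na(v)]
    out$n_lines[i] <- length(v)
    if (length(v)) out$mean_log10ic50[i] <- mean(v)
  }
  out
}
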