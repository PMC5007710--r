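#' Predict drug response from expression-defined clusters
#'
#' The package's end-to-end procedure: (1) COMPARE-rank all probes against
#' the compound's log10 IC50 profile and keep candidates with |r| above the
#' threshold; (2) z-standardize the candidate genes and cluster the cell
#' lines by complete linkage on pairwise-available Euclidean distances;
#' (3) cut the dendrogram into k clusters; (4) dichotomize lines at the
#' (median) log10 IC50 cut-off; (5) cross-tabulate cluster membership
#' against sensitivity and test the association with the plain chi-squared
#' statistic. All intermediates are kept on the returned object.
#'
#' @param expr an [expression_matrix()].
#' @param response a [drug_response_matrix()].
#' @param compound compound id of interest.
#' @param threshold COMPARE |r| cut-off for candidate genes (default 0.6).
#' @param k number of flat clusters (default 4).
#' @param cutoff sensitivity cut-off in log10 molar; default: the median of
#'   the compound's non-missing values.
#' @param min_pairs minimum complete pairs for every correlation.
#' @return An object of class `response_association` with elements
#'   `compare`, `candidates`, `tree`, `assignment`, `partition`,
#'   `contingency`, `association`, and scalars `statistic`, `df`,
#'   `p_value`, `cutoff_used`, plus the call parameters.
#' @examples
#' cfg <- sim_config(n_background = 200, seed = 1)
#' resp <- simulate_response(cfg)
#' sim <- simulate_expression(cfg, resp, "withanolide_1")
#' fit <- predict_response(sim$expression, resp, "withanolide_1")
#' print(fit)
#' @export
predict_response <- function(expr, response, compound, threshold = 0.6,
                             k = 4L, cutoff = NULL, min_pairs = 3L) {
  pair <- align_lines(response, expr)
  response <- pair$response
  expr <- pair$expression
  cmp <- run_compare(expr, response, compound, threshold = threshold,
                     min_pairs = min_pairs)
  cand <- candidate_ids(cmp)
  if (length(cand) < 2L) {
    stop("expression profile undefined: fewer than 2 candidate genes at ",
         "|r| > ", threshold, call. = FALSE)
  }
  sub <- expr$values[cand, , drop = FALSE]
  z <- standardize_matrix(sub, margin = 1L)
  d <- profile_dist(t(z))
  tree <- complete_linkage(d)
  assignment <- cut_tree(tree, k)
  partition <- dichotomize(response, compound, cutoff = cutoff)
  ct <- contingency_counts(partition, assignment)
  assoc <- chi_square(ct)
  structure(list(compound = compound, threshold = threshold, k = as.integer(k),
                 cutoff_used = partition$cutoff, min_pairs = min_pairs,
                 compare = cmp, candidates = cand, tree = tree,
                 assignment = assignment, partition = partition,
                 contingency = ct, association = assoc,
                 statistic = assoc$statistic, df = assoc$df,
                 p_value = assoc$p_value),
            class = "response_association")
}

#' @export
print.response_association <- function(x, ...) {
  cat(sprintf("response_association for %s\n", x$compound))
  cat(sprintf("  candidate genes (|r| > %.2f): %d (%d standard, %d reverse)\n",
              x$threshold, length(x$candidates),
              nrow(x$compare$standard), nrow(x$compare$reverse)))
  cat(sprintf("  %d clusters x {sensitive, resistant} at cutoff %.3g log10 M\n",
              x$k, x$cutoff_used))
  cat(sprintf("  chi-squared = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @export
summary.response_association <- function(object, ...) {
  print(object)
  cat("\ncontingency table:\n")
  print(object$contingency$counts)
  cat("\ncluster sizes:", paste(tabulate(object$assignment$labels,
                                         object$assignment$k),
                                collapse = ", "), "\n")
  if (any(object$association$low_expected)) {
    cat("note: expected counts < 5 in",
        sum(object$association$low_expected), "cell(s)\n")
  }
  invisible(object)
}

#' @export
plot.response_association <- function(x, ...) {
  plot(as.hclust(x$tree),
       main = sprintf("Cell lines on %d candidate genes (%s)",
                      length(x$candidates), x$compound),
       xlab = "", sub = "", ...)
}

#' Run configuration for the full pipeline
#'
#' Exactly one of a set of input paths or a simulation configuration must
#' be given; all defaults are recorded in the JSON sidecar that
#' [run_all()] writes.
#'
#' @param response_path,expression_path,panel_path input files (delimited
#'   text; expression may be GCT 1.2). `panel_path` optional.
#' @param simulation a [sim_config()] used instead of input files.
#' @param compound compound of interest (default: first withanolide-family
#'   compound for simulated data; mandatory for file input).
#' @param threshold COMPARE |r| cut-off (default 0.6).
#' @param k cluster count (default 4).
#' @param cutoff sensitivity cut-off; `NULL` = median.
#' @param seed integer seed recorded in the sidecar (mandatory for
#'   simulated input, where it overrides the simulation seed only if the
#'   simulation config lacks one).
#' @param out_dir output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(response_path = NULL, expression_path = NULL,
                       panel_path = NULL, simulation = NULL,
                       compound = NULL, threshold = 0.6, k = 4L,
                       cutoff = NULL, seed = NULL, out_dir) {
  has_paths <- !is.null(response_path) || !is.null(expression_path)
  has_sim <- !is.null(simulation)
  if (has_paths == has_sim) {
    stop("provide exactly one of input paths or a simulation config",
         call. = FALSE)
  }
  if (has_paths && (is.null(response_path) || is.null(expression_path))) {
    stop("file input needs both response_path and expression_path",
         call. = FALSE)
  }
  if (has_paths && is.null(compound)) {
    stop("compound is mandatory for file input", call. = FALSE)
  }
  if (has_sim && !inherits(simulation, "sim_config")) {
    stop("simulation must be a sim_config", call. = FALSE)
  }
  if (missing(out_dir)) stop("out_dir is mandatory", call. = FALSE)
  structure(list(response_path = response_path,
                 expression_path = expression_path,
                 panel_path = panel_path, simulation = simulation,
                 compound = compound, threshold = threshold,
                 k = as.integer(k), cutoff = cutoff,
                 seed = if (has_sim) simulation$seed else seed,
                 out_dir = out_dir),
            class = "run_config")
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  path
}

#' Run the whole analysis and write a report bundle
#'
#' Executes panel summary, cross-resistance, COMPARE, clustering and the
#' response-association test in order, writing per-stage TSV tables, a
#' Newick dendrogram, an association JSON, and a JSON run-metadata sidecar
#' that suffices to re-run the pipeline identically. A stage failure writes
#' a `FAILED` marker naming the stage and re-raises the error; outputs of
#' completed stages are retained.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress and timing to stderr (default TRUE).
#' @return Invisibly, a list of class `report_bundle` with all stage
#'   results and the paths written.
#' @export
run_all <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  paths <- character()
  stage <- "load_inputs"
  result <- tryCatch({
    if (!is.null(config$simulation)) {
      stage_log(verbose, stage, "simulating data (seed %d)",
                config$simulation$seed)
      response <- simulate_response(config$simulation)
      compound <- config$compound
      if (is.null(compound)) compound <- compound_ids(response)[1L]
      sim <- simulate_expression(config$simulation, response, compound)
      expr <- sim$expression
      truth <- sim$truth
      paths["truth"] <- write_tsv(truth, out("truth_table.tsv"))
      paths["response_in"] <- write_matrix(response, out("response.tsv"))
      paths["expression_in"] <- write_matrix(expr, out("expression.tsv"))
      paths["panel"] <- write_panel(response$panel, out("panel.tsv"))
    } else {
      panel <- if (!is.null(config$panel_path)) {
        read_panel(config$panel_path)
      }
      response <- read_matrix(config$response_path, "response", panel = panel)
      expr <- read_matrix(config$expression_path, "expression")
      compound <- config$compound
      truth <- NULL
    }
    pair <- align_lines(response, expr)
    response <- pair$response
    expr <- pair$expression
    stage_log(verbose, stage, "%d lines x %d compounds; %d probes",
              nrow(response$values), ncol(response$values),
              nrow(expr$values))

    stage <- "summarise_by_panel"
    t0 <- proc.time()[3L]
    panel_summary <- if (!is.null(response$panel)) {
      summarise_by_panel(response)
    }
    if (!is.null(panel_summary)) {
      paths["panel_summary"] <- write_tsv(panel_summary,
                                          out("panel_summary.tsv"))
    }
    stage_log(verbose, stage, "done in %.2fs", proc.time()[3L] - t0)

    stage <- "cross_resistance"
    t0 <- proc.time()[3L]
    xres <- cross_resistance(response, threshold = config$threshold)
    paths["cross_resistance"] <- write_tsv(as.data.frame(xres),
                                           out("cross_resistance.tsv"))
    wide <- format_cross_resistance(xres)
    paths["cross_resistance_matrix"] <- write_tsv(
      data.frame(compound = rownames(wide), wide, check.names = FALSE),
      out("cross_resistance_matrix.tsv"))
    stage_log(verbose, stage, "%d flagged pairs in %.2fs",
              sum(xres$cross_resistant), proc.time()[3L] - t0)

    stage <- "predict_response"
    t0 <- proc.time()[3L]
    fit <- predict_response(expr, response, compound,
                            threshold = config$threshold, k = config$k,
                            cutoff = config$cutoff)
    paths["compare"] <- write_tsv(fit$compare$table, out("compare.tsv"))
    paths["merges"] <- write_tsv(
      data.frame(node_a = fit$tree$merge[, 1L],
                 node_b = fit$tree$merge[, 2L],
                 height = fit$tree$height),
      out("dendrogram_merges.tsv"))
    paths["newick"] <- write_newick(fit$tree, out("dendrogram.nwk"))
    paths["clusters"] <- write_tsv(
      data.frame(line_id = names(fit$assignment$labels),
                 cluster = unname(fit$assignment$labels)),
      out("clusters.tsv"))
    paths["partition"] <- write_tsv(
      data.frame(line_id = names(fit$partition$labels),
                 label = as.character(fit$partition$labels)),
      out("partition.tsv"))
    cont <- fit$contingency$counts
    paths["contingency"] <- write_tsv(
      data.frame(cluster = rownames(cont), cont, check.names = FALSE),
      out("contingency.tsv"))
    assoc <- list(compound = compound, chi2 = fit$statistic, df = fit$df,
                  p = fit$p_value, cutoff = fit$cutoff_used,
                  n_classified = fit$contingency$n_classified,
                  n_candidates = length(fit$candidates),
                  low_expected_cells = sum(fit$association$low_expected))
    paths["association"] <- out("association.json")
    jsonlite::write_json(assoc, paths["association"], auto_unbox = TRUE,
                         digits = NA)
    stage_log(verbose, stage, "chi2 = %.3f, p = %.3g in %.2fs",
              fit$statistic, fit$p_value, proc.time()[3L] - t0)

    stage <- "sidecar"
    sidecar <- list(
      inputs = list(response_path = config$response_path,
                    expression_path = config$expression_path,
                    panel_path = config$panel_path,
                    simulation = if (!is.null(config$simulation)) {
                      unclass(config$simulation)
                    }),
      parameters = list(compound = compound, threshold = config$threshold,
                        k = config$k,
                        cutoff = if (is.null(config$cutoff)) "median"
                                 else config$cutoff),
      seed = config$seed,
      versions = list(package = as.character(utils::packageVersion("compareScreen")),
                      r = R.version.string),
      outputs = as.list(paths))
    paths["sidecar"] <- out("run_metadata.json")
    jsonlite::write_json(sidecar, paths["sidecar"], auto_unbox = TRUE,
                         digits = NA)

    structure(list(response = response, expression = expr, truth = truth,
                   panel_summary = panel_summary, cross_resistance = xres,
                   fit = fit, paths = paths, config = config),
              class = "report_bundle")
  }, error = function(e) {
    marker <- out("FAILED")
    writeLines(sprintf("stage '%s' failed: %s", stage,
                       conditionMessage(e)), marker)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle written to", x$config$out_dir, "\n")
  print(x$fit)
  invisible(x)
}
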