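#' Configuration for the synthetic screening-data generator
#'
#' Describes an NCI-60-like study: ~60 cell lines in 9 tumor-type panels,
#' compound families sharing a latent cross-resistance factor, and an
#' expression matrix of independent background genes plus a small planted
#' set whose expression correlates (positively or negatively) with one
#' compound's log10 IC50 profile.
#'
#' The response model for compound d in family F on line c is
#' `log10IC50(c, d) = mu_d + lambda_F * f_c + eps`, with `f_c` a standard
#' normal latent sensitivity factor drawn once per line and family,
#' `eps ~ N(0, noise_sd_response^2)`, and `mu_d ~ U(-7.5, -4.5)` so values
#' center in the dosing window of a 1e-8 to 1e-4 M screen. The theoretical
#' within-family correlation is `lambda^2 / (lambda^2 + noise_sd^2)`.
#'
#' Defaults mirror the screen the package analyzes: a family of 8
#' withanolide-like compounds and one of 3 nitrosourea-like compounds, both
#' with within-family correlation 0.7, plus 8 unrelated compounds
#' (`lambda = 0`); 2000 background genes and 20 planted genes at
#' `|rho| = 0.8` (10 positive, 10 negative).
#'
#' @param n_lines number of cell lines (default 60).
#' @param n_panels number of tumor-type panels, assigned round-robin
#'   (default 9; names drawn from the NCI tumor types).
#' @param families data frame with columns `family`, `n_compounds`,
#'   `lambda` (latent factor loading, log10 units).
#' @param n_background number of background genes independent of response.
#' @param planted data frame with columns `sign` (+1 or -1) and `rho`
#'   (target correlation magnitude, in (0,1)); use `NULL` for none.
#' @param noise_sd_response residual SD of log10 IC50 (log10 units).
#' @param noise_sd_expression residual SD of planted-gene expression.
#' @param missing_rate fraction of cells masked at random, in \[0, 0.5\].
#' @param panel_shift additive log10 IC50 shift applied to the first panel
#'   (negative = more sensitive, mimicking leukemia-line sensitivity);
#'   default 0.
#' @param seed integer RNG seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 60L,
                       n_panels = 9L,
                       families = default_families(),
                       n_background = 2000L,
                       planted = default_planted(),
                       noise_sd_response = 0.5,
                       noise_sd_expression = 1,
                       missing_rate = 0,
                       panel_shift = 0,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  n_lines <- as.integer(n_lines)
  n_panels <- as.integer(n_panels)
  if (n_lines < 1L || n_panels < 1L) stop("counts must be >= 1", call. = FALSE)
  families <- as.data.frame(families, stringsAsFactors = FALSE)
  stopifnot(all(c("family", "n_compounds", "lambda") %in% colnames(families)))
  if (any(families$n_compounds < 1L)) {
    stop("each family needs at least one compound", call. = FALSE)
  }
  if (any(families$lambda^2 + noise_sd_response^2 <= 0)) {
    stop("lambda and response noise imply zero variance", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    stopifnot(all(c("sign", "rho") %in% colnames(planted)))
    if (!all(planted$sign %in% c(-1, 1))) {
      stop("planted sign must be +1 or -1", call. = FALSE)
    }
    if (any(planted$rho <= 0 | planted$rho >= 1)) {
      stop("planted rho must lie in (0, 1)", call. = FALSE)
    }
  }
  if (missing_rate < 0 || missing_rate > 0.5) {
    stop("missing_rate must lie in [0, 0.5]", call. = FALSE)
  }
  if (n_background < 0L) stop("n_background must be >= 0", call. = FALSE)
  structure(list(n_lines = n_lines, n_panels = n_panels,
                 families = families, n_background = as.integer(n_background),
                 planted = planted,
                 noise_sd_response = noise_sd_response,
                 noise_sd_expression = noise_sd_expression,
                 missing_rate = missing_rate, panel_shift = panel_shift,
                 seed = seed),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_families <- function() {
  # lambda for intraclass correlation 0.7 at residual SD 0.5:
  # lambda^2/(lambda^2 + 0.25) = 0.7  =>  lambda = 0.5*sqrt(7/3)
  lam <- 0.5 * sqrt(7 / 3)
  data.frame(family = c("withanolide", "nitrosourea", "unrelated"),
             n_compounds = c(8L, 3L, 8L),
             lambda = c(lam, lam, 0),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_planted <- function() {
  data.frame(sign = rep(c(1, -1), each = 10L), rho = 0.8)
}

nci_panel_names <- c("leukemia", "colon", "breast", "CNS", "lung",
                     "melanoma", "ovarian", "renal", "prostate")

panel_labels_for <- function(config) {
  nm <- if (config$n_panels <= length(nci_panel_names)) {
    nci_panel_names[seq_len(config$n_panels)]
  } else {
    sprintf("panel%02d", seq_len(config$n_panels))
  }
  nm[((seq_len(config$n_lines) - 1L) %% config$n_panels) + 1L]
}

#' Simulate a drug response matrix
#'
#' Draws log10 IC50 values from the latent-factor model described in
#' [sim_config()]. The same configuration (same seed) always yields a
#' bit-identical matrix. Missing entries are injected at
#' `config$missing_rate` using the same seed.
#'
#' @param config a [sim_config()].
#' @return A [drug_response_matrix()] with panel annotation.
#' @export
simulate_response <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_lines
  fam <- config$families
  line_id <- sprintf("CL%02d", seq_len(n))
  panel <- cell_line_panel(line_id, panel_labels_for(config))
  # one latent sensitivity factor per line per family
  f <- matrix(stats::rnorm(n * nrow(fam)), nrow = n,
              dimnames = list(line_id, fam$family))
  cols <- list()
  for (k in seq_len(nrow(fam))) {
    for (j in seq_len(fam$n_compounds[k])) {
      mu <- stats::runif(1L, -7.5, -4.5)
      eps <- stats::rnorm(n, sd = config$noise_sd_response)
      cols[[sprintf("%s_%d", fam$family[k], j)]] <-
        mu + fam$lambda[k] * f[, k] + eps
    }
  }
  v <- do.call(cbind, cols)
  rownames(v) <- line_id
  if (config$panel_shift != 0) {
    first <- panel$line_id[panel$panel == panel$panel[1L]]
    v[first, ] <- v[first, ] + config$panel_shift
  }
  out <- drug_response_matrix(v, panel = panel)
  if (config$missing_rate > 0) {
    out <- inject_missing(out, config$missing_rate, seed = config$seed)
  }
  out
}

#' Simulate an expression matrix with planted correlated genes
#'
#' Each planted gene g with sign s and target correlation rho gets
#' `expression(g, c) = s * a * y_c + e`, where y is the target compound's
#' standardized log10 IC50 vector, `e ~ N(0, noise_sd_expression^2)`, and
#' `a = rho * noise_sd_expression / sqrt(1 - rho^2)` so that
#' `cor(expression, y)` has expectation `s * rho`. Background genes are
#' independent standard normal. Probe order is shuffled so planted genes do
#' not sit in a block. Uses the RNG stream seeded with `config$seed + 1` so
#' expression draws never reuse the response stream.
#'
#' @param config a [sim_config()].
#' @param response a [drug_response_matrix()], typically from
#'   [simulate_response()].
#' @param target_compound compound id whose profile the planted genes track.
#' @return A list with elements `expression` (an [expression_matrix()]) and
#'   `truth` (data frame `probe_id`, `sign`, `rho` of planted genes).
#' @export
simulate_expression <- function(config, response, target_compound) {
  stopifnot(inherits(config, "sim_config"),
            inherits(response, "drug_response_matrix"))
  if (!target_compound %in% compound_ids(response)) {
    stop("unknown target compound: ", target_compound, call. = FALSE)
  }
  y <- response$values[, target_compound]
  if (mean(is.na(y)) > 0.5) {
    stop("target compound has more than 50% missing response", call. = FALSE)
  }
  set.seed(config$seed + 1L)
  n <- length(y)
  y0 <- y
  y0[!is.na(y)] <- scale(y[!is.na(y)])[, 1L]
  y0[is.na(y0)] <- 0  # no signal contribution for unscreened lines
  n_plant <- if (is.null(config$planted)) 0L else nrow(config$planted)
  n_bg <- config$n_background
  sde <- config$noise_sd_expression
  rows <- vector("list", n_plant + n_bg)
  ids <- character(n_plant + n_bg)
  if (n_plant > 0L) {
    for (g in seq_len(n_plant)) {
      rho <- config$planted$rho[g]
      a <- rho * sde / sqrt(1 - rho^2)
      rows[[g]] <- config$planted$sign[g] * a * y0 +
        stats::rnorm(n, sd = sde)
      ids[g] <- sprintf("PLT%03d", g)
    }
  }
  if (n_bg > 0L) {
    bg <- matrix(stats::rnorm(n_bg * n), nrow = n_bg)
    for (g in seq_len(n_bg)) rows[[n_plant + g]] <- bg[g, ]
    ids[n_plant + seq_len(n_bg)] <- sprintf("BKG%04d", seq_len(n_bg))
  }
  v <- do.call(rbind, rows)
  ord <- sample.int(nrow(v))
  v <- v[ord, , drop = FALSE]
  ids <- ids[ord]
  dimnames(v) <- list(ids, names(y))
  ann <- data.frame(probe_id = ids,
                    symbol = sub("^(PLT|BKG)", "GENE_\\1", ids),
                    genbank = sprintf("SYN%05d", seq_along(ids)),
                    clone_id = sprintf("GC%05d", seq_along(ids)),
                    stringsAsFactors = FALSE)
  expr <- expression_matrix(v, annotations = ann)
  if (config$missing_rate > 0) {
    expr <- inject_missing(expr, config$missing_rate,
                           seed = config$seed + 1L)
  }
  truth <- if (n_plant > 0L) {
    data.frame(probe_id = sprintf("PLT%03d", seq_len(n_plant)),
               sign = config$planted$sign, rho = config$planted$rho,
               stringsAsFactors = FALSE)
  } else {
    data.frame(probe_id = character(), sign = numeric(), rho = numeric())
  }
  list(expression = expr, truth = truth)
}

#' Mask matrix cells at random
#'
#' Independently masks each cell with the given probability; the same seed
#' always produces the same mask.
#'
#' @param x a [drug_response_matrix()], [expression_matrix()] or plain
#'   matrix.
#' @param rate masking probability in \[0, 0.5\].
#' @param seed integer RNG seed.
#' @return Object of the same class with masked entries set to `NA`.
#' @export
inject_missing <- function(x, rate, seed) {
  if (rate < 0 || rate > 0.5) stop("rate must lie in [0, 0.5]", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  v <- if (is.matrix(x)) x else x$values
  if (rate > 0) {
    set.seed(as.integer(seed))
    mask <- matrix(stats::runif(length(v)) < rate, nrow = nrow(v))
    v[mask] <- NA_real_
  }
  if (is.matrix(x)) return(v)
  x$values <- v
  x
}
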