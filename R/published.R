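#' Published COMPARE candidate-gene table for withaferin A diacetate
#'
#' The 40 probes whose constitutive mRNA expression across the NCI-60 panel
#' correlated with log10 IC50 values for withaferin A diacetate at
#' |r| > 0.6 in the published screen, with their COMPARE coefficients,
#' clone ids, GenBank accessions and the dendrogram cluster each probe fell
#' into. Shipped as a worked real-data input for re-thresholding with
#' [filter_candidates()]-style cut-offs; the underlying screening and
#' microarray data are not publicly deposited, so the coefficients
#' themselves cannot be recomputed here.
#'
#' @return Data frame with columns `symbol`, `compare_r`, `id_no`,
#'   `genbank`, `cluster`.
#' @export
withaferin_candidates <- function() {
  path <- system.file("extdata", "withaferin_candidates.tsv",
                      package = "compareScreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Published cluster-by-sensitivity contingency table
#'
#' The 4 x 2 table of NCI-60 cell lines cross-classified by dendrogram
#' cluster (complete-linkage clustering on the 40 candidate genes) and by
#' sensitivity to withaferin A diacetate at the median log10 IC50 cut-off
#' of -6.5 (sensitive strictly below, resistant at or above). 59 of the 60
#' lines are classified. Feeding this table to [chi_square()] reproduces
#' the published association (chi-squared = 14.71, df = 3, p = 0.00208).
#'
#' @return Integer matrix, 4 clusters x {sensitive, resistant}.
#' @export
withaferin_contingency <- function() {
  matrix(c(3L, 9L, 4L, 6L, 2L, 17L, 18L, 0L), nrow = 4L,
         dimnames = list(cluster = paste0("cluster", 1:4),
                         response = c("sensitive", "resistant")))
}
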