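#' Filter similarity hits by asymmetric coverage and e-value
#'
#' Applies the standard pre-clustering filter to an all-vs-all similarity
#' edge list: a hit is retained only if it covers at least `cov_long_min` of
#' the longer protein, at least `cov_short_min` of the shorter protein, and
#' has e-value at most `evalue_max`. Defaults are 20%/80% asymmetric
#' coverage and 1e-4.
#'
#' @param graph similarity edge tibble with columns `protein1`, `protein2`,
#'   `score`, `evalue`, `cov_long`, `cov_short`.
#' @param cov_long_min minimum coverage of the longer protein (default 0.2).
#' @param cov_short_min minimum coverage of the shorter protein (default 0.8).
#' @param evalue_max maximum e-value (default 1e-4).
#' @return the filtered edge tibble (self-score attribute preserved).
#' @export
filter_hits <- function(graph, cov_long_min = 0.2, cov_short_min = 0.8,
                        evalue_max = 1e-4) {
  need <- c("cov_long", "cov_short", "evalue")
  if (!all(need %in% names(graph))) {
    abort("`graph` is missing coverage or e-value columns")
  }
  if (anyNA(graph$cov_long) || anyNA(graph$cov_short)) {
    abort("coverage fields must be present on all edges")
  }
  out <- graph |>
    filter(.data$cov_long >= cov_long_min,
           .data$cov_short >= cov_short_min,
           .data$evalue <= evalue_max)
  new_similarity_graph(out, self_scores(graph))
}
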