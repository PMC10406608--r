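#' Full homologous-group construction pipeline
#'
#' Runs the complete clustering stage on a raw similarity edge list:
#' coverage/e-value filtering, Markov clustering, cluster-network
#' construction, pruning to the maximum diameter, and profile-based cluster
#' merging.
#'
#' @param graph raw similarity edge tibble.
#' @param nodes optional character vector of all proteins (isolated proteins
#'   become singleton HGs).
#' @param inflation MCL inflation (default 2).
#' @param cov_long_min,cov_short_min,evalue_max hit-filter thresholds (see
#'   [filter_hits()]).
#' @param criteria [merge_criteria()] controlling the merge stage and the
#'   diameter bound.
#' @param profile_scorer optional scorer for [merge_clusters()]; the default
#'   builds [similarity_profile_scorer()] from the filtered graph.
#' @return tibble `protein`, `hg`: the final homologous groups.
#' @export
#' @examples
#' part <- planted_partition(3, 6)
#' g <- simulate_similarity_graph(part, seed = 1)
#' hg <- cluster_proteins(g, nodes = part$protein)
cluster_proteins <- function(graph, nodes = NULL, inflation = 2,
                             cov_long_min = 0.2, cov_short_min = 0.8,
                             evalue_max = 1e-4,
                             criteria = merge_criteria(),
                             profile_scorer = NULL) {
  filtered <- filter_hits(graph, cov_long_min, cov_short_min, evalue_max)
  part <- mcl_cluster(filtered, inflation = inflation, nodes = nodes)
  cg <- build_cluster_network(part, filtered)
  cg <- prune_to_diameter(cg, criteria$max_diameter)
  merge_clusters(cg, part, profile_scorer = profile_scorer,
                 criteria = criteria, graph = filtered)
}
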