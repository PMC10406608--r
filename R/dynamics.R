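#' Rank homologous groups by copy-number dynamics along a node path
#'
#' For each HG, sums the relative net change in reconstructed copy number
#' along a root-to-descendant chain of species-tree nodes:
#' `sum over branches of (copies(child) - copies(parent)) /
#' max(copies(parent), 1)`. The denominator clamp means a family newly
#' gained on a branch contributes its copy count. The most positive scores
#' are the most dynamically expanding families, the most negative the most
#' contracting.
#'
#' @param em an [aggregate_events()] result.
#' @param node_path integer vector of species-tree node ids forming a
#'   parent-to-descendant chain (e.g. the 9 successive ancestors spanning 8
#'   branches from a clade's first ancestor to a derived MRCA).
#' @return tibble `family`, `score`, `rank_expanding`, `rank_contracting`,
#'   sorted by descending score. HGs absent along the whole path score 0.
#' @export
dynamics_rank <- function(em, node_path) {
  si <- tree_index(em$tree)
  node_path <- as.integer(node_path)
  if (length(node_path) < 2L) abort("`node_path` needs >= 2 nodes")
  for (k in 2:length(node_path)) {
    if (is.na(si$parent[node_path[k]]) ||
        si$parent[node_path[k]] != node_path[k - 1L]) {
      abort("`node_path` must be a parent-to-child chain in the species tree")
    }
  }
  fams <- unique(em$by_family$family)
  cp <- em$by_family |>
    filter(.data$node %in% node_path) |>
    select("family", "node", "copies")
  wide <- tidyr::complete(cp, family = fams, node = node_path,
                          fill = list(copies = 0L))
  scores <- wide |>
    arrange(.data$family, match(.data$node, node_path)) |>
    group_by(.data$family) |>
    summarise(
      score = sum((.data$copies[-1L] - .data$copies[-length(node_path)]) /
                    pmax(.data$copies[-length(node_path)], 1)),
      .groups = "drop"
    )
  scores |>
    arrange(desc(.data$score), .data$family) |>
    mutate(rank_expanding = row_number(),
           rank_contracting = rank(.data$score, ties.method = "first"))
}

#' Per-node transcription-factor repertoire table
#'
#' Sums reconstructed ancestral copy numbers of TF-classified HGs per TF
#' family and species-tree node, the input for repertoire-diversity
#' trajectories (see [shannon_diversity()]).
#'
#' @param em an [aggregate_events()] result.
#' @param tf_families named character vector HG -> TF family label (HGs not
#'   present are ignored).
#' @return tibble `node`, `tf_family`, `copies`.
#' @export
tfome_table <- function(em, tf_families) {
  em$by_family |>
    filter(.data$family %in% names(tf_families)) |>
    mutate(tf_family = unname(tf_families[.data$family])) |>
    group_by(.data$node, .data$tf_family) |>
    summarise(copies = sum(.data$copies), .groups = "drop")
}
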