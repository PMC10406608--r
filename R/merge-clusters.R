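#' Merge criteria for profile-based cluster merging
#'
#' The acceptance thresholds a surviving cluster pair must meet to be
#' merged: e-value at most `evalue_cutoff`, coverage at least
#' `coverage_profile` on the profile side and `coverage_consensus` on the
#' consensus side, and a match score of at least `self_match_fraction` of
#' the self-match score.
#'
#' @param evalue_cutoff maximum e-value (default 1e-10).
#' @param coverage_profile minimum profile-side coverage (default 0.75).
#' @param coverage_consensus minimum consensus-side coverage (default 0.20).
#' @param self_match_fraction minimum score as a fraction of the self-match
#'   (default 0.75).
#' @param max_diameter maximum cluster-network diameter used upstream
#'   (default 3), carried for configuration completeness.
#' @return a list of class `merge_criteria`.
#' @export
merge_criteria <- function(evalue_cutoff = 1e-10, coverage_profile = 0.75,
                           coverage_consensus = 0.20,
                           self_match_fraction = 0.75, max_diameter = 3) {
  fr <- c(coverage_profile, coverage_consensus, self_match_fraction)
  if (any(fr <= 0) || any(fr > 1)) abort("fractions must be in (0, 1]")
  if (max_diameter < 1) abort("`max_diameter` must be >= 1")
  structure(
    list(evalue_cutoff = evalue_cutoff, coverage_profile = coverage_profile,
         coverage_consensus = coverage_consensus,
         self_match_fraction = self_match_fraction,
         max_diameter = max_diameter),
    class = "merge_criteria"
  )
}

#' Merge clusters linked by strong profile matches
#'
#' For every edge of the (pruned) cluster network, a pluggable
#' `profile_scorer` compares the two clusters; pairs meeting all
#' [merge_criteria()] are merged, transitively (union-find over passing
#' edges), so the output is a coarsening of the input partition.
#'
#' `profile_scorer(hg1, hg2)` must return a list with elements `evalue`,
#' `cov_profile`, `cov_consensus`, `score`, `self_score`. A scorer failure
#' on a pair skips that pair with a warning.
#'
#' @param cg a `cluster_graph` (ideally after [prune_to_diameter()]).
#' @param partition tibble `protein`, `hg`.
#' @param profile_scorer pairwise cluster comparison function; default
#'   [similarity_profile_scorer()] built from `graph`.
#' @param criteria a [merge_criteria()] object.
#' @param graph similarity edge tibble, required only when the default
#'   scorer is used.
#' @return tibble `protein`, `hg` with merged, canonically relabelled ids.
#' @export
merge_clusters <- function(cg, partition, profile_scorer = NULL,
                           criteria = merge_criteria(), graph = NULL) {
  edges <- as_tibble(cg)
  if (is.null(profile_scorer)) {
    if (is.null(graph)) {
      abort("supply `graph` when using the default profile scorer")
    }
    profile_scorer <- similarity_profile_scorer(graph, partition)
  }
  hgs <- sort(unique(partition$hg))
  parent <- setNames(seq_along(hgs), hgs)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      s <- tryCatch(profile_scorer(edges$hg1[k], edges$hg2[k]),
                    error = function(e) {
                      warn(paste0("profile scorer failed on (", edges$hg1[k],
                                  ", ", edges$hg2[k], "): ",
                                  conditionMessage(e)))
                      NULL
                    })
      if (is.null(s)) next
      ok <- s$evalue <= criteria$evalue_cutoff &&
        s$cov_profile >= criteria$coverage_profile &&
        s$cov_consensus >= criteria$coverage_consensus &&
        s$score >= criteria$self_match_fraction * s$self_score
      if (ok) {
        ri <- find(match(edges$hg1[k], hgs))
        rj <- find(match(edges$hg2[k], hgs))
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_along(hgs), find, integer(1))
  canonical_partition(tibble(
    protein = partition$protein,
    cluster = roots[match(partition$hg, hgs)]
  ))
}

#' Desk-scale profile scorer from the similarity graph
#'
#' A stand-in for profile-vs-consensus scoring that works from the edge list
#' alone (it is not equivalent to a profile HMM search): for a cluster pair
#' it reports the best inter-cluster e-value, the fraction of each cluster's
#' members touched by inter-cluster edges (profile side = larger cluster) as
#' the two coverages, the mean inter-cluster edge score as the match score,
#' and the mean within-cluster edge score of the profile-side cluster as the
#' self-match score (falling back to the member self-scores when a cluster
#' has no internal edges).
#'
#' @param graph similarity edge tibble with a `self_scores` attribute (see
#'   [simulate_similarity_graph()]); without one, singleton self-scores
#'   default to the maximum edge score.
#' @param partition tibble `protein`, `hg`.
#' @return a function `(hg1, hg2) -> list(evalue, cov_profile,
#'   cov_consensus, score, self_score)`.
#' @export
similarity_profile_scorer <- function(graph, partition) {
  memb <- setNames(partition$hg, partition$protein)
  self <- self_scores(graph)
  fallback <- if (nrow(graph)) max(graph$score) else 1
  function(hg1, hg2) {
    m1 <- names(memb)[memb == hg1]
    m2 <- names(memb)[memb == hg2]
    if (length(m2) > length(m1)) {
      tmp <- m1; m1 <- m2; m2 <- tmp  # profile side = larger cluster
    }
    inter <- graph[(graph$protein1 %in% m1 & graph$protein2 %in% m2) |
                     (graph$protein1 %in% m2 & graph$protein2 %in% m1), ]
    if (!nrow(inter)) {
      return(list(evalue = Inf, cov_profile = 0, cov_consensus = 0,
                  score = 0, self_score = fallback))
    }
    intra1 <- graph[graph$protein1 %in% m1 & graph$protein2 %in% m1, ]
    self_score <- if (nrow(intra1)) {
      mean(intra1$score)
    } else if (!is.null(self) && any(self$protein %in% m1)) {
      mean(self$self_score[self$protein %in% m1])
    } else {
      fallback
    }
    touched <- unique(c(inter$protein1, inter$protein2))
    list(
      evalue = min(inter$evalue),
      cov_profile = mean(m1 %in% touched),
      cov_consensus = mean(m2 %in% touched),
      score = mean(inter$score),
      self_score = self_score
    )
  }
}

#' Flag homologous groups dominated by a single species
#'
#' Optional composition sanity check: flags HGs in which more than
#' `max_fraction` of members come from one species, a pattern that can
#' indicate contamination or collapsed repeats.
#'
#' @param partition tibble `protein`, `hg`.
#' @param species named character vector protein -> species.
#' @param max_fraction domination threshold (default 0.9).
#' @return tibble `hg`, `top_species`, `fraction`, `flagged`.
#' @export
flag_species_dominated <- function(partition, species, max_fraction = 0.9) {
  partition |>
    mutate(species = unname(species[.data$protein])) |>
    group_by(.data$hg) |>
    summarise(
      top_species = names(sort(table(.data$species), decreasing = TRUE))[1L],
      fraction = max(table(.data$species)) / n(),
      .groups = "drop"
    ) |>
    mutate(flagged = .data$fraction > max_fraction)
}
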