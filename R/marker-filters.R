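#' Species of gene-tree leaves
#'
#' Gene-tree leaves are labelled `species|protein`; this extracts the
#' species part.
#'
#' @param labels character vector of leaf labels.
#' @param sep separator between species and protein id (default `"|"`).
#' @return character vector of species names.
#' @export
leaf_species <- function(labels, sep = "|") {
  vapply(strsplit(labels, sep, fixed = TRUE), `[[`, character(1), 1L)
}

#' Collapse same-species terminal duplications in a gene tree
#'
#' Repeatedly collapses every maximal monophyletic clade whose leaves all
#' belong to one species down to a single representative leaf, so the
#' output has no same-species terminal clades. The representative is the
#' leaf with the smallest mean distance to leaves of other species when a
#' distance matrix is supplied (the most "typical" copy), otherwise the
#' lexicographically smallest label. The operation is idempotent and never
#' removes the last representative of a species.
#'
#' @param tree `ape::phylo` gene tree (>= 2 leaves).
#' @param species optional named character vector leaf label -> species;
#'   default parses labels with [leaf_species()].
#' @param d optional symmetric distance matrix over leaf labels, used by the
#'   keep rule.
#' @return the collapsed `phylo`; degenerates to a single-leaf tree if the
#'   whole gene tree is one species.
#' @export
remove_terminal_duplicates <- function(tree, species = NULL, d = NULL) {
  if (length(tree$tip.label) < 2L) abort("tree must have >= 2 leaves")
  if (is.null(species)) {
    species <- setNames(leaf_species(tree$tip.label), tree$tip.label)
  }
  idx <- tree_index(tree)
  sp <- unname(species[tree$tip.label])
  if (anyNA(sp)) abort("every leaf must map to a known species")

  pick_keeper <- function(leaves) {
    if (!is.null(d)) {
      others <- setdiff(tree$tip.label, leaves)
      if (length(others)) {
        md <- vapply(leaves, function(l) mean(d[l, others]), double(1))
        return(leaves[order(md, leaves)][1L])
      }
    }
    sort(leaves)[1L]
  }

  if (length(unique(sp)) == 1L) {
    keep <- pick_keeper(tree$tip.label)
    return(structure(
      list(edge = matrix(c(2L, 1L), 1L), tip.label = keep, Nnode = 1L),
      class = "phylo", order = "cladewise"
    ))
  }

  # monophyletic single-species clades, maximal ones only
  mono_sp <- rep(NA_character_, idx$n_tip + tree$Nnode)
  mono_sp[seq_len(idx$n_tip)] <- sp
  for (v in idx$postorder) {
    kids <- idx$children[[v]]
    if (length(kids)) {
      ks <- unique(mono_sp[kids])
      mono_sp[v] <- if (length(ks) == 1L && !anyNA(ks)) ks else NA_character_
    }
  }
  drop <- character(0)
  for (v in idx$preorder) {
    if (v > idx$n_tip && !is.na(mono_sp[v]) &&
        (is.na(idx$parent[v]) || is.na(mono_sp[idx$parent[v]]))) {
      leaves <- tree$tip.label[subtree_tips(idx, v)]
      drop <- c(drop, setdiff(leaves, pick_keeper(leaves)))
    }
  }
  if (!length(drop)) return(tree)
  ape::drop.tip(tree, drop)
}

#' Mean pairwise distance filter for marker candidates
#'
#' Marker alignments whose mean pairwise amino-acid distance is at or above
#' `threshold` are too divergent for reliable species-tree inference and
#' are rejected.
#'
#' @param d symmetric distance matrix (>= 2 sequences).
#' @param threshold rejection threshold (default 1.5).
#' @return `TRUE` (pass: mean off-diagonal distance below `threshold`) or
#'   `FALSE`.
#' @export
mean_distance_filter <- function(d, threshold = 1.5) {
  d <- as.matrix(d)
  if (nrow(d) < 2L) abort("distance matrix must cover >= 2 sequences")
  mean(d[upper.tri(d)]) < threshold
}

#' Screen marker candidates for ancestral paralogy
#'
#' Builds an average-linkage hierarchy of the sequences and inspects its
#' first (root) split: if both sides share at least `min_shared` species,
#' the two sides look like paralogue clades predating the split and the
#' candidate fails. This overlap rule is one operational reading of
#' "low phylogenetic relations at the first split" (see the vignette).
#'
#' @param d symmetric distance matrix over sequences (>= 3 sequences).
#' @param species named character vector sequence -> species; default
#'   parses names with [leaf_species()].
#' @param min_shared minimum species overlap that triggers failure
#'   (default 2).
#' @return `TRUE` (pass) or `FALSE` (likely ancestral paralogy).
#' @export
ancestral_paralog_screen <- function(d, species = NULL, min_shared = 2) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) abort("need >= 3 sequences")
  labs <- rownames(d)
  if (is.null(species)) species <- setNames(leaf_species(labs), labs)
  sides <- cutree(hclust(as.dist(d), method = "average"), k = 2L)
  shared <- intersect(unique(species[labs[sides == 1L]]),
                      unique(species[labs[sides == 2L]]))
  length(shared) < min_shared
}

#' Alignment length and taxon-sampling filter
#'
#' @param length_aa trimmed alignment length in amino-acid residues.
#' @param n_species number of species represented.
#' @param min_length minimum length kept (default 60).
#' @param min_species minimum species count kept (default 30).
#' @return `TRUE` iff `length_aa >= min_length` and
#'   `n_species >= min_species`.
#' @export
alignment_size_filter <- function(length_aa, n_species, min_length = 60,
                                  min_species = 30) {
  stopifnot(length_aa >= 0, n_species >= 0)
  length_aa >= min_length & n_species >= min_species
}

#' Poisson-corrected amino-acid distance
#'
#' The bundled default distance for the marker filters when no model-based
#' distances are supplied: `d = -ln(1 - p)` for observed proportion of
#' differing sites `p`. It is a simple stand-in, not a WAG model distance.
#'
#' @param p matrix of observed difference proportions in `[0, 1)`.
#' @return matrix of corrected distances.
#' @export
poisson_corrected_distance <- function(p) {
  if (any(p < 0 | p >= 1)) abort("difference proportions must be in [0, 1)")
  -log(1 - p)
}
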