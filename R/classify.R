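#' Conservation of a homologous group within a species group
#'
#' The proportion of the group's species in which the HG has at least one
#' protein.
#'
#' @param hg_species character vector of species carrying the HG.
#' @param group character vector of species defining the group (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
conservation <- function(hg_species, group) {
  if (!length(group)) abort("`group` must be non-empty")
  length(intersect(unique(hg_species), group)) / length(unique(group))
}

#' Majority annotation rule
#'
#' An HG is assigned an annotation if a strict majority (> `threshold`) of
#' its member proteins carry it.
#'
#' @param has_label logical vector, one entry per member protein.
#' @param threshold strict lower bound on the carrying fraction
#'   (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
majority_annotation <- function(has_label, threshold = 0.5) {
  if (!length(has_label)) abort("empty HG cannot be classified")
  mean(has_label) > threshold
}

#' Protist-conserved HGs lost on the way to Dikarya
#'
#' Identifies HGs that were present in the Holomycota ancestor (their Dollo
#' gain node is at or above it), are absent from every Dikarya species, and
#' are either conserved (fraction >= `conservation_threshold`) in at least
#' one of the defined species groups or emerged at/before the Holomycota
#' node. These are the ancestral "protist" families shed during fungal
#' evolution.
#'
#' @param presence logical or 0/1 matrix, HGs x species.
#' @param gain_node named integer vector HG -> Dollo gain node (e.g.
#'   `aggregate_events()$gain_node`).
#' @param groups named list of character vectors (species groups).
#' @param holomycota_node species-tree node id of the first Holomycota
#'   ancestor.
#' @param dikarya character vector of Dikarya species.
#' @param stree rooted `ape::phylo` species tree.
#' @param conservation_threshold inclusive threshold (default 0.70).
#' @return character vector of HG ids.
#' @export
protist_conserved_lost <- function(presence, gain_node, groups,
                                   holomycota_node, dikarya, stree,
                                   conservation_threshold = 0.70) {
  si <- tree_index(stree)
  holo_sp <- names(si$tip_id)[si$tip_id %in% subtree_tips(si, holomycota_node)]
  hgs <- rownames(presence)
  out <- character(0)
  for (hg in hgs) {
    sp <- colnames(presence)[presence[hg, ] >= 1]
    g <- gain_node[[hg]]
    if (is.null(g) || is.na(g)) next
    # present in the Holomycota ancestor under Dollo: gained at or above the
    # node, with at least one carrier among its descendants
    early_origin <- is_ancestor(si, g, holomycota_node)
    if (!early_origin || !length(intersect(sp, holo_sp))) next
    if (length(intersect(sp, dikarya))) next
    conserved <- any(map_dbl(groups, ~ conservation(sp, .x)) >=
                       conservation_threshold)
    if (conserved || early_origin) out <- c(out, hg)
  }
  out
}

#' Novel-core HGs
#'
#' HGs that emerged strictly after a reference node (their Dollo gain node
#' is a strict descendant of it) and are conserved in at least
#' `conservation_threshold` of all species descending from their own gain
#' node.
#'
#' @inheritParams protist_conserved_lost
#' @param reference_node the node after which novelties are counted (the
#'   clade ancestor, e.g. the last universal fungal ancestor).
#' @return character vector of HG ids.
#' @export
novel_core <- function(presence, gain_node, reference_node, stree,
                       conservation_threshold = 0.70) {
  si <- tree_index(stree)
  hgs <- rownames(presence)
  out <- character(0)
  for (hg in hgs) {
    g <- gain_node[[hg]]
    if (is.null(g) || is.na(g)) next
    if (g == reference_node || !is_ancestor(si, reference_node, g)) next
    desc <- names(si$tip_id)[si$tip_id %in% subtree_tips(si, g)]
    sp <- colnames(presence)[presence[hg, ] >= 1]
    if (conservation(sp, desc) >= conservation_threshold) out <- c(out, hg)
  }
  out
}

#' Fungal-specific protein domains
#'
#' A domain counts as fungal specific if at least `threshold` of its
#' occurrences across taxonomic supergroups come from Holomycota.
#'
#' @param domain_table numeric matrix, domains x supergroups, of occurrence
#'   counts; must contain a `holomycota_column`.
#' @param threshold inclusive share threshold (default 0.99).
#' @param holomycota_column column name holding Holomycota counts
#'   (default `"Holomycota"`).
#' @return character vector of fungal-specific domain ids; zero-count
#'   domains are skipped with a warning.
#' @export
fungal_specific_domains <- function(domain_table, threshold = 0.99,
                                    holomycota_column = "Holomycota") {
  stopifnot(holomycota_column %in% colnames(domain_table))
  tot <- rowSums(domain_table)
  if (any(tot == 0)) {
    warn(paste0("skipping zero-count domains: ",
                paste(rownames(domain_table)[tot == 0], collapse = ", ")))
  }
  ok <- tot > 0
  share <- domain_table[ok, holomycota_column] / tot[ok]
  rownames(domain_table)[ok][share >= threshold]
}

#' Does an HG carry predominantly fungal-specific domains?
#'
#' @param protein_domains list of character vectors: per member protein,
#'   its domain ids.
#' @param fungal_domains character vector of fungal-specific domain ids.
#' @param threshold inclusive fraction of members that must carry at least
#'   one fungal-specific domain (default 0.75).
#' @return `TRUE` or `FALSE`.
#' @export
hg_fungal_domain_flag <- function(protein_domains, fungal_domains,
                                  threshold = 0.75) {
  if (!length(protein_domains)) return(FALSE)
  frac <- mean(map_lgl(protein_domains,
                       ~ length(intersect(.x, fungal_domains)) > 0))
  frac >= threshold
}

#' Classify an HG as a transcription-factor family
#'
#' An HG is a TF iff a strict majority of members carry a sequence-specific
#' DNA-binding domain (DBD) and no exclusion domain (domains characteristic
#' of non-TF processes such as metallopeptidases, ribonucleases, chromatin
#' remodelling or splicing) itself passes the majority rule. The family
#' label is looked up from the majority DBD.
#'
#' @param protein_domains list of character vectors, per member protein.
#' @param dbd_list character vector of DBD domain ids.
#' @param exclusion_domains character vector of excluding domain ids.
#' @param family_map named character vector DBD -> TF family label;
#'   defaults to the DBD id itself.
#' @param threshold strict majority threshold (default 0.5).
#' @return the TF family label, or `NA_character_` if the HG is not a TF.
#' @export
classify_tf <- function(protein_domains, dbd_list, exclusion_domains =
                          character(0), family_map = NULL, threshold = 0.5) {
  if (!length(protein_domains)) return(NA_character_)
  dbd_hits <- map(protein_domains, ~ intersect(.x, dbd_list))
  if (!majority_annotation(map_lgl(dbd_hits, ~ length(.x) > 0), threshold)) {
    return(NA_character_)
  }
  for (ex in exclusion_domains) {
    if (majority_annotation(map_lgl(protein_domains, ~ ex %in% .x),
                            threshold)) {
      return(NA_character_)
    }
  }
  counts <- sort(table(unlist(dbd_hits)), decreasing = TRUE)
  major <- names(counts)[1L]
  if (is.null(family_map)) major else unname(family_map[major]) %||% major
}

#' Classify an HG as a cell-surface transporter
#'
#' True iff a strict majority of members carry a transporter-characteristic
#' domain and the modal predicted localization among members is the plasma
#' membrane with a median localization score above `score_min`. Ties in the
#' localization mode are conservative (not a transporter).
#'
#' @param protein_domains list of character vectors, per member protein.
#' @param localizations character vector of predicted localizations, one
#'   per member.
#' @param loc_scores numeric localization scores, one per member.
#' @param transporter_domains character vector of transporter domain ids.
#' @param pm_label plasma-membrane label (default `"plasma membrane"`).
#' @param score_min strict minimum median score (default 15).
#' @param threshold strict majority threshold (default 0.5).
#' @return `TRUE` or `FALSE`.
#' @export
classify_transporter <- function(protein_domains, localizations, loc_scores,
                                 transporter_domains,
                                 pm_label = "plasma membrane",
                                 score_min = 15, threshold = 0.5) {
  if (!length(protein_domains)) return(FALSE)
  has_dom <- map_lgl(protein_domains,
                     ~ length(intersect(.x, transporter_domains)) > 0)
  if (!majority_annotation(has_dom, threshold)) return(FALSE)
  tab <- sort(table(localizations), decreasing = TRUE)
  if (length(tab) > 1L && tab[1L] == tab[2L]) return(FALSE)  # modal tie
  if (names(tab)[1L] != pm_label) return(FALSE)
  median(loc_scores[localizations == pm_label]) > score_min
}

#' Small-secreted-protein call for one protein
#'
#' @param length protein length in amino acids.
#' @param signal_peptide logical: predicted signal peptide.
#' @param transmembrane logical: predicted transmembrane helix.
#' @param max_length strict length bound (default 300: proteins shorter
#'   than 300 aa qualify).
#' @return logical vector: SSP calls.
#' @export
classify_ssp <- function(length, signal_peptide, transmembrane,
                         max_length = 300) {
  length < max_length & signal_peptide & !transmembrane
}

#' Shannon diversity of a family repertoire
#'
#' `-sum(p_i * ln(p_i))` over families with nonzero counts; the standard
#' diversity index of a repertoire (natural logarithm).
#'
#' @param family_counts non-negative numeric vector with positive sum.
#' @return non-negative real.
#' @export
#' @examples
#' shannon_diversity(c(1, 1))  # ln(2)
shannon_diversity <- function(family_counts) {
  if (any(family_counts < 0) || sum(family_counts) <= 0) {
    abort("`family_counts` must be non-negative with positive sum")
  }
  p <- family_counts[family_counts > 0] / sum(family_counts)
  -sum(p * log(p))
}
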