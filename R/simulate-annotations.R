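#' Default per-family annotation profile
#'
#' Builds the generating profile consumed by [simulate_annotations()]: one
#' row per family with the probabilities controlling domain content,
#' predicted subcellular localization, signal-peptide/transmembrane flags,
#' protein length and GO terms. Individual rows can then be edited to plant
#' families that are exactly "TF", "transporter", "extracellular" or "SSP"
#' under the package's classification rules.
#'
#' @param families character vector of family ids.
#' @return tibble with columns `family`, `domains` (`;`-separated domain ids
#'   applied jointly), `domain_prob`, `localization`, `loc_score_mean`,
#'   `sp_prob`, `tm_prob`, `length_mean`, `go` (`;`-separated GO ids),
#'   `go_prob`.
#' @export
annotation_profile <- function(families) {
  tibble(
    family = families,
    domains = paste0("DOM_", families),
    domain_prob = 0.9,
    localization = "cytosol",
    loc_score_mean = 20,
    sp_prob = 0,
    tm_prob = 0,
    length_mean = 400,
    go = paste0("GO:", sprintf("%07d", seq_along(families))),
    go_prob = 0.9
  )
}

#' Simulate a per-protein annotation table
#'
#' Generates the annotation table that drives every downstream classifier:
#' one protein per gene copy in `counts`, annotated according to the
#' per-family generating `profile`. Deterministic for a fixed seed.
#'
#' @param counts families x species integer copy-number matrix (e.g.
#'   `simulate_gene_content()$counts`).
#' @param profile per-family generating profile, as from
#'   [annotation_profile()]; must cover every family in `counts`.
#' @param supergroups named character vector mapping species to their
#'   taxonomic supergroup (default: every species `"Holomycota"`).
#' @param seed integer random seed; `NULL` uses the current RNG state.
#' @return tibble of class `annotation_table` with one row per protein:
#'   `protein`, `species`, `family`, `length`, `domains` (`;`-separated, may
#'   be empty), `localization`, `loc_score`, `signal_peptide`,
#'   `transmembrane`, `go` (`;`-separated, may be empty), `supergroup`.
#' @export
#' @examples
#' tr <- simulate_species_tree(5, seed = 1)
#' sim <- simulate_gene_content(tr, 10, seed = 2)
#' ann <- simulate_annotations(sim$counts, annotation_profile(rownames(sim$counts)),
#'                             seed = 3)
simulate_annotations <- function(counts, profile, supergroups = NULL,
                                 seed = NULL) {
  stopifnot(is.matrix(counts))
  fams <- rownames(counts)
  if (!all(fams %in% profile$family)) {
    abort("`profile` must contain a row for every family in `counts`")
  }
  if (is.null(supergroups)) {
    supergroups <- setNames(rep("Holomycota", ncol(counts)), colnames(counts))
  }
  if (!all(colnames(counts) %in% names(supergroups))) {
    abort("`supergroups` must name every species in `counts`")
  }
  if (!is.null(seed)) set.seed(seed)

  long <- as_tibble(counts, rownames = "family") |>
    tidyr::pivot_longer(-"family", names_to = "species", values_to = "n") |>
    filter(.data$n > 0L)
  rows <- long[rep(seq_len(nrow(long)), long$n), c("family", "species")]
  rows <- rows |>
    mutate(protein = sprintf("%s|%s_g%03d", .data$species, .data$family,
                             sequence(long$n)))
  prof <- profile[match(rows$family, profile$family), ]
  m <- nrow(rows)
  other_loc <- c("nucleus", "mitochondrion", "extracellular", "cytosol",
                 "plasma membrane")
  loc <- prof$localization
  flip <- runif(m) > 0.95  # small localization-prediction noise
  loc[flip] <- sample(other_loc, sum(flip), replace = TRUE)
  out <- tibble(
    protein = rows$protein,
    species = rows$species,
    family = rows$family,
    length = pmax(30L, as.integer(round(rnorm(m, prof$length_mean,
                                              prof$length_mean / 10)))),
    domains = ifelse(runif(m) < prof$domain_prob, prof$domains, ""),
    localization = loc,
    loc_score = pmax(0, rnorm(m, prof$loc_score_mean, 2)),
    signal_peptide = runif(m) < prof$sp_prob,
    transmembrane = runif(m) < prof$tm_prob,
    go = ifelse(runif(m) < prof$go_prob, prof$go, ""),
    supergroup = unname(supergroups[rows$species])
  )
  class(out) <- c("annotation_table", class(out))
  out
}

#' Split a `;`-separated annotation field into a character vector
#' @keywords internal
split_terms <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
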