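#' Default pipeline configuration
#'
#' All stage toggles, thresholds and seeds of the end-to-end analysis in
#' one validated list. Threshold defaults are the method's standard
#' operating point: 20%/80% asymmetric coverage with e-value 1e-4 before
#' clustering, MCL inflation 2.0, merge criteria 1e-10 / 75% / 20% / 75% of
#' self-match at network diameter 3, gene-tree support threshold 80,
#' marker filters 1.5 / 60 aa / 30 species, conservation 70%, majority rule
#' 50%, fungal-domain specificity 99%, HG fungal-domain fraction 75%,
#' plasma-membrane score 15, SSP length bound 300.
#'
#' @param ... named overrides of any default (unknown keys are rejected).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "cluster", "dollo", "classify", "ordinate"),
    seed = 1L,
    n_species = 12L,
    n_families = 60L,
    origination_rate = 1,
    duplication_rate = 0.1,
    loss_rate = 0.1,
    proteins_per_family = 6L,
    intra_edge_prob = 0.9,
    inter_edge_prob = 0.02,
    cov_long_min = 0.2,
    cov_short_min = 0.8,
    evalue_max = 1e-4,
    inflation = 2.0,
    merge_evalue = 1e-10,
    merge_cov_profile = 0.75,
    merge_cov_consensus = 0.20,
    merge_self_fraction = 0.75,
    max_diameter = 3L,
    support_threshold = 80,
    max_mean_distance = 1.5,
    min_alignment_length = 60L,
    min_marker_species = 30L,
    conservation_threshold = 0.70,
    majority_threshold = 0.50,
    fungal_domain_threshold = 0.99,
    hg_fungal_domain_threshold = 0.75,
    pm_score_min = 15,
    ssp_max_length = 300L,
    pcoa_min_proteins = 4L,
    pcoa_min_conservation = 0.5,
    enrichment_alpha = 0.05,
    dollo_mode = "counts"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste0("unknown configuration keys: ",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) abort(paste0("invalid config: ", what))
  chk(cfg$inflation > 1, "inflation must be > 1")
  chk(cfg$max_diameter >= 1, "max_diameter must be >= 1")
  fr <- c(cfg$merge_cov_profile, cfg$merge_cov_consensus,
          cfg$merge_self_fraction)
  chk(all(fr > 0 & fr <= 1), "merge fractions must be in (0, 1]")
  chk(cfg$conservation_threshold >= 0 && cfg$conservation_threshold <= 1,
      "conservation_threshold must be in [0, 1]")
  chk(cfg$dollo_mode %in% c("counts", "presence"), "dollo_mode")
  chk(all(cfg$stages %in%
            c("simulate", "cluster", "dollo", "classify", "ordinate",
              "enrich")), "unknown stage name")
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' Configurations round-trip through YAML unchanged; unknown keys in the
#' file are rejected by name.
#'
#' @param path YAML file path.
#' @param cfg a [pipeline_config()].
#' @return `read_config()` returns a `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' Executes the enabled stages in order — simulate gene content and a
#' similarity graph, build homologous groups, infer the Dollo event map,
#' classify repertoires, ordinate gene content — writing every stage's
#' outputs and a JSON manifest (seeds, thresholds, output checksums) to
#' `out_dir`. Reruns with an identical configuration are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @return a list of stage results (`simulation`, `hg`, `event_map`,
#'   `classification`, `ordination`, plus `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }

  if ("simulate" %in% config$stages) {
    tree <- simulate_species_tree(config$n_species, seed = config$seed)
    sim <- simulate_gene_content(
      tree, config$n_families,
      origination_rate = config$origination_rate,
      duplication_rate = config$duplication_rate,
      loss_rate = config$loss_rate,
      seed = config$seed + 1L
    )
    res$simulation <- sim
    emit("species_tree.nwk", function(p) ape::write.tree(tree, p))
    emit("copy_numbers.tsv", function(p) write_copy_matrix(sim$counts, p))
  }

  if ("cluster" %in% config$stages) {
    fams <- rownames(res$simulation$counts)
    part <- planted_partition(length(fams), config$proteins_per_family)
    part$family <- rep(fams, each = config$proteins_per_family)
    graph <- simulate_similarity_graph(
      part, intra_edge_prob = config$intra_edge_prob,
      inter_edge_prob = config$inter_edge_prob,
      seed = config$seed + 2L
    )
    hg <- cluster_proteins(
      graph, nodes = part$protein, inflation = config$inflation,
      cov_long_min = config$cov_long_min,
      cov_short_min = config$cov_short_min,
      evalue_max = config$evalue_max,
      criteria = merge_criteria(config$merge_evalue,
                                config$merge_cov_profile,
                                config$merge_cov_consensus,
                                config$merge_self_fraction,
                                config$max_diameter)
    )
    res$hg <- hg
    res$planted <- part
    emit("hg_membership.tsv", function(p) readr::write_tsv(hg, p))
  }

  if ("dollo" %in% config$stages) {
    em <- aggregate_events(res$simulation$counts, res$simulation$tree,
                           mode = config$dollo_mode)
    res$event_map <- em
    emit("event_map.tsv", function(p) write_event_map(em, p))
  }

  if ("classify" %in% config$stages) {
    counts <- res$simulation$counts
    ann <- simulate_annotations(counts, annotation_profile(rownames(counts)),
                                seed = config$seed + 3L)
    res$annotations <- ann
    res$classification <- tibble(
      family = rownames(counts),
      ssp_members = map_int(rownames(counts), function(f) {
        rows <- ann[ann$family == f, ]
        sum(classify_ssp(rows$length, rows$signal_peptide,
                         rows$transmembrane, config$ssp_max_length))
      })
    )
    emit("annotations.tsv", function(p) write_annotations(ann, p))
    emit("classification.tsv",
         function(p) readr::write_tsv(res$classification, p))
  }

  if ("ordinate" %in% config$stages) {
    pres <- res$simulation$counts
    ord <- gc_pcoa(binary_distance(pres), k = 2)
    res$ordination <- ord
    emit("pcoa_points.tsv", function(p) readr::write_tsv(ord$points, p))
    emit("mst_edges.tsv", function(p) readr::write_tsv(ord$mst, p))
  }

  manifest <- list(
    package = "dollodyn",
    version = as.character(utils::packageVersion("dollodyn")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    outputs = if (is.null(out_dir)) list() else {
      fs <- sort(list.files(out_dir))
      fs <- setdiff(fs, "manifest.json")
      as.list(setNames(
        vapply(file.path(out_dir, fs),
               function(f) rlang::hash(readLines(f, warn = FALSE)),
               character(1)),
        fs
      ))
    }
  )
  res$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
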