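#' Read and write the package's tabular formats
#'
#' Plain TSV readers/writers that round-trip the package's main tables:
#' similarity edge lists (`protein1`, `protein2`, `score`, `evalue`,
#' `cov_long`, `cov_short`), copy-number matrices (families as rows,
#' species as columns, first column `family`), annotation tables and event
#' maps. Trees travel as Newick via `ape::read.tree()` /
#' `ape::write.tree()`.
#'
#' @param x the object to write.
#' @param path file path.
#' @name dollodyn-io
NULL

#' @rdname dollodyn-io
#' @export
write_similarity_graph <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  self <- self_scores(x)
  if (!is.null(self)) {
    readr::write_tsv(self, paste0(path, ".self"))
  }
  invisible(path)
}

#' @rdname dollodyn-io
#' @export
read_similarity_graph <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  self_path <- paste0(path, ".self")
  self <- if (file.exists(self_path)) {
    readr::read_tsv(self_path, show_col_types = FALSE)
  } else {
    NULL
  }
  new_similarity_graph(edges, self)
}

#' @rdname dollodyn-io
#' @export
write_copy_matrix <- function(x, path) {
  readr::write_tsv(as_tibble(x, rownames = "family"), path)
  invisible(path)
}

#' @rdname dollodyn-io
#' @export
read_copy_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1L])
  mode(m) <- "integer"
  rownames(m) <- df$family
  m
}

#' @rdname dollodyn-io
#' @export
write_annotations <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "")
  invisible(path)
}

#' @rdname dollodyn-io
#' @export
read_annotations <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE) |>
    mutate(across(where(is.character), ~ tidyr::replace_na(.x, "")))
  class(out) <- c("annotation_table", class(out))
  out
}

#' @rdname dollodyn-io
#' @export
write_event_map <- function(x, path) {
  readr::write_tsv(x$by_node, path)
  readr::write_tsv(x$by_family, paste0(path, ".families"))
  invisible(path)
}
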