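#' Read a weighted interaction network from an edge-list file
#'
#' Edge lists are tab-separated with a header row and at least three columns:
#' two protein identifiers followed by one or more numeric score columns
#' (confidence, precision, BFDR, ...). Edges are undirected: duplicate
#' unordered pairs are collapsed keeping the maximum score, and self-edges are
#' dropped with a warning that counts them.
#'
#' @param path Path to a TSV file with header `protein_a  protein_b  score`
#'   (score column name configurable).
#' @param score_column Name of the numeric column holding the edge score.
#' @return An interaction network: a tibble with columns `protein_a`,
#'   `protein_b`, `score`, one row per unordered pair, `protein_a <
#'   protein_b` lexicographically.
#' @export
read_edge_list <- function(path, score_column = "score") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 3)
    abort("edge list must have at least 3 columns (two proteins and a score)")
  if (!score_column %in% names(raw))
    abort(paste0("score column '", score_column, "' not found in ", path))
  bad <- which(is.na(raw[[1]]) | is.na(raw[[2]]) | raw[[1]] == "" | raw[[2]] == "")
  if (length(bad) > 0)
    abort(paste0("malformed edge row at line ", bad[1] + 1L, " of ", path))
  score <- suppressWarnings(as.numeric(raw[[score_column]]))
  bad <- which(is.na(score) | !is.finite(score))
  if (length(bad) > 0)
    abort(paste0("non-numeric or missing score at line ", bad[1] + 1L, " of ", path))
  as_interaction_network(
    tibble::tibble(protein_a = raw[[1]], protein_b = raw[[2]], score = score)
  )
}

#' Coerce an edge table to a canonical interaction network
#'
#' Orders each pair lexicographically, drops self-edges (with a warning
#' giving the count), and collapses duplicate unordered pairs to their
#' maximum score.
#'
#' @param edges A data frame with columns `protein_a`, `protein_b`, `score`.
#' @return A tibble with one row per unordered pair.
#' @export
as_interaction_network <- function(edges) {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(edges)))
  if (!all(is.finite(edges$score))) abort("edge scores must be finite")
  self <- edges$protein_a == edges$protein_b
  if (any(self)) {
    warn(paste0("dropped ", sum(self), " self-edge(s)"))
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) == 0)
    return(tibble::tibble(protein_a = character(), protein_b = character(),
                          score = numeric()))
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  tibble::tibble(protein_a = a, protein_b = b, score = edges$score) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Filter network edges by score
#'
#' Retains edges with score strictly above (or strictly below) a threshold,
#' mirroring the usual confidence filters on interaction networks (for
#' example precision > 0.75 on co-fractionation pairs, or BFDR < 0.01 on
#' proximity-labelling interactions). Nodes left without edges simply no
#' longer appear, since the node set is derived from the edge table.
#'
#' @param net An interaction network tibble.
#' @param threshold Finite numeric cutoff.
#' @param keep `"above"` to keep `score > threshold`, `"below"` for
#'   `score < threshold`. Both are strict.
#' @return The filtered network tibble.
#' @export
filter_edges <- function(net, threshold, keep = c("above", "below")) {
  keep <- match.arg(keep)
  if (!is.finite(threshold) && !is.infinite(threshold))
    abort("threshold must be numeric")
  if (keep == "above") dplyr::filter(net, .data$score > threshold)
  else dplyr::filter(net, .data$score < threshold)
}

#' Nodes of an interaction network
#' @param net An interaction network tibble.
#' @return Sorted character vector of protein ids incident to at least one edge.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$protein_a, net$protein_b)))
}

#' Read a per-protein feature table
#'
#' Feature tables are TSV with a header; the first column holds the protein
#' identifier and every remaining column is numeric. This is the format for
#' precomputed embeddings (e.g. 9217-dimensional image embeddings) and the
#' format [node2vec_featurize()] and [write_feature_table()] emit.
#'
#' @param path Path to the table.
#' @param modality Optional modality name stored on the result.
#' @return A feature tibble: `protein_id` plus `d >= 2` numeric columns.
#' @export
read_feature_table <- function(path, modality = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(raw) < 3)
    abort("feature table needs >= 2 feature columns (d_m >= 2)")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    abort(paste0("duplicate protein id: ", ids[duplicated(ids)][1]))
  vals <- lapply(seq(2, ncol(raw)), function(j) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      abort(paste0("non-numeric value at row ", bad[1], ", column '",
                   names(raw)[j], "'"))
    v
  })
  out <- tibble::tibble(protein_id = ids)
  for (j in seq_along(vals)) out[[names(raw)[j + 1]]] <- vals[[j]]
  new_feature_table(out, modality %||% tools::file_path_sans_ext(basename(path)))
}

new_feature_table <- function(tbl, modality) {
  stopifnot(names(tbl)[1] == "protein_id")
  attr(tbl, "modality") <- modality
  tbl
}

#' Write a feature table
#' @param features A feature tibble (`protein_id` + numeric columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' Modality name of a feature table
#' @param features A feature tibble.
#' @return The stored modality name, or `NA` if unset.
#' @export
modality_name <- function(features) attr(features, "modality") %||% NA_character_

# numeric matrix with protein ids as rownames
feature_matrix <- function(features) {
  m <- as.matrix(features[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) < 2) abort("feature table needs d_m >= 2")
  if (anyNA(m) || !all(is.finite(m))) abort("feature matrix has non-finite values")
  rownames(m) <- features$protein_id
  m
}

#' Build the shared protein universe and coverage mask
#'
#' The universe is the lexicographically sorted union of protein ids over all
#' modalities; the coverage mask records which modalities measured each
#' protein. Every downstream step (training batches, unified averaging,
#' missing-modality handling) iterates over this universe.
#'
#' @param features Named list of >= 2 feature tibbles.
#' @return A list with `ids` (sorted character vector) and `coverage`
#'   (tibble: `protein_id` plus one logical column per modality).
#' @export
build_universe <- function(features) {
  if (length(features) < 2) abort("need at least 2 modalities")
  if (is.null(names(features)) || any(names(features) == ""))
    abort("'features' must be a named list of modalities")
  idx <- lapply(features, function(f) f$protein_id)
  ids <- sort(unique(unlist(idx)))
  if (length(ids) == 0) abort("empty protein universe")
  cov <- tibble::tibble(protein_id = ids)
  for (m in names(features)) cov[[m]] <- ids %in% idx[[m]]
  list(ids = ids, coverage = cov)
}

coverage_matrix <- function(universe) {
  m <- as.matrix(universe$coverage[, -1, drop = FALSE])
  rownames(m) <- universe$coverage$protein_id
  m
}
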