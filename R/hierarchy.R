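# Multiscale assembly mapping: threshold the proximity matrix into a series
# of networks, hand them to a pluggable pan-resolution community detector
# (HiDeF as published; a deterministic stub in tests), then score each
# detected assembly for known-term overlap and per-modality support.

#' Threshold a proximity matrix into proximity networks
#'
#' One network per fraction, each keeping the top fraction of most similar
#' pairs (edge score = proximity). The default fractions 0.2, 0.4, 0.6, 0.8,
#' 1.0 and 5.0 percent yield six nested networks for multiscale community
#' detection.
#'
#' @param prox Proximity matrix.
#' @param fractions Numeric vector of pair fractions in (0, 1).
#' @return Named list of interaction-network tibbles (names = percent labels).
#' @export
threshold_networks <- function(prox,
                               fractions = c(0.002, 0.004, 0.006, 0.008,
                                             0.01, 0.05)) {
  stopifnot(all(fractions > 0), all(fractions < 1))
  out <- lapply(fractions, function(f) top_fraction_pairs(prox, f))
  names(out) <- paste0(100 * fractions, "pct")
  out
}

#' Run pan-resolution community detection on proximity networks
#'
#' Invokes a pluggable external detector (the published HiDeF implementation)
#' jointly on the thresholded networks and parses its node and edge tables
#' into assembly records. The detector itself is not reimplemented here.
#'
#' `detector` may be: the path of a HiDeF-style executable, called as
#' `detector --g <edge lists...> --o <prefix> --k <persistence>
#' --maxres <maxres>` and expected to write `<prefix>.nodes` (lines
#' `name  size  member1 member2 ...  persistence`) and `<prefix>.edges`
#' (lines `parent  child  type`); or an R function
#' `function(networks, persistence, maxres)` returning a list with `nodes`
#' (tibble `name`, `members` list-column) and optional `edges` (tibble
#' `parent`, `child`) -- used for deterministic stubs in tests.
#'
#' @param networks List of interaction-network tibbles (see
#'   [threshold_networks()]).
#' @param persistence Persistence threshold k passed to the detector.
#' @param maxres Maximum resolution passed to the detector.
#' @param detector Executable path or R function; defaults to
#'   `hidef_finder.py` on the PATH.
#' @return Assembly tibble: `assembly_id`, `parent_id`, `n_members`,
#'   `members` (list-column of protein-id vectors).
#' @export
run_community_detection <- function(networks, persistence = 10, maxres = 80,
                                    detector = NULL) {
  if (is.function(detector)) {
    res <- detector(networks, persistence, maxres)
    return(assemblies_from_tables(res$nodes, res$edges))
  }
  exe <- detector %||% Sys.which("hidef_finder.py")
  if (is.null(exe) || !nzchar(exe) || !file.exists(exe))
    abort(paste0(
      "community detector executable not found; install HiDeF ",
      "(pip install hidef) or pass `detector = <path or function>`"))
  dir <- tempfile("hidef")
  dir.create(dir)
  paths <- vapply(seq_along(networks), function(i) {
    p <- file.path(dir, paste0("net", i, ".tsv"))
    readr::write_tsv(networks[[i]], p, col_names = FALSE, progress = FALSE)
    p
  }, character(1))
  prefix <- file.path(dir, "hierarchy")
  args <- c("--g", paths, "--o", prefix, "--k", persistence,
            "--maxres", maxres)
  inform(paste("running:", exe, paste(args, collapse = " ")))
  status <- system2(exe, args)
  if (status != 0) abort(paste0("community detector exited with status ", status))
  nodes_file <- paste0(prefix, ".nodes")
  if (!file.exists(nodes_file) || length(readLines(nodes_file)) == 0) {
    warn("community detector produced no assemblies")
    return(assemblies_from_tables(
      tibble::tibble(name = character(), members = list()), NULL))
  }
  nodes_raw <- readr::read_tsv(nodes_file, col_names = FALSE,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  nodes <- tibble::tibble(
    name = nodes_raw[[1]],
    members = strsplit(nodes_raw[[3]], " ", fixed = TRUE))
  edges_file <- paste0(prefix, ".edges")
  edges <- if (file.exists(edges_file)) {
    e <- readr::read_tsv(edges_file, col_names = FALSE,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
    if (nrow(e) > 0) tibble::tibble(parent = e[[1]], child = e[[2]]) else NULL
  } else NULL
  assemblies_from_tables(nodes, edges)
}

assemblies_from_tables <- function(nodes, edges = NULL) {
  if (nrow(nodes) == 0) {
    warn("empty assembly list")
    return(tibble::tibble(assembly_id = character(), parent_id = character(),
                          n_members = integer(), members = list()))
  }
  parent <- rep(NA_character_, nrow(nodes))
  if (!is.null(edges) && nrow(edges) > 0)
    parent <- edges$parent[match(nodes$name, edges$child)]
  tibble::tibble(assembly_id = nodes$name, parent_id = parent,
                 n_members = lengths(nodes$members), members = nodes$members)
}

#' Score assemblies for support by each original data modality
#'
#' For each assembly and each modality, compares the cosine similarities of
#' the assembly's proteins in that modality's *original* features against a
#' null distribution (pairs among proteins assigned to the root only, i.e.
#' members of no assembly) with a one-sided Wilcoxon rank-sum test;
#' Benjamini-Hochberg correction is applied across assemblies within each
#' modality. An assembly with fewer than 2 covered proteins in a modality
#' has *undefined* support there -- a third state, never conflated with
#' "unsupported".
#'
#' @param assemblies Assembly tibble from [run_community_detection()].
#' @param features Named list of original feature tibbles.
#' @param fdr FDR threshold (default 0.01).
#' @param root_only Optional explicit null protein set; defaults to universe
#'   proteins in no assembly.
#' @return Tibble `assembly_id`, `modality`, `n_covered`, `p_value`,
#'   `adj_p`, `support` (`"supported"`, `"unsupported"`, `"undefined"`).
#' @export
assembly_support <- function(assemblies, features, fdr = 0.01,
                             root_only = NULL) {
  mats <- lapply(features, feature_matrix)
  universe <- sort(unique(unlist(lapply(mats, rownames))))
  in_assembly <- unique(unlist(assemblies$members))
  root_only <- root_only %||% setdiff(universe, in_assembly)
  out <- list()
  for (m in names(mats)) {
    P <- proximity(mats[[m]])
    null_prot <- intersect(root_only, rownames(P))
    if (length(null_prot) < 2)
      abort(paste0("empty null for modality '", m,
                   "': < 2 root-only proteins covered"))
    null_vals <- P[null_prot, null_prot][upper.tri(diag(length(null_prot)))]
    rows <- purrr::map(seq_len(nrow(assemblies)), function(i) {
      ms <- intersect(assemblies$members[[i]], rownames(P))
      if (length(ms) < 2)
        return(tibble::tibble(assembly_id = assemblies$assembly_id[i],
                              modality = m, n_covered = length(ms),
                              p_value = NA_real_))
      vals <- P[ms, ms][upper.tri(diag(length(ms)))]
      p <- suppressWarnings(
        wilcox.test(vals, null_vals, alternative = "greater")$p.value)
      tibble::tibble(assembly_id = assemblies$assembly_id[i], modality = m,
                     n_covered = length(ms), p_value = p)
    })
    tab <- dplyr::bind_rows(rows)
    tab$adj_p <- NA_real_
    tested <- !is.na(tab$p_value)
    tab$adj_p[tested] <- p.adjust(tab$p_value[tested], method = "BH")
    tab$support <- dplyr::case_when(
      !tested ~ "undefined",
      tab$adj_p < fdr ~ "supported",
      TRUE ~ "unsupported")
    out[[m]] <- tab
  }
  dplyr::bind_rows(out)
}

#' Hypergeometric overlap of assemblies with known terms
#'
#' Upper-tail hypergeometric test of the overlap between each assembly and
#' each term (GO component, CORUM complex, ...) in a universe of
#' `universe_size` proteins, BH-corrected across all assembly-term tests.
#' An assembly-term match is flagged only when adjusted p < `fdr` AND the
#' Jaccard index exceeds `min_jaccard` -- the conjunction is deliberate: a
#' tiny p-value with marginal overlap is not called a known assembly.
#'
#' @param assemblies Assembly tibble.
#' @param terms Named list term id -> member proteins.
#' @param universe_size Number of proteins in the background universe.
#' @param fdr FDR threshold (default 0.01).
#' @param min_jaccard Jaccard cutoff (default 0.2, strict).
#' @return Tibble `assembly_id`, `term`, `n_overlap`, `p_value`, `adj_p`,
#'   `jaccard`, `flagged`.
#' @export
term_overlap <- function(assemblies, terms, universe_size, fdr = 0.01,
                         min_jaccard = 0.2) {
  if (universe_size < max(c(0, lengths(terms))))
    abort("universe_size smaller than the largest term")
  grid <- tidyr::expand_grid(i = seq_len(nrow(assemblies)),
                             term = names(terms))
  rows <- purrr::pmap(grid, function(i, term) {
    a <- assemblies$members[[i]]
    t_ <- terms[[term]]
    ov <- length(intersect(a, t_))
    p <- phyper(ov - 1, length(t_), universe_size - length(t_), length(a),
                lower.tail = FALSE)
    tibble::tibble(assembly_id = assemblies$assembly_id[i], term = term,
                   n_overlap = ov, p_value = p,
                   jaccard = ov / length(union(a, t_)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    return(tibble::tibble(assembly_id = character(), term = character(),
                          n_overlap = integer(), p_value = numeric(),
                          adj_p = numeric(), jaccard = numeric(),
                          flagged = logical()))
  out$adj_p <- p.adjust(out$p_value, method = "BH")
  out$flagged <- out$adj_p < fdr & out$jaccard > min_jaccard
  dplyr::arrange(out, .data$p_value)
}

#' Write assemblies as TSV
#' @param assemblies Assembly tibble.
#' @param path Output path (`assembly_id  parent_id  member1,member2,...`).
#' @export
write_assemblies <- function(assemblies, path) {
  tab <- tibble::tibble(
    assembly_id = assemblies$assembly_id,
    parent_id = assemblies$parent_id,
    members = vapply(assemblies$members, paste, character(1), collapse = ","))
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}
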