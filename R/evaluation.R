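#' Protein proximity matrix
#'
#' Pairwise cosine similarities ("protein proximities") between the rows of
#' an embedding -- the unified embedding, a single modality's latents, or any
#' feature table.
#'
#' @param emb Feature tibble (`protein_id` + numeric columns) or numeric
#'   matrix with protein-id rownames.
#' @return Symmetric matrix in `[-1, 1]` with unit diagonal, protein ids as
#'   dimnames.
#' @export
proximity <- function(emb) {
  X <- if (is.data.frame(emb)) feature_matrix(emb) else emb
  r <- sqrt(rowSums(X^2))
  if (any(r < 1e-12))
    abort(paste0("all-zero embedding row for protein ",
                 rownames(X)[which(r < 1e-12)[1]]))
  Z <- X / r
  P <- tcrossprod(Z)
  P[P > 1] <- 1
  P[P < -1] <- -1
  diag(P) <- 1
  P
}

# long tibble of all unordered pairs of a symmetric matrix
all_pairs <- function(P) {
  ids <- rownames(P)
  ut <- upper.tri(P)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]],
                 score = P[ut])
}

#' Extract the top fraction of most similar pairs
#'
#' Returns the `ceiling(fraction * n(n-1)/2)` unordered pairs with the
#' highest similarity. Ties at the cutoff are broken by lexicographic pair
#' order, so the result is deterministic.
#'
#' @param prox Proximity (or any symmetric score) matrix with id dimnames.
#' @param fraction Fraction of all unordered pairs to keep, in (0, 1).
#' @return Pair tibble `protein_a`, `protein_b`, `score`, with `protein_a <
#'   protein_b`.
#' @export
top_fraction_pairs <- function(prox, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  pairs <- all_pairs(prox)
  k <- ceiling(fraction * nrow(pairs))
  pairs |>
    dplyr::arrange(dplyr::desc(.data$score), .data$protein_a, .data$protein_b) |>
    head(k) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Derive a pair set from a samples-by-proteins value matrix
#'
#' Computes the pairwise Pearson correlation matrix over protein columns
#' (e.g. perturbation profiles or abundances across cell types) and extracts
#' the top fraction of most correlated pairs as interactions.
#'
#' @param mat Numeric matrix, samples in rows, proteins in columns (column
#'   names are protein ids). Needs >= 3 samples; constant columns are dropped
#'   with a warning.
#' @param fraction Fraction of pairs to keep.
#' @return Pair tibble as in [top_fraction_pairs()] (`score` = correlation).
#' @export
correlation_pairs <- function(mat, fraction = 0.01) {
  if (nrow(mat) < 3) abort("need >= 3 samples per protein")
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("dropping ", sum(sds == 0), " constant column(s)"))
    mat <- mat[, sds > 0, drop = FALSE]
  }
  top_fraction_pairs(cor(mat), fraction)
}

pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' AUROC from scores and binary labels
#'
#' The rank (Mann-Whitney) identity: the probability that a random positive
#' outranks a random negative, ties counted one half.
#'
#' @param scores Numeric vector.
#' @param labels Logical vector (`TRUE` = positive), same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    abort("degenerate AUROC: need >= 1 positive and >= 1 negative")
  rk <- rank(scores)
  (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Pairwise AUROC of a proximity matrix against a positive pair set
#'
#' The probability that a uniformly chosen positive pair has higher proximity
#' than a uniformly chosen negative pair, ties counted one half
#' (the Mann-Whitney / rank identity). Negative pairs are all other unordered
#' pairs within the restriction universe; the restriction defaults to
#' proteins present both in the proximity matrix and in the positive set.
#'
#' @param prox Proximity matrix.
#' @param positives Pair tibble (`protein_a`, `protein_b`).
#' @param restriction Optional character vector of protein ids delimiting the
#'   pair universe.
#' @return AUROC in `[0, 1]`.
#' @export
pair_auroc <- function(prox, positives, restriction = NULL) {
  ids <- rownames(prox)
  restriction <- restriction %||%
    intersect(ids, unique(c(positives$protein_a, positives$protein_b)))
  restriction <- intersect(ids, restriction)
  if (length(restriction) < 2) abort("restriction leaves < 2 proteins")
  P <- prox[restriction, restriction, drop = FALSE]
  pairs <- all_pairs(P)
  pos_keys <- pair_keys(positives$protein_a, positives$protein_b)
  lab <- pair_keys(pairs$protein_a, pairs$protein_b) %in% pos_keys
  auroc_scores(pairs$score, lab)
}

#' Recover annotation terms from protein proximities
#'
#' For each term, compares the proximities of all within-term protein pairs
#' to a null distribution -- all pairs among proteins assigned to the root
#' only (i.e. in no term) -- with a one-sided (greater) Wilcoxon rank-sum
#' test, then applies Benjamini-Hochberg correction across terms. A term is
#' recovered when its adjusted p-value is below `fdr`.
#'
#' @param prox Proximity matrix.
#' @param terms Named list: term id -> character vector of member proteins.
#'   Terms with fewer than 2 members inside the proximity universe are
#'   excluded from testing.
#' @param fdr FDR threshold (default 0.01, i.e. < 1% FDR).
#' @return Tibble `term`, `n_members`, `n_pairs`, `p_value`, `adj_p`,
#'   `recovered`, sorted by `p_value`.
#' @export
term_recovery <- function(prox, terms, fdr = 0.01) {
  ids <- rownames(prox)
  members <- lapply(terms, function(m) intersect(m, ids))
  root_only <- setdiff(ids, unique(unlist(members)))
  if (length(root_only) < 2)
    abort("empty null: no pairs among root-only proteins")
  null_vals <- prox[root_only, root_only][upper.tri(diag(length(root_only)))]
  tested <- names(members)[vapply(members, length, 1L) >= 2]
  if (length(tested) == 0)
    return(tibble::tibble(term = character(), n_members = integer(),
                          n_pairs = integer(), p_value = numeric(),
                          adj_p = numeric(), recovered = logical()))
  rows <- purrr::map(tested, function(tm) {
    ms <- members[[tm]]
    vals <- prox[ms, ms][upper.tri(diag(length(ms)))]
    p <- suppressWarnings(
      wilcox.test(vals, null_vals, alternative = "greater")$p.value)
    tibble::tibble(term = tm, n_members = length(ms),
                   n_pairs = length(vals), p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  out$adj_p <- p.adjust(out$p_value, method = "BH")
  out$recovered <- out$adj_p < fdr
  dplyr::arrange(out, .data$p_value)
}

#' Read / write two-column pair-set files
#'
#' @param path TSV with header and two protein-id columns.
#' @return Pair tibble with `protein_a < protein_b`, deduplicated,
#'   self-pairs dropped.
#' @export
read_pair_set <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  if (ncol(raw) < 2) abort("pair set needs 2 columns")
  a <- pmin(raw[[1]], raw[[2]]); b <- pmax(raw[[1]], raw[[2]])
  keep <- a != b
  dplyr::distinct(tibble::tibble(protein_a = a[keep], protein_b = b[keep])) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' @rdname read_pair_set
#' @param pairs Pair tibble.
#' @export
write_pair_set <- function(pairs, path) {
  readr::write_tsv(pairs[, c("protein_a", "protein_b")], path, progress = FALSE)
  invisible(path)
}

#' Read / write GMT term collections
#'
#' GMT: one term per line, tab-separated `term  description  member1 ...`.
#'
#' @param path GMT file path.
#' @return Named list term id -> character vector of members.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) abort("malformed GMT line (need term, description, members)")
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param terms Named list of member vectors.
#' @param descriptions Optional character vector of term descriptions.
#' @export
write_gmt <- function(terms, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(terms))
  lines <- vapply(seq_along(terms), function(i)
    paste(c(names(terms)[i], descriptions[i], terms[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
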