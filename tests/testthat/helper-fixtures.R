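# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# small random feature tibble
random_features <- function(ids, d, seed = 1, modality = "m") {
  set.seed(seed)
  X <- matrix(rnorm(length(ids) * d), length(ids), d)
  colnames(X) <- paste0("V", seq_len(d))
  coembed:::new_feature_table(
    dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(X)),
    modality)
}

# two disconnected cliques of size `m` each, unit scores
two_clique_network <- function(m = 10) {
  ids1 <- sprintf("A%02d", seq_len(m))
  ids2 <- sprintf("B%02d", seq_len(m))
  clique <- function(ids) {
    idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
    tibble::tibble(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]],
                   score = 1)
  }
  dplyr::bind_rows(clique(ids1), clique(ids2))
}

# tiny two-modality training problem with partial overlap
tiny_problem <- function(n = 24, d1 = 6, d2 = 8, seed = 5) {
  ids <- sprintf("P%02d", seq_len(n))
  f1 <- random_features(ids[1:(n - 4)], d1, seed = seed, modality = "a")
  f2 <- random_features(ids[5:n], d2, seed = seed + 1, modality = "b")
  list(a = f1, b = f2)
}
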