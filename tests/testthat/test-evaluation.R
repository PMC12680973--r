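test_that("proximity matches hand-computed cosine similarities", {
  X <- rbind(P1 = c(1, 0, 0), P2 = c(1, 1, 0), P3 = c(0, 0, 2))
  P <- proximity(X)
  expect_equal(P["P1", "P2"], 1 / sqrt(2))
  expect_equal(P["P1", "P3"], 0)
  expect_equal(P["P2", "P3"], 0)
  expect_equal(diag(P), c(P1 = 1, P2 = 1, P3 = 1))
  expect_equal(P, t(P))
  expect_error(proximity(rbind(P1 = c(0, 0))), "P1")
})

test_that("top-fraction pair extraction uses ceil counts and lexicographic ties", {
  set.seed(8)
  X <- matrix(rnorm(20 * 4), 20, 4,
              dimnames = list(sprintf("P%02d", 1:20), NULL))
  P <- proximity(X)
  # n = 20 -> 190 pairs; 1% -> ceil(1.9) = 2
  expect_equal(nrow(top_fraction_pairs(P, 0.01)), 2)
  expect_equal(nrow(top_fraction_pairs(P, 0.999)), 190)
  # all-tied scores: first k pairs in lexicographic order
  Q <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  got <- top_fraction_pairs(Q, 0.5)   # ceil(3) of 6 pairs
  expect_equal(got$protein_a, c("A", "A", "A"))
  expect_equal(got$protein_b, c("B", "C", "D"))
  # nesting: smaller fractions are subsets of larger ones
  k1 <- top_fraction_pairs(P, 0.05); k2 <- top_fraction_pairs(P, 0.2)
  keys <- function(p) paste(p$protein_a, p$protein_b)
  expect_true(all(keys(k1) %in% keys(k2)))
})

test_that("correlation-derived pairs rank identical columns first", {
  set.seed(9)
  M <- matrix(rnorm(30), 10, 3)
  M <- cbind(M, M[, 1])   # duplicate of column 1
  colnames(M) <- c("A", "B", "C", "D")
  pr <- correlation_pairs(M, fraction = 0.17)   # ceil(1.02) = 2 of 6
  expect_true(any(pr$protein_a == "A" & pr$protein_b == "D"))
  # anti-correlated pair ranks last
  M2 <- cbind(M[, 1:3], -M[, 1]); colnames(M2) <- c("A", "B", "C", "D")
  pr2 <- correlation_pairs(M2, fraction = 0.99)
  full <- proximity  # silence lints
  expect_false(any(pr2$protein_a == "A" & pr2$protein_b == "D" &
                     pr2$score > 0))
  # hand-checked correlation values
  pr3 <- correlation_pairs(M, fraction = 0.9)
  want <- cor(M)[cbind(pr3$protein_a, pr3$protein_b)]
  expect_equal(pr3$score, want)
  expect_warning(correlation_pairs(cbind(M, E = rep(1, 10)), 0.5), "constant")
  expect_error(correlation_pairs(M[1:2, ], 0.5), "3 samples")
})

test_that("pair AUROC equals the brute-force pairwise comparison", {
  # 8 proteins, hand-labelled 3 positive / lots of negative pairs is
  # awkward to stage through a matrix; instead stage scores directly on a
  # 5-protein universe: 10 pairs, 3 positives.
  ids <- paste0("P", 1:5)
  S <- matrix(0, 5, 5, dimnames = list(ids, ids))
  scores <- c(0.9, 0.8, 0.8, 0.7, 0.5, 0.5, 0.5, 0.3, 0.2, 0.1)
  S[upper.tri(S)] <- scores
  S <- S + t(S); diag(S) <- 1
  pos <- tibble::tibble(protein_a = c("P1", "P1", "P2"),
                        protein_b = c("P2", "P3", "P4"))
  got <- pair_auroc(S, pos, restriction = ids)
  # brute force over all pos x neg comparisons, ties count 1/2
  pairs <- coembed:::all_pairs(S)
  lab <- coembed:::pair_keys(pairs$protein_a, pairs$protein_b) %in%
    coembed:::pair_keys(pos$protein_a, pos$protein_b)
  brute <- mean(outer(pairs$score[lab], pairs$score[!lab],
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(got, brute)
})

test_that("pair AUROC hits 1 for perfect separation and 0.5 for all ties", {
  ids <- paste0("P", 1:6)
  S <- matrix(0.2, 6, 6, dimnames = list(ids, ids))
  pos <- tibble::tibble(protein_a = c("P1", "P2"), protein_b = c("P2", "P3"))
  S["P1", "P2"] <- S["P2", "P1"] <- 0.9
  S["P2", "P3"] <- S["P3", "P2"] <- 0.8
  diag(S) <- 1
  expect_equal(pair_auroc(S, pos, restriction = ids), 1)
  Sflat <- matrix(0.4, 6, 6, dimnames = list(ids, ids)); diag(Sflat) <- 1
  expect_equal(pair_auroc(Sflat, pos, restriction = ids), 0.5)
  expect_error(pair_auroc(Sflat, tibble::tibble(protein_a = character(),
                                                protein_b = character()),
                          restriction = ids), "degenerate|positive")
})

test_that("pair AUROC is invariant under strictly monotone score transforms", {
  set.seed(10)
  X <- matrix(rnorm(15 * 4), 15, 4,
              dimnames = list(sprintf("P%02d", 1:15), NULL))
  P <- proximity(X)
  pos <- top_fraction_pairs(P, 0.1)[, 1:2]
  a1 <- pair_auroc(P, pos, restriction = rownames(P))
  Q <- tanh(3 * P); diag(Q) <- 1
  expect_equal(pair_auroc(Q, pos, restriction = rownames(P)), a1)
})

test_that("term recovery separates coherent terms from null-like ones", {
  set.seed(12)
  # block world: proteins in T1 mutually similar, the rest orthogonal-ish
  n <- 40
  ids <- sprintf("P%02d", 1:n)
  base <- matrix(rnorm(n * 30, sd = 0.4), n, 30)
  base[1:8, ] <- base[1:8, ] + matrix(rep(rnorm(30), each = 8), 8, 30)
  rownames(base) <- ids
  P <- proximity(base)
  terms <- list(T1 = ids[1:8], T2 = ids[9:16], tiny = ids[17])
  out <- term_recovery(P, terms, fdr = 0.01)
  expect_false("tiny" %in% out$term)   # < 2 members excluded
  expect_true(out$recovered[out$term == "T1"])
  expect_false(out$recovered[out$term == "T2"])
  expect_true(all(out$adj_p >= out$p_value))
  expect_error(term_recovery(P, list(all = ids)), "null")
})

test_that("pair sets and GMT collections round-trip through disk", {
  pairs <- tibble::tibble(protein_a = c("A", "B"), protein_b = c("C", "A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_set(read_pair_set(write_pair_set(pairs, path)), path)
  got <- read_pair_set(path)
  expect_equal(got$protein_a, c("A", "A"))
  expect_equal(got$protein_b, c("B", "C"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  terms <- list(T1 = c("A", "B", "C"), T2 = c("D", "E"))
  write_gmt(terms, gmt)
  expect_equal(read_gmt(gmt), terms)
})
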