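make_prox <- function(n, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(sprintf("P%03d", 1:n), NULL))
  proximity(X)
}

test_that("proximity thresholding yields the expected network series", {
  P <- make_prox(100)
  nets <- threshold_networks(P)
  expect_length(nets, 6)
  # n = 100 -> 4950 pairs; 5% -> ceil(247.5) = 248 edges
  expect_equal(nrow(nets[["5pct"]]), 248)
  # non-decreasing edge counts, and nesting across fractions
  counts <- vapply(nets, nrow, 1L)
  expect_true(all(diff(counts) >= 0))
  keys <- function(p) paste(p$protein_a, p$protein_b)
  expect_true(all(keys(nets[["0.2pct"]]) %in% keys(nets[["5pct"]])))
  # edge score is the proximity value
  e <- nets[["1pct"]][1, ]
  expect_equal(e$score, P[e$protein_a, e$protein_b])
})

test_that("community detection parses a stubbed detector's tables", {
  P <- make_prox(20)
  nets <- threshold_networks(P, c(0.05, 0.2))
  stub <- function(networks, persistence, maxres) {
    expect_equal(persistence, 10)
    expect_equal(maxres, 80)
    list(nodes = tibble::tibble(
           name = c("Cluster0-0", "Cluster1-0"),
           members = list(sprintf("P%03d", 1:10), sprintf("P%03d", 11:16))),
         edges = tibble::tibble(parent = "Cluster0-0", child = "Cluster1-0"))
  }
  asm <- run_community_detection(nets, persistence = 10, maxres = 80,
                                 detector = stub)
  expect_equal(nrow(asm), 2)
  expect_equal(asm$n_members, c(10L, 6L))
  expect_equal(asm$parent_id, c(NA, "Cluster0-0"))
  expect_equal(asm$members[[2]], sprintf("P%03d", 11:16))
  # empty output -> empty assembly list with a warning
  empty_stub <- function(networks, persistence, maxres)
    list(nodes = tibble::tibble(name = character(), members = list()))
  expect_warning(asm0 <- run_community_detection(nets, detector = empty_stub),
                 "empty")
  expect_equal(nrow(asm0), 0)
})

test_that("a missing detector executable raises an actionable error", {
  P <- make_prox(10)
  nets <- threshold_networks(P, 0.2)
  expect_error(
    run_community_detection(nets, detector = "/nonexistent/hidef_finder.py"),
    "install")
})

test_that("assembly support distinguishes supported/unsupported/undefined", {
  set.seed(21)
  ids <- sprintf("P%03d", 1:60)
  centro <- rnorm(12)
  # modality a: proteins 1-10 coherent; modality b: random; modality c:
  # coherent as well but covers only one assembly protein
  mk <- function(rows, coherent, seed) {
    set.seed(seed)
    X <- matrix(rnorm(length(rows) * 12, sd = 1), length(rows), 12)
    if (length(coherent) > 0) {
      ci <- match(coherent, rows)
      X[ci, ] <- matrix(rep(centro, each = length(ci)), length(ci), 12) +
        matrix(rnorm(length(ci) * 12, sd = 0.15), length(ci), 12)
    }
    colnames(X) <- paste0("V", 1:12)
    coembed:::new_feature_table(
      dplyr::bind_cols(tibble::tibble(protein_id = rows), tibble::as_tibble(X)),
      "x")
  }
  asm <- tibble::tibble(assembly_id = "A1", parent_id = NA_character_,
                        n_members = 10L, members = list(ids[1:10]))
  feats <- list(a = mk(ids, ids[1:10], 1),
                b = mk(ids, character(), 2),
                c = mk(c(ids[1], ids[30:60]), ids[1], 3))
  sup <- assembly_support(asm, feats, fdr = 0.01)
  expect_equal(sup$support[sup$modality == "a"], "supported")
  expect_equal(sup$support[sup$modality == "b"], "unsupported")
  expect_equal(sup$support[sup$modality == "c"], "undefined")
  # invariant to protein ordering inside the assembly
  asm2 <- asm; asm2$members <- list(rev(ids[1:10]))
  expect_equal(assembly_support(asm2, feats, fdr = 0.01)$support, sup$support)
})

test_that("random assemblies are rarely called supported at 1% FDR", {
  set.seed(31)
  ids <- sprintf("P%03d", 1:80)
  X <- matrix(rnorm(80 * 10), 80, 10, dimnames = list(ids, NULL))
  colnames(X) <- paste0("V", 1:10)
  feats <- list(a = coembed:::new_feature_table(
    dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(X)),
    "a"))
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    members <- sample(ids, 8)
    asm <- tibble::tibble(assembly_id = "A", parent_id = NA_character_,
                          n_members = 8L, members = list(members))
    sup <- assembly_support(asm, feats, fdr = 0.01,
                            root_only = setdiff(ids, members))
    hits <- hits + (sup$support == "supported")
  }
  expect_lte(hits / reps, 0.05)
})

test_that("hypergeometric term overlap matches exact tail enumeration", {
  # overlap 3 between assembly of 10 and term of 10 in universe 100
  asm <- tibble::tibble(assembly_id = "A", parent_id = NA_character_,
                        n_members = 10L,
                        members = list(sprintf("P%03d", 1:10)))
  terms <- list(T1 = c(sprintf("P%03d", 8:10), sprintf("Q%03d", 1:7)))
  res <- term_overlap(asm, terms, universe_size = 100)
  # oracle: sum of choose() products over the upper tail
  tail_p <- sum(vapply(3:10, function(k)
    choose(10, k) * choose(90, 10 - k) / choose(100, 10), 1))
  expect_equal(res$p_value, tail_p, tolerance = 1e-12)
  expect_equal(res$n_overlap, 3L)
  expect_equal(res$jaccard, 3 / 17)
})

test_that("the known-assembly flag requires BOTH small FDR and Jaccard > 0.2", {
  ids <- sprintf("P%03d", 1:1000)
  asm <- tibble::tibble(assembly_id = c("exact", "lowjac"),
                        parent_id = NA_character_,
                        n_members = c(10L, 40L),
                        members = list(ids[1:10], ids[1:40]))
  terms <- list(T1 = ids[1:10])
  res <- term_overlap(asm, terms, universe_size = 1000)
  exact <- res[res$assembly_id == "exact", ]
  expect_equal(exact$jaccard, 1)
  expect_true(exact$flagged)
  expect_lt(exact$p_value, 1e-15)
  # full containment of the term but Jaccard 10/40 = 0.25 > 0.2 ... shrink:
  asm2 <- tibble::tibble(assembly_id = "big", parent_id = NA_character_,
                         n_members = 80L, members = list(ids[1:80]))
  res2 <- term_overlap(asm2, terms, universe_size = 1000)
  expect_lt(res2$p_value, 1e-10)
  expect_equal(res2$jaccard, 10 / 80)
  expect_false(res2$flagged)   # tiny p but Jaccard 0.125 <= 0.2
})
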