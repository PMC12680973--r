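test_that("batching chunks a seeded permutation of the universe", {
  ids <- sprintf("P%03d", 1:130)
  b <- make_batches(ids, 64, seed = 4)
  expect_equal(lengths(b), c(64L, 64L, 2L))
  expect_setequal(unlist(b), ids)
  expect_identical(make_batches(ids, 64, seed = 4), b)
  expect_false(identical(make_batches(ids, 64, seed = 5), b))
  expect_error(make_batches(ids, 1))
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(1)
  n <- 7
  Xs <- list(
    a = matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("P", 1:n), NULL)),
    b = matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("P", 3:7), NULL)))
  cfg <- coembed_config(latent_dim = 4, dropout = 0, epochs = 1,
                        batch_size = 8, seed = 2, margin = 0.3, lambda = 0.4)
  streams0 <- coembed:::new_streams(2, c("init"))
  model <- init_model(c(a = 5L, b = 6L), cfg, streams0)
  batch <- paste0("P", 1:n)
  loss_at <- function(params) {
    st <- coembed:::new_streams(77, c("partner", "negatives", "dropout"))
    coembed:::train_step(params, cfg, st, Xs, batch,
                         coembed:::adam_new(params))
  }
  base <- loss_at(model$params)
  eps <- 1e-6
  set.seed(3)
  for (m in c("a", "b")) for (part in c("enc", "dec")) {
    for (l in c("l1", "l2", "l3")) for (w in c("W", "b")) {
      P <- model$params
      arr <- P[[m]][[part]][[l]][[w]]
      for (i in sample(length(arr), min(3, length(arr)))) {
        Pp <- P; Pp[[m]][[part]][[l]][[w]][i] <- arr[i] + eps
        Pm <- P; Pm[[m]][[part]][[l]][[w]][i] <- arr[i] - eps
        num <- (loss_at(Pp)$L - loss_at(Pm)$L) / (2 * eps)
        ana <- base$grads[[m]][[part]][[l]][[w]][i]
        expect_equal(ana, num, tolerance = 1e-4)
      }
    }
  }
})

test_that("per-batch losses satisfy the affine combination identity", {
  prob <- tiny_problem()
  cfg <- coembed_config(latent_dim = 6, dropout = 0.2, epochs = 3,
                        batch_size = 8, seed = 6, lambda = 0.3)
  fit <- coembed(prob, cfg)
  h <- fit$history
  expect_equal(nrow(h), 3 * 3)    # 24 proteins / batch 8 -> 3 batches/epoch
  expect_equal(h$L, 0.3 * h$R + 0.7 * h$T, tolerance = 1e-6)
  expect_true(all(h$R >= 0) && all(h$T >= 0))
})

test_that("training is bitwise deterministic given the config seed", {
  prob <- tiny_problem()
  cfg <- coembed_config(latent_dim = 6, dropout = 0.5, epochs = 2,
                        batch_size = 8, seed = 11)
  f1 <- coembed(prob, cfg)
  f2 <- coembed(prob, cfg)
  expect_identical(f1$history[, c("epoch", "batch", "R", "T", "L")],
                   f2$history[, c("epoch", "batch", "R", "T", "L")])
  expect_identical(f1$unified, f2$unified)
  expect_identical(f1$latents, f2$latents)
  f3 <- coembed(prob, coembed_config(latent_dim = 6, dropout = 0.5,
                                     epochs = 2, batch_size = 8, seed = 12))
  expect_false(identical(f1$unified, f3$unified))
})

test_that("lambda = 1 silences the triplet gradient", {
  prob <- tiny_problem()
  base <- coembed_config(latent_dim = 6, dropout = 0, epochs = 2,
                         batch_size = 8, seed = 13, lambda = 1)
  f1 <- coembed(prob, base)
  # T is still reported but must not influence parameters: a run with a
  # different margin (which only changes T) yields identical parameters
  alt <- base; alt$margin <- 0.9
  f2 <- coembed(prob, alt)
  expect_identical(f1$model$params, f2$model$params)
  expect_false(identical(f1$history$T, f2$history$T))
})

test_that("training recovers planted communities in the unified space", {
  w <- plant_world(200, 8, seed = 21)
  fa <- feature_view(w, dim = 10, sigma = 0.2, coverage = 1, seed = 22,
                     modality = "a")
  fb <- feature_view(w, dim = 12, sigma = 0.2, coverage = 1, seed = 23,
                     modality = "b")
  cfg <- coembed_config(latent_dim = 16, epochs = 50, batch_size = 32,
                        seed = 24, learning_rate = 1e-3)
  fit <- coembed(list(a = fa, b = fb), cfg)
  h <- tidy(fit)
  expect_lt(h$L[nrow(h)], h$L[1])
  # within-community unified similarity should exceed between-community
  P <- proximity(fit$unified)
  comm <- setNames(w$assignment$community, w$assignment$protein_id)
  same <- outer(comm[rownames(P)], comm[colnames(P)], "==")
  ut <- upper.tri(P)
  wt <- suppressWarnings(wilcox.test(P[same & ut], P[!same & ut],
                                     alternative = "greater"))
  expect_lt(wt$p.value, 0.01)
})

test_that("missing-modality proteins still receive unified embeddings", {
  w <- plant_world(60, 3, seed = 31)
  fa <- feature_view(w, dim = 8, sigma = 0.3, coverage = 0.7, seed = 32,
                     modality = "a")
  fb <- feature_view(w, dim = 8, sigma = 0.3, coverage = 0.7, seed = 33,
                     modality = "b")
  feats <- list(a = fa, b = fb)
  fit <- coembed(feats, coembed_config(latent_dim = 8, epochs = 3,
                                       batch_size = 16, seed = 34))
  u <- unified_embedding(fit)
  expect_setequal(u$protein_id, union(fa$protein_id, fb$protein_id))
  # single-modality proteins: unified row equals the single latent row
  only_a <- setdiff(fa$protein_id, fb$protein_id)
  expect_gt(length(only_a), 0)
  expect_equal(fit$unified[only_a, ], fit$latents$a[only_a, ],
               ignore_attr = TRUE)
  expect_equal(unname(attr(fit$unified, "n_modalities")[only_a]),
               rep(1L, length(only_a)))
})

test_that("re-export writes identical embedding files", {
  prob <- tiny_problem()
  fit <- coembed(prob, coembed_config(latent_dim = 4, epochs = 2,
                                      batch_size = 8, seed = 41))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- export_embeddings(fit, d1)
  p2 <- export_embeddings(fit, d2)
  for (nm in names(p1))
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  u <- readr::read_tsv(p1[["unified"]], show_col_types = FALSE)
  expect_equal(nrow(u), length(fit$universe$ids))
})

test_that("training refuses problems where the triplet loss is undefined", {
  f1 <- random_features(c("A1", "A2", "A3"), 4, seed = 1, modality = "a")
  f2 <- random_features(c("B1", "B2", "B3"), 4, seed = 2, modality = "b")
  expect_error(coembed(list(a = f1, b = f2)), "triplet loss undefined")
})

test_that("checkpoints round-trip parameters and config", {
  skip_if_not_installed("jsonlite")
  prob <- tiny_problem()
  fit <- coembed(prob, coembed_config(latent_dim = 4, epochs = 1,
                                      batch_size = 8, seed = 51))
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(fit$model, path)
  back <- read_checkpoint(path)
  expect_equal(back$params, fit$model$params, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$config$latent_dim, 4L)
  X <- coembed:::feature_matrix(prob$a)
  expect_equal(coembed_encode(back, "a", X), coembed_encode(fit$model, "a", X),
               tolerance = 1e-12)
})
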