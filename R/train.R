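# Training orchestration: batching over the union universe, per-batch
# cross-modal reconstruction + triplet gradients, Adam updates, and export of
# per-modality and unified embeddings. All gradients are computed analytically
# (verified against numerical differentiation in the test suite).

#' Chunk the protein universe into training batches
#'
#' A seeded random permutation of the ids chunked into `batch_size` pieces;
#' the last batch may be short. Within a batch, each modality later
#' contributes only the proteins it covers.
#'
#' @param ids Character vector of protein ids.
#' @param batch_size Proteins per batch (>= 2).
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return List of character vectors.
#' @export
make_batches <- function(ids, batch_size, seed = NULL) {
  stopifnot(batch_size >= 2)
  perm <- if (is.null(seed)) sample(ids) else {
    st <- new_streams(seed, "batch")
    with_stream(st, "batch", sample(ids))
  }
  unname(split(perm, ceiling(seq_along(perm) / batch_size)))
}

tree_zero <- function(p) rapply(p, function(x) x * 0, how = "replace")
tree_add <- function(a, b) {
  if (is.list(a)) Map(tree_add, a, b) else a + b
}

adam_new <- function(params) {
  e <- new.env(parent = emptyenv())
  e$t <- 0L
  e$m <- tree_zero(params)
  e$v <- tree_zero(params)
  e
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  c1 <- 1 - beta1^opt$t
  c2 <- 1 - beta2^opt$t
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      r <- Map(rec, p, g, m, v)
      list(p = lapply(r, `[[`, "p"), m = lapply(r, `[[`, "m"),
           v = lapply(r, `[[`, "v"))
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      list(p = p - lr * (m2 / c1) / (sqrt(v2 / c2) + eps), m = m2, v = v2)
    }
  }
  r <- rec(params, grads, opt$m, opt$v)
  opt$m <- r$m
  opt$v <- r$v
  r$p
}

# gradient of mean-over-rows cosine distance w.r.t. Y, times `coef`
cosdist_grad_y <- function(X, Y, coef) {
  nx <- pmax(sqrt(rowSums(X^2)), 1e-12)
  ny <- pmax(sqrt(rowSums(Y^2)), 1e-12)
  dot <- rowSums(X * Y)
  -coef * (X / (nx * ny) - Y * (dot / (nx * ny^3)))
}

# one optimization step on a batch; returns updated params + loss components
train_step <- function(params, config, streams, Xs, batch, opt) {
  mods <- names(params)
  lam <- config$lambda
  rate <- config$dropout
  rows <- lapply(mods, function(m) batch[batch %in% rownames(Xs[[m]])])
  names(rows) <- mods
  active <- mods[vapply(rows, length, 1L) > 0]

  caches <- with_stream(streams, "dropout", {
    lapply(setNames(active, active), function(m)
      enc_forward(params[[m]], Xs[[m]][rows[[m]], , drop = FALSE], rate, TRUE))
  })
  Z <- lapply(caches, `[[`, "Z")
  grads <- tree_zero(params)
  dZ <- lapply(setNames(active, active),
               function(m) matrix(0, length(rows[[m]]), config$latent_dim))

  # reconstruction over all ordered pairs (a, b), a == b included
  R_pairs <- numeric(0)
  with_stream(streams, "dropout", {
    for (a in active) for (b in active) {
      shared <- intersect(rows[[a]], rows[[b]])
      key <- paste0(a, "->", b)
      if (length(shared) == 0) { R_pairs[key] <- 0; next }
      ia <- match(shared, rows[[a]])
      ib <- match(shared, rows[[b]])
      dc <- dec_forward(params[[a]], Z[[b]][ib, , drop = FALSE], rate, TRUE)
      Xt <- Xs[[a]][shared, , drop = FALSE]
      R_pairs[key] <- mean(row_cosine_distance(Xt, dc$Y))
      if (lam > 0) {
        dY <- cosdist_grad_y(Xt, dc$Y, lam / length(shared))
        bk <- dec_backward(params[[a]], dc, dY)
        grads[[a]]$dec <- tree_add(grads[[a]]$dec, bk$grads)
        dZ[[b]][ib, ] <- dZ[[b]][ib, , drop = FALSE] + bk$dZ
      }
    }
  })
  R_total <- sum(R_pairs)

  # triplet: one random partner modality per anchor modality, negatives
  # resampled uniformly (k != i) within the batch's shared set
  T_mods <- setNames(numeric(length(active)), active)
  if (length(active) >= 2) {
    partners <- with_stream(streams, "partner", {
      vapply(active, function(a) {
        others <- setdiff(active, a)
        others[sample.int(length(others), 1L)]
      }, character(1))
    })
    for (a in active) {
      b <- partners[[a]]
      shared <- intersect(rows[[a]], rows[[b]])
      n <- length(shared)
      if (n < 2) { T_mods[a] <- 0; next }
      ia <- match(shared, rows[[a]])
      ib <- match(shared, rows[[b]])
      k <- with_stream(streams, "negatives", {
        k <- sample.int(n, n, replace = TRUE)
        bad <- which(k == seq_len(n))
        while (length(bad) > 0) {
          k[bad] <- sample.int(n, length(bad), replace = TRUE)
          bad <- bad[k[bad] == bad]
        }
        k
      })
      Za <- Z[[a]][ia, , drop = FALSE]
      Zb <- Z[[b]][ib, , drop = FALSE]
      Zn <- Zb[k, , drop = FALSE]
      t_i <- (1 - rowSums(Za * Zb)) - (1 - rowSums(Za * Zn)) + config$margin
      T_mods[a] <- mean(pmax(t_i, 0))
      act <- which(t_i > 0)
      coef <- (1 - lam) / n
      if (coef > 0 && length(act) > 0) {
        dZ[[a]][ia[act], ] <- dZ[[a]][ia[act], , drop = FALSE] +
          coef * (Zn[act, , drop = FALSE] - Zb[act, , drop = FALSE])
        dZ[[b]][ib[act], ] <- dZ[[b]][ib[act], , drop = FALSE] -
          coef * Za[act, , drop = FALSE]
        agg <- rowsum(coef * Za[act, , drop = FALSE], group = k[act])
        tgt <- ib[as.integer(rownames(agg))]
        dZ[[b]][tgt, ] <- dZ[[b]][tgt, , drop = FALSE] + agg
      }
    }
  }
  T_total <- sum(T_mods)

  for (m in active)
    grads[[m]]$enc <- tree_add(grads[[m]]$enc,
                               enc_backward(params[[m]], caches[[m]], dZ[[m]]))

  params <- adam_step(opt, params, grads, config$learning_rate)
  list(params = params, grads = grads,
       R = R_total, T = T_total,
       L = combine_losses(R_total, T_total, lam),
       R_pairs = R_pairs, T_mods = T_mods)
}

#' Fit the multi-modal co-embedding model
#'
#' Trains one encoder/decoder pair per modality so that (i) every modality's
#' features can be reconstructed from every other modality's latent
#' (cross-modal cosine reconstruction loss, summed over all ordered modality
#' pairs including self-pairs) and (ii) the same protein's latents across
#' modalities are closer than latents of different proteins (cross-modal
#' triplet loss with margin). Proteins missing from a modality are simply
#' excluded from that modality's forward pass, so arbitrary coverage patterns
#' train. Fully deterministic given `config$seed` (single-threaded).
#'
#' @param features Named list of >= 2 feature tibbles (see
#'   [read_feature_table()], [node2vec_featurize()]).
#' @param config A [coembed_config()].
#' @param verbose Print per-epoch loss lines.
#' @return A `coembed_fit` with elements `model`, `config`, `history`
#'   (per-batch tibble: epoch, batch, R, T, L), `universe`, `latents` (named
#'   list of eval-mode latent matrices) and `unified` (universe x latent_dim
#'   matrix).
#' @export
coembed <- function(features, config = coembed_config(), verbose = FALSE) {
  if (length(features) < 2) abort("need >= 2 modalities")
  universe <- build_universe(features)
  Xs <- lapply(features, feature_matrix)
  mods <- names(Xs)
  overlaps <- utils::combn(mods, 2, function(p)
    length(intersect(rownames(Xs[[p[1]]]), rownames(Xs[[p[2]]]))), simplify = TRUE)
  if (max(overlaps) < 2)
    abort("triplet loss undefined: no modality pair shares >= 2 proteins")

  streams <- new_streams(config$seed,
                         c("init", "batch", "partner", "negatives", "dropout"))
  model <- init_model(vapply(Xs, ncol, 1L), config, streams)
  params <- model$params
  opt <- adam_new(params)

  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    batches <- with_stream(streams, "batch",
                           make_batches(universe$ids, config$batch_size))
    recs <- vector("list", length(batches))
    for (bi in seq_along(batches)) {
      st <- train_step(params, config, streams, Xs, batches[[bi]], opt)
      params <- st$params
      recs[[bi]] <- tibble::tibble(
        epoch = ep, batch = bi, R = st$R, T = st$T, L = st$L,
        R_pairs = list(st$R_pairs), T_mods = list(st$T_mods))
    }
    hist[[ep]] <- dplyr::bind_rows(recs)
    if (verbose) {
      h <- hist[[ep]]
      message(sprintf("epoch %3d  R %.4f  T %.4f  L %.4f",
                      ep, mean(h$R), mean(h$T), mean(h$L)))
    }
  }
  model$params <- params

  latents <- lapply(setNames(mods, mods),
                    function(m) coembed_encode(model, m, Xs[[m]]))
  unified <- unify_embeddings(latents, universe)
  structure(list(model = model, config = config,
                 history = dplyr::bind_rows(hist),
                 universe = universe, latents = latents, unified = unified),
            class = "coembed_fit")
}

#' @export
print.coembed_fit <- function(x, ...) {
  h <- x$history
  last <- h[h$epoch == max(h$epoch), ]
  cat("<coembed_fit> ", length(x$latents), " modalities, ",
      length(x$universe$ids), " proteins, ", max(h$epoch), " epochs\n",
      "  final epoch: R ", signif(mean(last$R), 4), "  T ",
      signif(mean(last$T), 4), "  L ", signif(mean(last$L), 4), "\n", sep = "")
  invisible(x)
}

#' Unified embedding as a tibble
#' @param fit A `coembed_fit`.
#' @return Tibble `protein_id`, latent columns `V1..`, and `n_modalities`.
#' @export
unified_embedding <- function(fit) {
  u <- fit$unified
  out <- tibble::as_tibble(u, .name_repair = ~ paste0("V", seq_len(ncol(u))))
  dplyr::bind_cols(tibble::tibble(protein_id = rownames(u)), out,
                   tibble::tibble(n_modalities = as.integer(attr(u, "n_modalities"))))
}

#' One modality's latent embedding as a tibble
#' @param fit A `coembed_fit`.
#' @param modality Modality name.
#' @return Feature tibble of unit-norm latent rows.
#' @export
modality_embedding <- function(fit, modality) {
  z <- fit$latents[[modality]]
  if (is.null(z)) abort(paste0("unknown modality: ", modality))
  out <- tibble::as_tibble(z, .name_repair = ~ paste0("V", seq_len(ncol(z))))
  new_feature_table(
    dplyr::bind_cols(tibble::tibble(protein_id = rownames(z)), out), modality)
}

#' Export per-modality and unified embeddings as TSV
#'
#' Re-exporting without retraining writes identical files: the latents are
#' eval-mode encodings fixed at fit time.
#'
#' @param fit A `coembed_fit`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
export_embeddings <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (m in names(fit$latents)) {
    p <- file.path(dir, paste0("latent_", m, ".tsv"))
    write_feature_table(modality_embedding(fit, m), p)
    paths[m] <- p
  }
  p <- file.path(dir, "unified.tsv")
  u <- unified_embedding(fit)
  readr::write_tsv(u[, setdiff(names(u), "n_modalities")], p, progress = FALSE)
  paths["unified"] <- p
  invisible(paths)
}
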