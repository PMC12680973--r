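# Two reference integration strategies the co-embedding is compared against:
# plain feature concatenation (with random fill for missing modalities) and a
# standard concatenating autoencoder trained only on fully covered proteins.

#' Concatenation baseline
#'
#' Horizontally concatenates each protein's per-modality feature vectors over
#' the union universe. When a protein is missing from a modality, that slot
#' is filled with a uniformly sampled existing row of the same modality
#' (seeded, so fills are reproducible).
#'
#' @param features Named list of feature tibbles.
#' @param seed Integer seed for the random fills.
#' @return Feature tibble over the union universe with `sum(d_m)` columns.
#' @export
concat_baseline <- function(features, seed = 1L) {
  universe <- build_universe(features)
  mats <- lapply(features, feature_matrix)
  streams <- new_streams(seed, "fill")
  blocks <- with_stream(streams, "fill", {
    lapply(mats, function(X) {
      out <- matrix(NA_real_, length(universe$ids), ncol(X),
                    dimnames = list(universe$ids, colnames(X)))
      present <- intersect(universe$ids, rownames(X))
      out[present, ] <- X[present, , drop = FALSE]
      missing <- setdiff(universe$ids, present)
      if (length(missing) > 0) {
        fill <- sample.int(nrow(X), length(missing), replace = TRUE)
        out[missing, ] <- X[fill, , drop = FALSE]
      }
      out
    })
  })
  M <- do.call(cbind, blocks)
  colnames(M) <- paste0("V", seq_len(ncol(M)))
  new_feature_table(
    dplyr::bind_cols(tibble::tibble(protein_id = rownames(M)),
                     tibble::as_tibble(M)),
    "concat")
}

#' Standard-autoencoder baseline
#'
#' Trains only on proteins covered by all modalities. Each modality is
#' encoded with one linear layer + ReLU to `latent_dim`, the per-modality
#' codes are concatenated and passed through one more linear layer to a
#' shared `latent_dim` vector, which is decoded back into each modality with
#' a linear layer; the objective is the summed mean-squared reconstruction
#' error. Adam, 50 epochs, batch size 64 by default.
#'
#' @param features Named list of feature tibbles.
#' @param latent_dim Shared latent dimension.
#' @param epochs Training epochs.
#' @param batch_size Proteins per batch.
#' @param learning_rate Adam learning rate.
#' @param seed Integer seed.
#' @return A list with `embedding` (feature tibble of latent vectors for the
#'   fully covered proteins), `history` (tibble `epoch`, `loss`) and the
#'   trained `params`.
#' @export
autoencoder_baseline <- function(features, latent_dim = 128L, epochs = 50L,
                                 batch_size = 64L, learning_rate = 1e-4,
                                 seed = 1L) {
  mats <- lapply(features, feature_matrix)
  mods <- names(mats)
  shared <- Reduce(intersect, lapply(mats, rownames))
  if (length(shared) < 2)
    abort("autoencoder baseline needs >= 2 proteins covered by all modalities")
  Xs <- lapply(mats, function(X) X[shared, , drop = FALSE])
  M <- length(mods)
  streams <- new_streams(seed, c("init", "batch"))
  params <- with_stream(streams, "init", {
    list(enc = lapply(Xs, function(X) init_linear(ncol(X), latent_dim)),
         mid = init_linear(M * latent_dim, latent_dim),
         dec = lapply(Xs, function(X) init_linear(latent_dim, ncol(X))))
  })
  opt <- adam_new(params)

  fwd <- function(params, Xb) {
    A <- lapply(mods, function(m) affine(Xb[[m]], params$enc[[m]]))
    H <- lapply(A, pmax, 0)
    C <- do.call(cbind, H)
    Zl <- affine(C, params$mid)
    Y <- lapply(mods, function(m) affine(Zl, params$dec[[m]]))
    names(Y) <- names(A) <- mods
    list(A = A, C = C, Zl = Zl, Y = Y)
  }

  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    batches <- with_stream(streams, "batch", make_batches(shared, batch_size))
    ep_loss <- 0
    for (batch in batches) {
      Xb <- lapply(Xs, function(X) X[batch, , drop = FALSE])
      f <- fwd(params, Xb)
      n <- length(batch)
      grads <- tree_zero(params)
      dZl <- matrix(0, n, latent_dim)
      loss <- 0
      for (m in mods) {
        E <- f$Y[[m]] - Xb[[m]]
        loss <- loss + mean(E^2)
        dY <- 2 * E / length(E)
        grads$dec[[m]] <- list(W = crossprod(f$Zl, dY), b = colSums(dY))
        dZl <- dZl + dY %*% t(params$dec[[m]]$W)
      }
      grads$mid <- list(W = crossprod(f$C, dZl), b = colSums(dZl))
      dC <- dZl %*% t(params$mid$W)
      for (i in seq_along(mods)) {
        m <- mods[i]
        dH <- dC[, ((i - 1) * latent_dim + 1):(i * latent_dim), drop = FALSE]
        dA <- dH * (f$A[[m]] > 0)
        grads$enc[[m]] <- list(W = crossprod(Xb[[m]], dA), b = colSums(dA))
      }
      params <- adam_step(opt, params, grads, learning_rate)
      ep_loss <- ep_loss + loss * n
    }
    hist[ep] <- ep_loss / length(shared)
  }

  Zl <- fwd(params, Xs)$Zl
  rownames(Zl) <- shared
  colnames(Zl) <- paste0("V", seq_len(latent_dim))
  list(
    embedding = new_feature_table(
      dplyr::bind_cols(tibble::tibble(protein_id = shared),
                       tibble::as_tibble(Zl)),
      "autoencoder"),
    history = tibble::tibble(epoch = seq_len(epochs), loss = hist),
    params = params
  )
}
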