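#' Model configuration
#'
#' Collects the hyperparameters of the co-embedding model. Defaults are the
#' published training settings: 128-dimensional latent space, dropout 0.5,
#' triplet margin 0.2, loss weight lambda 0.5, Adam learning rate 1e-4,
#' batch size 64. The epoch count defaults to 300: with a few hundred
#' proteins an epoch is only a handful of optimizer steps, and at the fixed
#' learning rate the total step budget -- not the data -- limits the fit, so
#' the default is sized for roughly a thousand steps; convergence is visible
#' in the loss log and cheap to extend.
#'
#' Hidden layer widths are derived from each modality's input dimension:
#' `h1 = max(latent_dim, round(d_m / 2))`, `h2 = max(latent_dim, round(d_m / 4))`,
#' a geometric taper that degenerates gracefully for small inputs.
#'
#' @param latent_dim Latent dimension of the shared space.
#' @param dropout Dropout rate in (0, 1) or 0 to disable.
#' @param margin Triplet margin epsilon (> 0).
#' @param lambda Weight of the reconstruction loss in `L = lambda * R +
#'   (1 - lambda) * T`; in `[0, 1]`.
#' @param learning_rate Adam learning rate.
#' @param batch_size Proteins per batch (>= 2).
#' @param epochs Training epochs.
#' @param seed Master seed; all randomness (init, batching, partner choice,
#'   negative sampling, dropout) derives from it through named substreams.
#' @param cross_decode Records the adopted reading of the cross-modal
#'   reconstruction term: decoder of the target modality applied to the
#'   source modality's latent (the only dimensionally consistent one).
#' @return A `coembed_config` list.
#' @export
coembed_config <- function(latent_dim = 128L, dropout = 0.5, margin = 0.2,
                           lambda = 0.5, learning_rate = 1e-4,
                           batch_size = 64L, epochs = 300L, seed = 1L,
                           cross_decode = TRUE) {
  stopifnot(latent_dim >= 2, lambda >= 0, lambda <= 1, margin > 0,
            dropout >= 0, dropout < 1, batch_size >= 2, epochs >= 1)
  structure(list(latent_dim = as.integer(latent_dim), dropout = dropout,
                 margin = margin, lambda = lambda,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 cross_decode = isTRUE(cross_decode)),
            class = "coembed_config")
}

hidden_sizes <- function(d_m, latent_dim) {
  c(h1 = max(latent_dim, round(d_m / 2)), h2 = max(latent_dim, round(d_m / 4)))
}

# Linear layers use the standard uniform fan-in initialization.
init_linear <- function(n_in, n_out) {
  b <- 1 / sqrt(n_in)
  list(W = matrix(runif(n_in * n_out, -b, b), n_in, n_out),
       b = runif(n_out, -b, b))
}

#' Initialize the encoder/decoder bank
#'
#' One encoder and one decoder per modality. The encoder is
#' dropout -> linear(d_m, h1) -> ReLU -> dropout -> linear(h1, h2) -> ReLU ->
#' linear(h2, latent) -> row-wise L2 normalization; the decoder mirrors it
#' without a terminal normalization (reconstructions live in raw feature
#' space): dropout -> linear(latent, h2) -> ReLU -> linear(h2, h1) -> ReLU ->
#' linear(h1, d_m).
#'
#' @param dims Named integer vector: modality name -> input dimension `d_m`.
#' @param config A [coembed_config()].
#' @param streams Optional RNG stream environment (created from
#'   `config$seed` when omitted).
#' @return A `coembed_model` holding per-modality parameter lists.
#' @export
init_model <- function(dims, config = coembed_config(), streams = NULL) {
  stopifnot(length(dims) >= 1, !is.null(names(dims)), all(dims >= 2))
  streams <- streams %||% new_streams(config$seed, "init")
  L <- config$latent_dim
  params <- with_stream(streams, "init", {
    lapply(dims, function(d) {
      h <- hidden_sizes(d, L)
      list(
        enc = list(l1 = init_linear(d, h[["h1"]]),
                   l2 = init_linear(h[["h1"]], h[["h2"]]),
                   l3 = init_linear(h[["h2"]], L)),
        dec = list(l1 = init_linear(L, h[["h2"]]),
                   l2 = init_linear(h[["h2"]], h[["h1"]]),
                   l3 = init_linear(h[["h1"]], d)),
        d_m = as.integer(d), h1 = h[["h1"]], h2 = h[["h2"]]
      )
    })
  })
  structure(list(params = params, config = config), class = "coembed_model")
}

#' @export
print.coembed_model <- function(x, ...) {
  cat("<coembed_model> ", length(x$params), " modalities, latent dim ",
      x$config$latent_dim, "\n", sep = "")
  for (m in names(x$params))
    cat("  ", m, ": d_m=", x$params[[m]]$d_m, " h1=", x$params[[m]]$h1,
        " h2=", x$params[[m]]$h2, "\n", sep = "")
  invisible(x)
}

affine <- function(X, lin) sweep(X %*% lin$W, 2, lin$b, "+")

drop_mask <- function(n, d, rate) {
  if (rate <= 0) return(NULL)
  matrix((runif(n * d) >= rate) / (1 - rate), n, d)
}

apply_drop <- function(X, mask) if (is.null(mask)) X else X * mask

l2norm_rows <- function(A) {
  r <- sqrt(rowSums(A^2))
  if (any(r < 1e-12)) {
    i <- which(r < 1e-12)[1]
    abort(paste0("cannot L2-normalize an (almost) zero vector (row ",
                 rownames(A)[i] %||% i, "); dead encoder output"))
  }
  list(Z = A / r, r = r)
}

# Forward pass through one encoder; returns latent plus the cache needed for
# backprop. Dropout masks are sampled here (train mode only) from the
# caller-managed RNG state.
enc_forward <- function(par, X, rate, train) {
  m0 <- if (train) drop_mask(nrow(X), ncol(X), rate) else NULL
  X0 <- apply_drop(X, m0)
  A1 <- affine(X0, par$enc$l1); H1 <- pmax(A1, 0)
  m1 <- if (train) drop_mask(nrow(H1), ncol(H1), rate) else NULL
  H1d <- apply_drop(H1, m1)
  A2 <- affine(H1d, par$enc$l2); H2 <- pmax(A2, 0)
  A3 <- affine(H2, par$enc$l3)
  rownames(A3) <- rownames(X)
  nz <- l2norm_rows(A3)
  list(Z = nz$Z, r = nz$r, X0 = X0, A1 = A1, H1d = H1d, A2 = A2, H2 = H2,
       m0 = m0, m1 = m1)
}

enc_backward <- function(par, cache, dZ) {
  dA3 <- (dZ - cache$Z * rowSums(dZ * cache$Z)) / cache$r
  g3 <- list(W = crossprod(cache$H2, dA3), b = colSums(dA3))
  dH2 <- dA3 %*% t(par$enc$l3$W)
  dA2 <- dH2 * (cache$A2 > 0)
  g2 <- list(W = crossprod(cache$H1d, dA2), b = colSums(dA2))
  dH1d <- dA2 %*% t(par$enc$l2$W)
  dH1 <- apply_drop(dH1d, cache$m1)
  dA1 <- dH1 * (cache$A1 > 0)
  g1 <- list(W = crossprod(cache$X0, dA1), b = colSums(dA1))
  list(l1 = g1, l2 = g2, l3 = g3)
}

dec_forward <- function(par, Z, rate, train) {
  m0 <- if (train) drop_mask(nrow(Z), ncol(Z), rate) else NULL
  Z0 <- apply_drop(Z, m0)
  B1 <- affine(Z0, par$dec$l1); G1 <- pmax(B1, 0)
  B2 <- affine(G1, par$dec$l2); G2 <- pmax(B2, 0)
  Y <- affine(G2, par$dec$l3)
  rownames(Y) <- rownames(Z)
  list(Y = Y, Z0 = Z0, B1 = B1, G1 = G1, B2 = B2, G2 = G2, m0 = m0)
}

dec_backward <- function(par, cache, dY) {
  g3 <- list(W = crossprod(cache$G2, dY), b = colSums(dY))
  dG2 <- dY %*% t(par$dec$l3$W)
  dB2 <- dG2 * (cache$B2 > 0)
  g2 <- list(W = crossprod(cache$G1, dB2), b = colSums(dB2))
  dG1 <- dB2 %*% t(par$dec$l2$W)
  dB1 <- dG1 * (cache$B1 > 0)
  g1 <- list(W = crossprod(cache$Z0, dB1), b = colSums(dB1))
  dZ0 <- dB1 %*% t(par$dec$l1$W)
  list(grads = list(l1 = g1, l2 = g2, l3 = g3),
       dZ = apply_drop(dZ0, cache$m0))
}

#' Encode a feature matrix into the latent space
#'
#' @param model A `coembed_model`.
#' @param modality Modality name.
#' @param x Feature tibble or numeric matrix with `d_m` columns (rownames or
#'   `protein_id` column carry the protein ids).
#' @param train_mode Apply dropout (training only); default eval mode is
#'   deterministic.
#' @return Matrix of unit-norm latent rows, one per input row.
#' @export
coembed_encode <- function(model, modality, x, train_mode = FALSE) {
  par <- model$params[[modality]]
  if (is.null(par)) abort(paste0("unknown modality: ", modality))
  X <- if (is.data.frame(x)) feature_matrix(x) else x
  if (ncol(X) != par$d_m)
    abort(paste0("dimension mismatch: modality '", modality, "' expects d_m=",
                 par$d_m, ", got ", ncol(X)))
  enc_forward(par, X, model$config$dropout, train_mode)$Z
}

#' Decode latent vectors back to a modality's feature space
#'
#' @inheritParams coembed_encode
#' @param z Matrix with `latent_dim` columns (any modality's latents; cross
#'   decoding through another modality's decoder is the basis of the
#'   cross-modal reconstruction loss).
#' @return Matrix with `d_m` columns of the named modality.
#' @export
coembed_decode <- function(model, modality, z, train_mode = FALSE) {
  par <- model$params[[modality]]
  if (is.null(par)) abort(paste0("unknown modality: ", modality))
  if (ncol(z) != model$config$latent_dim)
    abort(paste0("dimension mismatch: expected latent_dim=",
                 model$config$latent_dim, ", got ", ncol(z)))
  dec_forward(par, z, model$config$dropout, train_mode)$Y
}

#' Average per-modality latents into a unified embedding
#'
#' Each protein's unified coordinate is the element-wise mean of its latent
#' rows over the modalities that cover it; a protein measured by a single
#' modality keeps that modality's latent row exactly. The average is not
#' re-normalized by default: downstream cosine proximity is scale-invariant
#' and the mean of unit vectors preserves direction information.
#'
#' @param latents Named list of latent matrices (rownames = protein ids).
#' @param universe Universe list from [build_universe()] (or any object with
#'   `ids`); defaults to the union of latent rownames.
#' @param renorm Re-normalize unified rows to unit length.
#' @return Matrix universe x latent_dim with attribute `n_modalities`
#'   (integer vector of contributing-modality counts).
#' @export
unify_embeddings <- function(latents, universe = NULL, renorm = FALSE) {
  ids <- if (is.null(universe)) sort(unique(unlist(lapply(latents, rownames))))
         else universe$ids
  L <- ncol(latents[[1]])
  acc <- matrix(0, length(ids), L, dimnames = list(ids, colnames(latents[[1]])))
  cnt <- setNames(integer(length(ids)), ids)
  for (z in latents) {
    idx <- match(rownames(z), ids)
    if (anyNA(idx)) abort("latent rows outside the universe")
    acc[idx, ] <- acc[idx, , drop = FALSE] + z
    cnt[idx] <- cnt[idx] + 1L
  }
  if (any(cnt == 0))
    abort(paste0("protein covered by zero modalities: ", ids[cnt == 0][1]))
  out <- acc / cnt
  if (renorm) out <- l2norm_rows(out)$Z
  attr(out, "n_modalities") <- cnt
  out
}
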