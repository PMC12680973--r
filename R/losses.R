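#' Cosine distance
#'
#' `1 - cosine similarity`, in `[0, 2]`. Errors on (near-)zero vectors.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number.
#' @export
cosine_distance <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) abort("cosine distance undefined for zero vectors")
  1 - sum(u * v) / (nu * nv)
}

# Row-wise cosine distances between two conformable matrices.
row_cosine_distance <- function(X, Y) {
  nx <- sqrt(rowSums(X^2)); ny <- sqrt(rowSums(Y^2))
  if (any(nx < 1e-12) || any(ny < 1e-12))
    abort("cosine distance undefined for zero vectors")
  1 - rowSums(X * Y) / (nx * ny)
}

#' Cross-modal reconstruction loss for one modality pair
#'
#' `R[a,b]` is the mean cosine distance between modality `a`'s original
#' features and the reconstruction obtained by passing modality `b`'s latents
#' through modality `a`'s decoder, over the proteins shared by both
#' modalities.
#'
#' @param x_a Original feature matrix of modality `a` (rows = shared proteins).
#' @param y_ab Reconstructions `g_a(z_b)` for the same rows.
#' @return Mean cosine distance (a single number).
#' @export
reconstruction_loss_pair <- function(x_a, y_ab) {
  if (nrow(x_a) == 0) abort("empty shared protein set for reconstruction pair")
  stopifnot(nrow(x_a) == nrow(y_ab), ncol(x_a) == ncol(y_ab))
  mean(row_cosine_distance(x_a, y_ab))
}

#' Total reconstruction loss over all ordered modality pairs
#'
#' Sums `R[a,b]` over every ordered pair `(a, b)` of modalities including
#' `a == b` (self-reconstruction). Pairs with no shared protein contribute 0.
#' Computed in eval mode (no dropout).
#'
#' @param model A `coembed_model`.
#' @param features Named list of feature tibbles (or matrices), one per
#'   modality in the model.
#' @param proteins Optional protein-id subset (a batch); defaults to all.
#' @return A list with `total` and the per-pair tibble `pairs`
#'   (`modality_a`, `modality_b`, `n_shared`, `loss`).
#' @export
total_reconstruction_loss <- function(model, features, proteins = NULL) {
  mats <- lapply(features, function(f) if (is.data.frame(f)) feature_matrix(f) else f)
  mods <- names(model$params)
  stopifnot(all(mods %in% names(mats)))
  z <- lapply(mods, function(m) {
    rows <- rownames(mats[[m]])
    if (!is.null(proteins)) rows <- rows[rows %in% proteins]
    if (length(rows) == 0) return(NULL)
    coembed_encode(model, m, mats[[m]][rows, , drop = FALSE])
  })
  names(z) <- mods
  res <- list()
  for (a in mods) for (b in mods) {
    shared <- intersect(rownames(z[[a]]) %||% character(), rownames(z[[b]]) %||% character())
    loss <- if (length(shared) == 0) 0 else {
      y <- coembed_decode(model, a, z[[b]][shared, , drop = FALSE])
      reconstruction_loss_pair(mats[[a]][shared, , drop = FALSE], y)
    }
    res[[length(res) + 1]] <- tibble::tibble(
      modality_a = a, modality_b = b, n_shared = length(shared), loss = loss)
  }
  pairs <- dplyr::bind_rows(res)
  list(total = sum(pairs$loss), pairs = pairs)
}

#' Single triplet hinge term
#'
#' `max(D(anchor, pos) - D(anchor, neg) + margin, 0)` with `D` the cosine
#' distance: the anchor (a protein's latent in one modality) is pushed closer
#' to its positive (the same protein in another modality) than to a negative
#' (a different protein in that modality) by at least the margin.
#'
#' @param z_anchor,z_pos,z_neg Unit-norm latent vectors.
#' @param margin Triplet margin epsilon.
#' @return Non-negative hinge value.
#' @export
triplet_term <- function(z_anchor, z_pos, z_neg, margin = 0.2) {
  max(cosine_distance(z_anchor, z_pos) - cosine_distance(z_anchor, z_neg) + margin, 0)
}

#' Triplet loss of one modality against a partner modality
#'
#' Mean of [triplet_term()] over the proteins shared by the two modalities,
#' with the negative for each anchor passed in explicitly (the trainer draws
#' them, which keeps this function deterministic).
#'
#' @param z_a Anchor latents (shared proteins, unit rows).
#' @param z_b Partner latents for the same proteins, in the same row order.
#' @param negatives Integer vector: row index in `z_b` of each anchor's
#'   negative; `negatives[i] != i`.
#' @param margin Triplet margin epsilon.
#' @return Mean hinge value.
#' @export
triplet_loss_modality <- function(z_a, z_b, negatives, margin = 0.2) {
  n <- nrow(z_a)
  if (n < 2) abort("triplet loss needs >= 2 shared proteins")
  stopifnot(nrow(z_b) == n, length(negatives) == n, all(negatives != seq_len(n)))
  d_pos <- row_cosine_distance(z_a, z_b)
  d_neg <- row_cosine_distance(z_a, z_b[negatives, , drop = FALSE])
  mean(pmax(d_pos - d_neg + margin, 0))
}

#' Combine reconstruction and triplet losses
#'
#' `L = lambda * R + (1 - lambda) * T`.
#'
#' @param R Total reconstruction loss.
#' @param T_ Total triplet loss.
#' @param lambda Weight in `[0, 1]`.
#' @return A single number.
#' @export
combine_losses <- function(R, T_, lambda = 0.5) {
  stopifnot(lambda >= 0, lambda <= 1)
  lambda * R + (1 - lambda) * T_
}
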