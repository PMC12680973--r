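#' Tidy the training history of a co-embedding fit
#'
#' @param x A `coembed_fit`.
#' @param per Return `"epoch"` means (default) or raw `"batch"` records.
#' @param ... Unused.
#' @return Tibble with columns `epoch` (`batch`), `R`, `T`, `L`.
#' @export
tidy.coembed_fit <- function(x, per = c("epoch", "batch"), ...) {
  per <- match.arg(per)
  h <- x$history[, c("epoch", "batch", "R", "T", "L")]
  if (per == "batch") return(h)
  h |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(R = mean(.data$R), T = mean(.data$T), L = mean(.data$L),
                     .groups = "drop")
}

#' One-row summary of a co-embedding fit
#'
#' @param x A `coembed_fit`.
#' @param ... Unused.
#' @return One-row tibble: modality and protein counts, epochs, and the
#'   final-epoch mean losses.
#' @export
glance.coembed_fit <- function(x, ...) {
  last <- tidy(x)
  last <- last[nrow(last), ]
  tibble::tibble(
    n_modalities = length(x$latents),
    n_proteins = length(x$universe$ids),
    latent_dim = x$config$latent_dim,
    epochs = x$config$epochs,
    final_R = last$R, final_T = last$T, final_L = last$L)
}

#' Loss-convergence plot for a co-embedding fit
#'
#' Per-epoch mean reconstruction (R), triplet (T) and combined (L) losses.
#'
#' @param object A `coembed_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coembed_fit <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("R", "T", "L"), names_to = "loss",
                        values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Co-embedding training losses") +
    ggplot2::theme_minimal()
}

#' Distribution of proximities for positive versus negative pairs
#'
#' Visual companion to [pair_auroc()].
#'
#' @param prox Proximity matrix.
#' @param positives Pair tibble.
#' @param restriction Optional protein-id restriction (see [pair_auroc()]).
#' @return A ggplot object.
#' @export
plot_pair_distributions <- function(prox, positives, restriction = NULL) {
  ids <- rownames(prox)
  restriction <- restriction %||%
    intersect(ids, unique(c(positives$protein_a, positives$protein_b)))
  P <- prox[restriction, restriction, drop = FALSE]
  pairs <- all_pairs(P)
  pos_keys <- pair_keys(positives$protein_a, positives$protein_b)
  pairs$label <- ifelse(pair_keys(pairs$protein_a, pairs$protein_b) %in%
                          pos_keys, "positive", "negative")
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "protein proximity (cosine similarity)", y = "density") +
    ggplot2::theme_minimal()
}
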