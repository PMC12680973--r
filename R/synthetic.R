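# Synthetic multi-modality worlds with planted community structure: a
# stochastic block model for network views and a spherical Gaussian mixture
# for feature views -- the minimal generative family matching what the losses
# assume (modalities agree on latent proximity but differ in noise and
# coverage). Coverage is sampled independently per modality so the
# missing-data path is always exercised.

#' Plant a world of proteins with community assignments
#'
#' Community sizes are multinomial around balance with a floor of 2 members
#' each; proteins are assigned by a seeded shuffle.
#'
#' @param n Number of proteins (>= 2k).
#' @param k Number of communities.
#' @param seed Integer seed.
#' @return A `synthetic_world`: list with `n`, `k`, `assignment` (tibble
#'   `protein_id`, `community`) and `seed`.
#' @export
plant_world <- function(n, k, seed = 1L) {
  if (n < 2 * k) abort("need n >= 2k so every community has >= 2 members")
  streams <- new_streams(seed, "world")
  assignment <- with_stream(streams, "world", {
    sizes <- as.integer(rmultinom(1, n - 2L * k, rep(1 / k, k))) + 2L
    comm <- sample(rep(seq_len(k), sizes))
    tibble::tibble(
      protein_id = sprintf("P%04d", seq_len(n)),
      community = comm)
  })
  structure(list(n = as.integer(n), k = as.integer(k),
                 assignment = assignment, seed = as.integer(seed)),
            class = "synthetic_world")
}

sample_coverage <- function(ids, coverage) {
  n_keep <- round(coverage * length(ids))
  sort(sample(ids, n_keep))
}

#' Generate a network view of a synthetic world
#'
#' Stochastic block model over a coverage-sampled protein subset:
#' within-community edges with probability `p_in`, between-community with
#' `p_out`. Sampled proteins left without any edge are dropped with a
#' warning (networks define their node set through edges). Edge scores are
#' drawn uniformly in (0.5, 1] -- confidence-like, used only by filtering.
#'
#' @param world A `synthetic_world`.
#' @param p_in Within-community edge probability (> p_out).
#' @param p_out Between-community edge probability.
#' @param coverage Fraction of proteins measured by this view.
#' @param seed Integer seed.
#' @return Interaction-network tibble.
#' @export
network_view <- function(world, p_in, p_out, coverage = 1, seed = 1L) {
  stopifnot(p_in > p_out, p_out >= 0, p_in <= 1)
  streams <- new_streams(seed, "net")
  with_stream(streams, "net", {
    ids <- sample_coverage(world$assignment$protein_id, coverage)
    comm <- world$assignment$community[match(ids, world$assignment$protein_id)]
    idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
    same <- comm[idx[, 1]] == comm[idx[, 2]]
    prob <- ifelse(same, p_in, p_out)
    keep <- runif(nrow(idx)) < prob
    edges <- tibble::tibble(
      protein_a = ids[idx[keep, 1]],
      protein_b = ids[idx[keep, 2]],
      score = runif(sum(keep), 0.5, 1))
    isolated <- setdiff(ids, unique(c(edges$protein_a, edges$protein_b)))
    if (length(isolated) > 0)
      warn(paste0("dropped ", length(isolated),
                  " isolated sampled protein(s) from network view"))
    as_interaction_network(edges)
  })
}

#' Generate a feature view of a synthetic world
#'
#' Community centroids are drawn uniformly on the unit sphere in `dim`
#' dimensions; each covered protein's vector is its community centroid plus
#' isotropic Gaussian noise with standard deviation `sigma`.
#'
#' @param world A `synthetic_world`.
#' @param dim Feature dimension (>= 2).
#' @param sigma Noise standard deviation (>= 0).
#' @param coverage Fraction of proteins measured by this view.
#' @param seed Integer seed.
#' @param modality Modality name stored on the result.
#' @return Feature tibble.
#' @export
feature_view <- function(world, dim = 64, sigma = 0.3, coverage = 1,
                         seed = 1L, modality = "features") {
  stopifnot(dim >= 2, sigma >= 0)
  streams <- new_streams(seed, "feat")
  with_stream(streams, "feat", {
    centroids <- matrix(rnorm(world$k * dim), world$k, dim)
    centroids <- centroids / sqrt(rowSums(centroids^2))
    ids <- sample_coverage(world$assignment$protein_id, coverage)
    comm <- world$assignment$community[match(ids, world$assignment$protein_id)]
    X <- centroids[comm, , drop = FALSE] +
      matrix(rnorm(length(ids) * dim, sd = sigma), length(ids), dim)
    colnames(X) <- paste0("V", seq_len(dim))
    new_feature_table(
      dplyr::bind_cols(tibble::tibble(protein_id = ids), tibble::as_tibble(X)),
      modality)
  })
}

#' Ground-truth pair set of a synthetic world
#'
#' All within-community unordered pairs.
#'
#' @param world A `synthetic_world`.
#' @return Pair tibble `protein_a`, `protein_b`.
#' @export
world_pairs <- function(world) {
  world$assignment |>
    dplyr::group_by(.data$community) |>
    dplyr::group_map(function(g, key) {
      ids <- sort(g$protein_id)
      idx <- which(upper.tri(diag(length(ids))), arr.ind = TRUE)
      tibble::tibble(protein_a = ids[idx[, 1]], protein_b = ids[idx[, 2]])
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Ground-truth term collection of a synthetic world
#'
#' Communities as terms (`C1`, `C2`, ...). With `root_fraction > 0`, that
#' fraction of each community's members is removed from the collection so a
#' root-only null population exists for rank-sum testing.
#'
#' @param world A `synthetic_world`.
#' @param root_fraction Fraction of proteins withheld from all terms.
#' @param seed Seed for the withheld sample.
#' @return Named list community term -> member protein ids.
#' @export
world_terms <- function(world, root_fraction = 0, seed = 1L) {
  members <- split(world$assignment$protein_id, world$assignment$community)
  names(members) <- paste0("C", names(members))
  if (root_fraction > 0) {
    streams <- new_streams(seed, "root")
    members <- with_stream(streams, "root", {
      lapply(members, function(ms)
        sort(sample(ms, max(2, round((1 - root_fraction) * length(ms))))))
    })
  }
  members
}

#' Write a complete fixture bundle to disk
#'
#' Edge lists and feature tables in the exact formats the readers ingest,
#' plus the ground-truth pair set and the community term collection (GMT).
#'
#' @param world A `synthetic_world`.
#' @param views Named list of views (interaction-network or feature tibbles).
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(world, views, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(views)) {
    v <- views[[nm]]
    if (all(c("protein_a", "protein_b", "score") %in% names(v))) {
      p <- file.path(outdir, paste0(nm, "_edges.tsv"))
      readr::write_tsv(v, p, progress = FALSE)
    } else {
      p <- file.path(outdir, paste0(nm, "_features.tsv"))
      write_feature_table(v, p)
    }
    paths[nm] <- p
  }
  paths["pairs"] <- file.path(outdir, "truth_pairs.tsv")
  write_pair_set(world_pairs(world), paths[["pairs"]])
  paths["terms"] <- file.path(outdir, "truth_terms.gmt")
  write_gmt(world_terms(world), paths[["terms"]])
  paths["assignment"] <- file.path(outdir, "assignment.tsv")
  readr::write_tsv(world$assignment, paths[["assignment"]], progress = FALSE)
  invisible(paths)
}

#' Default synthetic benchmark conditions
#'
#' The standing benchmark used throughout the tests and the reproduction
#' script: 300 proteins in 10 planted communities; two network views (SBM,
#' `p_in = 0.3`, `p_out = 0.01`) and one feature view (dim 64, sigma 0.3),
#' each covering an independent 70% of proteins; network views featurized by
#' node2vec into 64 dimensions.
#'
#' @param seed Integer seed (default 7).
#' @param n2v_dim node2vec dimension for the network views.
#' @return List with `world`, `features` (named list of 3 feature tibbles)
#'   and `views` (the raw views).
#' @export
default_fixture <- function(seed = 7L, n2v_dim = 64L) {
  world <- plant_world(300, 10, seed = seed)
  net1 <- network_view(world, p_in = 0.3, p_out = 0.01, coverage = 0.7,
                       seed = seed + 1L)
  net2 <- network_view(world, p_in = 0.3, p_out = 0.01, coverage = 0.7,
                       seed = seed + 2L)
  img <- feature_view(world, dim = 64, sigma = 0.3, coverage = 0.7,
                      seed = seed + 3L, modality = "imaging")
  f1 <- node2vec_featurize(net1, dim = n2v_dim, seed = seed + 4L,
                           modality = "apms")
  f2 <- node2vec_featurize(net2, dim = n2v_dim, seed = seed + 5L,
                           modality = "plms")
  list(world = world,
       features = list(apms = f1, plms = f2, imaging = img),
       views = list(apms = net1, plms = net2, imaging = img))
}
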