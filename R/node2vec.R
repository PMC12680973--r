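#' Featurize an interaction network with node2vec
#'
#' Runs biased second-order random walks over the (unweighted) filtered
#' network and trains a skip-gram model with negative sampling on the walk
#' corpus, yielding one dense vector per node. The walk bias follows the
#' usual return / in-out parameterization: stepping from `t` to `v`, a
#' neighbour `x` of `v` is weighted `1/p` if `x == t`, `1` if `x` is also a
#' neighbour of `t`, and `1/q` otherwise. Defaults follow common practice for
#' protein interaction networks: `p = 2`, `q = 1`, walk length 80, 10 walks
#' per node, 1024 dimensions.
#'
#' Edge scores are used only upstream for filtering; walks treat the graph as
#' unweighted. Training is single-threaded and fully determined by `seed`.
#'
#' @param net Interaction network tibble (see [read_edge_list()]).
#' @param p Return parameter of the second-order walk bias.
#' @param q In-out parameter.
#' @param walk_length Steps per walk.
#' @param num_walks Walks started from each node.
#' @param dim Embedding dimension (>= 2).
#' @param window Skip-gram context window half-width.
#' @param negative Negative samples per positive pair.
#' @param epochs Skip-gram passes over the walk corpus.
#' @param alpha Initial skip-gram learning rate (linearly decayed).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @param modality Modality name stored on the result.
#' @return A feature tibble: `protein_id` plus `dim` numeric columns
#'   `V1..Vdim`, one row per network node, rows ordered lexicographically.
#' @export
node2vec_featurize <- function(net, p = 2, q = 1, walk_length = 80,
                               num_walks = 10, dim = 1024, window = 10,
                               negative = 5, epochs = 5, alpha = 0.025,
                               seed = 1L, modality = "network") {
  if (nrow(net) == 0) abort("cannot featurize an empty network")
  if (dim < 2) abort("dim must be >= 2")
  nodes <- network_nodes(net)
  n <- length(nodes)
  ia <- match(net$protein_a, nodes) - 1L
  ib <- match(net$protein_b, nodes) - 1L
  # symmetric CSR with sorted neighbour lists
  from <- c(ia, ib)
  to <- c(ib, ia)
  o <- order(from, to)
  from <- from[o]; to <- to[o]
  indptr <- c(0L, cumsum(tabulate(from + 1L, nbins = n)))
  walks <- .n2v_walks(as.integer(indptr), as.integer(to), p, q,
                      as.integer(walk_length), as.integer(num_walks),
                      as.double(seed))
  emb <- .sgns_embed(walks, n, as.integer(dim), as.integer(window),
                     as.integer(negative), as.integer(epochs),
                     alpha, as.double(seed))
  out <- tibble::as_tibble(emb, .name_repair = ~ paste0("V", seq_len(dim)))
  out <- dplyr::bind_cols(tibble::tibble(protein_id = nodes), out)
  new_feature_table(out, modality)
}
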