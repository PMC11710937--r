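# Resampling null models for the communication network: the jackknife
# subsampling null for component diversity and the node-subsampling null
# for adjusted density.

# list of component vectors, one per posture
posture_component_sets <- function(interactions) {
  interactions <- tibble::as_tibble(interactions)
  split(interactions$component_code, posture_uid(interactions))
}

# diversity of a set of postures = number of components with at least one
# co-occurrence partner = union of components over postures of size >= 2
diversity_of_postures <- function(comp_sets) {
  sizes <- lengths(comp_sets)
  length(unique(unlist(comp_sets[sizes >= 2], use.names = FALSE)))
}

#' Jackknife subsampling null for component diversity
#'
#' Draws repeated random subsamples of `n_sub` postures (without
#' replacement) from a reference period's cleaned postures, rebuilds the
#' co-occurrence network and records its component diversity, yielding the
#' null distribution of diversity expected from a reduction in sample size
#' alone.  The observed diversity of a comparison period is then judged
#' against the 0.025 and 0.975 percentiles of this null (two-tailed).
#'
#' @param interactions_ref Cleaned long-format interaction records of the
#'   reference period.
#' @param n_sub Subsample size: the number of postures in the comparison
#'   period (e.g. 439 late-drought postures drawn from the pre-drought set).
#' @param observed Observed diversity of the comparison period: an integer,
#'   or a `comm_network` from which [component_diversity()] is taken.
#' @param n_perm Number of subsamples (default 1000).
#' @param seed Integer seed.
#' @return A [permutation_result()] with `tail = "two_sided"`; its
#'   `$significant` field is `"less"` for a significant decrease.
#' @export
diversity_jackknife <- function(interactions_ref, n_sub, observed,
                                n_perm = 1000, seed = NULL) {
  assert_count(n_perm, "n_perm")
  if (inherits(observed, "comm_network")) observed <- component_diversity(observed)
  comp_sets <- posture_component_sets(interactions_ref)
  n_ref <- length(comp_sets)
  assert_count(n_sub, "n_sub")
  if (n_sub > n_ref) {
    stop_validation(sprintf(
      "`n_sub` (%d) exceeds the number of reference postures (%d).", n_sub, n_ref
    ))
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(n_ref, n_sub)
      diversity_of_postures(comp_sets[idx])
    }, numeric(1))
  })
  permutation_result(observed, nulls,
    tail = "two_sided", seed = seed,
    method = sprintf("jackknife subsampling of %d/%d postures", n_sub, n_ref)
  )
}

#' Node-subsampling null for adjusted density
#'
#' Draws repeated uniform random subsets of `n_nodes_sub` components from a
#' reference network, induces the subgraph on each subset (preserving the
#' components' observed connectivity) and recomputes the adjusted density,
#' with the impossible-pair correction evaluated on the subset's own
#' morphological group sizes.  This is the null of a repertoire that shrank
#' without any loss of combinatorial flexibility among the retained
#' signals; the comparison period's observed adjusted density is judged
#' two-tailed against the 0.025/0.975 percentiles.
#'
#' @param net_ref Reference-period `comm_network`.
#' @param n_nodes_sub Number of nodes observed in the comparison period.
#' @param observed Observed adjusted density of the comparison period: a
#'   number, or a `comm_network` from which [adjusted_density()] is taken.
#' @param n_perm Number of subsamples (default 1000).
#' @param seed Integer seed.
#' @return A [permutation_result()] with `tail = "two_sided"`.
#' @export
density_node_subsample_null <- function(net_ref, n_nodes_sub, observed,
                                        n_perm = 1000, seed = NULL) {
  assert_count(n_perm, "n_perm")
  if (inherits(observed, "comm_network")) observed <- adjusted_density(observed)
  n <- igraph::vcount(net_ref$graph)
  assert_count(n_nodes_sub, "n_nodes_sub")
  if (n_nodes_sub < 2) stop_validation("`n_nodes_sub` must be at least 2.")
  if (n_nodes_sub > n) {
    stop_validation(sprintf(
      "`n_nodes_sub` (%d) exceeds the reference network's node count (%d).",
      n_nodes_sub, n
    ))
  }
  adj <- igraph::as_adjacency_matrix(net_ref$graph, sparse = FALSE) > 0
  groups <- igraph::V(net_ref$graph)$group_id
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      idx <- sample.int(n, n_nodes_sub)
      m_sub <- sum(adj[idx, idx]) / 2
      possible <- choose(n_nodes_sub, 2) - sum(choose(table(groups[idx]), 2))
      if (possible <= 0) NA_real_ else m_sub / possible
    }, numeric(1))
  })
  permutation_result(observed, nulls,
    tail = "two_sided", seed = seed,
    method = sprintf("node subsampling of %d/%d components", n_nodes_sub, n)
  )
}
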