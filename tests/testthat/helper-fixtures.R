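# Shared fixture builders and independent oracles.  Oracles deliberately
# use brute-force formulations that share no code with the implementation.

adult_roster <- function(n, harem_id = "h01") {
  tibble::tibble(
    individual_id = sprintf("%s_i%02d", harem_id, seq_len(n)),
    harem_id = harem_id,
    age_sex_class = c("stallion", rep("nonlactating_female", n - 1)),
    age_months = 60
  )
}

# one scan row
scan_row <- function(period, ind, nb = NA_character_, harem = "h01",
                     behavior = "grazing") {
  tibble::tibble(
    harem_id = harem, period_id = period, individual_id = ind,
    behavior_code = behavior, neighbor_id = nb
  )
}

tiny_ethogram <- function() {
  ethogram(tibble::tibble(
    code = c(
      "ears_forward", "ears_back", "squeal", "nose_touch",
      "eyes_open", "tail_switch"
    ),
    modality = c("visual", "visual", "acoustic", "tactile", "visual", "visual"),
    group_id = c("ears", "ears", "squeal", "nose_touch", "eyes", "tail"),
    neutral = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  ))
}

# long-format interaction rows from a list of interactions, each a list of
# postures (character vectors of component codes)
make_interactions <- function(posture_lists, period = "pre_drought") {
  rows <- list()
  for (i in seq_along(posture_lists)) {
    for (s in seq_along(posture_lists[[i]])) {
      comps <- posture_lists[[i]][[s]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        interaction_id = sprintf("int%03d", i),
        period_label = period,
        focal_id = "f001",
        posture_seq = s,
        component_code = comps,
        context_tag = NA_character_
      )
    }
  }
  dplyr::bind_rows(rows)
}

# an ethogram where every listed code is its own singleton group
free_ethogram <- function(codes, modality = "visual") {
  ethogram(tibble::tibble(
    code = codes, modality = modality, group_id = codes, neutral = FALSE
  ))
}

# ---- independent oracles ----------------------------------------------------

# weighted Newman modularity from the definition:
# Q = (1/2W) * sum_ij (A_ij - k_i k_j / 2W) [c_i == c_j]
modularity_oracle <- function(graph, membership) {
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  W <- sum(A) / 2
  k <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - outer(k, k) / (2 * W)) * same) / (2 * W)
}

# diversity of a chosen set of postures, by brute-force pair search
diversity_oracle <- function(postures) {
  comps <- unique(unlist(postures))
  connected <- vapply(comps, function(u) {
    for (p in postures) {
      if (u %in% p && length(setdiff(p, u)) > 0) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
  sum(connected)
}

# adjusted density of a node subset, by brute-force loops over an edge list
adjusted_density_oracle <- function(edges, nodes, group_of) {
  m <- 0
  imp <- 0
  for (i in seq_along(nodes)) {
    for (j in seq_len(i - 1)) {
      u <- nodes[i]
      v <- nodes[j]
      hit <- any((edges$u == u & edges$v == v) | (edges$u == v & edges$v == u))
      if (hit) m <- m + 1
      if (group_of[u] == group_of[v]) imp <- imp + 1
    }
  }
  m / (choose(length(nodes), 2) - imp)
}

# Kolmogorov-Smirnov distance between two empirical distributions
ks_distance <- function(x, y) {
  v <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(v) - ecdf(y)(v)))
}

# exact binomial 95% acceptance interval for a count of successes
binom_interval <- function(n, p = 0.05) {
  c(qbinom(0.025, n, p), qbinom(0.975, n, p))
}
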