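# Cleaning filter, co-occurrence network construction, diversity, the
# impossible-pair correction, adjusted density and the resampling nulls.

test_that("cleaning removes postures with components seen in <2 interactions", {
  # "rare" occurs only in interaction 1 and contaminates 3 of 10 postures
  ints <- make_interactions(list(
    list(c("a", "rare"), c("b", "rare"), c("a", "b", "rare"), c("a", "b")),
    list(c("a", "b"), c("a", "c")),
    list(c("b", "c"), c("a", "c"), c("a", "b"), c("b", "c"))
  ))
  out <- clean_postures(ints)
  expect_equal(out$report$postures_in, 10)
  expect_equal(out$report$postures_removed, 3)
  expect_equal(out$report$postures_out, 7)
  expect_true("rare" %in% out$report$removed_components$code)
  expect_false("rare" %in% out$interactions$component_code)
  # boundary: a component in exactly two interactions is retained
  expect_true("c" %in% out$interactions$component_code)
  # convergence: re-cleaning the output removes nothing further
  again <- clean_postures(out$interactions)
  expect_equal(again$report$postures_removed, 0)
})

test_that("cleaning iterates to a fixed point when removals cascade", {
  # "x" is rare; removing its postures leaves "y" in a single interaction
  ints <- make_interactions(list(
    list(c("x", "y"), c("a", "b")),
    list(c("y", "a"), c("a", "b")),
    list(c("a", "b"))
  ))
  fix <- clean_postures(ints, iterate = TRUE)
  expect_false("y" %in% fix$interactions$component_code)
  expect_gt(fix$report$passes, 1)
  once <- clean_postures(ints, iterate = FALSE)
  expect_true("y" %in% once$interactions$component_code)
})

test_that("co-occurrence weights count postures (or interactions when asked)", {
  etho <- free_ethogram(c("a", "b", "c"))
  tri <- build_comm_network(make_interactions(list(list(c("a", "b", "c")))), etho)
  expect_equal(igraph::ecount(tri$graph), 3)
  expect_true(all(igraph::E(tri$graph)$weight == 1))

  two <- build_comm_network(
    make_interactions(list(list(c("a", "b"), c("a", "b")))), etho
  )
  expect_equal(igraph::ecount(two$graph), 1)
  expect_equal(igraph::E(two$graph)$weight, 2)
  # interaction-level weighting collapses repeats within an interaction
  two_i <- build_comm_network(
    make_interactions(list(list(c("a", "b"), c("a", "b")))), etho,
    weight_unit = "interaction"
  )
  expect_equal(igraph::E(two_i$graph)$weight, 1)

  # six-posture fixture against incidence-matrix pair counting
  posts <- list(
    list(c("a", "b"), c("b", "c")),
    list(c("a", "b", "c"), "a"),
    list(c("a", "c"), c("b", "c"))
  )
  net <- build_comm_network(make_interactions(posts), etho)
  flat <- unlist(posts, recursive = FALSE)
  M <- sapply(c("a", "b", "c"), function(u) {
    vapply(flat, function(p) u %in% p, logical(1))
  })
  O <- t(M) %*% M # oracle co-occurrence counts
  for (e in seq_len(igraph::ecount(net$graph))) {
    uv <- igraph::ends(net$graph, e)
    expect_equal(igraph::E(net$graph)$weight[e], O[uv[1], uv[2]])
  }
})

test_that("neutral subgraph strips neutral states and preserves weights", {
  etho <- tiny_ethogram()
  ints <- make_interactions(list(
    list(
      c("ears_forward", "eyes_open", "squeal"),
      c("ears_back", "eyes_open", "tail_switch")
    ),
    list(c("ears_forward", "squeal", "nose_touch"))
  ))
  net <- build_comm_network(ints, etho)
  sub <- neutral_subgraph(net, etho)
  expect_equal(sort(igraph::V(sub$graph)$name),
               c("ears_back", "ears_forward", "nose_touch", "squeal"))
  w <- igraph::E(sub$graph)$weight[
    igraph::get_edge_ids(sub$graph, c("ears_forward", "squeal"))
  ]
  expect_equal(w, 2)
  # an isolated node appears after stripping (ears_back only co-occurred
  # with neutrals), so diversity drops below node count
  expect_equal(component_diversity(sub), 3)

  all_neutral <- build_comm_network(
    make_interactions(list(list(c("eyes_open", "tail_switch")))), etho
  )
  empty <- neutral_subgraph(all_neutral, etho)
  expect_equal(igraph::vcount(empty$graph), 0)

  no_flags <- free_ethogram(c("a", "b"))
  net2 <- build_comm_network(make_interactions(list(list(c("a", "b")))), no_flags)
  expect_warning(same <- neutral_subgraph(net2, no_flags), "no neutral")
  expect_equal(igraph::vcount(same$graph), 2)
})

test_that("component diversity counts connected nodes only", {
  etho <- free_ethogram(c("a", "b", "c", "d", "e"))
  ints <- make_interactions(list(
    list(c("a", "b"), c("c", "d")),
    list("e", c("a", "c"))
  ))
  net <- build_comm_network(ints, etho)
  expect_equal(igraph::vcount(net$graph), 5)
  expect_equal(component_diversity(net), 4) # e is isolated

  lone <- build_comm_network(make_interactions(list(list("a"))), etho)
  expect_equal(component_diversity(lone), 0)
})

test_that("impossible pairs sum n(n-1)/2 over morphological groups", {
  expect_equal(impossible_pairs(c(6, 2, 2)), 17L)
  expect_equal(impossible_pairs(c(1, 1, 1)), 0L)
  expect_equal(impossible_pairs(2), 1L)
  etho <- tiny_ethogram() # ears has 2 states, others singletons
  expect_equal(impossible_pairs(etho), 1L)
  expect_equal(impossible_pairs(etho, codes = c("ears_forward", "squeal")), 0L)
})

test_that("adjusted density corrects for mutually exclusive pairs", {
  etho <- ethogram(tibble::tibble(
    code = c("A", "B", "C", "D"),
    modality = "visual",
    group_id = c("g1", "g1", "g2", "g2")
  ))
  net <- build_comm_network(
    make_interactions(list(list(c("A", "C")), list(c("B", "D")), list(c("A", "C")))),
    etho
  )
  expect_equal(adjusted_density(net), 2 / (choose(4, 2) - 2)) # 0.5

  # complete allowed graph: density 1
  full <- build_comm_network(
    make_interactions(list(
      list(c("A", "C"), c("A", "D"), c("B", "C"), c("B", "D"))
    )),
    etho
  )
  expect_equal(adjusted_density(full), 1)

  # singleton groups: equals igraph's ordinary density, and in general the
  # adjusted value can only exceed it
  free <- free_ethogram(c("A", "B", "C", "D"))
  net_free <- build_comm_network(
    make_interactions(list(list(c("A", "B"), c("C", "D")))), free
  )
  expect_equal(
    adjusted_density(net_free),
    igraph::edge_density(net_free$graph)
  )
  expect_gte(adjusted_density(net), igraph::edge_density(net$graph))
})

test_that("diversity jackknife: exhaustive subsample and decision rule", {
  etho <- free_ethogram(c("A", "B", "C", "D", "E", "F"))
  posts <- list(
    list(c("A", "B")), list(c("B", "C")), list(c("C", "D")),
    list("E"), list(c("E", "F")), list("A")
  )
  ints <- make_interactions(posts)
  # n_sub = all postures: every replicate equals the full diversity
  full_net <- build_comm_network(ints, etho)
  jk_full <- diversity_jackknife(ints, 6, component_diversity(full_net),
    n_perm = 50, seed = 1
  )
  expect_true(all(jk_full$null_values == component_diversity(full_net)))

  # null values can never exceed the reference diversity
  jk <- diversity_jackknife(ints, 3, 2, n_perm = 500, seed = 2)
  expect_true(all(jk$null_values <= component_diversity(full_net)))

  # observed far below the nulls is a significant decrease
  jk0 <- diversity_jackknife(ints, 5, 0, n_perm = 200, seed = 3)
  expect_equal(jk0$significant, "less")

  expect_error(diversity_jackknife(ints, 7, 5, n_perm = 10, seed = 1), "exceeds")
})

test_that("subsampled diversity is stochastically non-decreasing in n_sub", {
  es <- synthetic_ethogram(per_module = 10)
  rates <- setNames(
    10^seq(-1.3, 0, length.out = length(es$module_of)), names(es$module_of)
  )
  sim <- simulate_interactions(comm_sim_config(
    es,
    n_interactions = 300, base_rates = rates, seed = 21
  ))
  means <- vapply(c(30, 100, 300), function(k) {
    mean(diversity_jackknife(sim$interactions, k, 1,
      n_perm = 200, seed = 31
    )$null_values)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("density node-subsample null: degenerate and complete cases", {
  etho <- ethogram(tibble::tibble(
    code = c("A", "B", "C", "D"),
    modality = "visual", group_id = c("g1", "g1", "C", "D")
  ))
  net <- build_comm_network(
    make_interactions(list(list(c("A", "C"), c("B", "D"), c("C", "D")))), etho
  )
  obs <- adjusted_density(net)
  dn <- density_node_subsample_null(net, 4, obs, n_perm = 30, seed = 1)
  expect_true(all(dn$null_values == obs))

  # a complete allowed reference: every induced subgraph has density 1
  full <- build_comm_network(
    make_interactions(list(list(
      c("A", "C"), c("A", "D"), c("B", "C"), c("B", "D"), c("C", "D")
    ))), etho
  )
  dn_full <- density_node_subsample_null(full, 3, 1, n_perm = 50, seed = 2)
  expect_true(all(dn_full$null_values == 1))

  expect_error(density_node_subsample_null(net, 1, obs, n_perm = 5, seed = 1), "at least 2")
  expect_error(density_node_subsample_null(net, 9, obs, n_perm = 5, seed = 1), "exceeds")
})
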