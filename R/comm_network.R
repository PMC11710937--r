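# Multimodal signal co-occurrence networks: cleaning filter, construction,
# diversity, adjusted density and the mutually-exclusive-pair correction.

posture_uid <- function(interactions) {
  paste(interactions$interaction_id, interactions$posture_seq, sep = "\r")
}

#' Remove postures containing rare signal components
#'
#' A component observed in fewer than two distinct interactions is
#' considered too rare to analyse; every posture containing such a component
#' is removed.  Because removing postures can drop a further component below
#' the two-interaction threshold, the filter is by default iterated to a
#' fixed point; `iterate = FALSE` gives the single-pass behaviour.
#'
#' @param interactions Long-format interaction records
#'   (see [read_interaction_table()]).
#' @param iterate Re-apply the filter until nothing more is removed
#'   (default `TRUE`).
#' @return A list with `interactions` (the retained rows) and `report`, a
#'   list with `postures_in`, `postures_removed`, `postures_out`, `passes`,
#'   and `removed_components` (tibble of dropped codes with their
#'   interaction counts).
#' @export
clean_postures <- function(interactions, iterate = TRUE) {
  interactions <- tibble::as_tibble(interactions)
  postures_in <- length(unique(posture_uid(interactions)))
  removed <- tibble::tibble(code = character(0), n_interactions = integer(0))
  passes <- 0L
  repeat {
    passes <- passes + 1L
    counts <- dplyr::distinct(
      interactions,
      .data$component_code, .data$interaction_id
    ) |>
      dplyr::count(.data$component_code, name = "n_interactions")
    rare <- counts[counts$n_interactions < 2, ]
    if (nrow(rare) == 0 || nrow(interactions) == 0) break
    removed <- dplyr::bind_rows(
      removed,
      tibble::tibble(code = rare$component_code, n_interactions = rare$n_interactions)
    )
    uid <- posture_uid(interactions)
    bad_uid <- unique(uid[interactions$component_code %in% rare$component_code])
    interactions <- interactions[!uid %in% bad_uid, ]
    if (!iterate) break
  }
  postures_out <- length(unique(posture_uid(interactions)))
  list(
    interactions = interactions,
    report = list(
      postures_in = postures_in,
      postures_removed = postures_in - postures_out,
      postures_out = postures_out,
      passes = passes,
      removed_components = removed
    )
  )
}

#' Build a signal co-occurrence network
#'
#' Nodes are the signal components occurring in at least one posture of the
#' selected period; an undirected edge joins two components with weight
#' equal to the number of postures (default) or of distinct interactions in
#' which they were produced concurrently.  Postures are expected to be
#' cleaned first (see [clean_postures()]).
#'
#' @param interactions Long-format interaction records.
#' @param etho The [ethogram].
#' @param period_label Restrict to this `period_label` (default: all rows).
#' @param weight_unit `"posture"` (default) or `"interaction"`.
#' @return An object of class `comm_network`: list with the igraph `graph`
#'   (vertex attributes `group_id`, `modality`, `neutral`), `period_label`
#'   and `weight_unit`.
#' @export
build_comm_network <- function(interactions, etho, period_label = NULL,
                               weight_unit = c("posture", "interaction")) {
  weight_unit <- match.arg(weight_unit)
  interactions <- tibble::as_tibble(interactions)
  if (!is.null(period_label)) {
    interactions <- interactions[interactions$period_label %in% period_label, ]
  }
  interactions <- validate_interactions(interactions, etho)

  uid <- posture_uid(interactions)
  nodes <- sort(unique(interactions$component_code))
  comp_lists <- split(interactions$component_code, uid)
  pair_mats <- lapply(comp_lists, function(comps) {
    comps <- sort(unique(comps))
    if (length(comps) < 2) NULL else combn(comps, 2)
  })
  n_pairs <- vapply(pair_mats, function(m) if (is.null(m)) 0L else ncol(m), integer(1))
  pm <- do.call(cbind, pair_mats)
  pairs <- if (!is.null(pm)) {
    tibble::tibble(
      u = pm[1, ], v = pm[2, ],
      uid = rep(names(comp_lists), n_pairs)
    )
  } else {
    tibble::tibble(u = character(0), v = character(0), uid = character(0))
  }
  if (nrow(pairs) > 0 && weight_unit == "interaction") {
    pairs$uid <- sub("\r.*$", "", pairs$uid)
    pairs <- dplyr::distinct(pairs)
  }
  edges <- if (nrow(pairs) > 0) {
    dplyr::count(pairs, .data$u, .data$v, name = "weight")
  } else {
    tibble::tibble(u = character(0), v = character(0), weight = integer(0))
  }

  meta <- etho[match(nodes, etho$code), ]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v, weight = edges$weight),
    directed = FALSE,
    vertices = data.frame(
      name = nodes,
      group_id = meta$group_id,
      modality = meta$modality,
      neutral = meta$neutral
    )
  )
  structure(
    list(graph = g, period_label = period_label, weight_unit = weight_unit),
    class = "comm_network"
  )
}

#' @export
print.comm_network <- function(x, ...) {
  cat(sprintf(
    "Communication network%s: %d components, %d co-occurrence edges\n",
    if (!is.null(x$period_label)) paste0(" [", paste(x$period_label, collapse = ","), "]") else "",
    igraph::vcount(x$graph), igraph::ecount(x$graph)
  ))
  invisible(x)
}

as_comm_network <- function(graph, template) {
  structure(
    list(
      graph = graph,
      period_label = template$period_label,
      weight_unit = template$weight_unit
    ),
    class = "comm_network"
  )
}

#' Subgraph excluding neutral-state components
#'
#' Neutral states (e.g. "eyes open") co-occur with nearly everything and
#' dominate the network's connectivity; this induces the subgraph on the
#' non-neutral components, preserving the remaining edge weights.  No
#' re-cleaning is applied.
#'
#' @param net A [build_comm_network()] object.
#' @param etho The [ethogram] defining the neutral set.
#' @return A `comm_network` on the non-neutral components.
#' @export
neutral_subgraph <- function(net, etho) {
  neutral <- neutral_components(etho)
  if (length(neutral) == 0) {
    warn("Ethogram flags no neutral components; returning the network unchanged.")
    return(net)
  }
  keep <- setdiff(igraph::V(net$graph)$name, neutral)
  g <- igraph::induced_subgraph(net$graph, keep)
  as_comm_network(g, net)
}

#' Component diversity
#'
#' The number of connected nodes of the network: components with at least
#' one co-occurrence partner.  Isolated components (observed only in
#' single-component postures) do not count.
#'
#' @param net A [build_comm_network()] object.
#' @return Integer.
#' @export
component_diversity <- function(net) {
  sum(igraph::degree(net$graph) > 0)
}

#' Impossible co-occurrence pairs among mutually exclusive states
#'
#' Within one morphological group (e.g. ear positions) at most one state can
#' be held at a time, so states of the same group can never co-occur.  For a
#' group with `n` states present, `n * (n - 1) / 2` node pairs are therefore
#' impossible; this sums that quantity over the groups represented in the
#' node set at hand.
#'
#' @param x Either a `comm_network` (group sizes are taken from its current
#'   node set), an [ethogram] (optionally restricted via `codes`), or a
#'   numeric vector of group sizes.
#' @param codes Optional component codes restricting an ethogram.
#' @return Integer count of impossible pairs.
#' @examples
#' impossible_pairs(c(6, 2, 2)) # 15 + 1 + 1 = 17
#' @export
impossible_pairs <- function(x, codes = NULL) {
  sizes <- if (inherits(x, "comm_network")) {
    table(igraph::V(x$graph)$group_id)
  } else if (inherits(x, "ethogram")) {
    group_sizes(x, codes %||% x$code)
  } else if (is.numeric(x)) {
    x
  } else {
    stop_validation("`x` must be a comm_network, an ethogram, or group sizes.")
  }
  as.integer(sum(choose(as.numeric(sizes), 2)))
}

#' Adjusted network density
#'
#' Observed co-occurrence edges divided by the number of *realisable* node
#' pairs: all `choose(n, 2)` pairs minus the impossible within-group pairs
#' (see [impossible_pairs()]).  When every morphological group contributes a
#' single state the correction vanishes and this equals ordinary density.
#'
#' @param net A [build_comm_network()] object.
#' @return A number in `[0, 1]`, or `NA` (with a warning) when no realisable
#'   pair exists.
#' @export
adjusted_density <- function(net) {
  n <- igraph::vcount(net$graph)
  if (n < 2) {
    warn("Adjusted density undefined for fewer than two nodes; returning NA.")
    return(NA_real_)
  }
  possible <- choose(n, 2) - impossible_pairs(net)
  if (possible <= 0) {
    warn("No realisable pair among the present nodes; adjusted density NA.")
    return(NA_real_)
  }
  igraph::ecount(net$graph) / possible
}
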