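# Module (community) structure of the co-occurrence network, and the
# descriptive cross-period comparison of module membership.

#' Detect signal modules by fast-greedy modularity maximisation
#'
#' Runs greedy agglomerative modularity maximisation (Clauset-Newman-Moore)
#' on the weighted co-occurrence graph and returns the partition at maximum
#' modularity together with the modularity score Q.  Components within a
#' module co-occur more often with each other than expected from their
#' weighted degrees, so modules can be read as communicative contexts.  A
#' score above 0.3 conventionally indicates a repertoire of discrete
#' modules; the value is reported, never used as a filter.  Vertices are
#' processed in lexicographic code order, so the result is deterministic.
#'
#' @param net A [build_comm_network()] object.
#' @return A list with `modules` (tibble: `component`, `module` integer
#'   label) and `modularity_q`.  An edgeless graph yields one singleton
#'   module per node and `modularity_q = 0`.
#' @export
detect_modules <- function(net) {
  g <- net$graph
  if (igraph::vcount(g) == 0) {
    return(list(
      modules = tibble::tibble(component = character(0), module = integer(0)),
      modularity_q = 0
    ))
  }
  if (igraph::ecount(g) == 0) {
    return(list(
      modules = tibble::tibble(
        component = igraph::V(g)$name,
        module = seq_len(igraph::vcount(g))
      ),
      modularity_q = 0
    ))
  }
  perm <- order(igraph::V(g)$name)
  g <- igraph::permute(g, order(perm))
  fc <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  # cut the merge tree explicitly at the modularity-maximising step
  best <- which.max(fc$modularity)
  mem <- igraph::cut_at(fc, no = igraph::vcount(g) - (best - 1))
  q <- igraph::modularity(g, mem, weights = igraph::E(g)$weight)
  list(
    modules = tibble::tibble(
      component = igraph::V(g)$name,
      module = as.integer(mem)
    ),
    modularity_q = q
  )
}

# Align late modules to pre modules by plurality overlap of surviving
# components; returns a named map late_module -> pre_module (NA if no
# overlap).
match_modules <- function(flow) {
  surv <- flow[!is.na(flow$module_pre) & !is.na(flow$module_late_num), ]
  if (nrow(surv) == 0) {
    return(integer(0))
  }
  tab <- table(surv$module_late_num, surv$module_pre)
  best <- apply(tab, 1, function(row) as.integer(colnames(tab)[which.max(row)]))
  setNames(as.integer(best), rownames(tab))
}

#' Compare module membership across periods
#'
#' Long-format table of every component seen in either period with its
#' module in each: components absent from the late network are flagged
#' `"LOST"`, components new to it `"NEW"`.  Late modules are aligned to pre
#' modules by plurality overlap so that components can be classified as
#' retained (same aligned module), reassigned, lost or new; the table is
#' suitable for alluvial-style plotting.
#'
#' @param net_pre,net_late `comm_network` objects for the two periods.
#' @param modules_pre,modules_late Optional [detect_modules()] results
#'   (computed if missing).
#' @return A list with `flow` (tibble: `component`, `module_pre`,
#'   `module_late`, `status`) and `summary` (per pre-module counts of
#'   retained / reassigned / lost components).
#' @export
compare_modules <- function(net_pre, net_late,
                            modules_pre = NULL, modules_late = NULL) {
  modules_pre <- modules_pre %||% detect_modules(net_pre)
  modules_late <- modules_late %||% detect_modules(net_late)
  mp <- modules_pre$modules
  ml <- modules_late$modules
  comps <- sort(union(mp$component, ml$component))
  flow <- tibble::tibble(
    component = comps,
    module_pre = mp$module[match(comps, mp$component)],
    module_late_num = ml$module[match(comps, ml$component)]
  )
  map <- match_modules(flow)
  flow$status <- dplyr::case_when(
    is.na(flow$module_pre) ~ "new",
    is.na(flow$module_late_num) ~ "lost",
    !is.na(map[as.character(flow$module_late_num)]) &
      map[as.character(flow$module_late_num)] == flow$module_pre ~ "retained",
    TRUE ~ "reassigned"
  )
  flow$module_late <- ifelse(
    is.na(flow$module_late_num), "LOST", as.character(flow$module_late_num)
  )
  flow$module_late[flow$status == "new"] <- as.character(
    flow$module_late_num[flow$status == "new"]
  )
  summary <- flow[flow$status != "new", ] |>
    dplyr::count(.data$module_pre, .data$status) |>
    tidyr::pivot_wider(
      names_from = "status", values_from = "n", values_fill = 0L
    )
  list(
    flow = flow[, c("component", "module_pre", "module_late", "status")],
    summary = summary
  )
}

#' Per-modality summary of lost signal components
#'
#' Counts, for each sensory modality, the components present in the
#' reference-period network but absent from the late network.
#'
#' @param net_pre,net_late `comm_network` objects for the two periods.
#' @param etho The [ethogram] carrying modality annotations.
#' @return A tibble with `modality`, `lost`, `total`, `fraction`.
#' @export
modality_loss_summary <- function(net_pre, net_late, etho) {
  pre_nodes <- igraph::V(net_pre$graph)$name
  late_nodes <- igraph::V(net_late$graph)$name
  lost <- setdiff(pre_nodes, late_nodes)
  tab <- tibble::tibble(
    code = pre_nodes,
    modality = etho$modality[match(pre_nodes, etho$code)],
    lost = pre_nodes %in% lost
  )
  tab |>
    dplyr::group_by(.data$modality) |>
    dplyr::summarise(
      lost = sum(.data$lost),
      total = dplyr::n(),
      fraction = ifelse(.data$total > 0, .data$lost / .data$total, 0),
      .groups = "drop"
    )
}
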