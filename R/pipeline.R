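# End-to-end orchestration: ingest (or simulate) -> association networks and
# preferred-associate tests -> communication networks with resampling nulls
# and modules -> activity budgets -> results bundle on disk.

#' Run the full analysis pipeline
#'
#' Drives every stage of the analysis from a single configuration (an R
#' list, or the path of a YAML file with the same structure) and returns a
#' machine-readable results bundle, optionally writing its tables (CSV),
#' networks (GraphML) and manifest (JSON) under `out_dir`.  The run is
#' deterministic given the inputs, the seed and the flags; the manifest
#' records all three.
#'
#' Configuration fields (all optional unless noted):
#' \describe{
#'   \item{`simulate`}{`TRUE` to generate all inputs with the packaged
#'     generators (their parameters can be overridden via `sim`).}
#'   \item{`inputs`}{When not simulating: paths `scans`, `roster`,
#'     `interactions`, `ethogram`, `activity`, plus optional `steps`.}
#'   \item{`periods`}{Two period labels, reference first
#'     (default `c("pre_drought", "late_drought")`).}
#'   \item{`n_perm`}{Randomisations for every null model (default 1000).}
#'   \item{`seed`}{Master seed (default 1); stage seeds are derived from it.}
#'   \item{`out_dir`}{Output directory; omit to skip writing.}
#'   \item{`flags`}{Analysis toggles: `alone_rule`, `include_zero_dyads`,
#'     `weight_unit`, `preferred_null`, `iterate_cleaning`.}
#' }
#'
#' @param config A list, or path to a YAML file.
#' @return The results bundle (list), invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_perm %||% 1000L)
  if (n_perm < 1) stop_validation("`n_perm` must be at least 1.")
  periods <- config$periods %||% c("pre_drought", "late_drought")
  flags <- list(
    alone_rule = config$flags$alone_rule %||% "scan",
    include_zero_dyads = config$flags$include_zero_dyads %||% TRUE,
    weight_unit = config$flags$weight_unit %||% "posture",
    preferred_null = config$flags$preferred_null %||% "scans",
    iterate_cleaning = config$flags$iterate_cleaning %||% TRUE
  )

  data <- pipeline_inputs(config, periods, seed)
  assoc <- stage_association(data, periods, n_perm, seed, flags)
  comm <- stage_communication(data, periods, n_perm, seed, flags)
  budgets <- stage_budgets(data, periods)

  bundle <- list(
    manifest = list(
      package_version = as.character(utils::packageVersion("socioscope")),
      seed = seed, n_perm = n_perm, periods = periods, flags = flags,
      simulated = isTRUE(config[["simulate"]])
    ),
    association = assoc, communication = comm, budgets = budgets
  )
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, data, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

pipeline_inputs <- function(config, periods, seed) {
  if (isTRUE(config[["simulate"]])) {
    sim <- config[["sim"]] %||% list()
    scfg <- do.call(social_sim_config, utils::modifyList(
      list(seed = seed), sim$scans %||% list()
    ))
    pre_sc <- simulate_scans(scfg, period_prefix = "pre")
    scfg_late <- scfg
    scfg_late$seed <- seed + 1L
    late_sc <- simulate_scans(scfg_late, roster = pre_sc$roster, period_prefix = "late")

    espec <- synthetic_ethogram()
    mask <- sim$late_mask %||% head(espec$etho$code[!espec$etho$neutral], 6)
    # realistic abundance spectrum: component base rates log-spaced from
    # rare to common, so cleaning and the diversity null have bite
    rates <- setNames(
      10^seq(-1.3, 0, length.out = length(espec$module_of)),
      names(espec$module_of)
    )
    ccfg_pre <- do.call(comm_sim_config, utils::modifyList(
      list(
        ethogram_spec = espec, period_label = periods[1], seed = seed + 2L,
        n_interactions = 300, base_rates = rates
      ),
      sim$interactions_pre %||% list()
    ))
    ccfg_late <- do.call(comm_sim_config, utils::modifyList(
      list(
        ethogram_spec = espec, period_label = periods[2], seed = seed + 3L,
        n_interactions = 100, repertoire_mask = mask, base_rates = rates
      ),
      sim$interactions_late %||% list()
    ))
    int_pre <- simulate_interactions(ccfg_pre)
    int_late <- simulate_interactions(ccfg_late)

    targets_pre <- sim$budget_targets_pre %||% c(
      grazing = 0.42, standing = 0.098, vigilant = 0.046, resting = 0.07,
      social_grazing = 0.12, social_rest = 0.12, affiliation = 0.04,
      aggression = 0.016, greeting = 0.02, traveling = 0.05
    )
    targets_late <- sim$budget_targets_late %||% c(
      grazing = 0.54, standing = 0.071, vigilant = 0.026, resting = 0.05,
      social_grazing = 0.10, social_rest = 0.083, affiliation = 0.03,
      aggression = 0.01, greeting = 0.04, traveling = 0.05
    )
    bud_pre <- simulate_budgets(budget_sim_config(
      targets_pre,
      period_label = periods[1], seed = seed + 4L, steps_per_min = 18
    ))
    bud_late <- simulate_budgets(budget_sim_config(
      targets_late,
      period_label = periods[2], seed = seed + 5L, steps_per_min = 24
    ))
    list(
      roster = pre_sc$roster,
      scans = list(pre = pre_sc$scans, late = late_sc$scans),
      etho = espec$etho,
      interactions = dplyr::bind_rows(int_pre$interactions, int_late$interactions),
      activity = dplyr::bind_rows(bud_pre$intervals, bud_late$intervals),
      steps = dplyr::bind_rows(bud_pre$steps, bud_late$steps),
      truth = list(
        social = list(pre = pre_sc$truth, late = late_sc$truth),
        comm = list(pre = int_pre$truth, late = int_late$truth),
        budget = list(pre = bud_pre$truth, late = bud_late$truth)
      )
    )
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop_validation("Either `simulate: true` or `inputs:` is required.")
    for (f in c("scans", "roster", "interactions", "ethogram", "activity")) {
      if (is.null(inp[[f]])) stop_validation(paste0("`inputs$", f, "` is required."))
      if (!file.exists(inp[[f]])) stop_validation(paste0("No such file: ", inp[[f]]))
    }
    roster <- read_roster(inp$roster)
    etho <- read_ethogram(inp$ethogram)
    scans_all <- read_scan_table(inp$scans, roster = roster)
    per <- config$scan_period_map %||% list()
    split_scans <- if (length(per) == 2) {
      list(
        pre = scans_all[grepl(per[[1]], scans_all$period_id), ],
        late = scans_all[grepl(per[[2]], scans_all$period_id), ]
      )
    } else {
      list(pre = scans_all, late = scans_all[0, ])
    }
    steps <- if (!is.null(inp$steps)) {
      df <- read_delim_auto(inp$steps)
      df$n_steps <- as.numeric(df$n_steps)
      df$minutes_observed <- as.numeric(df$minutes_observed)
      df
    } else {
      NULL
    }
    list(
      roster = roster,
      scans = split_scans,
      etho = etho,
      interactions = read_interaction_table(inp$interactions, etho),
      activity = read_activity_table(inp$activity),
      steps = steps,
      truth = NULL
    )
  }
}

stage_association <- function(data, periods, n_perm, seed, flags) {
  tal <- list(
    pre = tally_dyads(data$scans$pre, data$roster, alone_rule = flags$alone_rule),
    late = tally_dyads(data$scans$late, data$roster, alone_rule = flags$alone_rule)
  )
  build_all <- function(tallies, label, scans) {
    ids <- unique(tallies$harem_id)
    nets <- purrr::map(ids, function(h) {
      build_harem_network(tallies, data$roster,
        harem_id = h, period_label = label,
        include_zero_dyads = flags$include_zero_dyads
      )
    })
    setNames(nets, ids)
  }
  nets <- list(
    pre = build_all(tal$pre, periods[1], data$scans$pre),
    late = build_all(tal$late, periods[2], data$scans$late)
  )
  run_tests <- function(nets_p, scans_p, offset) {
    purrr::imap(nets_p, function(net, h) {
      if (length(net$nodes) <= 4 || igraph::ecount(net$graph) < 1) {
        return(NULL)
      }
      preferred_associate_test(
        net,
        n_perm = n_perm,
        seed = seed + 100L + offset + match(h, names(nets_p)),
        null = flags$preferred_null,
        scans = scans_p, alone_rule = flags$alone_rule
      )
    }) |> purrr::compact()
  }
  tests <- list(
    pre = run_tests(nets$pre, data$scans$pre, 0L),
    late = run_tests(nets$late, data$scans$late, 1000L)
  )
  summary <- purrr::map_dfr(c("pre", "late"), function(p) {
    purrr::map_dfr(nets[[p]], function(net) {
      tibble::tibble(
        harem_id = net$harem_id, period = net$period_label,
        n_nodes = length(net$nodes), n_edges = igraph::ecount(net$graph),
        density = net$density, cv_harem = net$cv_harem,
        preferred_p = tests[[p]][[net$harem_id]]$p_value %||% NA_real_
      )
    })
  })
  list(
    tallies = tal, networks = nets, preferred_tests = tests,
    harem_summary = summary,
    regression = cross_period_dyad_regression(tal$pre, tal$late),
    paired = compare_periods(nets$pre, nets$late)
  )
}

stage_communication <- function(data, periods, n_perm, seed, flags) {
  by_period <- function(label) {
    data$interactions[data$interactions$period_label == label, ]
  }
  cl <- list(
    pre = clean_postures(by_period(periods[1]), iterate = flags$iterate_cleaning),
    late = clean_postures(by_period(periods[2]), iterate = flags$iterate_cleaning)
  )
  nets <- purrr::imap(cl, function(c_p, p) {
    build_comm_network(
      c_p$interactions, data$etho,
      period_label = if (p == "pre") periods[1] else periods[2],
      weight_unit = flags$weight_unit
    )
  })
  mods <- purrr::map(nets, detect_modules)
  n_late_post <- cl$late$report$postures_out
  n_late_nodes <- igraph::vcount(nets$late$graph)
  div_test <- if (n_late_post > 0 && n_late_post <= cl$pre$report$postures_out) {
    diversity_jackknife(
      cl$pre$interactions, n_late_post, component_diversity(nets$late),
      n_perm = n_perm, seed = seed + 201L
    )
  } else {
    NULL
  }
  dens_test <- if (n_late_nodes >= 2 && n_late_nodes <= igraph::vcount(nets$pre$graph)) {
    density_node_subsample_null(
      nets$pre, n_late_nodes, adjusted_density(nets$late),
      n_perm = n_perm, seed = seed + 202L
    )
  } else {
    NULL
  }
  list(
    cleaning = purrr::map(cl, "report"),
    networks = nets,
    summary = tibble::tibble(
      period = periods,
      n_postures = c(cl$pre$report$postures_out, cl$late$report$postures_out),
      diversity = c(component_diversity(nets$pre), component_diversity(nets$late)),
      adjusted_density = c(adjusted_density(nets$pre), adjusted_density(nets$late)),
      modularity_q = c(mods$pre$modularity_q, mods$late$modularity_q),
      n_modules = c(
        length(unique(mods$pre$modules$module)),
        length(unique(mods$late$modules$module))
      )
    ),
    modules = mods,
    module_flow = compare_modules(nets$pre, nets$late, mods$pre, mods$late),
    modality_loss = modality_loss_summary(nets$pre, nets$late, data$etho),
    diversity_test = div_test,
    density_test = dens_test
  )
}

stage_budgets <- function(data, periods) {
  budget <- compute_budget(
    data$activity,
    steps = data$steps, roster = data$roster
  )
  by_class <- if ("age_sex_class" %in% names(budget) &&
    !all(is.na(budget$age_sex_class))) {
    aggregate_budget(budget)
  } else {
    NULL
  }
  list(budget = budget, by_class = by_class)
}

write_bundle <- function(bundle, data, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$association$harem_summary,
    file.path(out_dir, "harem_summary.csv"),
    progress = FALSE
  )
  readr::write_csv(
    dplyr::bind_rows(
      bundle$association$tallies$pre |> dplyr::mutate(period = "pre"),
      bundle$association$tallies$late |> dplyr::mutate(period = "late")
    ),
    file.path(out_dir, "dyad_tallies.csv"),
    progress = FALSE
  )
  readr::write_csv(bundle$association$paired,
    file.path(out_dir, "paired_metrics.csv"),
    progress = FALSE
  )
  readr::write_csv(bundle$communication$summary,
    file.path(out_dir, "comm_summary.csv"),
    progress = FALSE
  )
  readr::write_csv(bundle$communication$module_flow$flow,
    file.path(out_dir, "module_flow.csv"),
    progress = FALSE
  )
  readr::write_csv(bundle$budgets$budget,
    file.path(out_dir, "budgets.csv"),
    progress = FALSE
  )
  net_dir <- file.path(out_dir, "networks")
  dir.create(net_dir, showWarnings = FALSE)
  for (p in c("pre", "late")) {
    for (net in bundle$association$networks[[p]]) {
      igraph::write_graph(
        net$graph,
        file.path(net_dir, sprintf("harem_%s_%s.graphml", net$harem_id, p)),
        format = "graphml"
      )
    }
    igraph::write_graph(
      bundle$communication$networks[[p]]$graph,
      file.path(net_dir, sprintf("comm_%s.graphml", p)),
      format = "graphml"
    )
  }
  perm_summ <- function(pt) {
    if (is.null(pt)) {
      return(NULL)
    }
    list(
      observed = pt$observed, p_value = pt$p_value, n_perm = pt$n_perm,
      tail = pt$tail, significant = pt$significant,
      null_mean = mean(pt$null_values),
      q_lower = pt$q_lower, q_upper = pt$q_upper
    )
  }
  jsonlite::write_json(
    list(
      manifest = bundle$manifest,
      cleaning = bundle$communication$cleaning,
      diversity_test = perm_summ(bundle$communication$diversity_test),
      density_test = perm_summ(bundle$communication$density_test),
      preferred_tests = purrr::map(
        bundle$association$preferred_tests,
        ~ purrr::map(.x, perm_summ)
      ),
      regression = as.list(bundle$association$regression)
    ),
    file.path(out_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
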