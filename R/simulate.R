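# Synthetic-data generators with planted ground truth.  The generators
# emulate the structure of the field data - harems of 2-13 members followed
# over repeated scan samples, interaction streams of multimodal postures
# with latent communicative contexts, and focal activity intervals - so
# every downstream stage can be exercised and scored without any download.

#' Configuration for the scan-sample generator
#'
#' Defaults mirror the study system: 21 harems of 2-13 members (mean ~5),
#' 40 sampling periods, members present in a given scan with probability
#' 0.9 and, when present, recorded without a neighbour within one body
#' length with probability 0.25.  Preferred dyads are planted by
#' multiplying the probability that the pair's members choose each other as
#' nearest neighbour.
#'
#' @param n_harems Number of harems.
#' @param n_periods Number of sampling periods.
#' @param size_range Inclusive harem size bounds; sizes are drawn as
#'   `2 + Poisson(3)` truncated to the range.
#' @param p_present Per-period presence probability of each member.
#' @param p_alone Probability a present member associates with nobody.
#' @param planted Optional tibble `harem_id`, `a_id`, `b_id`, `multiplier`
#'   of dyads whose mutual-choice weight is multiplied.
#' @param auto_plant Optional list `list(n_dyads =, multiplier =)`: plant
#'   that many random dyads per harem (recorded in the ground truth).
#' @param seed Master seed.
#' @return A list of class `social_sim_config`.
#' @export
social_sim_config <- function(n_harems = 21, n_periods = 40,
                              size_range = c(2, 13),
                              p_present = 0.9, p_alone = 0.25,
                              planted = NULL, auto_plant = NULL,
                              seed = 1L) {
  stopifnot(
    p_present >= 0, p_present <= 1, p_alone >= 0, p_alone <= 1,
    size_range[1] >= 2, size_range[2] >= size_range[1]
  )
  if (!is.null(planted) && any(planted$multiplier < 1)) {
    stop_validation("Planted multipliers must be >= 1.")
  }
  structure(
    list(
      n_harems = n_harems, n_periods = n_periods, size_range = size_range,
      p_present = p_present, p_alone = p_alone,
      planted = planted, auto_plant = auto_plant, seed = as.integer(seed)
    ),
    class = "social_sim_config"
  )
}

sim_roster <- function(cfg) {
  sizes <- pmin(
    pmax(2 + stats::rpois(cfg$n_harems, 3), cfg$size_range[1]),
    cfg$size_range[2]
  )
  purrr::map_dfr(seq_len(cfg$n_harems), function(h) {
    k <- sizes[h]
    classes <- c(
      "stallion",
      sample(c("lactating_female", "nonlactating_female", "juvenile"),
        k - 1,
        replace = TRUE, prob = c(0.3, 0.4, 0.3)
      )
    )
    ages <- ifelse(
      classes == "juvenile",
      sample(4:40, k, replace = TRUE),
      sample(36:240, k, replace = TRUE)
    )
    tibble::tibble(
      individual_id = sprintf("h%02d_i%02d", h, seq_len(k)),
      harem_id = sprintf("h%02d", h),
      age_sex_class = classes,
      age_months = as.numeric(ages)
    )
  })
}

#' Simulate nearest-neighbour scan samples
#'
#' Per period, each member of each harem is present with `p_present`; each
#' present member is recorded alone with `p_alone`, otherwise it names a
#' nearest neighbour drawn from the other present members with planted
#' dyads upweighted by their multiplier.  Draws are independent per
#' individual; the downstream tally symmetrises them.
#'
#' @param cfg A [social_sim_config()].
#' @param roster Optional pre-built roster (one is generated otherwise).
#' @param period_prefix Prefix for period ids (keeps periods from different
#'   calls distinct).
#' @return A list with `scans` (validated scan records), `roster`, and
#'   `truth` (list: `planted` dyads, per-harem `choice_weights` matrices).
#' @export
simulate_scans <- function(cfg, roster = NULL, period_prefix = "p") {
  with_seed(cfg$seed, {
    if (is.null(roster)) roster <- sim_roster(cfg)
    planted <- cfg$planted
    if (!is.null(cfg$auto_plant)) {
      ap <- cfg$auto_plant
      extra <- purrr::map_dfr(split(roster, roster$harem_id), function(r) {
        if (nrow(r) < 2) {
          return(NULL)
        }
        n_d <- min(ap$n_dyads %||% 1L, choose(nrow(r), 2))
        pairs <- t(combn(r$individual_id, 2))
        take <- sample.int(nrow(pairs), n_d)
        tibble::tibble(
          harem_id = r$harem_id[1],
          a_id = pairs[take, 1], b_id = pairs[take, 2],
          multiplier = ap$multiplier %||% 3
        )
      })
      planted <- dplyr::bind_rows(planted, extra)
    }
    harems <- split(roster, roster$harem_id)
    weights <- purrr::map(harems, function(r) {
      ids <- r$individual_id
      w <- matrix(1, nrow(r), nrow(r), dimnames = list(ids, ids))
      diag(w) <- 0
      if (!is.null(planted)) {
        pl <- planted[planted$harem_id == r$harem_id[1], ]
        if (nrow(pl) > 0) {
          w[cbind(pl$a_id, pl$b_id)] <- pl$multiplier
          w[cbind(pl$b_id, pl$a_id)] <- pl$multiplier
        }
      }
      w
    })
    scans <- purrr::map_dfr(harems, function(r) {
      ids <- r$individual_id
      w <- weights[[r$harem_id[1]]]
      purrr::map_dfr(seq_len(cfg$n_periods), function(t) {
        present <- ids[stats::runif(length(ids)) < cfg$p_present]
        if (length(present) == 0) {
          return(NULL)
        }
        neighbor <- vapply(present, function(i) {
          others <- setdiff(present, i)
          if (length(others) == 0 || stats::runif(1) < cfg$p_alone) {
            NA_character_
          } else {
            others[sample.int(length(others), 1, prob = w[i, others])]
          }
        }, character(1))
        tibble::tibble(
          harem_id = r$harem_id[1],
          period_id = sprintf("%s%04d", period_prefix, t),
          individual_id = present,
          behavior_code = sample(
            c("grazing", "resting", "standing", "vigilant"),
            length(present),
            replace = TRUE, prob = c(0.5, 0.2, 0.2, 0.1)
          ),
          neighbor_id = unname(neighbor)
        )
      })
    })
    scans <- validate_scans(scans, roster)
    list(
      scans = scans, roster = roster,
      truth = list(planted = planted, choice_weights = weights)
    )
  })
}

#' Synthetic ethogram with planted context modules
#'
#' Builds a component inventory shaped like a real multimodal repertoire:
#' `n_neutral` neutral baseline states, plus `per_module` active components
#' for each planted context module (by default aggression-, greeting- and
#' affiliation-like).  The first `shared_groups` components of every module
#' are states of shared morphological groups (one state per module, so
#' group size equals the number of modules - these are the mutually
#' exclusive body-part states); remaining components are singleton groups.
#' Each module carries one acoustic and two tactile components, the rest
#' visual.
#'
#' @param modules Character vector of context-module names.
#' @param per_module Active components per module.
#' @param n_neutral Number of neutral states.
#' @param shared_groups Number of morphological groups shared across
#'   modules.
#' @return A list with `etho` (the [ethogram]) and `module_of` (named
#'   vector: active component code -> module name).
#' @export
synthetic_ethogram <- function(modules = c("aggression", "greeting", "affiliation"),
                               per_module = 10, n_neutral = 6,
                               shared_groups = 4) {
  if (shared_groups > per_module) {
    stop_validation("`shared_groups` cannot exceed `per_module`.")
  }
  active <- purrr::map_dfr(seq_along(modules), function(m) {
    codes <- sprintf("%s_%02d", modules[m], seq_len(per_module))
    group_id <- ifelse(
      seq_len(per_module) <= shared_groups,
      sprintf("bodypart_%02d", seq_len(per_module)),
      codes
    )
    modality <- rep("visual", per_module)
    if (per_module >= shared_groups + 1) modality[shared_groups + 1] <- "acoustic"
    if (per_module >= shared_groups + 3) {
      modality[(shared_groups + 2):(shared_groups + 3)] <- "tactile"
    }
    tibble::tibble(
      code = codes, modality = modality, group_id = group_id,
      neutral = FALSE, module = modules[m]
    )
  })
  neutral <- tibble::tibble(
    code = sprintf("neutral_%02d", seq_len(n_neutral)),
    modality = "visual",
    group_id = sprintf("neutral_state_%02d", seq_len(n_neutral)),
    neutral = TRUE, module = NA_character_
  )
  all <- dplyr::bind_rows(active, neutral)
  list(
    etho = ethogram(all[, c("code", "modality", "group_id", "neutral")]),
    module_of = setNames(active$module, active$code)
  )
}

#' Configuration for the interaction/posture generator
#'
#' Each interaction samples a latent context (one of the planted modules);
#' each posture then includes every active component independently with
#' probability `p_within` if the component belongs to the context module
#' and `p_between` otherwise, scaled by the component's base rate (the
#' rarity dial used to exercise the cleaning filter), and each neutral
#' state with probability `p_neutral`.  At most one state per morphological
#' group is kept, so group exclusivity holds by construction.  A repertoire
#' mask lists components that are never produced, simulating signal loss in
#' a later period.
#'
#' @param ethogram_spec Result of [synthetic_ethogram()] (list with `etho`
#'   and `module_of`).
#' @param n_interactions Number of interactions.
#' @param postures_per_interaction Mean postures per interaction
#'   (`1 + Poisson(mean - 1)`).
#' @param p_within,p_between Within-/between-context inclusion
#'   probabilities.
#' @param p_neutral Inclusion probability of each neutral state.
#' @param base_rates Named numeric vector of per-component rate multipliers
#'   (default 1 for all).
#' @param repertoire_mask Character vector of component codes zeroed out.
#' @param period_label Label stamped on the records.
#' @param seed Master seed.
#' @return A list of class `comm_sim_config`.
#' @export
comm_sim_config <- function(ethogram_spec = synthetic_ethogram(),
                            n_interactions = 150,
                            postures_per_interaction = 4,
                            p_within = 0.4, p_between = 0.02,
                            p_neutral = 0.6,
                            base_rates = NULL,
                            repertoire_mask = character(0),
                            period_label = "pre_drought",
                            seed = 1L) {
  stopifnot(
    p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
    p_neutral >= 0, p_neutral <= 1, n_interactions >= 1
  )
  etho <- ethogram_spec$etho
  if (nrow(etho) == 0) stop_validation("Empty component inventory.")
  rates <- setNames(rep(1, nrow(etho)), etho$code)
  if (!is.null(base_rates)) rates[names(base_rates)] <- base_rates
  structure(
    list(
      etho = etho, module_of = ethogram_spec$module_of,
      n_interactions = n_interactions,
      postures_per_interaction = postures_per_interaction,
      p_within = p_within, p_between = p_between, p_neutral = p_neutral,
      base_rates = rates, repertoire_mask = repertoire_mask,
      period_label = period_label, seed = as.integer(seed)
    ),
    class = "comm_sim_config"
  )
}

#' Simulate coded interactions of multimodal postures
#'
#' @param cfg A [comm_sim_config()].
#' @return A list with `interactions` (validated long-format records) and
#'   `truth` (list: `module_of`, `context` per interaction, `mask`).
#' @export
simulate_interactions <- function(cfg) {
  with_seed(cfg$seed, {
    etho <- cfg$etho
    modules <- unique(cfg$module_of)
    active <- names(cfg$module_of)
    neutral <- neutral_components(etho)
    gm <- group_map(etho)
    contexts <- sample(modules, cfg$n_interactions, replace = TRUE)
    n_post <- 1 + stats::rpois(
      cfg$n_interactions, max(cfg$postures_per_interaction - 1, 0)
    )
    n_total <- sum(n_post)
    post_int <- rep(seq_len(cfg$n_interactions), n_post) # posture -> interaction
    post_ctx <- contexts[post_int]

    # inclusion-probability matrix, postures x components
    comps <- c(active, neutral)
    prob <- matrix(
      rep(cfg$p_between * cfg$base_rates[comps], each = n_total),
      n_total, length(comps),
      dimnames = list(NULL, comps)
    )
    for (m in modules) {
      in_m <- which(comps %in% active[cfg$module_of == m])
      prob[post_ctx == m, in_m] <- matrix(
        rep(cfg$p_within * cfg$base_rates[comps[in_m]], each = sum(post_ctx == m)),
        sum(post_ctx == m), length(in_m)
      )
    }
    if (length(neutral) > 0) {
      in_n <- which(comps %in% neutral)
      prob[, in_n] <- matrix(
        rep(cfg$p_neutral * cfg$base_rates[neutral], each = n_total),
        n_total, length(in_n)
      )
    }
    prob[, colnames(prob) %in% cfg$repertoire_mask] <- 0
    sel <- matrix(stats::runif(length(prob)), nrow(prob)) < prob
    colnames(sel) <- comps

    # group exclusivity: within each multi-state morphological group keep at
    # most one selected state per posture
    for (grp in unique(gm[comps])) {
      cols <- which(gm[comps] == grp)
      if (length(cols) < 2) next
      multi <- which(rowSums(sel[, cols, drop = FALSE]) > 1)
      for (r in multi) {
        on <- cols[sel[r, cols]]
        sel[r, setdiff(on, on[sample.int(length(on), 1)])] <- FALSE
      }
    }
    # no empty postures: back-fill one context component
    empty <- which(rowSums(sel) == 0)
    for (r in empty) {
      pool <- setdiff(active[cfg$module_of == post_ctx[r]], cfg$repertoire_mask)
      if (length(pool) == 0) pool <- setdiff(comps, cfg$repertoire_mask)
      if (length(pool) == 0) stop_validation("Repertoire mask leaves no component.")
      pick <- if (length(pool) == 1) pool else {
        sample(pool, 1, prob = cfg$base_rates[pool])
      }
      sel[r, pick] <- TRUE
    }

    hits <- which(sel, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], colnames(sel)[hits[, 2]]), , drop = FALSE]
    post_seq <- sequence(n_post) # posture index within its interaction
    interactions <- tibble::tibble(
      interaction_id = sprintf("int%05d", post_int[hits[, 1]]),
      period_label = cfg$period_label,
      focal_id = sprintf("f%03d", 1 + (post_int[hits[, 1]] %% 20)),
      posture_seq = post_seq[hits[, 1]],
      component_code = colnames(sel)[hits[, 2]],
      context_tag = post_ctx[hits[, 1]]
    )
    interactions <- validate_interactions(interactions, etho)
    list(
      interactions = interactions,
      truth = list(
        module_of = cfg$module_of,
        context = setNames(contexts, sprintf("int%05d", seq_along(contexts))),
        mask = cfg$repertoire_mask
      )
    )
  })
}

#' Configuration for the activity-interval generator
#'
#' @param targets Named vector of target category proportions (must sum
#'   to 1, no negatives).
#' @param n_focals Number of focal individuals.
#' @param period_label Label stamped on the records.
#' @param windows Subsample windows to fill (default all three 5-minute
#'   windows).
#' @param window_s Coded seconds per window (default 300).
#' @param steps_per_min Target step rate written to the steps table.
#' @param seed Master seed.
#' @return A list of class `budget_sim_config`.
#' @export
budget_sim_config <- function(targets, n_focals = 10,
                              period_label = "pre_drought",
                              windows = SUBSAMPLE_WINDOWS,
                              window_s = 300,
                              steps_per_min = 20,
                              seed = 1L) {
  if (any(targets < 0)) stop_validation("Target proportions must be non-negative.")
  if (abs(sum(targets) - 1) > 1e-8) {
    stop_validation("Target proportions must sum to 1.")
  }
  structure(
    list(
      targets = targets, n_focals = n_focals, period_label = period_label,
      windows = windows, window_s = window_s, steps_per_min = steps_per_min,
      seed = as.integer(seed)
    ),
    class = "budget_sim_config"
  )
}

#' Simulate focal activity intervals and step counts
#'
#' Each window of each focal is partitioned into contiguous intervals whose
#' durations match the target proportions up to whole-second rounding.
#' Zero-duration windows are excluded with a warning.
#'
#' @param cfg A [budget_sim_config()].
#' @return A list with `intervals` (validated activity records), `steps`
#'   (per-focal step counts over the coded minutes) and `truth` (the target
#'   proportions).
#' @export
simulate_budgets <- function(cfg) {
  with_seed(cfg$seed, {
    if (cfg$window_s <= 0) {
      warn("Zero-duration window requested; no intervals generated.")
      return(list(
        intervals = tibble::tibble(
          focal_id = character(0), period_label = character(0),
          behavior_category = character(0), subsample_window = character(0),
          start_s = numeric(0), end_s = numeric(0)
        ),
        steps = NULL, truth = list(targets = cfg$targets)
      ))
    }
    cats <- names(cfg$targets)
    intervals <- purrr::map_dfr(seq_len(cfg$n_focals), function(f) {
      purrr::map_dfr(cfg$windows, function(w) {
        secs <- floor(cfg$targets * cfg$window_s)
        left <- cfg$window_s - sum(secs)
        if (left > 0) {
          frac <- cfg$targets * cfg$window_s - secs
          bump <- order(frac, decreasing = TRUE)[seq_len(left)]
          secs[bump] <- secs[bump] + 1
        }
        keep <- secs > 0
        if (!any(keep)) {
          return(NULL)
        }
        ord <- sample(which(keep)) # shuffle interval order within the window
        ends <- cumsum(secs[ord])
        tibble::tibble(
          focal_id = sprintf("f%03d", f),
          period_label = cfg$period_label,
          behavior_category = cats[ord],
          subsample_window = w,
          start_s = c(0, ends[-length(ends)]),
          end_s = ends
        )
      })
    })
    intervals <- validate_activity(intervals)
    minutes <- length(cfg$windows) * cfg$window_s / 60
    steps <- tibble::tibble(
      focal_id = sprintf("f%03d", seq_len(cfg$n_focals)),
      period_label = cfg$period_label,
      n_steps = round(cfg$steps_per_min * minutes),
      minutes_observed = minutes
    )
    list(intervals = intervals, steps = steps, truth = list(targets = cfg$targets))
  })
}
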