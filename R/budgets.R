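# Activity budgets over the coded behaviour taxonomy, step rates, active
# interaction rates, and the juvenile partner-shift contingency table.

#' Default activity-budget taxonomy
#'
#' The coded behaviour categories and their broad classes: self-maintenance
#' behaviours, passive social behaviours (proximity-based, concurrent with a
#' self-maintenance behaviour: social grazing, social rest) and active
#' social behaviours (dedicated interactions with no concurrent maintenance
#' function).  Passive social categories supersede their concurrent
#' maintenance category, so time is never double-counted.
#'
#' @return A tibble with columns `category` and `class`.
#' @export
default_taxonomy <- function() {
  tibble::tibble(
    category = c(
      "drinking", "grazing", "geophagy", "elimination", "olfactory_inspection",
      "traveling", "vigilant", "resting", "hygiene", "standing", "other",
      "social_grazing", "social_rest",
      "affiliation", "aggression", "greeting", "harem_maintenance", "sex", "play"
    ),
    class = c(
      rep("self_maintenance", 11),
      rep("passive_social", 2),
      rep("active_social", 6)
    )
  )
}

#' Compute per-focal activity budgets
#'
#' For each focal individual and period, the proportion of coded time spent
#' in each behaviour category, over the 5-minute subsample windows.  Only
#' coded time enters the denominator.  Off-camera travel bouts supplied as
#' ordinary `traveling` intervals are merged in.  Steps-per-minute is joined
#' from the step counts when given.
#'
#' @param intervals Validated activity intervals (see
#'   [read_activity_table()]).
#' @param steps Optional tibble with `focal_id`, `period_label`, `n_steps`,
#'   `minutes_observed`.
#' @param taxonomy Behaviour taxonomy (default [default_taxonomy()]).
#' @param roster Optional roster; adds `age_sex_class` to the output.
#' @return A long tibble: `focal_id`, `period_label`, `category`, `class`,
#'   `seconds`, `proportion` (per focal x period the proportions sum to 1),
#'   plus `steps_per_min` and `age_sex_class` when available.
#' @export
compute_budget <- function(intervals, steps = NULL, taxonomy = default_taxonomy(),
                           roster = NULL) {
  intervals <- validate_activity(tibble::as_tibble(intervals), taxonomy)
  intervals$duration <- intervals$end_s - intervals$start_s
  budget <- intervals |>
    dplyr::group_by(.data$focal_id, .data$period_label, .data$behavior_category) |>
    dplyr::summarise(seconds = sum(.data$duration), .groups = "drop") |>
    dplyr::group_by(.data$focal_id, .data$period_label) |>
    dplyr::mutate(proportion = .data$seconds / sum(.data$seconds)) |>
    dplyr::ungroup() |>
    dplyr::rename(category = "behavior_category") |>
    dplyr::left_join(taxonomy, by = "category")
  if (!is.null(steps)) {
    steps <- tibble::as_tibble(steps)
    steps$steps_per_min <- steps$n_steps / steps$minutes_observed
    budget <- dplyr::left_join(
      budget,
      steps[, c("focal_id", "period_label", "steps_per_min")],
      by = c("focal_id", "period_label")
    )
  }
  if (!is.null(roster)) {
    budget <- dplyr::left_join(
      budget,
      tibble::as_tibble(roster)[, c("individual_id", "age_sex_class")],
      by = c(focal_id = "individual_id")
    )
  }
  budget
}

#' Aggregate budgets by age/sex class
#'
#' Weighted mean of the per-focal category proportions (weighted by each
#' focal's coded seconds), reproducible from the per-focal rows.
#'
#' @param budget Output of [compute_budget()] including `age_sex_class`.
#' @return A tibble: `period_label`, `age_sex_class`, `category`,
#'   `proportion`.
#' @export
aggregate_budget <- function(budget) {
  if (!"age_sex_class" %in% names(budget)) {
    stop_validation("Budget rows need `age_sex_class` (pass a roster to compute_budget).")
  }
  totals <- budget |>
    dplyr::group_by(.data$focal_id, .data$period_label) |>
    dplyr::summarise(total_s = sum(.data$seconds), .groups = "drop")
  budget |>
    dplyr::left_join(totals, by = c("focal_id", "period_label")) |>
    dplyr::group_by(.data$period_label, .data$age_sex_class, .data$category) |>
    dplyr::summarise(
      proportion = sum(.data$proportion * .data$total_s) / sum(.data$total_s),
      .groups = "drop"
    )
}

#' Active social interaction rate
#'
#' Number of *active* social interactions per 30-minute observation block;
#' passive (proximity-based) social behaviour does not count as an
#' interaction.
#'
#' @param events Tibble of interaction events with `focal_id`,
#'   `period_label` and either a logical `active` column or a `category`
#'   column resolved through `taxonomy`.
#' @param blocks Tibble with `focal_id`, `period_label`, `n_blocks`: the
#'   number of 30-minute blocks each focal was observed.
#' @param taxonomy Behaviour taxonomy (default [default_taxonomy()]).
#' @return A tibble `focal_id`, `period_label`, `n_active`, `n_blocks`,
#'   `interactions_per_30min` (`NA` for zero observed blocks).
#' @export
interaction_rate <- function(events, blocks, taxonomy = default_taxonomy()) {
  events <- tibble::as_tibble(events)
  blocks <- tibble::as_tibble(blocks)
  if (!"active" %in% names(events)) {
    if (!"category" %in% names(events)) {
      stop_validation("`events` needs an `active` flag or a `category` column.")
    }
    cls <- taxonomy$class[match(events$category, taxonomy$category)]
    if (anyNA(cls)) {
      stop_validation("Event categor(ies) absent from taxonomy.")
    }
    events$active <- cls == "active_social"
  }
  counts <- events |>
    dplyr::filter(.data$active) |>
    dplyr::count(.data$focal_id, .data$period_label, name = "n_active")
  out <- blocks |>
    dplyr::left_join(counts, by = c("focal_id", "period_label")) |>
    dplyr::mutate(
      n_active = dplyr::coalesce(.data$n_active, 0L),
      interactions_per_30min = ifelse(
        .data$n_blocks > 0, .data$n_active / .data$n_blocks, NA_real_
      )
    )
  out[, c("focal_id", "period_label", "n_active", "n_blocks", "interactions_per_30min")]
}

#' Juvenile partner-shift contingency table
#'
#' Cross-tabulates juveniles' active interactions by period and by whether
#' the partner was the juvenile's mother, producing the 2 x 2 table (and
#' per-period non-maternal proportions) that a chi-square test of partner
#' shift consumes.  Interactions of juveniles with no known mother are
#' excluded with a warning.
#'
#' @param events Tibble with `focal_id`, `period_label`, `partner_id`, one
#'   row per interaction of a juvenile focal.
#' @param pedigree Tibble with `individual_id`, `mother_id`.
#' @return A list with `table` (2 x 2 matrix, periods x
#'   `c("mother", "non_maternal")`) and `proportions` (tibble of per-period
#'   non-maternal shares).
#' @export
partner_shift_table <- function(events, pedigree) {
  events <- tibble::as_tibble(events)
  pedigree <- tibble::as_tibble(pedigree)
  mother <- setNames(pedigree$mother_id, pedigree$individual_id)
  known <- events$focal_id %in% pedigree$individual_id &
    !is.na(mother[events$focal_id])
  if (any(!known)) {
    warn(sprintf(
      "%d interaction(s) of juveniles with unknown mother excluded.", sum(!known)
    ))
    events <- events[known, ]
  }
  events$partner <- ifelse(
    events$partner_id == mother[events$focal_id], "mother", "non_maternal"
  )
  tab <- table(
    factor(events$period_label),
    factor(events$partner, levels = c("mother", "non_maternal"))
  )
  props <- events |>
    dplyr::group_by(.data$period_label) |>
    dplyr::summarise(
      n = dplyr::n(),
      non_maternal_share = mean(.data$partner == "non_maternal"),
      .groups = "drop"
    )
  list(table = unclass(tab), proportions = props)
}
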