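# Reading and validating the tabular inputs: scan samples, coded
# interactions (long format: one row per posture x component), activity
# intervals, and the harem roster.  Files are UTF-8 CSV/TSV with a header
# row; column names can be remapped through a config list so arbitrary field
# exports can be ingested without editing them.

SCAN_COLUMNS <- c("harem_id", "period_id", "individual_id", "behavior_code", "neighbor_id")
INTERACTION_COLUMNS <- c("interaction_id", "period_label", "focal_id", "posture_seq", "component_code")
ACTIVITY_COLUMNS <- c("focal_id", "period_label", "behavior_category", "subsample_window", "start_s", "end_s")
ROSTER_COLUMNS <- c("individual_id", "harem_id", "age_sex_class")
AGE_SEX_CLASSES <- c("stallion", "lactating_female", "nonlactating_female", "juvenile")
SUBSAMPLE_WINDOWS <- c("w5_10", "w15_20", "w25_30")
ALONE_TOKEN <- "NONE"

read_delim_auto <- function(path, delim = NULL) {
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, trim_ws = TRUE
  )
}

apply_column_map <- function(df, required, config, what) {
  map <- config$columns
  if (!is.null(map)) {
    for (canonical in names(map)) {
      src <- map[[canonical]]
      if (!src %in% names(df)) {
        stop_validation(sprintf(
          "Column `%s` (mapped to `%s`) not found in %s file.", src, canonical, what
        ))
      }
      names(df)[names(df) == src] <- canonical
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_validation(sprintf(
      "%s file is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  df
}

#' Read a harem roster
#'
#' The roster lists every known individual with its harem, age/sex class
#' (`stallion`, `lactating_female`, `nonlactating_female` or `juvenile`) and,
#' optionally, age in months (used for the older-than-one-year network
#' filter).
#'
#' @param path Path to a CSV/TSV file with columns `individual_id`,
#'   `harem_id`, `age_sex_class` and optionally `age_months`.
#' @param config Optional list with `columns` (named character vector mapping
#'   canonical names to file column names) and `delim`.
#' @return A tibble, one row per individual.
#' @export
read_roster <- function(path, config = list()) {
  if (!file.exists(path)) stop_validation(paste0("No such file: ", path))
  df <- read_delim_auto(path, config$delim)
  df <- apply_column_map(df, ROSTER_COLUMNS, config, "roster")
  if (!"age_months" %in% names(df)) df$age_months <- NA_real_
  df$age_months <- as.numeric(df$age_months)
  validate_roster(df[, c(ROSTER_COLUMNS, "age_months")])
}

#' @rdname read_roster
#' @param roster A roster data frame to validate in place.
#' @export
validate_roster <- function(roster) {
  roster <- tibble::as_tibble(roster)
  dup <- roster$individual_id[duplicated(roster$individual_id)]
  if (length(dup) > 0) {
    stop_validation(paste0(
      "Duplicate individual id(s) in roster: ", paste(unique(dup), collapse = ", ")
    ))
  }
  bad <- setdiff(unique(roster$age_sex_class), AGE_SEX_CLASSES)
  if (length(bad) > 0) {
    stop_validation(paste0(
      "Unknown age/sex class(es): ", paste(bad, collapse = ", "),
      ". Allowed: ", paste(AGE_SEX_CLASSES, collapse = ", ")
    ))
  }
  if (any(!is.na(roster$age_months) & roster$age_months < 0)) {
    stop_validation("`age_months` must be non-negative.")
  }
  roster
}

#' Read nearest-neighbour scan samples
#'
#' One row per individual per sampling period, recording its behaviour and
#' its nearest neighbour (an individual within one body length) or the
#' explicit token `NONE` when no harem member was that close.  `NONE` is
#' deliberately distinct from an empty cell: it asserts the individual was
#' observed alone, whereas a blank is a data-entry gap and is rejected.
#'
#' @param path Path to a CSV/TSV file with columns `harem_id`, `period_id`,
#'   `individual_id`, `behavior_code`, `neighbor_id`.
#' @param roster Optional roster tibble; when supplied, individual and
#'   neighbour ids are checked against it (unknown ids are a hard error) and
#'   both members of a record must belong to the record's harem.
#' @param config Optional list with `columns` mapping, `delim`, and
#'   `alone_token` (default `"NONE"`).
#' @return A tibble of validated scan records; `neighbor_id` is `NA` for
#'   individuals observed alone.
#' @export
read_scan_table <- function(path, roster = NULL, config = list()) {
  if (!file.exists(path)) stop_validation(paste0("No such file: ", path))
  df <- read_delim_auto(path, config$delim)
  df <- apply_column_map(df, SCAN_COLUMNS, config, "scan")
  df <- df[, SCAN_COLUMNS]
  token <- config$alone_token %||% ALONE_TOKEN
  df$neighbor_id[df$neighbor_id == token] <- NA_character_
  validate_scans(df, roster = roster)
}

#' @rdname read_scan_table
#' @param scans A scan-record data frame to validate in place (`neighbor_id`
#'   `NA` = observed alone).
#' @export
validate_scans <- function(scans, roster = NULL) {
  scans <- tibble::as_tibble(scans)[, SCAN_COLUMNS]
  blank <- which(is.na(scans$individual_id) | scans$individual_id == "" |
    (!is.na(scans$neighbor_id) & scans$neighbor_id == ""))
  if (length(blank) > 0) {
    stop_validation(paste0(
      "Blank individual or neighbour id at row(s): ",
      paste(head(blank, 10), collapse = ", ")
    ))
  }
  selfie <- which(!is.na(scans$neighbor_id) & scans$neighbor_id == scans$individual_id)
  if (length(selfie) > 0) {
    stop_validation(paste0(
      "neighbor_id equals individual_id at row(s): ",
      paste(head(selfie, 10), collapse = ", ")
    ))
  }
  dup <- duplicated(scans[, c("period_id", "individual_id")])
  if (any(dup)) {
    stop_validation(paste0(
      "Individual recorded twice in one sampling period at row(s): ",
      paste(head(which(dup), 10), collapse = ", ")
    ))
  }
  if (!is.null(roster)) {
    known <- roster$individual_id
    offenders <- setdiff(
      c(scans$individual_id, scans$neighbor_id[!is.na(scans$neighbor_id)]),
      known
    )
    if (length(offenders) > 0) {
      stop_validation(paste0(
        "Id(s) absent from roster: ", paste(offenders, collapse = ", ")
      ))
    }
    harem_of <- setNames(roster$harem_id, roster$individual_id)
    wrong <- which(harem_of[scans$individual_id] != scans$harem_id |
      (!is.na(scans$neighbor_id) & harem_of[scans$neighbor_id] != scans$harem_id))
    if (length(wrong) > 0) {
      stop_validation(paste0(
        "Record member(s) not belonging to the stated harem at row(s): ",
        paste(head(wrong, 10), collapse = ", ")
      ))
    }
  }
  scans
}

#' @rdname read_scan_table
#' @param x Validated scan tibble to write.
#' @param out_path Output CSV path; alone individuals are written with the
#'   `NONE` token.
#' @export
write_scan_table <- function(x, out_path, config = list()) {
  token <- config$alone_token %||% ALONE_TOKEN
  x <- tibble::as_tibble(x)[, SCAN_COLUMNS]
  x$neighbor_id[is.na(x$neighbor_id)] <- token
  readr::write_csv(x, out_path, progress = FALSE)
  invisible(out_path)
}

#' Read coded interactions in long posture format
#'
#' An interaction is an ordered sequence of multimodal postures; a posture is
#' the set of signal components produced concurrently.  The file carries one
#' row per component per posture, with `posture_seq` numbering postures
#' within an interaction.  Every component code must exist in the ethogram,
#' and no posture may contain two states of the same morphological group.
#'
#' @param path Path to a CSV/TSV file with columns `interaction_id`,
#'   `period_label`, `focal_id`, `posture_seq`, `component_code` and
#'   optionally `context_tag`.
#' @param etho An [ethogram].
#' @param config Optional list with `columns` mapping and `delim`.
#' @return A validated tibble in the same long format, `posture_seq` integer.
#' @export
read_interaction_table <- function(path, etho, config = list()) {
  if (!file.exists(path)) stop_validation(paste0("No such file: ", path))
  df <- read_delim_auto(path, config$delim)
  df <- apply_column_map(df, INTERACTION_COLUMNS, config, "interaction")
  if (!"context_tag" %in% names(df)) df$context_tag <- NA_character_
  df <- df[, c(INTERACTION_COLUMNS, "context_tag")]
  df$posture_seq <- as.integer(df$posture_seq)
  validate_interactions(df, etho)
}

#' @rdname read_interaction_table
#' @param interactions Long-format interaction records to validate in place.
#' @export
validate_interactions <- function(interactions, etho) {
  interactions <- tibble::as_tibble(interactions)
  if (!"context_tag" %in% names(interactions)) interactions$context_tag <- NA_character_
  unknown <- setdiff(unique(interactions$component_code), etho$code)
  if (length(unknown) > 0) {
    stop_validation(paste0(
      "Component code(s) absent from ethogram: ", paste(unknown, collapse = ", ")
    ))
  }
  if (anyNA(interactions$posture_seq)) {
    stop_validation("`posture_seq` must be an integer for every row.")
  }
  gm <- group_map(etho)
  key <- paste(interactions$interaction_id, interactions$posture_seq, sep = "\r")
  grp <- gm[interactions$component_code]
  clash_key <- paste(key, grp, sep = "\r")
  dup_comp <- duplicated(paste(key, interactions$component_code, sep = "\r"))
  if (any(dup_comp)) {
    stop_validation("Duplicate component within one posture.")
  }
  clashes <- duplicated(clash_key)
  if (any(clashes)) {
    bad_groups <- unique(grp[clashes])
    stop_validation(paste0(
      "Posture with two components from one morphological group: ",
      paste(bad_groups, collapse = ", ")
    ))
  }
  interactions
}

#' @rdname read_interaction_table
#' @param x Validated interaction tibble to write.
#' @param out_path Output CSV path.
#' @export
write_interaction_table <- function(x, out_path) {
  readr::write_csv(
    tibble::as_tibble(x)[, c(INTERACTION_COLUMNS, "context_tag")],
    out_path,
    progress = FALSE
  )
  invisible(out_path)
}

#' Read focal activity intervals
#'
#' Intervals of coded behaviour within the three 5-minute subsample windows
#' of each focal video (minutes 5-10, 15-20 and 25-30).  Intervals of one
#' focal within one window must not overlap.
#'
#' @param path Path to a CSV/TSV file with columns `focal_id`,
#'   `period_label`, `behavior_category`, `subsample_window` (one of
#'   `w5_10`, `w15_20`, `w25_30`), `start_s`, `end_s`.
#' @param taxonomy Optional behaviour taxonomy tibble (see
#'   [default_taxonomy()]); when supplied, categories are checked against it.
#' @param config Optional list with `columns` mapping and `delim`.
#' @return A validated tibble with numeric `start_s`, `end_s`.
#' @export
read_activity_table <- function(path, taxonomy = NULL, config = list()) {
  if (!file.exists(path)) stop_validation(paste0("No such file: ", path))
  df <- read_delim_auto(path, config$delim)
  df <- apply_column_map(df, ACTIVITY_COLUMNS, config, "activity")
  df <- df[, ACTIVITY_COLUMNS]
  df$start_s <- as.numeric(df$start_s)
  df$end_s <- as.numeric(df$end_s)
  validate_activity(df, taxonomy)
}

#' @rdname read_activity_table
#' @param intervals Activity-interval records to validate in place.
#' @export
validate_activity <- function(intervals, taxonomy = NULL) {
  intervals <- tibble::as_tibble(intervals)
  bad_win <- setdiff(unique(intervals$subsample_window), SUBSAMPLE_WINDOWS)
  if (length(bad_win) > 0) {
    stop_validation(paste0(
      "Unknown subsample window(s): ", paste(bad_win, collapse = ", "),
      ". Allowed: ", paste(SUBSAMPLE_WINDOWS, collapse = ", ")
    ))
  }
  rev_rows <- which(!(intervals$end_s > intervals$start_s))
  if (length(rev_rows) > 0) {
    stop_validation(paste0(
      "Interval end must exceed start at row(s): ",
      paste(head(rev_rows, 10), collapse = ", ")
    ))
  }
  if (!is.null(taxonomy)) {
    bad <- setdiff(unique(intervals$behavior_category), taxonomy$category)
    if (length(bad) > 0) {
      stop_validation(paste0(
        "Behaviour categor(ies) absent from taxonomy: ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  check_interval_overlap(intervals)
  intervals
}

check_interval_overlap <- function(intervals) {
  parts <- split(
    intervals,
    list(intervals$focal_id, intervals$period_label, intervals$subsample_window),
    drop = TRUE
  )
  for (part in parts) {
    if (nrow(part) < 2) next
    ord <- order(part$start_s)
    starts <- part$start_s[ord]
    ends <- part$end_s[ord]
    if (any(starts[-1] < ends[-length(ends)])) {
      stop_validation(sprintf(
        "Overlapping intervals for focal `%s` in window `%s` (%s).",
        part$focal_id[1], part$subsample_window[1], part$period_label[1]
      ))
    }
  }
  invisible(intervals)
}
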