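# The ethogram: the inventory of signal components, their sensory modality,
# their mutually exclusive morphological group, and the neutral-state flag.

MODALITIES <- c("visual", "acoustic", "tactile", "chemical")

#' Create an ethogram from a component table
#'
#' An ethogram lists every signal component that can appear in a coded
#' posture.  Each component carries a sensory modality and belongs to exactly
#' one morphological group: the set of mutually exclusive states of one body
#' part (e.g. ear positions), of which at most one can be held at a time.
#' Components flagged `neutral` are baseline states (e.g. "eyes open") that
#' are typically highly central in co-occurrence networks and can be stripped
#' with [neutral_subgraph()].
#'
#' @param components A data frame with columns `code`, `modality`, `group_id`,
#'   and optionally `label` (defaults to `code`) and `neutral` (defaults to
#'   `FALSE`).
#' @return A tibble of class `ethogram`.
#' @examples
#' ethogram(data.frame(
#'   code = c("ears_forward", "ears_back", "squeal"),
#'   modality = c("visual", "visual", "acoustic"),
#'   group_id = c("ears", "ears", "squeal")
#' ))
#' @export
ethogram <- function(components) {
  components <- tibble::as_tibble(components)
  required <- c("code", "modality", "group_id")
  missing <- setdiff(required, names(components))
  if (length(missing) > 0) {
    stop_validation(paste0(
      "Ethogram is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  if (!"label" %in% names(components)) components$label <- components$code
  if (!"neutral" %in% names(components)) components$neutral <- FALSE
  components$neutral <- as.logical(components$neutral)
  components <- components[, c("code", "label", "modality", "group_id", "neutral")]

  dup <- components$code[duplicated(components$code)]
  if (length(dup) > 0) {
    stop_validation(paste0(
      "Duplicate component code(s) in ethogram: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  bad_mod <- setdiff(unique(components$modality), MODALITIES)
  if (length(bad_mod) > 0) {
    stop_validation(paste0(
      "Unknown modality value(s): ", paste(bad_mod, collapse = ", "),
      ". Allowed: ", paste(MODALITIES, collapse = ", ")
    ))
  }
  if (anyNA(components$code) || anyNA(components$group_id)) {
    stop_validation("Ethogram codes and group ids may not be missing.")
  }
  class(components) <- c("ethogram", class(components))
  components
}

#' Read an ethogram from a YAML or delimited file
#'
#' YAML files must contain a top-level `components` list whose entries have
#' fields `code`, `modality`, `group` (or `group_id`), and optionally `label`
#' and `neutral`.  CSV/TSV files must carry the same names as columns.
#'
#' @param path Path to a `.yaml`/`.yml`, `.csv` or `.tsv` file.
#' @return An [ethogram] tibble.
#' @export
read_ethogram <- function(path) {
  if (!file.exists(path)) stop_validation(paste0("No such file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    raw <- yaml::read_yaml(path)
    if (is.null(raw$components)) {
      stop_validation("Ethogram YAML must have a top-level `components` list.")
    }
    rows <- purrr::map(raw$components, function(cmp) {
      tibble::tibble(
        code = cmp$code %||% NA_character_,
        label = cmp$label %||% cmp$code,
        modality = cmp$modality %||% NA_character_,
        group_id = cmp$group_id %||% cmp$group %||% NA_character_,
        neutral = isTRUE(cmp$neutral)
      )
    })
    df <- dplyr::bind_rows(rows)
  } else {
    df <- read_delim_auto(path)
    if ("group" %in% names(df) && !"group_id" %in% names(df)) {
      df <- dplyr::rename(df, group_id = "group")
    }
  }
  ethogram(df)
}

#' Neutral-state components of an ethogram
#'
#' @param etho An [ethogram].
#' @return Character vector of component codes flagged as neutral states.
#' @export
neutral_components <- function(etho) {
  etho$code[etho$neutral]
}

#' Morphological group sizes over a set of components
#'
#' @param etho An [ethogram].
#' @param codes Component codes to restrict to (default: all).
#' @return Named integer vector: number of states per morphological group
#'   among `codes`.
#' @export
group_sizes <- function(etho, codes = etho$code) {
  unknown <- setdiff(codes, etho$code)
  if (length(unknown) > 0) {
    stop_validation(paste0(
      "Component code(s) absent from ethogram: ",
      paste(unknown, collapse = ", ")
    ))
  }
  sub <- etho[etho$code %in% codes, ]
  tab <- table(sub$group_id)
  setNames(as.integer(tab), names(tab))
}

# map code -> group_id
group_map <- function(etho) {
  setNames(etho$group_id, etho$code)
}

#' Write an ethogram to YAML
#'
#' @param etho An [ethogram].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(etho, path) {
  comps <- purrr::pmap(
    list(etho$code, etho$label, etho$modality, etho$group_id, etho$neutral),
    function(code, label, modality, group_id, neutral) {
      list(
        code = code, label = label, modality = modality,
        group = group_id, neutral = neutral
      )
    }
  )
  yaml::write_yaml(list(components = comps), path)
  invisible(path)
}
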