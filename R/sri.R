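# Dyadic association from nearest-neighbour scan samples: the simple ratio
# index (SRI) and the per-pair period tallies behind it.

#' Simple ratio index of association
#'
#' `sri = x / (y_a + y_b + y_ab + x)`, where `x` is the number of sampling
#' periods in which the two individuals were in association, `y_a` and `y_b`
#' the periods in which each was observed alone, and `y_ab` the periods in
#' which both were observed but not in association.  All arguments are
#' vectorised.
#'
#' @param x,y_a,y_b,y_ab Non-negative period counts.
#' @return Numeric in `[0, 1]`.  A pair with an all-zero denominator (never
#'   jointly observable) gets 0 with a warning.
#' @examples
#' compute_sri(3, 1, 1, 0) # 0.6
#' compute_sri(2, 1, 0, 1) # 0.5
#' @export
compute_sri <- function(x, y_a, y_b, y_ab) {
  counts <- cbind(x, y_a, y_b, y_ab)
  if (any(counts < 0, na.rm = TRUE)) {
    stop_validation("SRI counts must be non-negative.")
  }
  denom <- x + y_a + y_b + y_ab
  out <- ifelse(denom > 0, x / denom, 0)
  if (any(denom == 0)) {
    warn("SRI denominator zero for some pair(s); index reported as 0.")
  }
  as.numeric(out)
}

# Compact per-harem representation of the scan data, used by both the tally
# and the scan-permutation null so that a permutation replicate never has to
# touch data frames.
#
# Returns: ids (character), T periods, and per-period integer structures:
#   present[[t]]  indices observed in period t
#   alone[[t]]    indices observed alone: NONE neighbour record and not
#                 named as anyone's neighbour (symmetrised)
#   pairs[[t]]    2-column integer matrix of associated pairs (symmetrised,
#                 deduplicated, a < b)
scan_period_data <- function(scans) {
  ids <- sort(unique(c(scans$individual_id, scans$neighbor_id[!is.na(scans$neighbor_id)])))
  idx <- setNames(seq_along(ids), ids)
  periods <- split(scans, scans$period_id)
  pd <- purrr::map(periods, function(p) {
    # an individual named as someone's neighbour was observed even if its
    # own record is missing from the period
    present <- sort(unique(unname(
      idx[c(p$individual_id, p$neighbor_id[!is.na(p$neighbor_id)])]
    )))
    named <- !is.na(p$neighbor_id)
    if (any(named)) {
      a <- unname(idx[p$individual_id[named]])
      b <- unname(idx[p$neighbor_id[named]])
      pr <- cbind(pmin(a, b), pmax(a, b))
      pr <- pr[!duplicated(paste(pr[, 1], pr[, 2])), , drop = FALSE]
      in_pair <- unique(as.vector(pr))
    } else {
      pr <- matrix(integer(0), ncol = 2)
      in_pair <- integer(0)
    }
    none_rec <- unname(idx[p$individual_id[!named]])
    alone <- setdiff(none_rec, in_pair)
    list(present = present, alone = alone, pairs = pr)
  })
  list(ids = ids, n = length(ids), periods = unname(pd))
}

# Accumulate the per-pair period counts from a scan_period_data object.
# alone_rule:
#   "scan"     - y_a counts periods in which a was observed alone (explicit
#                NONE neighbour, not named by anyone); a period with both
#                members present and both (or neither) alone falls to y_ab.
#   "presence" - classic Cairns-Schwager reading: y_a counts periods with
#                only a observed, and every both-present non-associated
#                period is y_ab.  Counts then partition the periods in which
#                at least one member was observed.
tally_counts <- function(pd, alone_rule = c("scan", "presence")) {
  alone_rule <- match.arg(alone_rule)
  n <- pd$n
  X <- matrix(0, n, n)
  B <- matrix(0, n, n)
  n_alone <- numeric(n)
  both_alone <- matrix(0, n, n)
  M1 <- matrix(0, n, n) # [a,b]: a alone, b present and not alone
  P_only <- matrix(0, n, n) # [a,b]: a present, b absent
  n_present <- numeric(n)

  for (p in pd$periods) {
    pres <- p$present
    B[pres, pres] <- B[pres, pres] + 1
    n_present[pres] <- n_present[pres] + 1
    if (nrow(p$pairs) > 0) {
      X[p$pairs] <- X[p$pairs] + 1
    }
    al <- p$alone
    if (length(al) > 0) {
      n_alone[al] <- n_alone[al] + 1
      both_alone[al, al] <- both_alone[al, al] + 1
      not_al <- setdiff(pres, al)
      if (length(not_al) > 0) M1[al, not_al] <- M1[al, not_al] + 1
    }
    absent <- seq_len(n)[-pres]
    if (length(absent) > 0) P_only[pres, absent] <- P_only[pres, absent] + 1
  }
  X <- X + t(X)
  diag(X) <- 0
  diag(B) <- 0

  if (alone_rule == "scan") {
    # y_a = periods a alone and b not alone (b present-with-others or absent)
    Ya <- matrix(n_alone, n, n) - both_alone
    diag(Ya) <- 0
    Yab <- B - X - M1 - t(M1)
  } else {
    Ya <- P_only
    Yab <- B - X
  }
  list(X = X, Ya = Ya, Yab = Yab, B = B, n_present = n_present)
}

counts_to_tallies <- function(pd, ct) {
  n <- pd$n
  if (n < 2) {
    return(tibble::tibble(
      a_id = character(0), b_id = character(0),
      x = integer(0), y_a = integer(0), y_b = integer(0), y_ab = integer(0),
      sri = numeric(0)
    ))
  }
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- ct$n_present[ut[, 1]] > 0 & ct$n_present[ut[, 2]] > 0
  ut <- ut[keep, , drop = FALSE]
  x <- ct$X[ut]
  y_a <- ct$Ya[ut]
  y_b <- ct$Ya[ut[, c(2, 1), drop = FALSE]]
  y_ab <- ct$Yab[ut]
  denom <- x + y_a + y_b + y_ab
  tibble::tibble(
    a_id = pd$ids[ut[, 1]],
    b_id = pd$ids[ut[, 2]],
    x = as.integer(x),
    y_a = as.integer(y_a),
    y_b = as.integer(y_b),
    y_ab = as.integer(y_ab),
    sri = ifelse(denom > 0, x / denom, 0)
  )
}

#' Tally dyadic association counts from scan samples
#'
#' For every unordered pair of harem mates observed in at least one sampling
#' period, counts the periods in association (`x`), observed alone (`y_a`,
#' `y_b`) and both observed but not in association (`y_ab`), and computes the
#' simple ratio index.  The nearest-neighbour relation is symmetrised: a pair
#' is in association in a period if either member named the other as nearest
#' neighbour.
#'
#' Two readings of "observed alone" are available.  Under the default
#' `alone_rule = "scan"`, an individual is alone in a period when its record
#' carries the explicit no-neighbour token and nobody named it; an individual
#' absent from a period contributes to no count for that period.  Under
#' `"presence"`, `y_a` counts periods in which only `a` was observed
#' (the classic formulation), so the four counts partition the periods in
#' which at least one member was observed.
#'
#' @param scans Validated scan records (see [read_scan_table()]).
#' @param roster Optional roster; when given, tallies are computed per harem
#'   using roster membership, otherwise per `harem_id` in the scan records.
#' @param alone_rule `"scan"` (default) or `"presence"`.
#' @return A tibble with columns `harem_id`, `a_id`, `b_id` (`a_id < b_id`),
#'   `x`, `y_a`, `y_b`, `y_ab`, `sri`.  Empty scans give an empty tibble.
#' @export
tally_dyads <- function(scans, roster = NULL, alone_rule = c("scan", "presence")) {
  alone_rule <- match.arg(alone_rule)
  scans <- tibble::as_tibble(scans)
  if (nrow(scans) == 0) {
    return(tibble::tibble(
      harem_id = character(0), a_id = character(0), b_id = character(0),
      x = integer(0), y_a = integer(0), y_b = integer(0), y_ab = integer(0),
      sri = numeric(0)
    ))
  }
  if (!is.null(roster)) {
    validate_scans(scans, roster)
  }
  parts <- split(scans, scans$harem_id)
  out <- purrr::imap(parts, function(sc, hid) {
    pd <- scan_period_data(sc)
    ct <- tally_counts(pd, alone_rule)
    t <- counts_to_tallies(pd, ct)
    t$harem_id <- hid
    t
  })
  dplyr::bind_rows(out)[, c("harem_id", "a_id", "b_id", "x", "y_a", "y_b", "y_ab", "sri")]
}
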