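# Per-harem, per-period nearest-neighbour association networks and their
# metrics; the preferred-associate permutation test; cross-period
# comparisons.

#' Build a harem association network
#'
#' Nodes are the harem's members older than one year (unknown ages are kept,
#' on the assumption that unaged animals are adults); edges join pairs with
#' a positive simple ratio index and carry it as weight.  Node metrics are
#' degree (number of positive-SRI associates), the mean and the coefficient
#' of variation of the node's dyadic SRI values.  Harem-level metrics are
#' network density (edges over possible pairs) and the CV of the harem's
#' dyadic SRI values.
#'
#' By default the mean/CV computations include the structural zeros of
#' co-resident dyads never seen in association, so that heterogeneity is
#' measured over the full set of possible bonds; set
#' `include_zero_dyads = FALSE` to restrict to realised bonds only.
#'
#' @param tallies Dyad tallies from [tally_dyads()] (one harem's rows).
#' @param roster Roster tibble restricted to or containing the harem.
#' @param harem_id Harem to build (required when `tallies`/`roster` span
#'   several harems).
#' @param period_label Label stored on the network (e.g. `"pre_drought"`).
#' @param min_age_months Minimum age for inclusion (default 12).
#' @param include_zero_dyads Include zero-SRI co-resident dyads in mean/CV
#'   computations (default `TRUE`).
#' @return An object of class `harem_network`: a list with the igraph
#'   `graph`, the `dyads` tibble, `node_metrics`, `density`, `cv_harem` and
#'   the build settings.  A harem with fewer than two eligible members gets
#'   `density = NA`.
#' @export
build_harem_network <- function(tallies, roster, harem_id = NULL,
                                period_label = NULL,
                                min_age_months = 12,
                                include_zero_dyads = TRUE) {
  tallies <- tibble::as_tibble(tallies)
  roster <- tibble::as_tibble(roster)
  if (is.null(harem_id)) {
    hid <- unique(c(tallies$harem_id, roster$harem_id))
    if (length(hid) != 1) {
      stop_validation("Multiple harems present; supply `harem_id`.")
    }
    harem_id <- hid
  }
  roster <- roster[roster$harem_id == harem_id, ]
  if ("harem_id" %in% names(tallies)) {
    tallies <- tallies[tallies$harem_id == harem_id, ]
  }
  eligible <- roster$individual_id[is.na(roster$age_months) |
    roster$age_months >= min_age_months]
  tallies <- tallies[tallies$a_id %in% eligible & tallies$b_id %in% eligible, ]
  nodes <- sort(intersect(eligible, unique(c(tallies$a_id, tallies$b_id))))

  edges <- tallies[tallies$sri > 0, c("a_id", "b_id", "sri")]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a_id, to = edges$b_id, weight = edges$sri),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )

  n <- length(nodes)
  density <- if (n < 2) NA_real_ else nrow(edges) / choose(n, 2)
  dyad_values <- if (include_zero_dyads) tallies$sri else tallies$sri[tallies$sri > 0]
  cv_harem <- if (length(dyad_values) >= 2 && mean(dyad_values) > 0) {
    suppressWarnings(coefficient_of_variation(dyad_values))
  } else {
    NA_real_
  }

  node_metrics <- purrr::map_dfr(nodes, function(v) {
    vals <- c(tallies$sri[tallies$a_id == v], tallies$sri[tallies$b_id == v])
    if (!include_zero_dyads) vals <- vals[vals > 0]
    tibble::tibble(
      individual_id = v,
      degree = sum(vals > 0),
      mean_sri = if (length(vals) > 0) mean(vals) else NA_real_,
      cv_sri = if (length(vals) >= 2 && mean(vals) > 0) {
        suppressWarnings(coefficient_of_variation(vals))
      } else if (length(vals) >= 2) {
        NA_real_
      } else {
        NA_real_
      }
    )
  })
  if (nrow(node_metrics) > 0 && any(node_metrics$degree > n - 1)) {
    stop("internal error: degree exceeds n - 1") # nocov
  }

  structure(
    list(
      harem_id = harem_id,
      period_label = period_label,
      graph = g,
      nodes = nodes,
      dyads = tallies,
      node_metrics = node_metrics,
      density = density,
      cv_harem = cv_harem,
      settings = list(
        min_age_months = min_age_months,
        include_zero_dyads = include_zero_dyads,
        cv_sd_type = "sample"
      )
    ),
    class = "harem_network"
  )
}

#' @export
print.harem_network <- function(x, ...) {
  cat(sprintf(
    "Harem network `%s`%s: %d nodes, %d edges, density %.3g, CV %.3g\n",
    x$harem_id,
    if (!is.null(x$period_label)) paste0(" [", x$period_label, "]") else "",
    length(x$nodes), igraph::ecount(x$graph), x$density, x$cv_harem
  ))
  invisible(x)
}

# CV of dyadic weights over the dyads among *connected* nodes: the m edge
# weights plus one structural zero per non-adjacent pair of connected nodes.
# This is the statistic the edge-permutation null varies through (isolated
# nodes drop out of an edge-list network, changing the zero count).
cv_connected_dyads <- function(weights, n_connected) {
  m <- length(weights)
  zeros <- choose(n_connected, 2) - m
  vals <- c(weights, rep(0, zeros))
  if (length(vals) < 2 || mean(vals) <= 0) {
    return(NA_real_)
  }
  sd(vals) / mean(vals)
}

#' Test for preferred associates within a harem
#'
#' Compares the observed heterogeneity of a harem's association strengths
#' (the coefficient of variation of its dyadic SRI values) against a null
#' distribution, with the upper-tail convention: `p` is the proportion of
#' null CVs at least as high as the observed one.  A significantly high CV
#' indicates preferred associates.  The analysis is restricted to harems
#' with more than four members, below which strong bonds with every member
#' are attainable and the CV carries little meaning.
#'
#' Two null models are provided:
#'
#' * `null = "edges"` - network randomization: each replicate places the
#'   observed multiset of SRI weights onto a uniformly random simple graph
#'   with the same node and edge counts, and recomputes the CV of the dyadic
#'   weights among the randomized network's connected nodes (structural
#'   zeros included).  Because the weight multiset itself is held fixed,
#'   this null varies only through the number of nodes the random graph
#'   leaves isolated; it is retained as the literal network-permutation
#'   procedure, but has essentially no power against dyadic preference.
#' * `null = "scans"` - data-stream permutation: each replicate relabels the
#'   identities of the individuals present within every sampling period
#'   independently, retallies the SRIs and recomputes the harem CV.  This
#'   preserves each period's group composition and association structure
#'   while breaking dyad identity across periods, and is the null to use
#'   for inference about social preference.
#'
#' @param net A [build_harem_network()] object.
#' @param n_perm Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @param null `"edges"` (default, the network-randomization null) or
#'   `"scans"`.
#' @param scans Scan records for the harem (required for `null = "scans"`).
#' @param convention P-value counting convention, see [permutation_result()].
#' @param alone_rule Tally rule for `null = "scans"`, see [tally_dyads()].
#' @return A [permutation_result()] (`tail = "upper"`).
#' @export
preferred_associate_test <- function(net, n_perm = 1000, seed = NULL,
                                     null = c("edges", "scans"),
                                     scans = NULL,
                                     convention = c("count", "plus_one"),
                                     alone_rule = c("scan", "presence")) {
  null <- match.arg(null)
  convention <- match.arg(convention)
  assert_count(n_perm, "n_perm")
  if (n_perm < 1) stop_validation("`n_perm` must be at least 1.")
  n <- length(net$nodes)
  if (n <= 4) {
    stop_validation(sprintf(
      "Preferred-associate test requires more than 4 individuals; harem `%s` has %d.",
      net$harem_id, n
    ))
  }
  m <- igraph::ecount(net$graph)
  if (m < 1) stop_validation("Network has no edges; nothing to randomize.")
  weights <- igraph::E(net$graph)$weight

  if (null == "edges") {
    k_obs <- sum(igraph::degree(net$graph) > 0)
    observed <- cv_connected_dyads(weights, k_obs)
    all_pairs <- t(combn(n, 2))
    nulls <- with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        take <- sample.int(nrow(all_pairs), m)
        k <- length(unique(as.vector(all_pairs[take, ])))
        cv_connected_dyads(weights, k)
      }, numeric(1))
    })
    return(permutation_result(observed, nulls,
      tail = "upper", seed = seed,
      convention = convention, method = "edge randomization (fixed nodes and edges)"
    ))
  }

  # scan-permutation null
  if (is.null(scans)) {
    stop_validation("`null = \"scans\"` requires the harem's scan records.")
  }
  alone_rule <- match.arg(alone_rule)
  scans <- tibble::as_tibble(scans)
  scans <- scans[scans$harem_id == net$harem_id, ]
  # restrict to the network's (age-filtered) node set; a neighbour outside
  # it (e.g. a foal) is treated as no neighbour among the analysed nodes
  scans <- scans[scans$individual_id %in% net$nodes, ]
  scans$neighbor_id[
    !is.na(scans$neighbor_id) & !(scans$neighbor_id %in% net$nodes)
  ] <- NA_character_
  pd <- scan_period_data(scans)
  nn <- pd$n
  ut <- which(upper.tri(matrix(0, nn, nn)), arr.ind = TRUE)
  lt <- ut[, c(2, 1), drop = FALSE]
  harem_cv_from_counts <- function(ct) {
    keep <- ct$n_present[ut[, 1]] > 0 & ct$n_present[ut[, 2]] > 0
    x <- ct$X[ut][keep]
    y_a <- ct$Ya[ut][keep]
    y_b <- ct$Ya[lt][keep]
    y_ab <- ct$Yab[ut][keep]
    denom <- x + y_a + y_b + y_ab
    vals <- ifelse(denom > 0, x / denom, 0)
    if (!net$settings$include_zero_dyads) vals <- vals[vals > 0]
    if (length(vals) < 2 || mean(vals) <= 0) {
      return(NA_real_)
    }
    sd(vals) / mean(vals)
  }
  observed <- harem_cv_from_counts(tally_counts(pd, alone_rule))
  relab_map <- integer(nn)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_perm), function(r) {
      pd_r <- pd
      pd_r$periods <- lapply(pd$periods, function(p) {
        pres <- p$present
        relab_map[pres] <- pres[sample.int(length(pres))]
        pairs <- p$pairs
        if (nrow(pairs) > 0) {
          a <- relab_map[pairs[, 1]]
          b <- relab_map[pairs[, 2]]
          pairs <- cbind(pmin(a, b), pmax(a, b))
        }
        list(present = pres, alone = relab_map[p$alone], pairs = pairs)
      })
      harem_cv_from_counts(tally_counts(pd_r, alone_rule))
    }, numeric(1))
  })
  permutation_result(observed, nulls,
    tail = "upper", seed = seed,
    convention = convention, method = "within-period identity permutation"
  )
}

#' Regress dyadic association strength across periods
#'
#' Ordinary least squares of the late-period SRI on the pre-period SRI over
#' the dyads present in both periods, quantifying whether bond strength
#' carries over.
#'
#' @param tallies_pre,tallies_late Tallies from [tally_dyads()] for the two
#'   periods.
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`,
#'   `p_value` and `n_dyads`, or (with a warning) all-`NA` when fewer than
#'   three dyads are shared.
#' @export
cross_period_dyad_regression <- function(tallies_pre, tallies_late) {
  pre <- tibble::as_tibble(tallies_pre)
  late <- tibble::as_tibble(tallies_late)
  key <- function(d) paste(d$harem_id, pair_key(d$a_id, d$b_id), sep = "\r")
  shared <- dplyr::inner_join(
    dplyr::tibble(k = key(pre), sri_pre = pre$sri),
    dplyr::tibble(k = key(late), sri_late = late$sri),
    by = "k"
  )
  if (nrow(shared) < 3) {
    warn("Fewer than 3 dyads shared across periods; regression not run.")
    return(tibble::tibble(
      slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
      p_value = NA_real_, n_dyads = nrow(shared)
    ))
  }
  fit <- lm(sri_late ~ sri_pre, data = shared)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = if (nrow(shared) > 2 && s$fstatistic[1] > 0) {
      unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
        lower.tail = FALSE
      ))
    } else {
      NA_real_
    },
    n_dyads = nrow(shared)
  )
}

#' Paired comparison of network metrics across periods
#'
#' Builds a long-format table of harem-, node- and dyad-level metrics for
#' the units (harems, individuals, dyads) present in both periods, ready for
#' paired tests (Wilcoxon signed-rank etc., which are left to standard
#' routines).
#'
#' @param nets_pre,nets_late Lists of [build_harem_network()] objects, named
#'   or keyed by their `harem_id`.
#' @return A tibble with columns `level` (`"harem"`, `"node"`, `"dyad"`),
#'   `metric`, `harem_id`, `unit_id`, `pre`, `late`, `delta`.  Empty (with a
#'   warning) when no harem is shared.
#' @export
compare_periods <- function(nets_pre, nets_late) {
  by_id <- function(nets) setNames(nets, purrr::map_chr(nets, "harem_id"))
  pre <- by_id(nets_pre)
  late <- by_id(nets_late)
  shared <- intersect(names(pre), names(late))
  if (length(shared) == 0) {
    warn("No harem present in both periods; empty comparison.")
    return(tibble::tibble(
      level = character(0), metric = character(0), harem_id = character(0),
      unit_id = character(0), pre = numeric(0), late = numeric(0),
      delta = numeric(0)
    ))
  }
  rows <- purrr::map(shared, function(h) {
    a <- pre[[h]]
    b <- late[[h]]
    harem_rows <- tibble::tibble(
      level = "harem",
      metric = c("density", "cv_harem"),
      harem_id = h, unit_id = h,
      pre = c(a$density, a$cv_harem),
      late = c(b$density, b$cv_harem)
    )
    nodes <- intersect(a$node_metrics$individual_id, b$node_metrics$individual_id)
    node_rows <- purrr::map_dfr(c("degree", "mean_sri", "cv_sri"), function(mt) {
      am <- a$node_metrics[match(nodes, a$node_metrics$individual_id), ]
      bm <- b$node_metrics[match(nodes, b$node_metrics$individual_id), ]
      tibble::tibble(
        level = "node", metric = mt, harem_id = h, unit_id = nodes,
        pre = as.numeric(am[[mt]]), late = as.numeric(bm[[mt]])
      )
    })
    ka <- pair_key(a$dyads$a_id, a$dyads$b_id)
    kb <- pair_key(b$dyads$a_id, b$dyads$b_id)
    kd <- intersect(ka, kb)
    dyad_rows <- tibble::tibble(
      level = "dyad", metric = "sri", harem_id = h,
      unit_id = gsub("\r", "--", kd, fixed = TRUE),
      pre = a$dyads$sri[match(kd, ka)],
      late = b$dyads$sri[match(kd, kb)]
    )
    dplyr::bind_rows(harem_rows, node_rows, dyad_rows)
  })
  out <- dplyr::bind_rows(rows)
  out$delta <- out$late - out$pre
  out
}
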