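# Harem network construction, metrics, the preferred-associate test and
# cross-period comparison.

# build a network directly from a hand-specified dyad table
net_from_dyads <- function(dyads, n, include_zero_dyads = TRUE) {
  roster <- adult_roster(n)
  ids <- roster$individual_id
  all_pairs <- t(combn(ids, 2))
  tal <- tibble::tibble(
    harem_id = "h01", a_id = all_pairs[, 1], b_id = all_pairs[, 2],
    x = 0L, y_a = 0L, y_b = 0L, y_ab = 0L, sri = 0
  )
  for (r in seq_len(nrow(dyads))) {
    hit <- tal$a_id == dyads$a[r] & tal$b_id == dyads$b[r]
    tal$sri[hit] <- dyads$w[r]
  }
  build_harem_network(tal, roster,
    harem_id = "h01",
    include_zero_dyads = include_zero_dyads
  )
}

test_that("density and degree follow the edge structure", {
  complete3 <- net_from_dyads(
    tibble::tibble(
      a = c("h01_i01", "h01_i01", "h01_i02"),
      b = c("h01_i02", "h01_i03", "h01_i03"), w = 0.5
    ),
    n = 3
  )
  expect_equal(complete3$density, 1)
  expect_equal(complete3$node_metrics$degree, c(2, 2, 2))

  half4 <- net_from_dyads(
    tibble::tibble(
      a = c("h01_i01", "h01_i01", "h01_i02"),
      b = c("h01_i02", "h01_i03", "h01_i04"), w = c(0.4, 0.2, 0.1)
    ),
    n = 4
  )
  expect_equal(half4$density, 3 / choose(4, 2))

  # zero-variance dyadic SRIs give cv_sri 0 (zero dyads excluded)
  nm <- net_from_dyads(
    tibble::tibble(
      a = c("h01_i01", "h01_i01", "h01_i01"),
      b = c("h01_i02", "h01_i03", "h01_i04"), w = 0.2
    ),
    n = 4, include_zero_dyads = FALSE
  )
  expect_equal(
    nm$node_metrics$cv_sri[nm$node_metrics$individual_id == "h01_i01"], 0
  )
})

test_that("eligibility: under-one-year individuals are excluded, tiny harems degrade", {
  roster <- adult_roster(4)
  roster$age_months[4] <- 6 # a foal
  scans <- dplyr::bind_rows(
    scan_row("p1", "h01_i01", "h01_i02"), scan_row("p1", "h01_i02", "h01_i01"),
    scan_row("p1", "h01_i03", "h01_i04"), scan_row("p1", "h01_i04", "h01_i03")
  )
  tal <- tally_dyads(scans, roster)
  net <- build_harem_network(tal, roster, harem_id = "h01")
  expect_false("h01_i04" %in% net$nodes)

  lone <- build_harem_network(tal[0, ], adult_roster(1), harem_id = "h01")
  expect_true(is.na(lone$density))
})

test_that("preferred-associate test enforces the >4-member restriction", {
  small <- net_from_dyads(
    tibble::tibble(a = "h01_i01", b = "h01_i02", w = 0.5),
    n = 4
  )
  expect_error(
    preferred_associate_test(small, n_perm = 10, seed = 1),
    "more than 4"
  )
})

test_that("edge-null test returns ties as non-significant for uniform weights", {
  # all weights equal and dense enough that no placement isolates a node:
  # every null CV ties the observed one, p = 1 under the count convention
  pairs <- t(combn(sprintf("h01_i%02d", 1:5), 2))
  net <- net_from_dyads(
    tibble::tibble(a = pairs[, 1], b = pairs[, 2], w = 0.3),
    n = 5
  )
  pt <- preferred_associate_test(net, n_perm = 50, seed = 3, null = "edges")
  expect_equal(pt$p_value, 1)
  expect_equal(pt$significant, "ns")
})

test_that("scan-permutation null flags a harem with one dominant bond", {
  withr::with_seed(42, {
    ros <- adult_roster(6)
    cfg <- social_sim_config(
      n_harems = 1, n_periods = 40, size_range = c(6, 6),
      planted = tibble::tibble(
        harem_id = "h01", a_id = "h01_i01", b_id = "h01_i02", multiplier = 6
      ),
      seed = 99
    )
    sim <- simulate_scans(cfg, roster = ros)
    tal <- tally_dyads(sim$scans, ros)
    net <- build_harem_network(tal, ros, harem_id = "h01")
    pt <- preferred_associate_test(net,
      n_perm = 400, seed = 7,
      null = "scans", scans = sim$scans
    )
    expect_lt(pt$p_value, 0.05)
    # the p-value obeys the count/n convention exactly
    expect_equal(
      pt$p_value, sum(pt$null_values >= pt$observed) / pt$n_perm
    )
  })
})

test_that("permutation result conventions count ties toward the tail", {
  pr <- permutation_result(2, c(1, 2, 3, 3), tail = "upper")
  expect_equal(pr$p_value, 3 / 4) # 2, 3, 3 are >= 2
  pr1 <- permutation_result(2, c(1, 2, 3, 3), tail = "upper", convention = "plus_one")
  expect_equal(pr1$p_value, 4 / 5)
  pr2 <- permutation_result(4, c(1, 2, 3, 3), tail = "upper")
  expect_equal(pr2$p_value, 0)
})

test_that("cross-period dyadic regression matches the closed-form oracle", {
  mk <- function(sri) {
    tibble::tibble(
      harem_id = "h01",
      a_id = sprintf("a%02d", seq_along(sri)),
      b_id = sprintf("b%02d", seq_along(sri)),
      x = 1L, y_a = 0L, y_b = 0L, y_ab = 0L, sri = sri
    )
  }
  pre <- c(0.1, 0.3, 0.5, 0.8)
  late <- c(0.2, 0.35, 0.4, 0.9)
  fit <- cross_period_dyad_regression(mk(pre), mk(late))
  # normal equations solved independently
  X <- cbind(1, pre)
  beta <- solve(t(X) %*% X, t(X) %*% late)
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$slope, beta[2], tolerance = 1e-12)
  resid <- late - X %*% beta
  r2 <- 1 - sum(resid^2) / sum((late - mean(late))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-12)

  # a perfect fit makes summary.lm grumble; only the coefficients matter
  ident <- suppressWarnings(cross_period_dyad_regression(mk(pre), mk(pre)))
  expect_equal(ident$slope, 1)
  expect_equal(ident$r_squared, 1)

  withr::with_seed(5, {
    big_pre <- runif(400)
    big_late <- runif(400) # independent of pre
    indep <- cross_period_dyad_regression(mk(big_pre), mk(big_late))
    expect_lt(indep$r_squared, 0.02)
  })

  expect_warning(
    out <- cross_period_dyad_regression(mk(pre)[1:2, ], mk(late)[1:2, ]),
    "Fewer than 3"
  )
  expect_true(is.na(out$slope))
})

test_that("paired cross-period table restricts to shared units and tracks deltas", {
  dy <- tibble::tibble(
    a = c("h01_i01", "h01_i02"), b = c("h01_i02", "h01_i03"), w = c(0.4, 0.2)
  )
  net_pre <- net_from_dyads(dy, n = 3)
  same <- compare_periods(list(net_pre), list(net_pre))
  expect_true(all(same$delta == 0))

  dy_late <- dy
  dy_late$w[1] <- 0.2 # first edge halved
  net_late <- net_from_dyads(dy_late, n = 3)
  cmp <- compare_periods(list(net_pre), list(net_late))
  d <- cmp[cmp$level == "dyad", ]
  expect_equal(
    d$delta[d$unit_id == "h01_i01--h01_i02"], -0.2
  )
  expect_equal(d$delta[d$unit_id == "h01_i02--h01_i03"], 0)

  # an individual present only in pre is excluded from node rows
  net_small <- net_from_dyads(dy[1, ], n = 2)
  cmp2 <- compare_periods(list(net_pre), list(net_small))
  expect_false("h01_i03" %in% cmp2$unit_id[cmp2$level == "node"])

  expect_warning(
    empty <- compare_periods(list(net_pre), list()),
    "No harem"
  )
  expect_equal(nrow(empty), 0)
})
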