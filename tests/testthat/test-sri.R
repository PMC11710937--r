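# The simple ratio index and the per-pair period tallies.

test_that("compute_sri reproduces hand evaluations and stays in [0, 1]", {
  expect_equal(compute_sri(3, 1, 1, 0), 0.6)
  expect_equal(compute_sri(2, 1, 0, 1), 0.5)
  expect_equal(compute_sri(0, 2, 1, 3), 0)
  expect_equal(compute_sri(5, 0, 0, 0), 1)
  expect_warning(out <- compute_sri(0, 0, 0, 0), "zero")
  expect_equal(out, 0)
  expect_error(compute_sri(-1, 0, 0, 0), "non-negative")
  # vectorised
  expect_equal(compute_sri(c(3, 2), c(1, 1), c(1, 0), c(0, 1)), c(0.6, 0.5))
})

test_that("tallies match the hand-worked five-period fixture", {
  # a and b neighbours in 3 of 5 shared periods; a observed alone once
  # (b with c), b observed alone once (a with c); never both-present-apart
  scans <- dplyr::bind_rows(
    scan_row("p1", "a", "b"), scan_row("p1", "b", "a"), scan_row("p1", "c"),
    scan_row("p2", "a", "b"), scan_row("p2", "b", "a"), scan_row("p2", "c"),
    scan_row("p3", "a", "b"), scan_row("p3", "b", "a"), scan_row("p3", "c"),
    scan_row("p4", "a"), scan_row("p4", "b", "c"), scan_row("p4", "c", "b"),
    scan_row("p5", "a", "c"), scan_row("p5", "b"), scan_row("p5", "c", "a")
  )
  tal <- tally_dyads(scans)
  ab <- tal[tal$a_id == "a" & tal$b_id == "b", ]
  expect_equal(ab$x, 3L)
  expect_equal(ab$y_a, 1L)
  expect_equal(ab$y_b, 1L)
  expect_equal(ab$y_ab, 0L)
  expect_equal(ab$sri, 0.6)
  # under the presence rule the same fixture gives x = 3, y_ab = 2
  tal_p <- tally_dyads(scans, alone_rule = "presence")
  ab_p <- tal_p[tal_p$a_id == "a" & tal_p$b_id == "b", ]
  expect_equal(ab_p$x, 3L)
  expect_equal(ab_p$y_ab, 2L)
  expect_equal(ab_p$sri, 0.6)
})

test_that("extreme pairs give sri 0 and 1; empty scans give empty tallies", {
  apart <- dplyr::bind_rows(
    scan_row("p1", "a", "c"), scan_row("p1", "b"), scan_row("p1", "c", "a"),
    scan_row("p2", "a"), scan_row("p2", "b", "c"), scan_row("p2", "c", "b")
  )
  tal <- tally_dyads(apart)
  expect_equal(tal$sri[tal$a_id == "a" & tal$b_id == "b"], 0)

  always <- dplyr::bind_rows(
    scan_row("p1", "a", "b"), scan_row("p1", "b", "a"),
    scan_row("p2", "a", "b"), scan_row("p2", "b", "a")
  )
  tal2 <- tally_dyads(always)
  expect_equal(tal2$sri, 1)

  empty <- tally_dyads(scans = tibble::tibble(
    harem_id = character(0), period_id = character(0),
    individual_id = character(0), behavior_code = character(0),
    neighbor_id = character(0)
  ))
  expect_equal(nrow(empty), 0)
})

test_that("tallies are symmetric under who names whom", {
  # only a names b
  one_way <- dplyr::bind_rows(
    scan_row("p1", "a", "b"), scan_row("p1", "b")
  )
  # only b names a
  other_way <- dplyr::bind_rows(
    scan_row("p1", "a"), scan_row("p1", "b", "a")
  )
  expect_equal(tally_dyads(one_way)$x, 1L)
  expect_equal(
    as.data.frame(tally_dyads(one_way)),
    as.data.frame(tally_dyads(other_way))
  )
})

test_that("SRI is monotone in added association / both-present-apart periods", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      # random base history for a pair inside a 4-member harem
      n_periods <- sample(3:8, 1)
      base <- purrr::map_dfr(seq_len(n_periods), function(t) {
        p <- sprintf("p%02d", t)
        rows <- list(scan_row(p, "c", "d"), scan_row(p, "d", "c"))
        if (runif(1) < 0.8) {
          rows <- c(rows, list(
            scan_row(p, "a", sample(c(NA, "b", "c"), 1)),
            scan_row(p, "b", sample(c(NA, "a", "d"), 1))
          ))
        }
        dplyr::bind_rows(rows)
      })
      sri0 <- function(sc) {
        t <- tally_dyads(sc)
        t$sri[t$a_id == "a" & t$b_id == "b"]
      }
      s0 <- sri0(base)
      if (length(s0) == 0) next
      plus_assoc <- dplyr::bind_rows(
        base,
        scan_row("zz1", "a", "b"), scan_row("zz1", "b", "a")
      )
      plus_apart <- dplyr::bind_rows(
        base,
        scan_row("zz1", "a", "c"), scan_row("zz1", "c", "a"),
        scan_row("zz1", "b", "d"), scan_row("zz1", "d", "b")
      )
      expect_gte(sri0(plus_assoc), s0)
      expect_lte(sri0(plus_apart), s0)
      expect_true(all(dplyr::between(tally_dyads(base)$sri, 0, 1)))
    }
  })
})

test_that("presence-rule counts partition the at-least-one-observed periods", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      cfg <- social_sim_config(
        n_harems = 1, n_periods = 12, size_range = c(4, 6),
        p_present = 0.7, seed = 500 + rep
      )
      sim <- simulate_scans(cfg)
      tal <- tally_dyads(sim$scans, sim$roster, alone_rule = "presence")
      periods_seen <- function(id) {
        unique(sim$scans$period_id[
          sim$scans$individual_id == id |
            (!is.na(sim$scans$neighbor_id) & sim$scans$neighbor_id == id)
        ])
      }
      for (r in seq_len(nrow(tal))) {
        expected <- length(union(
          periods_seen(tal$a_id[r]), periods_seen(tal$b_id[r])
        ))
        expect_equal(
          tal$x[r] + tal$y_a[r] + tal$y_b[r] + tal$y_ab[r], expected
        )
      }
      # scan rule: x + y_ab never exceeds the both-present period count,
      # and all counts are non-negative
      tal_s <- tally_dyads(sim$scans, sim$roster, alone_rule = "scan")
      expect_true(all(tal_s[, c("x", "y_a", "y_b", "y_ab")] >= 0))
    }
  })
})

test_that("coefficient of variation matches hand values and edge cases", {
  expect_equal(coefficient_of_variation(c(0.1, 0.3)), sd(c(0.1, 0.3)) / 0.2)
  expect_equal(round(coefficient_of_variation(c(0.1, 0.3)), 4), 0.7071)
  expect_equal(coefficient_of_variation(c(0.2, 0.2, 0.2)), 0)
  expect_warning(out <- coefficient_of_variation(0.5), "two values")
  expect_true(is.na(out))
  expect_warning(out2 <- coefficient_of_variation(c(0, 0)), "mean")
  expect_true(is.na(out2))
  # population variant is smaller by sqrt((n-1)/n)
  v <- c(0.1, 0.2, 0.6)
  expect_equal(
    coefficient_of_variation(v, "population"),
    coefficient_of_variation(v) * sqrt(2 / 3)
  )
})
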