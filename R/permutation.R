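# Container and conventions for permutation / resampling null models.

#' Construct a permutation-test result
#'
#' Bundles the observed statistic, the vector of null replicates, and the
#' p-value under the requested tail and counting convention.  The default
#' convention follows the count/n rule (number of null values at least as
#' extreme as the observed, divided by the number of replicates), with ties
#' counted toward the tail; the `"plus_one"` convention, (count + 1)/(n + 1),
#' is available as an alternative.
#'
#' For `tail = "two_sided"` the p-value is twice the smaller tail proportion
#' (capped at 1), and the decision recorded in `$significant` follows the
#' percentile rule: `"greater"` when the observed value exceeds the 0.975
#' quantile of the null, `"less"` when it falls below the 0.025 quantile,
#' `"ns"` otherwise, with ties resolved conservatively as non-significant.
#'
#' @param observed Observed value of the statistic.
#' @param null_values Numeric vector of null replicates.
#' @param tail `"upper"`, `"lower"`, or `"two_sided"`.
#' @param seed Seed used to generate the replicates (stored for the record).
#' @param convention `"count"` (default) or `"plus_one"`.
#' @param method Free-text label of the null model.
#' @param alpha Two-sided significance level for the percentile decision.
#' @return An object of class `perm_test`: a list with elements `observed`,
#'   `null_values`, `p_value`, `n_perm`, `seed`, `tail`, `method`,
#'   `q_lower`, `q_upper` and `significant`.
#' @export
permutation_result <- function(observed, null_values,
                               tail = c("upper", "lower", "two_sided"),
                               seed = NULL,
                               convention = c("count", "plus_one"),
                               method = NULL,
                               alpha = 0.05) {
  tail <- match.arg(tail)
  convention <- match.arg(convention)
  null_values <- as.numeric(null_values)
  n <- length(null_values)
  if (n < 1) stop_validation("At least one null replicate is required.")

  p_tail <- function(count) {
    if (convention == "count") count / n else (count + 1) / (n + 1)
  }
  p_up <- p_tail(sum(null_values >= observed))
  p_lo <- p_tail(sum(null_values <= observed))
  p <- switch(tail,
    upper = p_up,
    lower = p_lo,
    two_sided = min(1, 2 * min(p_up, p_lo))
  )

  q <- quantile(null_values, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  significant <- if (tail == "two_sided") {
    if (!is.na(observed) && observed > q[2]) {
      "greater"
    } else if (!is.na(observed) && observed < q[1]) {
      "less"
    } else {
      "ns"
    }
  } else if (!is.na(p) && p < alpha) "yes" else "ns"

  structure(
    list(
      observed = observed,
      null_values = null_values,
      p_value = p,
      n_perm = n,
      seed = seed,
      tail = tail,
      convention = convention,
      method = method,
      q_lower = q[1],
      q_upper = q[2],
      significant = significant
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Permutation test", if (!is.null(x$method)) paste0("(", x$method, ")"), "\n")
  cat(sprintf("  observed: %.6g\n", x$observed))
  cat(sprintf(
    "  null: n = %d, mean = %.6g, 2.5%% = %.6g, 97.5%% = %.6g\n",
    x$n_perm, mean(x$null_values), x$q_lower, x$q_upper
  ))
  cat(sprintf(
    "  p (%s, %s convention) = %.4g [%s]\n",
    x$tail, x$convention, x$p_value, x$significant
  ))
  invisible(x)
}
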