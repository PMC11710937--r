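# Internal helpers shared across modules.

# Run `expr` under a deterministic RNG state without disturbing the caller's
# stream.  All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stop_validation <- function(msg) {
  abort(msg, class = "socioscope_validation_error")
}

assert_count <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != floor(x)) {
    stop_validation(sprintf("`%s` must be a single non-negative integer.", name))
  }
  invisible(as.integer(x))
}

# unordered pair key, stable under swapping a and b
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Coefficient of variation
#'
#' Standard deviation divided by the mean, the dispersion measure used both
#' for an individual's bond strengths and for a harem's dyadic association
#' indices.  The sample standard deviation (n - 1 denominator) is the
#' default; the population variant can be requested for comparison with
#' software that uses it.
#'
#' @param values Numeric vector.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return A single number, or `NA` (with a warning) when fewer than two
#'   values are supplied or the mean is not positive.
#' @examples
#' coefficient_of_variation(c(0.1, 0.3))
#' @export
coefficient_of_variation <- function(values, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    warn("CV requires at least two values; returning NA.")
    return(NA_real_)
  }
  m <- mean(values)
  if (m <= 0) {
    warn("CV undefined for non-positive mean; returning NA.")
    return(NA_real_)
  }
  s <- sd(values)
  if (sd_type == "population") {
    n <- length(values)
    s <- s * sqrt((n - 1) / n)
  }
  s / m
}
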