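# broom-style tidiers for the package's fitted/test objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn hotspot_significance One row per null simulation.
#' @param x A `hotspot_test` / `null_distribution` object.
#' @param ... Unused.
#' @method tidy null_distribution
#' @export
tidy.null_distribution <- function(x, ...) {
  tibble(simulation = seq_along(x$fractions), fraction = x$fractions)
}

#' @describeIn simulate_null One-row summary of the null distribution.
#' @param x A `null_distribution` object.
#' @param ... Unused.
#' @method glance null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble(n_sim = x$n_sim, space_size = x$space_size,
         min_support = x$min_support, mean_fraction = mean(x$fractions),
         sd_fraction = stats::sd(x$fractions))
}

#' @describeIn hotspot_significance One-row tidy summary of the test.
#' @method tidy hotspot_test
#' @export
tidy.hotspot_test <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean, null_sd = x$null_sd,
         statistic = x$statistic, df = x$df, p_value = x$p_value,
         degenerate = x$degenerate)
}

#' @describeIn hotspot_significance Alias of `tidy()` for this object.
#' @method glance hotspot_test
#' @export
glance.hotspot_test <- function(x, ...) tidy.hotspot_test(x, ...)
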