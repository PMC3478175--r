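#' Tidy a power-law fit
#'
#' @param x A `powerlaw_fit` from [fit_powerlaw()].
#' @param ... Unused.
#' @return A tibble with one row per regression term (`log10(size)` slope
#'   is the avalanche exponent alpha) and columns `term`, `estimate`.
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "log10(size)"),
                 estimate = c(x$intercept, x$alpha))
}

#' One-row summary of a power-law fit
#'
#' @param x A `powerlaw_fit` from [fit_powerlaw()].
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `intercept`, `r_squared`,
#'   `fit_min`, `fit_max`, `n_sizes_used`, `n_avalanches`, `accepted`.
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, intercept = x$intercept,
                 r_squared = x$r_squared,
                 fit_min = x$fit_min, fit_max = x$fit_max,
                 n_sizes_used = x$n_sizes_used,
                 n_avalanches = x$n_avalanches, accepted = x$accepted)
}

#' Per-session table of a study
#'
#' @param x An `avalanche_study` from [run_study()].
#' @param ... Unused.
#' @return The per-session tibble (`session_id`, `condition`, `alpha`,
#'   `r_squared`, `n_avalanches`, `accepted`, `error`).
#' @method tidy avalanche_study
#' @export
tidy.avalanche_study <- function(x, ...) x$sessions

#' One-row summary of a study
#'
#' @param x An `avalanche_study` from [run_study()].
#' @param ... Unused.
#' @return A one-row tibble: session/condition counts, exclusions, and
#'   the smallest pairwise p-value (NA when no comparison was possible).
#' @method glance avalanche_study
#' @export
glance.avalanche_study <- function(x, ...) {
  tibble::tibble(
    n_sessions = nrow(x$sessions),
    n_conditions = nrow(x$groups),
    n_excluded = x$n_excluded,
    n_comparisons = nrow(x$comparisons),
    min_p_value = if (nrow(x$comparisons)) min(x$comparisons$p_value) else NA_real_)
}
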