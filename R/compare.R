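#' Run the full pipeline on one recording
#'
#' Composes filter -> detect -> bin -> extract -> distribution -> fit and
#' returns the power-law fit with full provenance (every configuration
#' value and seed that produced it). Errors raised by a stage are
#' re-signalled with the stage name prefixed, so a degenerate session is
#' attributable.
#'
#' @param rec A [recording()].
#' @param config A [pipeline_config()].
#' @return A `powerlaw_fit` (see [fit_powerlaw()]) whose `provenance`
#'   echoes the pipeline configuration and the recording's own provenance.
#' @export
alpha_for_recording <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "recording"), inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("stage %s: %s", name, conditionMessage(e))))
  }
  raster <- stage("detect", detect_nlfp(rec, config$detection))
  frames <- stage("bin", bin_raster(raster, config$bin_ms))
  av <- stage("extract", extract_avalanches(frames, config$drop_boundary))
  dist <- stage("distribution", size_distribution(av))
  fit <- stage("fit", fit_powerlaw(dist, config$fit))
  fit$provenance <- list(
    pipeline = list(
      detection = unclass(config$detection), bin_ms = config$bin_ms,
      fit = unclass(config$fit), alpha_level = config$alpha_level,
      drop_boundary = config$drop_boundary, rng_seed = config$rng_seed),
    recording = c(list(condition = rec$condition,
                       session_id = rec$session_id,
                       sampling_rate_hz = rec$sampling_rate_hz,
                       n_channels = nrow(rec$samples)),
                  rec$provenance),
    n_events = nrow(raster))
  fit
}

#' Compare fitted alpha between two groups (Student's t-test)
#'
#' Two-sided, two-sample, equal-variance (Student's) t-test on per-session
#' alpha values, with `df = n_a + n_b - 2`. Welch's unequal-variance
#' variant is available behind `var_equal = FALSE`.
#'
#' @param a,b Numeric vectors of per-session alpha values (each `n >= 2`).
#' @param alpha_level Significance level (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @param var_equal Pool variances (Student's test, default `TRUE`).
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `t_statistic`, `df`, `p_value`, `significant`.
#' @examples
#' compare_groups(c(-1.2, -1.3, -1.25), c(-1.0, -1.05, -0.95))
#' @export
compare_groups <- function(a, b, alpha_level = 0.05,
                           labels = c("a", "b"), var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    abort("compare_groups: each group needs n >= 2 sessions")
  if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b))
    abort("degenerate comparison: both groups constant and equal")
  tt <- t.test(a, b, var.equal = var_equal)
  tibble::tibble(
    group_a = labels[[1]], group_b = labels[[2]],
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha_level)
}

#' Run a full synthetic study end to end
#'
#' Analyses every session of a study with [alpha_for_recording()],
#' summarises alpha per condition (mean, SD, SEM over sessions), and runs
#' all pairwise Student's t-tests between conditions. Sessions whose fit
#' fails the R-squared acceptance criterion, or that error out (e.g. no
#' avalanches), are excluded from group statistics and reported.
#'
#' @param study An `avalanche_study_design` from [make_study()] (lazy
#'   designs are simulated and rendered one session at a time), or a bare
#'   list of [recording()]s carrying condition labels.
#' @param config A [pipeline_config()].
#' @return A list of class `avalanche_study` with elements `sessions`
#'   (per-session tibble), `groups` (per-condition summaries over accepted
#'   sessions), `comparisons` (pairwise tests), `n_excluded`, and `config`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
run_study <- function(study, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(study, "avalanche_study_design")) {
    n <- nrow(study$design)
    get_rec <- function(i) study$recordings[[i]] %||% realize_session(study, i)
  } else {
    n <- length(study)
    get_rec <- function(i) study[[i]]
  }
  if (n < 1) abort("run_study: no sessions")

  sessions <- purrr::map_dfr(seq_len(n), function(i) {
    rec <- get_rec(i)
    row <- tibble::tibble(session_id = rec$session_id,
                          condition = rec$condition)
    res <- tryCatch({
      fit <- alpha_for_recording(rec, config)
      tibble::tibble(alpha = fit$alpha, r_squared = fit$r_squared,
                     n_avalanches = fit$n_avalanches,
                     accepted = fit$accepted, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(alpha = NA_real_, r_squared = NA_real_,
                     n_avalanches = NA_integer_, accepted = FALSE,
                     error = conditionMessage(e))
    })
    rm(rec)
    dplyr::bind_cols(row, res)
  })

  usable <- dplyr::filter(sessions, .data$accepted)
  n_excluded <- nrow(sessions) - nrow(usable)
  if (n_excluded > 0)
    message(sprintf("run_study: %d session(s) excluded (fit rejected or stage error)",
                    n_excluded))
  groups <- dplyr::summarise(
    dplyr::group_by(usable, .data$condition),
    n = dplyr::n(), mean_alpha = mean(.data$alpha),
    sd_alpha = sd(.data$alpha),
    sem_alpha = sd(.data$alpha) / sqrt(dplyr::n()), .groups = "drop")

  conds <- groups$condition[groups$n >= 2]
  comparisons <- if (length(conds) >= 2) {
    purrr::map_dfr(utils::combn(conds, 2, simplify = FALSE), function(pr) {
      compare_groups(usable$alpha[usable$condition == pr[[1]]],
                     usable$alpha[usable$condition == pr[[2]]],
                     alpha_level = config$alpha_level, labels = pr)
    })
  } else {
    tibble::tibble()
  }

  structure(list(sessions = sessions, groups = groups,
                 comparisons = comparisons, n_excluded = n_excluded,
                 config = config,
                 master_seed = if (inherits(study, "avalanche_study_design"))
                   study$master_seed),
            class = "avalanche_study")
}

#' @export
print.avalanche_study <- function(x, ...) {
  cat(sprintf("<avalanche_study> %d sessions (%d excluded), %d condition(s)\n",
              nrow(x$sessions), x$n_excluded, nrow(x$groups)))
  print(x$groups)
  if (nrow(x$comparisons)) {
    cat("comparisons:\n")
    print(x$comparisons)
  }
  invisible(x)
}
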