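# Direct age-standardization of smoothed rates with Monte Carlo
# propagation of posterior uncertainty: R_i = sum_j w_j * theta[i,j], with
# theta[i,j] sampled from its gamma posterior.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Crude (unsmoothed) age-standardized rates
#'
#' The directly standardized rate computed from raw age-specific crude
#' rates: `R_i = sum_j w_j * y[i,j] / n[i,j]`.
#'
#' @param cube A `count_cube`.
#' @param weights Standard-population age weights (normalized, one per age
#'   group).
#' @return Named numeric vector of rates (events per person-year), one per
#'   region.
#' @export
crude_standardized <- function(cube, weights) {
  stopifnot(inherits(cube, "count_cube"))
  weights <- check_weights(weights, ncol(cube$y))
  drop((cube$y / cube$n) %*% weights)
}

check_weights <- function(weights, J) {
  if (length(weights) != J)
    stop(sprintf("expected %d age weights, got %d", J, length(weights)),
         call. = FALSE)
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("age weights must be nonnegative and sum to 1 (see normalize_standard)",
         call. = FALSE)
  weights
}

#' Monte Carlo posterior of an age-standardized rate
#'
#' Samples each age group's gamma posterior independently and forms the
#' weighted sum, so the uncertainty of the smoothed age-specific rates
#' propagates into the standardized rate. The point estimate is the mean of
#' the draws and the interval their empirical 2.5/97.5 percentiles.
#'
#' @param shape,rate Posterior gamma parameters, one per age group.
#' @param weights Standard-population age weights.
#' @param n_draws Number of Monte Carlo draws (at least 1000), default
#'   10000.
#' @param seed RNG seed; the same seed reproduces the draws exactly.
#' @param level Credible level, default 0.95.
#' @return List with `draws`, `point_estimate`, and `ci = c(lo, hi)`.
#' @export
standardized_posterior <- function(shape, rate, weights, n_draws = 10000,
                                   seed = 42, level = 0.95) {
  J <- length(shape)
  if (length(rate) != J || anyNA(shape) || anyNA(rate))
    stop("need one (shape, rate) posterior per age group", call. = FALSE)
  weights <- check_weights(weights, J)
  if (n_draws < 1000) stop("n_draws must be at least 1000", call. = FALSE)
  draws <- with_seed(seed, {
    th <- matrix(stats::rgamma(n_draws * J, shape = rep(shape, each = n_draws),
                               rate = rep(rate, each = n_draws)),
                 n_draws, J)
    drop(th %*% weights)
  })
  a <- (1 - level) / 2
  list(draws = draws,
       point_estimate = mean(draws),
       ci = unname(stats::quantile(draws, c(a, 1 - a))))
}

# Batch version over all regions of an eb_fit; returns a data frame with
# one row per region (estimate, lo, hi). Draw order is fixed (age group
# within region) so results are reproducible for a given seed.
standardize_fit <- function(fit, weights, n_draws = 10000, seed = 42,
                            level = 0.95) {
  stopifnot(inherits(fit, "eb_fit"))
  R <- nrow(fit$shape); J <- ncol(fit$shape)
  weights <- check_weights(weights, J)
  a <- (1 - level) / 2
  with_seed(seed, {
    acc <- matrix(0, n_draws, R)
    for (j in seq_len(J)) {
      th <- matrix(stats::rgamma(n_draws * R, shape = rep(fit$shape[, j], each = n_draws),
                                 rate = rep(fit$rate[, j], each = n_draws)),
                   n_draws, R)
      acc <- acc + weights[j] * th
    }
    ci <- apply(acc, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    data.frame(region_id = fit$cube$region_ids,
               estimate = colMeans(acc), lo = ci[1, ], hi = ci[2, ],
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

#' Classify estimate reliability from its credible interval
#'
#' An estimate is unreliable when the width of its 95% credible interval
#' exceeds the point estimate itself.
#'
#' @param estimate Point estimate(s).
#' @param lo,hi Interval endpoints.
#' @return Logical vector, `TRUE` where unreliable.
#' @export
classify_reliability <- function(estimate, lo, hi) {
  if (any(hi < lo)) stop("interval with hi < lo", call. = FALSE)
  (hi - lo) > estimate
}

#' Combine per-method reliability flags into an alert code
#'
#' Three alert types are reported: an unreliable nonspatial estimate, an
#' unreliable spatial estimate, and an unreliable estimate overall (neither
#' method reliable).
#'
#' @param ns_unreliable,sp_unreliable Logical vectors from
#'   [classify_reliability()] for the nonspatial and spatial estimates.
#' @return Character vector: `"none"`, `"unreliable_nonspatial"`,
#'   `"unreliable_spatial"`, or `"unreliable_both"`.
#' @export
combine_alerts <- function(ns_unreliable, sp_unreliable) {
  ifelse(ns_unreliable & sp_unreliable, "unreliable_both",
  ifelse(ns_unreliable, "unreliable_nonspatial",
  ifelse(sp_unreliable, "unreliable_spatial", "none")))
}

#' Compare a credible interval with a reference rate
#'
#' A region's rate differs significantly from the reference when its 95%
#' credible interval excludes the reference: `"higher"` when the whole
#' interval lies above it, `"lower"` when below, otherwise
#' `"not_different"`. An interval can be wide enough to flag the estimate
#' as unreliable and still lie entirely below (or above) the reference.
#'
#' @param lo,hi Interval endpoints.
#' @param reference Positive reference rate (e.g. the domain's crude
#'   age-standardized rate).
#' @return Character vector of classifications.
#' @export
classify_vs_reference <- function(lo, hi, reference) {
  if (any(reference <= 0)) stop("reference rate must be positive", call. = FALSE)
  if (any(hi < lo)) stop("interval with hi < lo", call. = FALSE)
  ifelse(lo > reference, "higher", ifelse(hi < reference, "lower", "not_different"))
}

#' Per-region output records: smoothed standardized rates, alerts, and
#' significance classes
#'
#' Runs the full estimation stage for a count cube: crude standardized
#' rates, nonspatial and/or spatial EB smoothing, Monte Carlo standardized
#' posteriors, reliability alerts, and classification against the domain's
#' crude age-standardized rate.
#'
#' @param cube A `count_cube`.
#' @param weights Standard-population age weights.
#' @param method `"nonspatial"`, `"spatial"`, or `"both"` (default).
#' @param nd An `nb_dict` (required unless `method = "nonspatial"`).
#' @param prior_weight Optional prior-weight override, see [eb_fit()].
#' @param n_draws,seed Monte Carlo settings, see [standardized_posterior()].
#' @param scale Output scale; rates are reported per `scale` person-years
#'   (default 100000).
#' @return Data frame with one row per region and columns `region_id`,
#'   `crude_std_rate`, `ns_rate`, `ns_lo`, `ns_hi`, `sp_rate`, `sp_lo`,
#'   `sp_hi`, `alert`, `ns_vs_ref`, `sp_vs_ref`. Columns of a method not
#'   run are `NA`; its reliability is treated as unreliable when combining
#'   alerts is not applicable, so `alert` then reflects the single method
#'   run (`"none"` or the method-specific alert). The attribute
#'   `reference_rate` records the reference on the output scale.
#' @export
region_estimates <- function(cube, weights, method = c("both", "nonspatial", "spatial"),
                             nd = NULL, prior_weight = NULL, n_draws = 10000,
                             seed = 42, scale = 1e5) {
  method <- match.arg(method)
  stopifnot(inherits(cube, "count_cube"))
  weights <- check_weights(weights, ncol(cube$y))
  if (!is.numeric(scale) || scale <= 0) stop("scale must be positive", call. = FALSE)

  crude <- crude_standardized(cube, weights)
  # reference: the whole domain's crude age-standardized rate
  reference <- sum(weights * global_rates(cube))

  out <- data.frame(region_id = cube$region_ids,
                    crude_std_rate = crude * scale,
                    ns_rate = NA_real_, ns_lo = NA_real_, ns_hi = NA_real_,
                    sp_rate = NA_real_, sp_lo = NA_real_, sp_hi = NA_real_,
                    alert = NA_character_,
                    ns_vs_ref = NA_character_, sp_vs_ref = NA_character_,
                    row.names = NULL, stringsAsFactors = FALSE)

  ns_unrel <- sp_unrel <- NULL
  if (method %in% c("both", "nonspatial")) {
    fit <- eb_fit(cube, "nonspatial", prior_weight = prior_weight)
    std <- standardize_fit(fit, weights, n_draws = n_draws, seed = seed)
    out$ns_rate <- std$estimate * scale
    out$ns_lo <- std$lo * scale
    out$ns_hi <- std$hi * scale
    ns_unrel <- classify_reliability(std$estimate, std$lo, std$hi)
    out$ns_vs_ref <- classify_vs_reference(std$lo, std$hi, reference)
  }
  if (method %in% c("both", "spatial")) {
    fit <- eb_fit(cube, "spatial", nd = nd, prior_weight = prior_weight)
    std <- standardize_fit(fit, weights, n_draws = n_draws, seed = seed + 1L)
    out$sp_rate <- std$estimate * scale
    out$sp_lo <- std$lo * scale
    out$sp_hi <- std$hi * scale
    sp_unrel <- classify_reliability(std$estimate, std$lo, std$hi)
    out$sp_vs_ref <- classify_vs_reference(std$lo, std$hi, reference)
  }

  out$alert <- if (method == "both") combine_alerts(ns_unrel, sp_unrel)
    else if (method == "nonspatial") ifelse(ns_unrel, "unreliable_nonspatial", "none")
    else ifelse(sp_unrel, "unreliable_spatial", "none")

  attr(out, "reference_rate") <- reference * scale
  out
}
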