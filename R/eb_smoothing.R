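# Conjugate Poisson-gamma empirical Bayes smoothing of age-specific rates.
#
# Model per region i and age group j:
#   y[i,j] | theta[i,j] ~ Poisson(n[i,j] * theta[i,j])
#   theta[i,j] ~ Gamma(shape = t[i,j] * m[j], rate = m[j])
# where t is the smoothing target (global rate for nonspatial smoothing,
# pooled neighbor crude rate for spatial smoothing) and m[j] is the prior
# weight in person-years: the prior carries as much information as m[j]
# person-years of observation. Conjugacy gives the closed-form posterior
#   theta[i,j] | y ~ Gamma(y[i,j] + t[i,j]*m[j], n[i,j] + m[j]).

#' Pooled age-specific rates of the whole spatial domain
#'
#' The nonspatial smoothing target: for each age group, total events over
#' total person-years across all regions.
#'
#' @param cube A `count_cube`.
#' @return Numeric vector of rates (events per person-year), one per age
#'   group.
#' @export
global_rates <- function(cube) {
  stopifnot(inherits(cube, "count_cube"))
  colSums(cube$y) / colSums(cube$n)
}

#' Pooled neighborhood age-specific rates
#'
#' The spatial smoothing target: for each region, the crude rate of its
#' combined contiguous neighbors (the focal region excluded). Regions whose
#' neighborhood provides no signal fall back to the domain-wide rate: when
#' the region is an island, when the neighbors' pooled person-years are
#' zero, or when the neighbors have zero events (a gamma prior cannot be
#' centered at zero).
#'
#' @param cube A `count_cube`.
#' @param nd An `nb_dict` covering every region in the cube.
#' @return Numeric matrix (regions x age groups) of target rates.
#' @export
neighborhood_rates <- function(cube, nd) {
  stopifnot(inherits(cube, "count_cube"), inherits(nd, "nb_dict"))
  missing <- setdiff(cube$region_ids, names(nd$neighbors))
  if (length(missing) > 0)
    stop(sprintf("region(s) missing from neighborhood dictionary: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  r <- global_rates(cube)
  t_mat <- matrix(NA_real_, nrow(cube$y), ncol(cube$y),
                  dimnames = dimnames(cube$y))
  for (i in seq_along(cube$region_ids)) {
    nbr <- intersect(nd$neighbors[[cube$region_ids[i]]], cube$region_ids)
    if (length(nbr) == 0) {
      t_mat[i, ] <- r
      next
    }
    ysum <- colSums(cube$y[nbr, , drop = FALSE])
    nsum <- colSums(cube$n[nbr, , drop = FALSE])
    ti <- ifelse(nsum > 0 & ysum > 0, ysum / nsum, r)
    t_mat[i, ] <- ti
  }
  t_mat
}

#' Default prior weight: the median region's person-years
#'
#' The degree of smoothing is predetermined, not estimated: by default the
#' prior for each age group carries the information of one typical region,
#' the across-region median of `n[i, j]`.
#'
#' @param cube A `count_cube`.
#' @return Numeric vector, one prior weight (person-years) per age group.
#' @export
default_prior_weight <- function(cube) {
  stopifnot(inherits(cube, "count_cube"))
  apply(cube$n, 2, stats::median)
}

#' Construct a gamma prior from a target rate and a prior weight
#'
#' @param target Positive target rate(s) (events per person-year) the prior
#'   is centered on.
#' @param weight Positive prior weight(s) in person-years.
#' @return List with numeric `shape` (`target * weight`) and `rate`
#'   (`weight`); the prior mean equals `target` exactly.
#' @export
make_prior <- function(target, weight) {
  if (any(!is.finite(target)) || any(target <= 0))
    stop("prior target rate must be positive (apply the zero-rate fallback first)",
         call. = FALSE)
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("prior weight must be positive", call. = FALSE)
  list(shape = target * weight, rate = weight)
}

#' Conjugate posterior update for Poisson counts with a gamma prior
#'
#' @param y Nonnegative event count(s).
#' @param n Positive person-years at risk.
#' @param prior A [make_prior()] list (`shape`, `rate`).
#' @return List with posterior `shape = y + prior shape` and
#'   `rate = n + prior rate`. The posterior mean
#'   `(y + shape) / (n + rate)` is the weighted compromise
#'   `(n/(n+rate)) * y/n + (rate/(n+rate)) * prior mean`.
#' @export
posterior_update <- function(y, n, prior) {
  if (any(y < 0) || any(y != floor(y)))
    stop("event counts must be nonnegative integers", call. = FALSE)
  if (any(!is.finite(n)) || any(n <= 0))
    stop("person-years must be positive", call. = FALSE)
  list(shape = y + prior$shape, rate = n + prior$rate)
}

#' Equal-tailed credible interval of a gamma posterior
#'
#' @param post A posterior list (`shape`, `rate`).
#' @param level Credible level in (0, 1), default 0.95.
#' @return Numeric vector `c(lo, hi)` of rate quantiles (for vector input,
#'   a 2-column matrix).
#' @export
posterior_interval <- function(post, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  a <- (1 - level) / 2
  lo <- stats::qgamma(a, shape = post$shape, rate = post$rate)
  hi <- stats::qgamma(1 - a, shape = post$shape, rate = post$rate)
  if (length(lo) == 1) c(lo, hi) else cbind(lo = lo, hi = hi)
}

#' Fit empirical Bayes smoothing to a count cube
#'
#' Computes, for every region x age-group cell, the smoothing target, the
#' gamma prior, and the conjugate posterior, using either the nonspatial
#' (domain-rate) or spatial (neighborhood-rate) target.
#'
#' Age groups whose target rate is zero (no events anywhere relevant) use
#' the half-event continuity fallback `0.5 / sum_i n[i, j]` as the target,
#' since a gamma prior cannot have mean zero.
#'
#' @param cube A `count_cube`.
#' @param method `"nonspatial"` or `"spatial"`.
#' @param nd An `nb_dict`; required when `method = "spatial"`.
#' @param prior_weight Optional numeric vector (one per age group)
#'   overriding [default_prior_weight()].
#' @return An object of class `eb_fit`: list with matrices `shape`, `rate`
#'   (posterior parameters), `target`, vector `prior_weight`, the `method`,
#'   and the input `cube`.
#' @export
eb_fit <- function(cube, method = c("nonspatial", "spatial"), nd = NULL,
                   prior_weight = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(cube, "count_cube"))
  J <- ncol(cube$y)
  if (is.null(prior_weight)) prior_weight <- default_prior_weight(cube)
  if (length(prior_weight) == 1) prior_weight <- rep(prior_weight, J)
  if (length(prior_weight) != J || any(prior_weight <= 0))
    stop("prior_weight must be positive, one value per age group",
         call. = FALSE)

  fallback <- 0.5 / colSums(cube$n)          # half-event pseudo-rate
  if (method == "nonspatial") {
    r <- global_rates(cube)
    r <- ifelse(r > 0, r, fallback)
    target <- matrix(r, nrow(cube$y), J, byrow = TRUE,
                     dimnames = dimnames(cube$y))
  } else {
    if (is.null(nd))
      stop("spatial smoothing needs a neighborhood dictionary", call. = FALSE)
    target <- neighborhood_rates(cube, nd)
    for (j in seq_len(J))
      target[, j] <- ifelse(target[, j] > 0, target[, j], fallback[j])
  }

  m <- matrix(prior_weight, nrow(cube$y), J, byrow = TRUE)
  prior <- make_prior(target, m)
  post <- posterior_update(cube$y, cube$n, prior)
  structure(list(shape = post$shape, rate = post$rate, target = target,
                 prior_weight = prior_weight, method = method, cube = cube),
            class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  cat(sprintf("eb_fit (%s): %d regions x %d age groups; prior weight %s person-years\n",
              x$method, nrow(x$shape), ncol(x$shape),
              paste(signif(x$prior_weight, 3), collapse = ", ")))
  invisible(x)
}
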