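# Simulation harness: synthetic truth on a region lattice, replicate
# Poisson count datasets, and estimator comparison by per-region rMSE and
# credible-interval coverage.

# Default age-specific base rates (events per person-year) for the six
# adult age groups 35-44 ... 85+, calibrated to heart-disease-like
# mortality magnitudes.
default_base_rates <- c(1e-4, 4e-4, 1.2e-3, 3.5e-3, 9e-3, 2e-2)

# 2000 US standard population shares for ages 35+ renormalized to sum 1.
default_std_weights <- c(0.3175, 0.2641, 0.1709, 0.1293, 0.0878, 0.0304)

# Deterministic stream seed derived from a master seed (kept within the
# 32-bit integer range R's RNG accepts).
derive_seed <- function(seed, stream, k) {
  (as.double(seed) * 1000 + stream * 100003 + k) %% 2147483647
}

#' Define a synthetic simulation scenario on a region grid
#'
#' Builds the fixed "truth" of a simulation study: a rectangular lattice of
#' regions with heterogeneous person-years and known age-specific rates.
#' Person-years are log-uniform across `pop_range` independently per cell.
#' True rates are `base_rates[j] * exp(g_i)` with a region-level
#' log-relative risk `g_i` composed of a smooth diagonal gradient of
#' amplitude `gradient` plus Gaussian noise (`noise_sd`), shared across age
#' groups, so rates increase with age in every region and vary smoothly in
#' space (giving the spatial smoother signal).
#'
#' @param nrow,ncol Grid dimensions (at least 2 x 2). Default 10 x 10.
#' @param age_breaks Lower age-group boundaries, default
#'   `c(35, 45, 55, 65, 75, 85)` (six groups, 35-44 through 85+).
#' @param base_rates Age-specific rates at the domain center, one per age
#'   group, events per person-year.
#' @param pop_range Range (min, max) of per-cell person-years, default
#'   `c(500, 50000)`.
#' @param gradient Half-range of the diagonal log-rate gradient, default
#'   0.15.
#' @param noise_sd Standard deviation of region log-rate noise, default
#'   0.09.
#' @param std_weights Standard-population age weights; default the 2000 US
#'   standard shares for ages 35+ renormalized.
#' @param n_replicates Number of replicate datasets, default 100.
#' @param seed Master seed; the same seed reproduces the scenario and every
#'   replicate exactly.
#' @return An object of class `sim_scenario`: list with `lambda` (true
#'   rates, regions x age groups), `n` (person-years), `region_ids`,
#'   `scheme`, `weights`, `true_std` (true age-standardized rates), grid
#'   dims, `n_replicates`, `seed`.
#' @export
make_scenario <- function(nrow = 10, ncol = 10,
                          age_breaks = c(35, 45, 55, 65, 75, 85),
                          base_rates = default_base_rates,
                          pop_range = c(500, 50000),
                          gradient = 0.15, noise_sd = 0.09,
                          std_weights = default_std_weights,
                          n_replicates = 100, seed = 42) {
  if (nrow < 2 || ncol < 2) stop("grid must be at least 2 x 2", call. = FALSE)
  if (any(pop_range <= 0) || pop_range[2] < pop_range[1])
    stop("pop_range must be positive with min <= max", call. = FALSE)
  if (n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  scheme <- parse_age_scheme(age_breaks)
  J <- length(scheme)
  if (length(base_rates) != J || any(base_rates < 0))
    stop("base_rates must be nonnegative, one per age group", call. = FALSE)
  if (is.unsorted(base_rates))
    stop("base_rates must be nondecreasing in age", call. = FALSE)
  weights <- check_weights(std_weights, J)

  R <- nrow * ncol
  ids <- paste0("r", rep(seq_len(nrow), each = ncol),
                "c", rep(seq_len(ncol), times = nrow))
  row_i <- rep(seq_len(nrow), each = ncol)
  col_i <- rep(seq_len(ncol), times = nrow)
  # diagonal coordinate scaled to [-1, 1]
  u <- (row_i - 1) / (nrow - 1) + (col_i - 1) / (ncol - 1) - 1

  sc <- with_seed(derive_seed(seed, 1, 0), {
    g <- gradient * u + stats::rnorm(R, 0, noise_sd)
    n <- matrix(if (pop_range[1] == pop_range[2]) rep(pop_range[1], R * J)
                else exp(stats::runif(R * J, log(pop_range[1]), log(pop_range[2]))),
                R, J, dimnames = list(ids, scheme$labels))
    lambda <- outer(exp(g), base_rates)
    dimnames(lambda) <- dimnames(n)
    list(g = g, n = n, lambda = lambda)
  })

  structure(list(lambda = sc$lambda, n = sc$n, region_ids = ids,
                 scheme = scheme, weights = weights,
                 true_std = drop(sc$lambda %*% weights),
                 nrow = nrow, ncol = ncol,
                 n_replicates = n_replicates, seed = seed),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("sim_scenario: %d x %d grid, %d age groups, %d replicates, seed %s\n",
              x$nrow, x$ncol, length(x$scheme), x$n_replicates,
              format(x$seed)))
  cat(sprintf("  true standardized rates: %.1f-%.1f per 100,000\n",
              1e5 * min(x$true_std), 1e5 * max(x$true_std)))
  invisible(x)
}

#' Simulate one replicate count dataset from a scenario
#'
#' Draws `y[i, j] ~ Poisson(n[i, j] * lambda[i, j])` independently, with a
#' replicate-specific seed derived from the scenario's master seed.
#'
#' @param scn A [make_scenario()] object.
#' @param replicate Replicate index (1-based).
#' @return A `count_cube` with the scenario's person-years.
#' @export
simulate_counts <- function(scn, replicate = 1) {
  stopifnot(inherits(scn, "sim_scenario"))
  y <- with_seed(derive_seed(scn$seed, 2, replicate), {
    matrix(stats::rpois(length(scn$lambda), scn$n * scn$lambda),
           nrow(scn$lambda), ncol(scn$lambda), dimnames = dimnames(scn$lambda))
  })
  storage.mode(y) <- "integer"
  structure(list(y = y, n = scn$n, region_ids = scn$region_ids,
                 scheme = scn$scheme), class = "count_cube")
}

#' Run the simulation study: rMSE and coverage of the three estimators
#'
#' For each replicate dataset, computes the unsmoothed (crude), nonspatial
#' EB, and spatial EB age-standardized rate estimates plus Monte Carlo 95%
#' credible intervals for the two smoothed estimators, then summarizes per
#' region the root mean square error against the true standardized rate,
#' and the coverage of the intervals (pooled over regions x replicates, and
#' per region).
#'
#' @param scn A [make_scenario()] object.
#' @param n_draws Monte Carlo draws per standardized posterior, default
#'   10000.
#' @param prior_weight Optional prior-weight override, see [eb_fit()].
#' @param level Credible level, default 0.95.
#' @return An object of class `sim_result`: list with `rmse` (data frame:
#'   region_id, unsmoothed, nonspatial, spatial), `mean_rmse` (named
#'   vector), `coverage` (named vector: nonspatial, spatial, pooled over
#'   region x replicate), `coverage_both` (pooled additionally over the two
#'   methods), `region_coverage` (data frame per region), and
#'   `n_replicates`.
#' @export
run_study <- function(scn, n_draws = 10000, prior_weight = NULL, level = 0.95) {
  stopifnot(inherits(scn, "sim_scenario"))
  if (scn$n_replicates < 2) stop("need at least 2 replicates", call. = FALSE)
  nd <- build_adjacency(grid_polygons(scn$nrow, scn$ncol, scn$region_ids),
                        rule = "queen")
  R <- length(scn$region_ids)
  nrep <- scn$n_replicates
  truth <- scn$true_std

  se <- list(unsmoothed = matrix(NA_real_, R, nrep),
             nonspatial = matrix(NA_real_, R, nrep),
             spatial = matrix(NA_real_, R, nrep))
  cover <- list(nonspatial = matrix(NA, R, nrep),
                spatial = matrix(NA, R, nrep))

  for (rep_i in seq_len(nrep)) {
    cube <- simulate_counts(scn, rep_i)
    se$unsmoothed[, rep_i] <- (crude_standardized(cube, scn$weights) - truth)^2
    for (method in c("nonspatial", "spatial")) {
      fit <- eb_fit(cube, method, nd = nd, prior_weight = prior_weight)
      std <- standardize_fit(fit, scn$weights, n_draws = n_draws,
                             seed = derive_seed(scn$seed, 3 + (method == "spatial"),
                                                rep_i),
                             level = level)
      se[[method]][, rep_i] <- (std$estimate - truth)^2
      cover[[method]][, rep_i] <- std$lo <= truth & truth <= std$hi
    }
  }

  rmse <- data.frame(region_id = scn$region_ids,
                     unsmoothed = sqrt(rowMeans(se$unsmoothed)),
                     nonspatial = sqrt(rowMeans(se$nonspatial)),
                     spatial = sqrt(rowMeans(se$spatial)),
                     row.names = NULL, stringsAsFactors = FALSE)
  coverage <- c(nonspatial = mean(cover$nonspatial),
                spatial = mean(cover$spatial))
  structure(list(
    rmse = rmse,
    mean_rmse = c(unsmoothed = mean(rmse$unsmoothed),
                  nonspatial = mean(rmse$nonspatial),
                  spatial = mean(rmse$spatial)),
    coverage = coverage,
    coverage_both = mean(c(cover$nonspatial, cover$spatial)),
    region_coverage = data.frame(region_id = scn$region_ids,
                                 nonspatial = rowMeans(cover$nonspatial),
                                 spatial = rowMeans(cover$spatial),
                                 row.names = NULL, stringsAsFactors = FALSE),
    n_replicates = nrep), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result over %d replicates\n", x$n_replicates))
  cat("  mean rMSE (per person-year):",
      paste(names(x$mean_rmse), signif(x$mean_rmse, 4), sep = "=",
            collapse = ", "), "\n")
  cat("  95% CI coverage:",
      paste(names(x$coverage), round(x$coverage, 3), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}
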