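test_that("global rates pool events over the whole domain", {
  cube <- toy_cube(y = matrix(c(2, 3), 2, 1), n = matrix(1000, 2, 1))
  expect_equal(unname(global_rates(cube)), 0.0025)

  cube0 <- toy_cube(y = matrix(0L, 3, 2), n = matrix(500, 3, 2))
  expect_equal(unname(global_rates(cube0)), c(0, 0))

  one <- toy_cube(y = matrix(c(4L, 1L), 1, 2), n = matrix(c(800, 200), 1, 2))
  expect_equal(unname(global_rates(one)), c(4 / 800, 1 / 200))
})

test_that("neighborhood rates pool neighbors only, with fallbacks", {
  cube <- toy_cube(y = matrix(c(10, 4, 6), 3, 1),
                   n = matrix(1000, 3, 1), ids = c("i", "k1", "k2"))
  nd <- toy_nb(list(i = c("k1", "k2"), k1 = "i", k2 = "i"))
  t_mat <- neighborhood_rates(cube, nd)
  expect_equal(unname(t_mat["i", ]), 0.005)        # focal region excluded
  expect_equal(unname(t_mat["k1", ]), 0.01)        # only neighbor is i

  # island falls back to the global rate
  nd_island <- toy_nb(list(i = character(0), k1 = "k2", k2 = "k1"))
  t_isl <- neighborhood_rates(cube, nd_island)
  expect_equal(unname(t_isl["i", ]), unname(global_rates(cube)))

  # neighbors with zero events fall back to the global rate: a gamma prior
  # cannot be centered at zero
  cube2 <- toy_cube(y = matrix(c(10, 0, 0), 3, 1),
                    n = matrix(1000, 3, 1), ids = c("i", "k1", "k2"))
  t2 <- neighborhood_rates(cube2, nd)
  expect_equal(unname(t2["i", ]), unname(global_rates(cube2)))

  expect_error(neighborhood_rates(cube, toy_nb(list(i = character(0)))),
               "missing from neighborhood")
})

test_that("priors encode the target rate with person-year weight", {
  pr <- make_prior(0.002, 1000)
  expect_equal(pr$shape, 2)
  expect_equal(pr$rate, 1000)
  expect_error(make_prior(0, 1000), "positive")
  expect_error(make_prior(0.1, -1), "positive")

  # limits of the posterior mean: infinite weight -> target, zero -> crude
  y <- 12; n <- 3000; t <- 0.002
  post_big <- posterior_update(y, n, make_prior(t, 1e12))
  expect_equal(post_big$shape / post_big$rate, t, tolerance = 1e-6)
  post_small <- posterior_update(y, n, make_prior(t, 1e-9))
  expect_equal(post_small$shape / post_small$rate, y / n, tolerance = 1e-6)
})

test_that("posterior update follows Poisson-gamma conjugacy", {
  post <- posterior_update(3, 2000, make_prior(0.002, 1000))
  expect_equal(post$shape, 5)
  expect_equal(post$rate, 3000)
  expect_equal(post$shape / post$rate, 5 / 3000)

  post0 <- posterior_update(0, 1000, list(shape = 2, rate = 1000))
  expect_equal(post0$shape / post0$rate, 0.001)    # half the prior mean

  expect_error(posterior_update(-1, 10, make_prior(1, 1)), "nonnegative")
  expect_error(posterior_update(2, 0, make_prior(1, 1)), "positive")
})

test_that("posterior mean is the precision-weighted compromise (random cases)", {
  withr::with_seed(21, {
    for (rep in 1:200) {
      y <- rpois(1, 20); n <- runif(1, 10, 1e5)
      alpha <- runif(1, 0.1, 50); beta <- runif(1, 10, 1e5)
      post <- posterior_update(y, n, list(shape = alpha, rate = beta))
      expected <- (n / (n + beta)) * (y / n) + (beta / (n + beta)) * (alpha / beta)
      expect_equal(post$shape / post$rate, expected, tolerance = 1e-12)
    }
  })
})

test_that("credible intervals are equal-tailed gamma quantiles", {
  post <- list(shape = 5, rate = 3000)
  ci <- posterior_interval(post)
  expect_equal(pgamma(ci[1], 5, 3000), 0.025, tolerance = 1e-10)
  expect_equal(pgamma(ci[2], 5, 3000), 0.975, tolerance = 1e-10)
  expect_lt(ci[1], post$shape / post$rate)
  expect_gt(ci[2], post$shape / post$rate)
  expect_error(posterior_interval(post, level = 1.2), "level")

  withr::with_seed(22, {
    for (rep in 1:50) {
      sh <- runif(1, 0.3, 80); rt <- runif(1, 50, 5e4)
      ci <- posterior_interval(list(shape = sh, rate = rt))
      expect_equal(pgamma(ci[2], sh, rt) - pgamma(ci[1], sh, rt), 0.95,
                   tolerance = 1e-8)
    }
  })

  # concentration: at fixed mean, growing shape shrinks the interval to 0
  widths <- vapply(c(10, 1e3, 1e5), function(sh)
    diff(posterior_interval(list(shape = sh, rate = sh / 0.002))), numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_lt(widths[3], 1e-4)
})

test_that("shrinkage is convex and monotone in the prior weight", {
  withr::with_seed(23, {
    for (rep in 1:100) {
      y <- rpois(1, 8); n <- runif(1, 100, 1e4)
      t <- runif(1, 1e-4, 0.05)
      m <- runif(1, 10, 1e5)
      mean_post <- function(m) {
        p <- posterior_update(y, n, make_prior(t, m))
        p$shape / p$rate
      }
      mu <- mean_post(m)
      expect_gte(mu, min(y / n, t) - 1e-15)
      expect_lte(mu, max(y / n, t) + 1e-15)
      # larger weight moves the mean toward the target
      mu2 <- mean_post(m * 10)
      expect_lte(abs(mu2 - t), abs(mu - t) + 1e-15)
    }
  })
})

test_that("posterior intervals are calibrated under the assumed model", {
  # theta ~ prior, y ~ Poisson(n * theta): 95% intervals must cover theta
  # at rate 0.95 up to Monte Carlo error
  withr::with_seed(24, {
    n_sim <- 4000
    t <- 0.003; m <- 2000; n <- 5000
    theta <- rgamma(n_sim, shape = t * m, rate = m)
    y <- rpois(n_sim, n * theta)
    post <- posterior_update(y, rep(n, n_sim), make_prior(rep(t, n_sim), m))
    ci <- posterior_interval(post)
    covered <- mean(ci[, "lo"] <= theta & theta <= ci[, "hi"])
    expect_lt(abs(covered - 0.95), 3 * sqrt(0.95 * 0.05 / n_sim) + 0.001)
  })
})

test_that("spatial and nonspatial smoothing coincide on a symmetric domain", {
  # four identical regions, each neighboring all others: the leave-one-out
  # neighborhood rate equals the global rate
  cube <- toy_cube(y = matrix(3L, 4, 2), n = matrix(1500, 4, 2))
  nd <- toy_nb(stats::setNames(lapply(1:4, function(i)
    paste0("R", setdiff(1:4, i))), paste0("R", 1:4)))
  f_ns <- eb_fit(cube, "nonspatial")
  f_sp <- eb_fit(cube, "spatial", nd = nd)
  expect_equal(f_sp$target, f_ns$target)
  expect_equal(f_sp$shape, f_ns$shape)
  expect_equal(f_sp$rate, f_ns$rate)
})

test_that("eb_fit applies the half-event fallback when an age group has no events", {
  cube <- toy_cube(y = cbind(c(2L, 3L), c(0L, 0L)), n = matrix(1000, 2, 2))
  fit <- eb_fit(cube, "nonspatial")
  expect_equal(unname(fit$target[, 2]), rep(0.5 / 2000, 2))
  expect_true(all(fit$shape > 0))

  # default prior weight is the median region's person-years per age group
  cube2 <- toy_cube(y = matrix(1L, 3, 1),
                    n = matrix(c(100, 400, 900), 3, 1))
  expect_equal(unname(default_prior_weight(cube2)), 400)
  fit2 <- eb_fit(cube2, "nonspatial")
  expect_equal(unname(fit2$rate[, 1]), c(100, 400, 900) + 400)
})
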