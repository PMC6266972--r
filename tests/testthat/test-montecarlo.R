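test_that("the lognormal fit recovers known parameters and gates on K-S", {
  x <- with_seed_test(42, exp(stats::rnorm(5000, 1, 0.5)))
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$mu - 1), 0.03)
  expect_lt(abs(fit$sigma - 0.5), 0.03)
  expect_true(fit$usable)
  expect_gt(fit$ks_p, 0.05)
  # degenerate input: sigma 0, flagged
  flat <- fit_lognormal(rep(3.7, 10))
  expect_equal(flat$sigma, 0)
  expect_false(flat$usable)
  # invalid inputs
  expect_error(fit_lognormal(c(1, 2)), "at least 3")
  expect_error(fit_lognormal(c(1, 0, 2)), "> 0")
  expect_error(fit_lognormal(c(1, -1, 2)), "> 0")
})

test_that("soil draws are seeded, positive and centred on the fitted log-mean", {
  fit <- structure(list(mu = 1, sigma = 0.5, ks_statistic = 0.01, ks_p = 0.9,
                        n = 100, usable = TRUE), class = "lognormal_fit")
  d1 <- draw_soils(fit, 10000, seed = 7)
  d2 <- draw_soils(fit, 10000, seed = 7)
  expect_identical(d1, d2)
  expect_true(all(d1 > 0))
  expect_lt(abs(mean(log(d1)) - 1), 0.02)
  # zero-variance fit degenerates to a point mass
  fit0 <- structure(list(mu = 2, sigma = 0, ks_statistic = NA, ks_p = NA,
                         n = 10, usable = FALSE), class = "lognormal_fit")
  expect_true(all(draw_soils(fit0, 5, seed = 1) == exp(2)))
  # an unusable (non-degenerate) fit is refused
  bad <- structure(list(mu = 1, sigma = 0.5, ks_statistic = 0.5, ks_p = 0.01,
                        n = 100, usable = FALSE), class = "lognormal_fit")
  expect_error(draw_soils(bad, 5, seed = 1), "unusable")
})

test_that("superposition ensembles equal literal per-replicate simulation", {
  fit <- fit_lognormal(with_seed_test(5, exp(stats::rnorm(50, log(22.1), 0.4))))
  args <- list(fit = fit, env = toy_env(), geom = toy_geometry(),
               rt = toy_rt(), atm = toy_atm(),
               growth = default_growth_params(),
               cfg = simulation_config(), flux = toy_flux())
  sup <- do.call(run_ensemble, c(args, list(n_rep = 5, seed = 3,
                                            method = "superposition")))
  dir <- do.call(run_ensemble, c(args, list(n_rep = 5, seed = 3,
                                            method = "direct")))
  expect_identical(sup$draws, dir$draws)
  expect_equal(sup$outputs, dir$outputs, tolerance = 1e-12)
  # single-replicate ensembles carry no density and say so
  one <- do.call(run_ensemble, c(args, list(n_rep = 1, seed = 3)))
  expect_null(one$density)
  expect_match(one$density_flag, "n_rep")
})

test_that("a lognormal soil ensemble stays lognormal through the linear model", {
  # soil is the only varied input; no atmospheric source, so the outputs are
  # an exact positive multiple of the draws
  fit <- fit_lognormal(with_seed_test(8, exp(stats::rnorm(200, log(22.1), 0.4))))
  ens <- run_ensemble(fit, toy_env(c_a = 0), toy_geometry(), toy_rt(),
                      toy_atm(), default_growth_params(),
                      simulation_config(), toy_flux(),
                      n_rep = 10000, seed = 11)
  for (p in c("root", "grain")) {
    out_fit <- fit_lognormal(ens$outputs[, p])
    expect_gt(out_fit$ks_p, 0.05)
    expect_lt(abs(out_fit$sigma - fit$sigma), 0.02)
  }
  # doubling the log-mean shifts the output log-median by the same amount
  fit2 <- structure(fit, class = "lognormal_fit")
  fit2$mu <- fit$mu + log(2)
  ens2 <- run_ensemble(fit2, toy_env(c_a = 0), toy_geometry(), toy_rt(),
                       toy_atm(), default_growth_params(),
                       simulation_config(), toy_flux(),
                       n_rep = 10000, seed = 11)
  shift <- stats::median(log(ens2$outputs[, "grain"])) -
    stats::median(log(ens$outputs[, "grain"]))
  expect_equal(shift, log(2), tolerance = 0.02)
})

test_that("seeded ensembles are bitwise reproducible end to end", {
  fit <- fit_lognormal(with_seed_test(5, exp(stats::rnorm(50, 3, 0.3))))
  run <- function() {
    run_ensemble(fit, toy_env(), toy_geometry(), toy_rt(), toy_atm(),
                 default_growth_params(), simulation_config(), toy_flux(),
                 n_rep = 500, seed = 99)
  }
  a <- run()
  b <- run()
  expect_identical(a$draws, b$draws)
  expect_identical(a$outputs, b$outputs)
})

test_that("ensemble means converge like one over the square root of n", {
  fit <- structure(list(mu = log(22.1), sigma = 0.4, ks_statistic = 0.01,
                        ks_p = 0.9, n = 200, usable = TRUE),
                   class = "lognormal_fit")
  lr_mean <- function(n_rep, seed) {
    ens <- run_ensemble(fit, toy_env(c_a = 0), toy_geometry(), toy_rt(),
                        toy_atm(), default_growth_params(),
                        simulation_config(), toy_flux(),
                        n_rep = n_rep, seed = seed)
    mean(ens$outputs[, "root"])
  }
  sd_of_means <- function(n_rep) {
    stats::sd(vapply(1:12, function(s) lr_mean(n_rep, s), numeric(1)))
  }
  s100 <- sd_of_means(100)
  s10000 <- sd_of_means(10000)
  ratio <- s100 / s10000
  expect_gt(ratio, 10 / 2.5)
  expect_lt(ratio, 10 * 2.5)
})

test_that("density overlays separate matching from disjoint distributions", {
  set.seed(4)
  x <- stats::rlnorm(4000, 1, 0.3)
  self <- density_overlay(x, x)
  expect_gt(self$overlap, 0.95)
  far <- density_overlay(x, x + 1000)
  expect_lt(far$overlap, 0.05)
  expect_true(all(c("x", "density_model", "density_measured") %in%
                    names(self$grid)))
  expect_error(density_overlay(x, numeric(0)), "empty")
})
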