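# simulate a Gaussian random field with exponential covariance on given sites
sim_exp_field <- function(x, y, sd, range_par, seed) {
  d <- as.matrix(stats::dist(cbind(x, y)))
  Sigma <- sd^2 * exp(-d / range_par)
  diag(Sigma) <- diag(Sigma) + 1e-10
  with_seed_test(seed, as.numeric(crossprod(chol(Sigma), stats::rnorm(length(x)))))
}

test_that("the empirical semivariogram matches hand-computed cases", {
  # constant field: gamma identically zero
  set.seed(1)
  x <- stats::runif(30, 0, 100)
  y <- stats::runif(30, 0, 100)
  emp <- empirical_variogram(x, y, rep(5, 30))
  expect_true(all(emp$gamma == 0))
  # two sites at distance d with values 1 and 3: one pair, gamma = 2
  expect_warning(
    expect_warning(
      emp2 <- empirical_variogram(c(0, 30), c(0, 40), c(1, 3), n_lags = 1),
      "fewer than 5"
    ),
    "extending cutoff"
  )
  expect_equal(nrow(emp2), 1)
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$lag, 50)
  expect_error(suppressWarnings(empirical_variogram(c(1, 1), c(2, 2), c(0, 1))),
               "co-located")
})

test_that("variogram fitting recovers known structures", {
  # pure nugget: white noise -> the fitted curve is flat at the sill from
  # the shortest observed lag on (nugget and a zero-range partial sill are
  # observationally equivalent, so flatness is the identifiable property)
  set.seed(2)
  x <- stats::runif(200, 0, 1000)
  y <- stats::runif(200, 0, 1000)
  v <- stats::rnorm(200, 0, 1)
  emp <- empirical_variogram(x, y, v)
  vg <- fit_variogram(emp, "exponential")
  g_short <- soilwheat:::vg_gamma(vg, min(emp$lag))
  expect_equal(g_short / vg$sill, 1, tolerance = 0.2)
  expect_equal(vg$sill, stats::var(v), tolerance = 0.3)

  # noise-free spherical curve: parameter recovery within 10%
  truth <- variogram_model("spherical", nugget = 0.2, sill = 1.2, range = 300)
  lags <- seq(10, 500, by = 20)
  emp_syn <- data.frame(lag = lags,
                        gamma = soilwheat:::vg_gamma(truth, lags),
                        n_pairs = rep(50, length(lags)))
  fit <- fit_variogram(emp_syn, "spherical")
  expect_equal(fit$nugget, 0.2, tolerance = 0.1)
  expect_equal(fit$sill, 1.2, tolerance = 0.1)
  expect_equal(fit$range, 300, tolerance = 0.1)

  # simulated exponential fields recover the range within +/- 30%; one
  # realisation over a finite domain carries real sampling noise, so the
  # check uses the median over three independent fields
  ranges <- vapply(c(9, 10, 11), function(s) {
    vals <- sim_exp_field(x, y, sd = 1, range_par = 150, seed = s)
    emp3 <- empirical_variogram(x, y, vals, n_lags = 15)
    fit_variogram(emp3, "exponential")$range
  }, numeric(1))
  expect_gt(stats::median(ranges), 150 * 0.7)
  expect_lt(stats::median(ranges), 150 * 1.3)

  expect_error(fit_variogram(emp_syn[1, ], "spherical"), "at least 3")
})

test_that("ordinary kriging is exact at samples and its weights sum to one", {
  set.seed(3)
  x <- stats::runif(25, 0, 2000)
  y <- stats::runif(25, 0, 2000)
  vals <- sim_exp_field(x, y, sd = 1, range_par = 500, seed = 13) + 10
  vg <- variogram_model("exponential", nugget = 0, sill = 1, range = 500)
  at_samples <- krige(x, y, vals, vg, grid = data.frame(x = x, y = y),
                      return_weights = TRUE)
  expect_lt(max(abs(at_samples$pred - vals)), 1e-8)
  w <- attr(at_samples, "weights")
  expect_lt(max(abs(colSums(w) - 1)), 1e-10)
  expect_true(all(at_samples$var >= 0))
  # weights at arbitrary points also honour the unbiasedness constraint
  grid <- krige(x, y, vals, vg, grid = c(7, 7), return_weights = TRUE)
  expect_lt(max(abs(colSums(attr(grid, "weights")) - 1)), 1e-10)
  expect_equal(nrow(grid), 49)
})

test_that("kriging degenerates gracefully and rejects duplicate sites", {
  vg <- variogram_model("exponential", nugget = 0, sill = 1, range = 100)
  x <- c(0, 100, 0, 100)
  y <- c(0, 0, 100, 100)
  # constant data give a constant surface
  flat <- krige(x, y, rep(2.5, 4), vg, grid = c(4, 4))
  expect_true(all(abs(flat$pred - 2.5) < 1e-10))
  expect_error(krige(c(x, 0), c(y, 0), rep(1, 5), vg, grid = c(2, 2)),
               "singular|duplicate")
})

test_that("a two-site midpoint prediction solves the hand-built kriging system", {
  # two sites 100 m apart, unit-sill exponential variogram with range 50;
  # by symmetry the midpoint weights are 1/2 each, and the kriging variance
  # follows from the hand-solved 3x3 system
  vg <- variogram_model("exponential", nugget = 0, sill = 1, range = 50)
  mid <- krige(c(0, 100), c(0, 0), c(2, 6), vg,
               grid = data.frame(x = 50, y = 0), return_weights = TRUE)
  w <- attr(mid, "weights")[, 1]
  expect_equal(unname(w[1]), unname(w[2]), tolerance = 1e-12)
  expect_equal(unname(w[1]), 0.5, tolerance = 1e-12)
  expect_equal(mid$pred, 4, tolerance = 1e-12)
  # hand solution: lambda = 1/2 each, mu = gamma(50) - gamma(100)/2,
  # variance = lambda . gamma0 + mu = 2 gamma(50) - gamma(100)/2... evaluated
  g50 <- 1 - exp(-1)
  g100 <- 1 - exp(-2)
  mu <- g50 - g100 / 2
  expect_equal(mid$var, g50 + mu, tolerance = 1e-12)
})

test_that("kriging predictions are invariant under coordinate translation", {
  set.seed(6)
  x <- stats::runif(20, 0, 1000)
  y <- stats::runif(20, 0, 1000)
  vals <- sim_exp_field(x, y, 1, 300, seed = 21)
  vg <- variogram_model("spherical", nugget = 0.1, sill = 1, range = 400)
  pts <- data.frame(x = c(200, 700), y = c(300, 800))
  base <- krige(x, y, vals, vg, grid = pts)
  shifted <- krige(x + 5000, y - 3000, vals, vg,
                   grid = transform(pts, x = x + 5000, y = y - 3000))
  expect_equal(base$pred, shifted$pred, tolerance = 1e-9)
  expect_equal(base$var, shifted$var, tolerance = 1e-9)
})

test_that("leave-one-out error shrinks as the site density doubles", {
  vg <- variogram_model("exponential", nugget = 0, sill = 1, range = 400)
  smooth_field <- function(n, seed) {
    set.seed(seed)
    x <- stats::runif(n, 0, 1000)
    y <- stats::runif(n, 0, 1000)
    list(x = x, y = y, v = sin(x / 300) + cos(y / 300))
  }
  err <- vapply(c(30, 60, 120), function(n) {
    f <- smooth_field(n, seed = 31)
    mean(krige_loocv(f$x, f$y, f$v, vg)$abs_error)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("prediction errors bin into the three reporting classes", {
  ec <- error_classes(c(1, 1.4, 3), c(1, 1, 1))
  expect_equal(as.character(ec$class), c("lt25", "25to50", "gt50"))
  # boundary ratios: 0.25 belongs to the middle class, 0.5 to the top class
  ec2 <- error_classes(c(1.25, 1.5, 0.5), c(1, 1, 1))
  expect_equal(as.character(ec2$class), c("25to50", "gt50", "gt50"))
  all_good <- error_classes(c(3, 7), c(3, 7))
  expect_equal(unname(all_good$counts["lt25"]), 2L)
  pred <- c(1.3, 0.77)
  expect_equal(as.character(error_classes(1.3 * c(1, 1), c(1, 1))$class),
               c("25to50", "25to50"))
  expect_error(error_classes(1, 0), "> 0")
})
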