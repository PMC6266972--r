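#' Empirical semivariogram
#'
#' Classical (Matheron) estimator: half the mean squared difference of the
#' field per distance bin. Bins are equal-width up to half the maximum
#' pairwise distance; if that cutoff would leave no pairs (degenerate tiny
#' designs) it is extended to the maximum distance with a warning.
#'
#' @param x,y Planar site coordinates (m).
#' @param values Per-site scalar field.
#' @param n_lags Number of distance bins.
#' @param cutoff Maximum pair distance to use; default half the maximum
#'   pairwise distance.
#'
#' @return Data frame with columns \code{lag} (bin midpoint), \code{gamma},
#'   \code{n_pairs}; empty bins are dropped.
#' @export
empirical_variogram <- function(x, y, values, n_lags = 12, cutoff = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n)
  if (n < 2L) stop("need at least 2 sites")
  if (n < 5L) warning("fewer than 5 sites: the semivariogram will be unstable")
  d <- as.matrix(stats::dist(cbind(x, y)))
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[iu]
  if (max(h) == 0) stop("all sites are co-located")
  sq <- (values[iu[, 1]] - values[iu[, 2]])^2 / 2
  if (is.null(cutoff)) cutoff <- max(h) / 2
  if (!any(h <= cutoff)) {
    warning("no pairs within half the maximum distance; extending cutoff")
    cutoff <- max(h)
  }
  keep <- h <= cutoff
  h <- h[keep]; sq <- sq[keep]
  breaks <- seq(0, cutoff, length.out = n_lags + 1)
  bin <- cut(h, breaks, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    data.frame(lag = mean(h[bin == b]), gamma = mean(sq[bin == b]),
               n_pairs = sum(bin == b))
  }))
  rownames(out) <- NULL
  out
}

#' Variogram model
#'
#' @param model "spherical", "exponential" or "gaussian".
#' @param nugget Nugget variance, >= 0.
#' @param sill Total sill, >= nugget.
#' @param range Range parameter, > 0 (for exponential/gaussian the
#'   distance-scale parameter; effective range ~3x / ~sqrt(3)x larger).
#'
#' @return An object of class \code{variogram_model}.
#' @export
variogram_model <- function(model = c("spherical", "exponential", "gaussian"),
                            nugget, sill, range) {
  model <- match.arg(model)
  if (!is.finite(nugget) || nugget < 0) stop("nugget must be >= 0")
  if (!is.finite(sill) || sill < nugget) stop("sill must be >= nugget")
  if (!is.finite(range) || range <= 0) stop("range must be > 0")
  structure(list(model = model, nugget = nugget, sill = sill, range = range),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model %s> nugget=%g, sill=%g, range=%g\n",
              x$model, x$nugget, x$sill, x$range))
  invisible(x)
}

# semivariance gamma(h) for a variogram model; vectorized over h
vg_gamma <- function(vg, h) {
  psill <- vg$sill - vg$nugget
  g <- switch(vg$model,
    spherical = ifelse(h >= vg$range, psill,
                       psill * (1.5 * h / vg$range - 0.5 * (h / vg$range)^3)),
    exponential = psill * (1 - exp(-h / vg$range)),
    gaussian = psill * (1 - exp(-(h / vg$range)^2))
  )
  ifelse(h > 0, vg$nugget + g, 0)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Weighted least squares with pair counts as weights. If the requested model
#' fails to converge, an exponential model with moment-based starting values
#' is fitted instead and flagged via the \code{fallback} attribute.
#'
#' @param emp Output of \code{\link{empirical_variogram}}, >= 3 bins.
#' @param model Model family to fit.
#' @return A \code{\link{variogram_model}}.
#' @export
fit_variogram <- function(emp, model = c("spherical", "exponential", "gaussian")) {
  model <- match.arg(model)
  if (nrow(emp) < 3L) stop("need at least 3 non-empty lag bins")
  max_lag <- max(emp$lag)
  # range bounded to (0, 3 * max lag]: beyond that the model is not
  # identifiable from the empirical curve and the WLS surface degenerates
  par_to_vg <- function(fam, p) {
    variogram_model(fam, nugget = exp(p[1]), sill = exp(p[1]) + exp(p[2]),
                    range = 3 * max_lag * stats::plogis(p[3]))
  }
  obj_for <- function(fam) {
    function(p) {
      vg <- par_to_vg(fam, p)
      sum(emp$n_pairs * (vg_gamma(vg, emp$lag) - emp$gamma)^2)
    }
  }
  start <- c(log(max(min(emp$gamma), 1e-8 * max(emp$gamma, 1e-12))),
             log(max(max(emp$gamma) - min(emp$gamma), 1e-10)),
             stats::qlogis(1 / 6))
  fit <- tryCatch(stats::optim(start, obj_for(model), method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
  fallback <- FALSE
  if (is.null(fit) || fit$convergence != 0) {
    fallback <- TRUE
    model <- "exponential"
    start <- c(log(max(min(emp$gamma), 1e-10)),
               log(max(stats::weighted.mean(emp$gamma, emp$n_pairs), 1e-10)),
               stats::qlogis(1 / 9))
    fit <- stats::optim(start, obj_for(model), method = "Nelder-Mead",
                        control = list(maxit = 5000))
    warning("requested variogram fit did not converge; ",
            "falling back to an exponential model")
  }
  vg <- par_to_vg(model, fit$par)
  attr(vg, "fallback") <- fallback
  attr(vg, "objective") <- fit$value
  vg
}

#' Ordinary kriging
#'
#' Best linear unbiased prediction with weights constrained to sum to 1
#' (Lagrange multiplier formulation of the semivariance system). Exact at
#' sample locations when the nugget is zero.
#'
#' @param x,y Sample coordinates (planar, m); >= 2 sites, no duplicates.
#' @param values Sample values.
#' @param vg A \code{\link{variogram_model}}.
#' @param grid Prediction locations: either a data frame with columns
#'   \code{x}, \code{y}, or \code{c(nx, ny)} for a regular grid over the
#'   sample bounding box.
#' @param return_weights If TRUE, attach the n x m kriging weight matrix.
#'
#' @return An object of class \code{risk_grid}: data frame with \code{x},
#'   \code{y}, \code{pred}, \code{var}; weights in
#'   \code{attr(, "weights")} when requested.
#' @export
krige <- function(x, y, values, vg, grid, return_weights = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n, length(values) == n,
            inherits(vg, "variogram_model"))
  if (n < 2L) stop("need at least 2 sites")
  d <- as.matrix(stats::dist(cbind(x, y)))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0) {
    stop("duplicate coordinates at site pairs: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  }
  if (is.numeric(grid) && length(grid) == 2L) {
    gx <- seq(min(x), max(x), length.out = grid[1])
    gy <- seq(min(y), max(y), length.out = grid[2])
    grid <- expand.grid(x = gx, y = gy)
  }
  stopifnot(all(c("x", "y") %in% names(grid)))
  m <- nrow(grid)
  A <- rbind(cbind(vg_gamma(vg, d), 1), c(rep(1, n), 0))
  d0 <- sqrt(outer(x, grid$x, `-`)^2 + outer(y, grid$y, `-`)^2)
  B <- rbind(vg_gamma(vg, d0), rep(1, m))
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system: ", conditionMessage(e))
  })
  lambda <- sol[seq_len(n), , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- as.numeric(crossprod(lambda, values))
  kvar <- colSums(lambda * B[seq_len(n), , drop = FALSE]) + mu
  kvar <- pmax(kvar, 0)
  out <- data.frame(x = grid$x, y = grid$y, pred = pred, var = kvar)
  class(out) <- c("risk_grid", "data.frame")
  if (return_weights) attr(out, "weights") <- lambda
  out
}

#' Leave-one-out cross-validation of ordinary kriging
#'
#' @inheritParams krige
#' @return Data frame with per-site \code{observed}, \code{pred} and
#'   \code{abs_error}.
#' @export
krige_loocv <- function(x, y, values, vg) {
  n <- length(x)
  pred <- vapply(seq_len(n), function(i) {
    krige(x[-i], y[-i], values[-i], vg,
          grid = data.frame(x = x[i], y = y[i]))$pred
  }, numeric(1))
  data.frame(site = seq_len(n), observed = values, pred = pred,
             abs_error = abs(pred - values))
}

#' Classify prediction errors into the three risk-reporting ranges
#'
#' Relative error |prediction - measured| / measured binned into
#' [0, 0.25), [0.25, 0.5) and [0.5, Inf) (a ratio of exactly 0.25 falls in
#' the middle class, exactly 0.5 in the top class).
#'
#' @param predicted,measured Per-validation-site vectors; measured must be
#'   positive everywhere.
#' @return List with \code{ratio}, per-site \code{class} (factor with levels
#'   lt25, 25to50, gt50) and \code{counts}.
#' @export
error_classes <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  if (any(measured <= 0)) stop("measured values must be > 0 at every site")
  ratio <- abs(predicted - measured) / measured
  cls <- cut(ratio, breaks = c(0, 0.25, 0.5, Inf), right = FALSE,
             include.lowest = TRUE, labels = c("lt25", "25to50", "gt50"))
  list(ratio = ratio, class = cls, counts = table(cls))
}
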