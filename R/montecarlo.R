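# run the RNG under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Fit a lognormal distribution to soil concentrations
#'
#' Takes logs, estimates the normal mean and sample SD, and applies a
#' Kolmogorov-Smirnov test of the logs against Normal(mu, sigma) with the
#' estimated parameters (no small-sample correction of the K-S reference
#' distribution is applied). The fit is flagged unusable when the K-S p-value
#' is <= 0.05 or the sample is degenerate (constant).
#'
#' @param c_soil Vector of soil concentrations (mg/kg), all > 0, n >= 3.
#' @return An object of class \code{lognormal_fit}: \code{mu}, \code{sigma},
#'   \code{ks_statistic}, \code{ks_p}, \code{n}, \code{usable}.
#' @export
fit_lognormal <- function(c_soil) {
  if (length(c_soil) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(c_soil)) || any(c_soil <= 0)) {
    stop("all concentrations must be finite and > 0 (log undefined otherwise)")
  }
  lx <- log(c_soil)
  mu <- mean(lx)
  sigma <- stats::sd(lx)
  if (sigma == 0) {
    return(structure(list(mu = mu, sigma = 0, ks_statistic = NA_real_,
                          ks_p = NA_real_, n = length(lx), usable = FALSE),
                     class = "lognormal_fit"))
  }
  ks <- suppressWarnings(stats::ks.test(lx, "pnorm", mean = mu, sd = sigma))
  structure(list(mu = mu, sigma = sigma,
                 ks_statistic = unname(ks$statistic),
                 ks_p = ks$p.value, n = length(lx),
                 usable = ks$p.value > 0.05),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> mu=%.4f sigma=%.4f n=%d  K-S D=%.4f p=%.4f  %s\n",
              x$mu, x$sigma, x$n,
              ifelse(is.na(x$ks_statistic), NaN, x$ks_statistic),
              ifelse(is.na(x$ks_p), NaN, x$ks_p),
              if (x$usable) "usable" else "UNUSABLE"))
  invisible(x)
}

#' Draw soil concentrations from a fitted lognormal
#'
#' @param fit A usable \code{\link{fit_lognormal}} result.
#' @param n_rep Number of draws, >= 1.
#' @param seed Integer seed; identical seeds give bitwise-identical draws.
#' @return Vector of n_rep positive concentrations (mg/kg).
#' @export
draw_soils <- function(fit, n_rep, seed) {
  stopifnot(inherits(fit, "lognormal_fit"))
  if (!fit$usable && fit$sigma > 0) stop("fit flagged unusable (K-S p <= 0.05)")
  if (n_rep < 1) stop("n_rep must be >= 1")
  with_seed(seed, exp(stats::rnorm(n_rep, fit$mu, fit$sigma)))
}

# Basis simulations exploiting the linearity of the accumulation equation in
# the source concentrations: finals = soil_total * soil_coef + atm_part,
# with the soluble/exchangeable split preserved through given fractions.
linear_response <- function(env, geom, rt, atm, growth, cfg, flux,
                            frac_s, frac_t) {
  env_unit <- metal_environment(env$metal, c_total = 1,
                                c_s = frac_s, c_t = frac_t, c_a = 0,
                                m_s = env$m_s, k_sw = env$k_sw)
  soil_coef <- simulate_accumulation(env_unit, geom, rt, atm, growth, cfg,
                                     flux)$final
  atm_part <- numeric(4)
  names(atm_part) <- wheat_parts()
  if (env$c_a > 0) {
    env_atm <- metal_environment(env$metal, c_total = env$c_total,
                                 c_s = 0, c_t = 0, c_a = env$c_a,
                                 m_s = env$m_s, k_sw = env$k_sw)
    atm_part <- simulate_accumulation(env_atm, geom, rt, atm, growth, cfg,
                                      flux)$final
  }
  list(soil_coef = soil_coef, atm_part = atm_part)
}

#' Monte Carlo ensemble through the accumulation model
#'
#' Draws soil totals from a fitted lognormal, scales the soluble and
#' exchangeable fractions proportionally (preserving the reference
#' environment's fraction ratios) and records the final tissue
#' concentrations of every replicate. Only the soil concentration varies;
#' atmosphere and all other parameters are held fixed.
#'
#' Because the accumulation equation is linear in the source concentrations,
#' the default method computes two basis simulations and scales them per
#' draw, which agrees with running the simulator once per replicate to
#' machine precision; \code{method = "direct"} performs the literal
#' per-replicate loop.
#'
#' @param fit A usable \code{\link{fit_lognormal}} result.
#' @param env Reference \code{\link{metal_environment}} (supplies the
#'   soluble/exchangeable fraction ratios and the fixed atmosphere).
#' @param geom,rt,atm,growth,cfg,flux Model inputs as in
#'   \code{\link{simulate_accumulation}}.
#' @param n_rep Number of replicates (default 10000).
#' @param seed Integer seed.
#' @param method "superposition" (default) or "direct".
#'
#' @return An object of class \code{ensemble_result}: \code{draws},
#'   \code{outputs} (n_rep x part, mg/kg), \code{n_rep}, \code{seed},
#'   \code{density} (per-part kernel density estimates, NULL and flagged when
#'   n_rep < 2).
#' @export
run_ensemble <- function(fit, env, geom, rt, atm, growth,
                         cfg = simulation_config(),
                         flux = list(q_up = 1, phloem_fraction = 0.5),
                         n_rep = 10000, seed = 1,
                         method = c("superposition", "direct")) {
  method <- match.arg(method)
  draws <- draw_soils(fit, n_rep, seed)
  if (env$c_total <= 0) stop("reference c_total must be > 0 to define fractions")
  frac_s <- env$c_s / env$c_total
  frac_t <- env$c_t / env$c_total
  parts <- wheat_parts()
  if (method == "superposition") {
    lr <- linear_response(env, geom, rt, atm, growth, cfg, flux,
                          frac_s, frac_t)
    outputs <- outer(draws, lr$soil_coef[parts]) +
      matrix(lr$atm_part[parts], nrow = n_rep, ncol = 4, byrow = TRUE)
  } else {
    outputs <- matrix(NA_real_, nrow = n_rep, ncol = 4)
    for (i in seq_len(n_rep)) {
      env_i <- metal_environment(env$metal, c_total = draws[i],
                                 c_s = frac_s * draws[i],
                                 c_t = frac_t * draws[i],
                                 c_a = env$c_a, m_s = env$m_s,
                                 k_sw = env$k_sw)
      res <- tryCatch(
        simulate_accumulation(env_i, geom, rt, atm, growth, cfg, flux),
        error = function(e) stop("simulator failed at replicate ", i, ": ",
                                 conditionMessage(e))
      )
      outputs[i, ] <- res$final[parts]
    }
  }
  colnames(outputs) <- parts
  dens <- NULL
  if (n_rep >= 2) {
    dens <- lapply(parts, function(p) stats::density(outputs[, p]))
    names(dens) <- parts
  }
  structure(list(draws = draws, outputs = outputs, n_rep = n_rep,
                 seed = seed, density = dens,
                 density_flag = if (n_rep < 2) "undefined for n_rep < 2" else NULL),
            class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> n_rep=%d seed=%d\n", x$n_rep, x$seed))
  print(signif(apply(x$outputs, 2, stats::quantile,
                     probs = c(0.05, 0.5, 0.95)), 4))
  invisible(x)
}

#' Density overlay of ensemble outputs against measurements
#'
#' Builds a Freedman-Diaconis histogram of the measured values and a kernel
#' density estimate of the ensemble outputs on a shared support, and reports
#' an overlap coefficient (integral of the pointwise minimum of the two
#' normalized densities, in [0, 1]).
#'
#' @param ensemble An \code{\link{run_ensemble}} result or a numeric vector
#'   of model outputs for one part.
#' @param measured Non-empty numeric vector of measured concentrations.
#' @param part Which part to extract when \code{ensemble} is an
#'   \code{ensemble_result}.
#'
#' @return List with \code{grid} (data frame: x, density_model,
#'   density_measured), \code{hist} (the measured histogram object) and
#'   \code{overlap}.
#' @export
density_overlay <- function(ensemble, measured, part = "grain") {
  x_mod <- if (inherits(ensemble, "ensemble_result")) {
    ensemble$outputs[, part]
  } else {
    as.numeric(ensemble)
  }
  if (length(x_mod) < 2L) stop("need at least 2 model values for a density")
  if (length(measured) == 0L) stop("empty measured vector")
  lo <- min(x_mod, measured)
  hi <- max(x_mod, measured)
  pad <- 0.1 * (hi - lo + .Machine$double.eps)
  grid_x <- seq(lo - pad, hi + pad, length.out = 512)
  d_mod <- stats::density(x_mod, from = min(grid_x), to = max(grid_x), n = 512)
  d_mea <- stats::density(measured, from = min(grid_x), to = max(grid_x), n = 512)
  h <- graphics::hist(measured, breaks = "FD", plot = FALSE)
  dx <- diff(d_mod$x[1:2])
  overlap <- sum(pmin(d_mod$y, d_mea$y)) * dx
  list(grid = data.frame(x = d_mod$x, density_model = d_mod$y,
                         density_measured = d_mea$y),
       hist = h, overlap = min(overlap, 1))
}

#' Plot a density overlay
#'
#' Measured-value histogram (bars) with the ensemble probability density
#' curve on the same axes.
#'
#' @param overlay A \code{\link{density_overlay}} result.
#' @param main Plot title.
#' @export
plot_density_overlay <- function(overlay, main = "model ensemble vs measurements") {
  h <- overlay$hist
  ylim <- c(0, max(h$density, overlay$grid$density_model))
  plot(h, freq = FALSE, col = "darkseagreen", border = "white",
       ylim = ylim, main = main, xlab = "concentration (mg/kg)")
  graphics::lines(overlay$grid$x, overlay$grid$density_model,
                  col = "firebrick", lwd = 2)
  invisible(overlay)
}
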