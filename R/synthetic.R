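#' Specification of a synthetic sampling campaign
#'
#' Describes a study-shaped survey: sites scattered over a rectangular
#' extent, lognormal soil concentrations with exponential spatial
#' autocorrelation on the log scale, bioavailable fractions, and
#' multiplicative measurement noise on model-derived tissue concentrations
#' at the mature sites. Defaults mirror a 52-site survey with 32 mature
#' wheat sites.
#'
#' @param n_sites Number of sites, >= 3.
#' @param extent Rectangle \code{c(xmin, xmax, ymin, ymax)} (m).
#' @param metals Named list, per metal: \code{log_mean}, \code{log_sd}
#'   (of ln concentration in mg/kg) and \code{range} (spatial correlation
#'   range, m).
#' @param soluble_fraction,exchangeable_fraction Fractions of the total soil
#'   concentration that are water-soluble / exchangeable; their sum must be
#'   <= 1.
#' @param soil_solution_ratio Conversion ratio mg/kg -> mg/L for the
#'   dissolved fractions (L solution per kg soil), default 1.
#' @param measurement_noise_cv CV of the multiplicative lognormal measurement
#'   noise, >= 0.
#' @param n_mature Number of sites carrying tissue measurements, <= n_sites.
#' @param seed Integer seed.
#'
#' @return An object of class \code{synthetic_field_spec}.
#' @export
synthetic_field_spec <- function(n_sites = 52,
                                 extent = c(0, 5000, 0, 5000),
                                 metals = list(
                                   Cu = list(log_mean = log(22.1), log_sd = 0.4, range = 800),
                                   Cd = list(log_mean = log(0.6),  log_sd = 0.5, range = 800),
                                   Pb = list(log_mean = log(36.3), log_sd = 0.4, range = 800),
                                   Ni = list(log_mean = log(28.9), log_sd = 0.4, range = 800)
                                 ),
                                 soluble_fraction = 0.05,
                                 exchangeable_fraction = 0.10,
                                 soil_solution_ratio = 1,
                                 measurement_noise_cv = 0.3,
                                 n_mature = 32, seed = 1) {
  if (n_sites < 3L) stop("n_sites must be >= 3")
  if (n_mature > n_sites || n_mature < 0) stop("need 0 <= n_mature <= n_sites")
  if (soluble_fraction < 0 || exchangeable_fraction < 0 ||
      soluble_fraction + exchangeable_fraction > 1) {
    stop("fractions must be >= 0 and sum to <= 1")
  }
  if (measurement_noise_cv < 0) stop("measurement_noise_cv must be >= 0")
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3]) {
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans")
  }
  structure(list(n_sites = as.integer(n_sites), extent = extent,
                 metals = metals, soluble_fraction = soluble_fraction,
                 exchangeable_fraction = exchangeable_fraction,
                 soil_solution_ratio = soil_solution_ratio,
                 measurement_noise_cv = measurement_noise_cv,
                 n_mature = as.integer(n_mature), seed = as.integer(seed)),
            class = "synthetic_field_spec")
}

#' Generate a spatially autocorrelated synthetic soil field
#'
#' Site coordinates are uniform over the extent. Per metal, log
#' concentrations are a draw from a Gaussian process with exponential
#' covariance \code{log_sd^2 * exp(-d / range)} (i.i.d. normal in the
#' range -> 0 limit), exponentiated to strictly positive totals. Soluble and
#' exchangeable concentrations are derived from the fractions via the
#' soil-solution ratio.
#'
#' @param spec A \code{\link{synthetic_field_spec}}.
#' @return A sample-table data frame: \code{site_id}, \code{x}, \code{y},
#'   \code{mature}, and per metal \code{<metal>_total} (mg/kg),
#'   \code{<metal>_cs}, \code{<metal>_ct} (mg/L), plus empty tissue columns
#'   \code{<metal>_root} ... \code{<metal>_grain} (mg/kg).
#' @export
generate_soil_field <- function(spec) {
  stopifnot(inherits(spec, "synthetic_field_spec"))
  n <- spec$n_sites
  with_seed(spec$seed, {
    x <- stats::runif(n, spec$extent[1], spec$extent[2])
    y <- stats::runif(n, spec$extent[3], spec$extent[4])
    tab <- data.frame(site_id = sprintf("S%02d", seq_len(n)), x = x, y = y,
                      mature = seq_len(n) %in% sample.int(n, spec$n_mature))
    d <- as.matrix(stats::dist(cbind(x, y)))
    for (metal in names(spec$metals)) {
      mspec <- spec$metals[[metal]]
      if (mspec$range > 0) {
        Sigma <- mspec$log_sd^2 * exp(-d / mspec$range)
        diag(Sigma) <- diag(Sigma) + 1e-10
        L <- chol(Sigma)
        lz <- mspec$log_mean + as.numeric(crossprod(L, stats::rnorm(n)))
      } else {
        lz <- stats::rnorm(n, mspec$log_mean, mspec$log_sd)
      }
      total <- exp(lz)
      key <- tolower(metal)
      tab[[paste0(key, "_total")]] <- total
      tab[[paste0(key, "_cs")]] <-
        total * spec$soluble_fraction / spec$soil_solution_ratio
      tab[[paste0(key, "_ct")]] <-
        total * spec$exchangeable_fraction / spec$soil_solution_ratio
      for (p in wheat_parts()) tab[[paste0(key, "_", p)]] <- NA_real_
    }
    attr(tab, "spec") <- spec
    tab
  })
}

#' Fill model-derived noisy tissue measurements into a sample table
#'
#' For every mature site and configured metal, the accumulation model is
#' evaluated at the site's soil concentrations (exploiting the model's
#' linearity in the sources via two basis simulations per metal, which is
#' exact) and multiplied by unit-mean lognormal noise with the given CV.
#'
#' @param table A sample table from \code{\link{generate_soil_field}} (or
#'   \code{\link{read_samples}}).
#' @param config A loaded model configuration (\code{\link{load_config}}).
#' @param noise_cv Measurement-noise CV, >= 0; 0 gives exact model outputs.
#' @param seed Integer seed.
#' @param metals Metals to fill; default all metals in the config that have
#'   columns in the table.
#'
#' @return The table with tissue columns filled at mature sites.
#' @export
generate_measurements <- function(table, config, noise_cv = 0.3, seed = 1,
                                  metals = NULL) {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  stopifnot(inherits(config, "metal_config"))
  if (is.null(metals)) {
    in_table <- sub("_total$", "", grep("_total$", names(table), value = TRUE))
    metals <- names(config$metals)[tolower(names(config$metals)) %in% in_table]
  }
  mature_idx <- which(table$mature)
  parts <- wheat_parts()
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    for (metal in metals) {
      key <- tolower(metal)
      inp <- config_inputs(config, metal)
      env <- inp$env
      # per-unit (c_s + c_t) response and fixed atmospheric part
      lr <- linear_response(env, inp$geom, inp$rt, inp$atm, inp$growth,
                            inp$cfg, inp$flux, frac_s = 1, frac_t = 0)
      src <- table[[paste0(key, "_cs")]] + table[[paste0(key, "_ct")]]
      for (p in parts) {
        base <- src[mature_idx] * lr$soil_coef[[p]] + lr$atm_part[[p]]
        noise <- if (noise_cv == 0) 1 else {
          exp(stats::rnorm(length(mature_idx), -sdlog^2 / 2, sdlog))
        }
        col <- paste0(key, "_", p)
        table[[col]][mature_idx] <- base * noise
      }
    }
    table
  })
}
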