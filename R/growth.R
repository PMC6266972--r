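#' Wheat compartments
#'
#' The four wheat compartments tracked by the model, in their fixed
#' serialization order: root, stem, leaf, grain.
#'
#' @return Character vector of the four part labels.
#' @export
wheat_parts <- function() c("root", "stem", "leaf", "grain")

#' Logistic growth parameters for one wheat compartment
#'
#' @param part One of \code{wheat_parts()}.
#' @param m0 Initial mass (kg), \code{0 < m0 < mmax}.
#' @param mmax Maximal mass (kg).
#' @param g Growth coefficient (1/d), positive.
#' @param emergence_day Day the compartment starts to exist (d). The logistic
#'   clock starts at emergence; mass is 0 before. Default 0; grain
#'   conventionally emerges around day 50.
#'
#' @return An object of class \code{growth_params}.
#' @export
growth_params <- function(part, m0, mmax, g, emergence_day = 0) {
  part <- match.arg(part, wheat_parts())
  stopifnot(is.numeric(m0), is.numeric(mmax), is.numeric(g),
            length(m0) == 1L, length(mmax) == 1L, length(g) == 1L)
  if (!is.finite(m0) || !is.finite(mmax) || !is.finite(g) ||
      !is.finite(emergence_day)) {
    stop("growth parameters must be finite")
  }
  if (m0 <= 0 || m0 >= mmax) stop("need 0 < m0 < mmax for part '", part, "'")
  if (g <= 0) stop("growth coefficient g must be positive")
  if (emergence_day < 0) stop("emergence_day must be >= 0")
  structure(list(part = part, m0 = m0, mmax = mmax, g = g,
                 emergence_day = emergence_day),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params %s> m0=%g kg, mmax=%g kg, g=%g 1/d, emergence=%g d\n",
              x$part, x$m0, x$mmax, x$g, x$emergence_day))
  invisible(x)
}

#' Default growth parameters
#'
#' Per-compartment logistic parameters for a winter-wheat season: initial and
#' maximal dry mass and growth coefficient for root, stem, leaf and grain,
#' with grain emerging 50 d after sowing.
#'
#' @return Named list of \code{\link{growth_params}}, one per part.
#' @export
default_growth_params <- function() {
  list(
    root  = growth_params("root",  2.5e-3,  0.25, 0.0075, 0),
    stem  = growth_params("stem",  1.25e-3, 0.45, 0.08,   0),
    leaf  = growth_params("leaf",  1.25e-3, 0.05, 0.08,   0),
    grain = growth_params("grain", 5.6e-6,  0.56, 0.14,   50)
  )
}

#' Closed-form logistic mass of one compartment
#'
#' M(t) = Mmax / (1 + ((Mmax - M0)/M0) * exp(-g * (t - emergence))) for
#' t >= emergence_day; 0 before emergence.
#'
#' @param params A \code{\link{growth_params}} object.
#' @param t Time since sowing (d), scalar or vector, non-negative and finite.
#'
#' @return Mass (kg), same length as \code{t}.
#' @export
logistic_mass <- function(params, t) {
  stopifnot(inherits(params, "growth_params"), is.numeric(t))
  if (any(!is.finite(t))) stop("t must be finite")
  if (any(t < 0)) stop("t must be >= 0")
  td <- t - params$emergence_day
  m <- params$mmax /
    (1 + ((params$mmax - params$m0) / params$m0) * exp(-params$g * td))
  m[td < 0] <- 0
  m
}

#' Mass trajectories for all compartments
#'
#' @param all_params List of \code{\link{growth_params}}, at most one per part.
#' @param t_grid Strictly increasing time grid starting at 0 (d).
#'
#' @return A \code{mass_series}: list with \code{t}, matrix \code{M}
#'   (time x part, kg) and empty flux slots filled by
#'   \code{\link{flux_series}}.
#' @export
mass_series <- function(all_params, t_grid = seq(0, 160, by = 0.5)) {
  if (length(t_grid) == 0L) stop("empty time grid")
  if (t_grid[1] != 0) stop("time grid must start at 0")
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0)) {
    stop("time grid must be strictly increasing")
  }
  parts <- vapply(all_params, function(p) p$part, character(1))
  if (anyDuplicated(parts)) stop("duplicate parts in growth parameter list")
  M <- matrix(0, nrow = length(t_grid), ncol = length(parts),
              dimnames = list(NULL, parts))
  for (p in all_params) M[, p$part] <- logistic_mass(p, t_grid)
  structure(list(t = t_grid, M = M, Q_up = NULL, Q_down = NULL,
                 params = all_params),
            class = "mass_series")
}

#' Fill xylem/phloem volumetric fluxes into a mass series
#'
#' Xylem (down-up) flux is taken proportional to compartment mass,
#' Q_up(t) = q_up * M(t); phloem (up-down) flux is a fixed fraction of it,
#' Q_down = phloem_fraction * Q_up, so Q_down < Q_up always.
#'
#' @param series A \code{\link{mass_series}}.
#' @param q_up Per-mass xylem flux coefficient, L/(kg d); scalar or named
#'   per-part vector, non-negative.
#' @param phloem_fraction Dimensionless in [0, 1); scalar or named per part.
#'
#' @return The series with \code{Q_up} and \code{Q_down} matrices filled (L/d).
#' @export
flux_series <- function(series, q_up, phloem_fraction) {
  stopifnot(inherits(series, "mass_series"))
  parts <- colnames(series$M)
  q_up <- expand_per_part(q_up, parts, "q_up")
  pf <- expand_per_part(phloem_fraction, parts, "phloem_fraction")
  if (any(q_up < 0)) stop("q_up must be >= 0")
  if (any(pf < 0) || any(pf >= 1)) {
    stop("phloem_fraction must lie in [0, 1): phloem flux cannot reach xylem flux")
  }
  series$Q_up <- sweep(series$M, 2, q_up[parts], `*`)
  series$Q_down <- sweep(series$Q_up, 2, pf[parts], `*`)
  series$q_up <- q_up
  series$phloem_fraction <- pf
  series
}

# recycle a scalar or validate a named per-part vector
expand_per_part <- function(x, parts, what) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), length(parts)), parts)
  }
  if (!all(parts %in% names(x))) {
    stop(what, " must be a scalar or named for every part: ",
         paste(parts, collapse = ", "))
  }
  out <- as.numeric(x[parts])
  names(out) <- parts
  out
}

#' Write a mass/flux series as long-format CSV
#'
#' Columns: t, part, mass_kg, q_up, q_down.
#'
#' @param series A \code{\link{mass_series}} (fluxes optional).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_mass_series <- function(series, path) {
  parts <- colnames(series$M)
  df <- do.call(rbind, lapply(parts, function(p) {
    data.frame(t = series$t, part = p, mass_kg = series$M[, p],
               q_up = if (is.null(series$Q_up)) NA_real_ else series$Q_up[, p],
               q_down = if (is.null(series$Q_down)) NA_real_ else series$Q_down[, p])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
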