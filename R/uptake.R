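#' Soil and atmosphere environment for one metal at one site
#'
#' @param metal Metal label, one of "Cu", "Pb", "Cd", "Ni" (other labels are
#'   accepted with a warning so the machinery generalises).
#' @param c_total Total soil concentration (mg/kg).
#' @param c_s Water-soluble soil concentration (mg/L).
#' @param c_t Exchangeable soil concentration (mg/L).
#' @param c_a Atmospheric concentration (mg/m3).
#' @param m_s Soil mass in the rooting volume (kg), positive.
#' @param k_sw Soil-water partition coefficient (L/kg), positive.
#'
#' @return An object of class \code{metal_environment}.
#' @export
metal_environment <- function(metal, c_total, c_s, c_t, c_a, m_s, k_sw) {
  known <- c("Cu", "Pb", "Cd", "Ni")
  if (!metal %in% known) {
    warning("metal '", metal, "' is outside the calibrated set (",
            paste(known, collapse = ", "), ")")
  }
  conc <- c(c_total = c_total, c_s = c_s, c_t = c_t, c_a = c_a)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0")
  }
  if (!is.finite(m_s) || m_s <= 0) stop("soil mass m_s must be > 0")
  if (!is.finite(k_sw) || k_sw <= 0) stop("partition coefficient k_sw must be > 0")
  structure(list(metal = metal, c_total = c_total, c_s = c_s, c_t = c_t,
                 c_a = c_a, m_s = m_s, k_sw = k_sw),
            class = "metal_environment")
}

#' Geometry and partitioning of one wheat compartment
#'
#' @param part One of \code{wheat_parts()}.
#' @param area Surface area (m2), >= 0.
#' @param water_content Water content W (L/kg), >= 0.
#' @param k_iw Part-water partition coefficient (L/kg), > 0.
#' @param permeability Surface permeability (m/d); meaningful for leaf and
#'   grain only (atmospheric pathway), \code{NA} otherwise.
#'
#' @return An object of class \code{part_geometry}.
#' @export
part_geometry <- function(part, area, water_content, k_iw, permeability = NA_real_) {
  part <- match.arg(part, wheat_parts())
  if (area < 0) stop("area must be >= 0")
  if (water_content < 0) stop("water_content must be >= 0")
  if (!is.finite(k_iw) || k_iw <= 0) stop("k_iw must be > 0")
  if (!is.na(permeability) && !part %in% c("leaf", "grain")) {
    stop("permeability applies to leaf and grain only")
  }
  structure(list(part = part, area = area, water_content = water_content,
                 k_iw = k_iw, permeability = permeability),
            class = "part_geometry")
}

#' Atmospheric particle parameters
#'
#' @param f_p Adsorption fraction of atmospheric particulate matter, in [0, 1].
#' @param v_dep Particle deposition velocity (m/d), >= 0.
#' @return An object of class \code{atmosphere_params}.
#' @export
atmosphere_params <- function(f_p, v_dep) {
  if (!is.finite(f_p) || f_p < 0 || f_p > 1) stop("f_p must lie in [0, 1]")
  if (!is.finite(v_dep) || v_dep < 0) stop("v_dep must be >= 0")
  structure(list(f_p = f_p, v_dep = v_dep), class = "atmosphere_params")
}

#' Root transport parameters
#'
#' @param q Root volumetric flux Q (L/d), >= 0.
#' @param f_c Volume conversion parameter (L/m3), >= 0.
#' @param d_r Diffusion rate of elements in roots (m/d), >= 0.
#' @return An object of class \code{root_transport}.
#' @export
root_transport <- function(q, f_c, d_r) {
  v <- c(q = q, f_c = f_c, d_r = d_r)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("root transport parameters must be finite and >= 0")
  }
  structure(list(q = q, f_c = f_c, d_r = d_r), class = "root_transport")
}

#' Inter-compartment transfer rate
#'
#' Rate at which part j absorbs metal from part i through sap flow:
#' r = Q_j / (K_iw * M_j), with Q_j the volumetric flux of the receiving part,
#' K_iw the source part's partition coefficient and M_j the receiving mass.
#'
#' @param q_j Volumetric flux of the receiving part (L/d), >= 0.
#' @param k_iw Source-part partition coefficient (L/kg), > 0.
#' @param m_j Mass of the receiving part (kg), > 0.
#'
#' @return Rate (1/d).
#' @export
transfer_rate <- function(q_j, k_iw, m_j) {
  if (!is.finite(k_iw) || k_iw <= 0) stop("k_iw must be > 0")
  if (!is.finite(q_j) || q_j < 0) stop("q_j must be >= 0")
  if (!is.finite(m_j) || m_j < 0) stop("m_j must be >= 0")
  if (m_j == 0) stop("receiving compartment has zero mass (pre-emergence query)")
  q_j / (k_iw * m_j)
}

#' Root uptake rate from soil
#'
#' Additive advection (transpiration pull) and diffusion pathways:
#' r = (Q + A_R * f_c * D_R) / (M_S * K_SW).
#'
#' @param rt A \code{\link{root_transport}} object.
#' @param a_r Root surface area (m2), >= 0.
#' @param env A \code{\link{metal_environment}} (provides M_S and K_SW).
#'
#' @return Rate (1/d).
#' @export
root_uptake_rate <- function(rt, a_r, env) {
  stopifnot(inherits(rt, "root_transport"), inherits(env, "metal_environment"))
  if (a_r < 0) stop("root area must be >= 0")
  (rt$q + a_r * rt$f_c * rt$d_r) / (env$m_s * env$k_sw)
}

#' Atmospheric uptake rate of a surface compartment
#'
#' Metabolic (cuticular permeation) plus non-metabolic (particle deposition)
#' pathways: r = A * P * (1 - f_P) + A * v_dep * f_P. Applies identically to
#' leaf and grain with their own area and permeability. Units m3/d; multiplied
#' by the atmospheric concentration (mg/m3) downstream.
#'
#' @param area Surface area (m2), >= 0.
#' @param permeability Surface permeability P (m/d), >= 0.
#' @param atm An \code{\link{atmosphere_params}} object.
#'
#' @return Volumetric uptake rate (m3/d).
#' @export
atmos_rate <- function(area, permeability, atm) {
  stopifnot(inherits(atm, "atmosphere_params"))
  if (area < 0) stop("area must be >= 0")
  if (!is.finite(permeability) || permeability < 0) stop("permeability must be >= 0")
  area * permeability * (1 - atm$f_p) + area * atm$v_dep * atm$f_p
}

#' Compose a serial transfer pathway into an effective rate
#'
#' The first stage keeps its native units; each further stage enters as a
#' dimensionless transfer efficiency r * tau, with tau a reference time
#' (default 1 d). A one-element chain is the identity.
#'
#' @param chain Numeric vector of elementary rates, all >= 0, non-empty.
#' @param tau Reference time (d), > 0.
#'
#' @return Effective pathway rate, units of the first stage.
#' @export
compose_pathway <- function(chain, tau = 1) {
  if (length(chain) == 0L) stop("empty pathway chain")
  if (any(!is.finite(chain)) || any(chain < 0)) stop("chain rates must be >= 0")
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (length(chain) == 1L) return(chain[[1]])
  chain[[1]] * prod(chain[-1] * tau)
}

# Core rate algebra at one instant, given masses (kg) and fluxes (L/d) as
# named per-part vectors. Pre-emergence compartments (mass 0) contribute zero
# rates when zero_unemerged, otherwise transfer_rate() raises.
rates_at <- function(geom, env, rt, atm, masses, q_up, q_down, tau = 1,
                     zero_unemerged = FALSE) {
  K <- vapply(geom, function(g) g$k_iw, numeric(1))
  edge <- function(flux, k_src, m_recv) {
    if (m_recv == 0) {
      if (zero_unemerged) return(0)
      stop("querying an edge into an unemerged compartment")
    }
    transfer_rate(flux, k_src, m_recv)
  }
  el <- c(
    S_R  = root_uptake_rate(rt, geom$root$area, env),
    R_St = edge(q_up["stem"],    K["root"], masses["stem"]),
    St_L = edge(q_up["leaf"],    K["stem"], masses["leaf"]),
    St_G = edge(q_up["grain"],   K["stem"], masses["grain"]),
    L_St = edge(q_down["stem"],  K["leaf"], masses["stem"]),
    St_R = edge(q_down["root"],  K["stem"], masses["root"]),
    A_L  = atmos_rate(geom$leaf$area,  geom$leaf$permeability,  atm),
    A_G  = atmos_rate(geom$grain$area, geom$grain$permeability, atm)
  )
  names(el) <- c("S_R", "R_St", "St_L", "St_G", "L_St", "St_R", "A_L", "A_G")
  soil <- c(
    root  = compose_pathway(el["S_R"], tau),
    stem  = compose_pathway(el[c("S_R", "R_St")], tau),
    leaf  = compose_pathway(el[c("S_R", "R_St", "St_L")], tau),
    grain = compose_pathway(el[c("S_R", "R_St", "St_G")], tau)
  )
  atmos <- c(
    root  = compose_pathway(el[c("A_L", "L_St", "St_R")], tau),
    stem  = compose_pathway(el[c("A_L", "L_St")], tau),
    leaf  = compose_pathway(el["A_L"], tau),
    grain = compose_pathway(el["A_G"], tau)
  )
  loss <- c(
    root  = el[["R_St"]],
    stem  = el[["St_L"]] + el[["St_G"]] + el[["St_R"]],
    leaf  = el[["L_St"]],
    grain = 0
  )
  list(elementary = el, composed_soil = soil, composed_atmos = atmos,
       loss = loss)
}

#' Build the full rate set at one time point
#'
#' Computes the eight elementary edges (soil-to-root, the five inter-part sap
#' edges, and the two atmospheric edges), the composed soil and atmosphere
#' pathway rates per part, and the per-part loss rates (sum of outgoing
#' elementary edges; grain has no outgoing edge, so its loss rate is 0).
#' Down-up edges use the xylem flux of the receiving part; up-down edges use
#' its phloem flux.
#'
#' @param geom Named list of \code{\link{part_geometry}}, one per part.
#' @param env A \code{\link{metal_environment}}.
#' @param rt A \code{\link{root_transport}}.
#' @param atm An \code{\link{atmosphere_params}}.
#' @param series A \code{\link{mass_series}} with fluxes filled.
#' @param t Time (d) within the series grid (linear interpolation between
#'   grid points).
#' @param tau Pathway composition reference time (d).
#' @param zero_unemerged If TRUE, edges into a compartment that has not yet
#'   emerged (mass 0) are reported as 0 instead of raising an error.
#'
#' @return An object of class \code{rate_set} with elements
#'   \code{elementary}, \code{composed_soil}, \code{composed_atmos},
#'   \code{loss}, all in 1/d (atmospheric elementary edges in m3/d).
#' @export
build_rate_set <- function(geom, env, rt, atm, series, t, tau = 1,
                           zero_unemerged = FALSE) {
  stopifnot(inherits(series, "mass_series"))
  if (is.null(series$Q_up)) stop("series has no fluxes; call flux_series() first")
  if (t < min(series$t) || t > max(series$t)) stop("t outside the series grid")
  parts <- colnames(series$M)
  at_t <- function(mat) {
    stats::setNames(vapply(parts, function(p) {
      stats::approx(series$t, mat[, p], xout = t)$y
    }, numeric(1)), parts)
  }
  rs <- rates_at(geom, env, rt, atm, at_t(series$M), at_t(series$Q_up),
                 at_t(series$Q_down), tau = tau,
                 zero_unemerged = zero_unemerged)
  structure(rs, class = "rate_set", t = t)
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set @ t=%g d>\n", attr(x, "t")))
  cat("  elementary (1/d; A_* in m3/d):\n")
  print(signif(x$elementary, 4))
  cat("  composed soil pathway:\n"); print(signif(x$composed_soil, 4))
  cat("  composed atmosphere pathway:\n"); print(signif(x$composed_atmos, 4))
  cat("  loss rates k_i:\n"); print(signif(x$loss, 4))
  invisible(x)
}
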