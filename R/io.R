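# Expected unit per parameter symbol. Every numeric leaf in the config is a
# mapping {value, unit, source}; the declared unit must match the expected
# unit string exactly (the loader refuses mixed-unit input).
unit_schema <- list(
  simulation = list(t_end = "d", dt = "d", tau = "d", grain_emergence = "d"),
  growth = list(m0 = "kg", mmax = "kg", g = "1/d", emergence_day = "d"),
  geometry = list(area = "m2", water_content = "L/kg", permeability = "m/d"),
  atmosphere = list(f_p = "-", v_dep = "m/d"),
  root_transport = list(q = "L/d", f_c = "L/m3", d_r = "m/d"),
  soil = list(m_s = "kg"),
  flux = list(q_up = "L/(kg d)", phloem_fraction = "-"),
  metal = list(c_total = "mg/kg", c_s = "mg/L", c_t = "mg/L",
               c_a = "mg/m3", k_sw = "L/kg", k_iw = "L/kg")
)

# read one {value, unit, source} leaf, validating the declared unit
read_leaf <- function(node, name, unit, where, prov) {
  if (is.null(node)) {
    stop("missing mandatory parameter '", name, "' in ", where)
  }
  if (!is.list(node)) {
    stop("parameter '", name, "' in ", where,
         " must be a mapping with value/unit/source")
  }
  unknown <- setdiff(names(node), c("value", "unit", "source"))
  if (length(unknown) > 0) {
    stop("unknown keys for '", name, "' in ", where, ": ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(node$value) || !is.numeric(node$value)) {
    stop("parameter '", name, "' in ", where, " has no numeric value")
  }
  if (is.null(node$unit) || !identical(as.character(node$unit), unit)) {
    stop("unit mismatch for '", name, "' in ", where, ": expected '", unit,
         "', got '", if (is.null(node$unit)) "<none>" else node$unit, "'")
  }
  src <- if (is.null(node$source)) "placeholder" else as.character(node$source)
  prov$rows[[length(prov$rows) + 1L]] <-
    data.frame(parameter = paste0(where, ".", name), source = src)
  as.numeric(node$value)
}

check_keys <- function(node, allowed, where) {
  unknown <- setdiff(names(node), allowed)
  if (length(unknown) > 0) {
    stop("unknown key(s) in ", where, ": ", paste(unknown, collapse = ", "))
  }
}

#' Load and validate a model configuration
#'
#' Reads a YAML configuration in which every numeric parameter is declared
#' as \code{{value, unit, source}}. Units are validated against each symbol's
#' expected unit; unknown keys are rejected; a provenance entry is attached
#' per parameter and parameters whose source is "placeholder" are flagged in
#' a message. The \code{simulation}, \code{growth} and \code{flux} blocks may
#' be omitted, in which case package defaults are used with a warning;
#' \code{geometry}, \code{atmosphere}, \code{root_transport}, \code{soil}
#' and \code{metals} are mandatory.
#'
#' @param path Path to the YAML file.
#' @return An object of class \code{metal_config}.
#' @seealso \code{\link{config_inputs}}, \code{\link{default_config_path}}
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("simulation", "growth", "geometry", "atmosphere",
                    "root_transport", "soil", "flux", "metals"), "config")
  for (blk in c("geometry", "atmosphere", "root_transport", "soil", "metals")) {
    if (is.null(raw[[blk]])) stop("missing mandatory block '", blk, "'")
  }
  prov <- new.env()
  prov$rows <- list()
  parts <- wheat_parts()

  # simulation -------------------------------------------------------------
  sim_defaults <- list(t_end = 160, dt = 0.5, tau = 1, grain_emergence = 50,
                       integrator = "rk4")
  if (is.null(raw$simulation)) {
    warning("no 'simulation' block; using defaults (t_end 160 d, dt 0.5 d)")
    simulation <- sim_defaults
  } else {
    check_keys(raw$simulation, c(names(unit_schema$simulation), "integrator"),
               "simulation")
    simulation <- lapply(stats::setNames(nm = names(unit_schema$simulation)),
                         function(k) {
      if (is.null(raw$simulation[[k]])) sim_defaults[[k]]
      else read_leaf(raw$simulation[[k]], k, unit_schema$simulation[[k]],
                     "simulation", prov)
    })
    simulation$integrator <- if (is.null(raw$simulation$integrator)) "rk4"
                             else match.arg(raw$simulation$integrator,
                                            c("rk4", "euler"))
  }

  # growth -----------------------------------------------------------------
  if (is.null(raw$growth)) {
    warning("no 'growth' block; using default logistic growth parameters")
    growth <- default_growth_params()
  } else {
    check_keys(raw$growth, parts, "growth")
    growth <- lapply(stats::setNames(nm = parts), function(p) {
      blk <- raw$growth[[p]]
      if (is.null(blk)) stop("growth block missing part '", p, "'")
      check_keys(blk, names(unit_schema$growth), paste0("growth.", p))
      vals <- lapply(stats::setNames(nm = names(unit_schema$growth)),
                     function(k) {
        if (k == "emergence_day" && is.null(blk[[k]])) return(0)
        read_leaf(blk[[k]], k, unit_schema$growth[[k]],
                  paste0("growth.", p), prov)
      })
      growth_params(p, vals$m0, vals$mmax, vals$g, vals$emergence_day)
    })
  }

  # geometry ---------------------------------------------------------------
  check_keys(raw$geometry, parts, "geometry")
  geometry <- lapply(stats::setNames(nm = parts), function(p) {
    blk <- raw$geometry[[p]]
    if (is.null(blk)) stop("geometry block missing part '", p, "'")
    allowed <- c("area", "water_content",
                 if (p %in% c("leaf", "grain")) "permeability")
    check_keys(blk, allowed, paste0("geometry.", p))
    out <- list(
      area = read_leaf(blk$area, "area", "m2", paste0("geometry.", p), prov),
      water_content = read_leaf(blk$water_content, "water_content", "L/kg",
                                paste0("geometry.", p), prov),
      permeability = NA_real_
    )
    if (p %in% c("leaf", "grain")) {
      out$permeability <- read_leaf(blk$permeability, "permeability", "m/d",
                                    paste0("geometry.", p), prov)
    }
    out
  })

  # atmosphere / root transport / soil --------------------------------------
  check_keys(raw$atmosphere, names(unit_schema$atmosphere), "atmosphere")
  atmosphere <- atmosphere_params(
    f_p = read_leaf(raw$atmosphere$f_p, "f_p", "-", "atmosphere", prov),
    v_dep = read_leaf(raw$atmosphere$v_dep, "v_dep", "m/d", "atmosphere", prov)
  )
  check_keys(raw$root_transport, names(unit_schema$root_transport),
             "root_transport")
  rt <- root_transport(
    q = read_leaf(raw$root_transport$q, "q", "L/d", "root_transport", prov),
    f_c = read_leaf(raw$root_transport$f_c, "f_c", "L/m3", "root_transport", prov),
    d_r = read_leaf(raw$root_transport$d_r, "d_r", "m/d", "root_transport", prov)
  )
  check_keys(raw$soil, names(unit_schema$soil), "soil")
  soil <- list(m_s = read_leaf(raw$soil$m_s, "m_s", "kg", "soil", prov))

  # flux -------------------------------------------------------------------
  if (is.null(raw$flux)) {
    warning("no 'flux' block; using q_up = 1 L/(kg d), phloem_fraction = 0.5")
    flux <- list(q_up = stats::setNames(rep(1, 4), parts),
                 phloem_fraction = stats::setNames(rep(0.5, 4), parts))
  } else {
    check_keys(raw$flux, c("q_up", "phloem_fraction"), "flux")
    per_part_leaf <- function(node, key, unit) {
      check_keys(node, parts, paste0("flux.", key))
      vapply(stats::setNames(nm = parts), function(p) {
        read_leaf(node[[p]], p, unit, paste0("flux.", key), prov)
      }, numeric(1))
    }
    flux <- list(
      q_up = per_part_leaf(raw$flux$q_up, "q_up", "L/(kg d)"),
      phloem_fraction = per_part_leaf(raw$flux$phloem_fraction,
                                      "phloem_fraction", "-")
    )
  }

  # metals -----------------------------------------------------------------
  metals <- lapply(stats::setNames(nm = names(raw$metals)), function(m) {
    blk <- raw$metals[[m]]
    check_keys(blk, names(unit_schema$metal), paste0("metals.", m))
    if (is.null(blk$k_sw)) {
      stop("metals.", m, ": missing K_SW (soil-water partition coefficient, ",
           "required by the root uptake rate)")
    }
    out <- lapply(stats::setNames(nm = setdiff(names(unit_schema$metal), "k_iw")),
                  function(k) {
      read_leaf(blk[[k]], k, unit_schema$metal[[k]], paste0("metals.", m), prov)
    })
    if (is.null(blk$k_iw)) stop("metals.", m, ": missing k_iw block")
    check_keys(blk$k_iw, parts, paste0("metals.", m, ".k_iw"))
    out$k_iw <- vapply(stats::setNames(nm = parts), function(p) {
      read_leaf(blk$k_iw[[p]], p, "L/kg", paste0("metals.", m, ".k_iw"), prov)
    }, numeric(1))
    out
  })

  provenance <- do.call(rbind, prov$rows)
  placeholders <- provenance$parameter[provenance$source == "placeholder"]
  if (length(placeholders) > 0) {
    message(length(placeholders),
            " parameter(s) carry placeholder (non-authoritative) values: ",
            paste(utils::head(placeholders, 8), collapse = ", "),
            if (length(placeholders) > 8) ", ..." else "")
  }
  structure(list(simulation = simulation, growth = growth,
                 geometry = geometry, atmosphere = atmosphere,
                 root_transport = rt, soil = soil, flux = flux,
                 metals = metals, provenance = provenance,
                 path = normalizePath(path)),
            class = "metal_config")
}

#' @export
print.metal_config <- function(x, ...) {
  cat(sprintf("<metal_config> metals: %s; t_end=%g d, dt=%g d, integrator=%s\n",
              paste(names(x$metals), collapse = ", "),
              x$simulation$t_end, x$simulation$dt, x$simulation$integrator))
  invisible(x)
}

#' Path to the shipped placeholder configuration
#'
#' The shipped configuration mirrors the full parameter inventory (soil,
#' atmosphere, crop geometry, partition coefficients, transport) with
#' documented, non-authoritative placeholder values calibrated only to
#' reproduce the qualitative tissue-concentration orderings.
#'
#' @return File path.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "soilwheat",
              mustWork = TRUE)
}

#' Assemble simulator inputs for one metal from a configuration
#'
#' @param config A \code{\link{load_config}} result.
#' @param metal Metal name present in the configuration.
#' @return List with \code{env}, \code{geom}, \code{rt}, \code{atm},
#'   \code{growth}, \code{cfg} (a \code{\link{simulation_config}}) and
#'   \code{flux}, ready for \code{\link{simulate_accumulation}}.
#' @export
config_inputs <- function(config, metal) {
  stopifnot(inherits(config, "metal_config"))
  if (!metal %in% names(config$metals)) {
    stop("metal '", metal, "' not in config (",
         paste(names(config$metals), collapse = ", "), ")")
  }
  m <- config$metals[[metal]]
  geom <- lapply(stats::setNames(nm = wheat_parts()), function(p) {
    g <- config$geometry[[p]]
    part_geometry(p, area = g$area, water_content = g$water_content,
                  k_iw = m$k_iw[[p]], permeability = g$permeability)
  })
  list(
    env = metal_environment(metal, c_total = m$c_total, c_s = m$c_s,
                            c_t = m$c_t, c_a = m$c_a,
                            m_s = config$soil$m_s, k_sw = m$k_sw),
    geom = geom,
    rt = config$root_transport,
    atm = config$atmosphere,
    growth = config$growth,
    cfg = simulation_config(t_end = config$simulation$t_end,
                            dt = config$simulation$dt,
                            grain_emergence = config$simulation$grain_emergence,
                            integrator = config$simulation$integrator,
                            tau = config$simulation$tau),
    flux = config$flux
  )
}

#' Read a site sample table from CSV
#'
#' Requires columns \code{site_id}, \code{x}, \code{y} and at least one
#' \code{<metal>_total} concentration column. Missing tissue measurements
#' (\code{<metal>_root} ... \code{<metal>_grain}) are allowed; missing or
#' negative soil concentrations are rejected with the offending row and
#' column named. A \code{mature} column is derived from the presence of
#' tissue values when absent.
#'
#' @param path CSV path.
#' @return Validated sample-table data frame.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty sample table")
  need <- c("site_id", "x", "y")
  if (!all(need %in% names(tab))) {
    stop("sample table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$site_id)) {
    stop("duplicate site_id: ",
         paste(unique(tab$site_id[duplicated(tab$site_id)]), collapse = ", "))
  }
  if (any(!is.finite(tab$x)) || any(!is.finite(tab$y))) {
    stop("non-finite coordinates")
  }
  if (all(abs(tab$x) <= 180) && all(abs(tab$y) <= 90)) {
    warning("coordinates look angular (lat/lon); ",
            "planar metric coordinates are expected")
  }
  soil_cols <- grep("_(total|cs|ct)$", names(tab), value = TRUE)
  if (!any(grepl("_total$", soil_cols))) {
    stop("no <metal>_total soil concentration column found")
  }
  for (col in soil_cols) {
    bad <- which(is.na(tab[[col]]) | tab[[col]] < 0)
    if (length(bad) > 0) {
      stop("missing or negative soil concentration in column '", col,
           "', row(s) ", paste(bad, collapse = ", "))
    }
  }
  tissue_cols <- grep(paste0("_(", paste(wheat_parts(), collapse = "|"), ")$"),
                      names(tab), value = TRUE)
  for (col in tissue_cols) {
    bad <- which(!is.na(tab[[col]]) & tab[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative tissue concentration in column '", col, "', row(s) ",
           paste(bad, collapse = ", "))
    }
  }
  if (!"mature" %in% names(tab)) {
    tab$mature <- if (length(tissue_cols) > 0) {
      rowSums(!is.na(tab[, tissue_cols, drop = FALSE])) > 0
    } else FALSE
  }
  tab
}

#' Write a sample table to CSV
#'
#' Numeric columns are written with full double precision so a write/read
#' round trip is lossless well beyond 12 significant digits.
#'
#' @param table Sample-table data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_samples <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration hash, seed, package and R versions and the
#' assumption log of a run, enabling exact replay.
#'
#' @param config A \code{\link{load_config}} result (its source file is
#'   hashed) or NULL.
#' @param seed Integer seed used for the run.
#' @param out Output JSON path.
#' @param assumptions Character vector of modeling assumptions exercised.
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, seed, out, assumptions = character()) {
  hash <- if (!is.null(config) && !is.null(config$path) &&
              file.exists(config$path)) {
    unname(tools::md5sum(config$path))
  } else NA_character_
  manifest <- list(
    config_md5 = hash,
    config_path = if (is.null(config)) NA_character_ else config$path,
    seed = seed,
    package = "soilwheat",
    package_version = as.character(utils::packageVersion("soilwheat")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    assumptions = assumptions
  )
  jsonlite::write_json(manifest, out, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
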