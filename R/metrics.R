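#' Root mean square of a concentration vector
#'
#' @param x Non-empty numeric vector, finite.
#' @return sqrt(mean(x^2)).
#' @export
rms <- function(x) {
  if (length(x) == 0L) stop("empty vector")
  if (any(!is.finite(x))) stop("non-finite values")
  sqrt(mean(x^2))
}

#' Value difference rate between modeled and measured concentrations
#'
#' |RMS(modeled) - RMS(measured)| / RMS(measured).
#'
#' @param x_mod Modeled values.
#' @param x_mea Measured values; must have positive RMS.
#' @return Dimensionless fraction >= 0.
#' @export
value_difference_rate <- function(x_mod, x_mea) {
  r_mea <- rms(x_mea)
  if (r_mea == 0) stop("measured RMS is zero")
  abs(rms(x_mod) - r_mea) / r_mea
}

#' Coefficient of variation
#'
#' Standard deviation over arithmetic mean. The sample (n - 1) standard
#' deviation is the default, matching field-sample usage; set
#' \code{sample = FALSE} for the population form.
#'
#' @param x Non-empty numeric vector with non-zero mean.
#' @param sample Use the n - 1 denominator (default TRUE).
#' @return Dimensionless CV.
#' @export
cv <- function(x, sample = TRUE) {
  if (length(x) == 0L) stop("empty vector")
  m <- mean(x)
  if (m == 0) stop("mean is zero; CV undefined")
  s <- if (sample) stats::sd(x) else sqrt(mean((x - m)^2))
  s / m
}

#' Fluctuation difference rate between modeled and measured dispersion
#'
#' |CV_mod - CV_mea| / CV_mea. Accepts either raw vectors or precomputed CVs.
#'
#' @param x_mod Modeled values, or a single precomputed CV.
#' @param x_mea Measured values, or a single precomputed CV; CV must be
#'   non-zero.
#' @param precomputed If TRUE, treat the inputs as CV scalars.
#' @param sample Passed to \code{\link{cv}} for raw vectors.
#' @return Dimensionless fraction >= 0.
#' @export
fluctuation_difference_rate <- function(x_mod, x_mea, precomputed = FALSE,
                                        sample = TRUE) {
  cv_mod <- if (precomputed) x_mod else cv(x_mod, sample = sample)
  cv_mea <- if (precomputed) x_mea else cv(x_mea, sample = sample)
  if (cv_mea == 0) stop("measured CV is zero")
  abs(cv_mod - cv_mea) / cv_mea
}

#' Bioconcentration factors
#'
#' Whole-plant and grain bioconcentration factors relative to total soil
#' concentration. The whole-plant concentration is the sum of the four part
#' concentrations (root + stem + leaf + grain); this convention reproduces
#' the conventional BCF_sw bookkeeping for per-part reported means.
#'
#' @param parts Named numeric vector of tissue concentrations (mg/kg) with
#'   names root, stem, leaf, grain.
#' @param c_soil Total soil concentration (mg/kg), > 0.
#'
#' @return Named vector \code{c(bcf_sw, bcf_sg)}.
#' @export
bcf <- function(parts, c_soil) {
  if (!is.finite(c_soil) || c_soil <= 0) stop("c_soil must be > 0")
  need <- wheat_parts()
  if (!all(need %in% names(parts))) {
    stop("parts must be named with ", paste(need, collapse = ", "))
  }
  if (any(parts[need] < 0)) stop("tissue concentrations must be >= 0")
  c(bcf_sw = sum(parts[need]) / c_soil,
    bcf_sg = unname(parts["grain"]) / c_soil)
}

#' Model-vs-measurement agreement report
#'
#' Joins modeled and measured tissue concentrations on (site, metal, part)
#' and computes, per metal x part over sites: RMS of each series, the value
#' difference rate, both CVs and the fluctuation difference rate. Per-metal
#' and overall summaries average the rates over parts within each metal, then
#' over metals (equal weights).
#'
#' @param modeled,measured Data frames with columns \code{site}, \code{metal},
#'   \code{part}, \code{value} (mg/kg).
#' @param sample Use sample (n - 1) standard deviation in CVs.
#'
#' @return List with \code{by_group}, \code{by_metal} and \code{overall}
#'   data frames.
#' @export
metrics_report <- function(modeled, measured, sample = TRUE) {
  need <- c("site", "metal", "part", "value")
  if (!all(need %in% names(modeled)) || !all(need %in% names(measured))) {
    stop("inputs need columns site, metal, part, value")
  }
  m <- merge(modeled, measured, by = c("site", "metal", "part"),
             suffixes = c("_mod", "_mea"))
  if (nrow(m) == 0L) stop("no overlapping (site, metal, part) records")
  groups <- unique(m[, c("metal", "part")])
  by_group <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- m[m$metal == groups$metal[i] & m$part == groups$part[i], ]
    data.frame(
      metal = groups$metal[i], part = groups$part[i], n = nrow(g),
      rms_mod = rms(g$value_mod), rms_mea = rms(g$value_mea),
      v_dr = value_difference_rate(g$value_mod, g$value_mea),
      cv_mod = cv(g$value_mod, sample = sample),
      cv_mea = cv(g$value_mea, sample = sample),
      f_dr = fluctuation_difference_rate(g$value_mod, g$value_mea,
                                         sample = sample)
    )
  }))
  by_metal <- do.call(rbind, lapply(split(by_group, by_group$metal), function(g) {
    data.frame(metal = g$metal[1], v_dr = mean(g$v_dr), f_dr = mean(g$f_dr))
  }))
  rownames(by_metal) <- NULL
  overall <- data.frame(v_dr = mean(by_metal$v_dr), f_dr = mean(by_metal$f_dr))
  list(by_group = by_group, by_metal = by_metal, overall = overall)
}
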