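#' Construct an ELSD power-law calibration curve
#'
#' The evaporative light-scattering detector responds to analyte mass as a
#' power law; with a co-injected internal standard (IS) the working model is
#' \deqn{A_{TTGS}/A_{IS} = a \, (C_{TTGS}/C_{IS})^b}
#' relating the TAG/IS peak-area ratio to the concentration ratio.
#'
#' @param a positive multiplicative coefficient.
#' @param b positive exponent.
#' @param r_squared optional goodness of fit (on the fitting scale).
#' @param fit_scale scale the curve was fitted on (`"log-log"` or
#'   `"direct"`); informational.
#' @param n number of calibration points, if known.
#' @return an object of class `power_calibration`.
#' @export
power_calibration <- function(a, b, r_squared = NA_real_,
                              fit_scale = "log-log", n = NA_integer_) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive number", call. = FALSE)
  structure(list(a = a, b = b, r_squared = r_squared,
                 fit_scale = fit_scale, n = n),
            class = "power_calibration")
}

#' Fit the ELSD internal-standard power calibration
#'
#' Fits \eqn{y = a x^b} to concentration-ratio / area-ratio pairs from a
#' dilution series.  The default fit is ordinary least squares on the
#' log-log scale (\eqn{\log y = \log a + b \log x}), where the power model is
#' linear and the multiplicative detector noise is closest to homoscedastic;
#' \eqn{R^2} is reported on that scale.  `method = "direct"` refines the
#' log-log estimates by nonlinear least squares on the original scale.
#'
#' @param conc_ratio concentration ratios \eqn{C_{TTGS}/C_{IS}} (> 0).
#' @param area_ratio area ratios \eqn{A_{TTGS}/A_{IS}} (> 0); alternatively
#'   pass a two-column data frame `(conc_ratio, area_ratio)` as the first
#'   argument.
#' @param method `"loglog"` (default) or `"direct"`.
#' @return a [power_calibration] with `a`, `b` and `r_squared`.
#' @examples
#' x <- c(0.2, 0.4, 0.6, 0.8, 1.0) / 0.05
#' fit_power_calibration(x, 0.4568 * x^1.4353)
#' @export
fit_power_calibration <- function(conc_ratio, area_ratio = NULL,
                                  method = c("loglog", "direct")) {
  method <- match.arg(method)
  if (is.data.frame(conc_ratio)) {
    area_ratio <- conc_ratio[[2L]]
    conc_ratio <- conc_ratio[[1L]]
  }
  x <- as.numeric(conc_ratio)
  y <- as.numeric(area_ratio)
  if (length(x) != length(y))
    stop("'conc_ratio' and 'area_ratio' lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("at least 3 calibration points are required", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("all calibration points must be finite and strictly positive",
         call. = FALSE)
  fit <- stats::lm(log(y) ~ log(x))
  a <- exp(unname(stats::coef(fit)[1L]))
  b <- unname(stats::coef(fit)[2L])
  ly <- log(y)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((ly - mean(ly))^2)
  scale <- "log-log"
  if (method == "direct") {
    nfit <- stats::nls(y ~ a * x^b, start = list(a = a, b = b),
                       control = stats::nls.control(maxiter = 200,
                                                    scaleOffset = 1))
    a <- unname(stats::coef(nfit)[["a"]])
    b <- unname(stats::coef(nfit)[["b"]])
    r2 <- 1 - sum(stats::resid(nfit)^2) / sum((y - mean(y))^2)
    scale <- "direct"
  }
  if (b <= 0)
    stop("fitted exponent is not positive; calibration data are not a rising power law",
         call. = FALSE)
  power_calibration(a, b, r_squared = r2, fit_scale = scale,
                    n = length(x))
}

#' @export
print.power_calibration <- function(x, digits = 4, ...) {
  cat(sprintf("<power_calibration> y = %.*g * x^%.*g", digits, x$a,
              digits, x$b))
  if (is.finite(x$r_squared))
    cat(sprintf("  (R^2 = %.4f, %s fit%s)", x$r_squared, x$fit_scale,
                if (is.na(x$n)) "" else sprintf(", n = %d", x$n)))
  cat("\n")
  invisible(x)
}

#' @export
summary.power_calibration <- function(object, ...) {
  cat("ELSD internal-standard power calibration\n")
  print(object)
  cat(sprintf("inverse: x = (y / %.6g)^(1/%.6g)\n", object$a, object$b))
  invisible(object)
}

#' @export
coef.power_calibration <- function(object, ...) {
  c(a = object$a, b = object$b)
}

#' Predicted area ratio for a concentration ratio
#'
#' @param object a [power_calibration].
#' @param conc_ratio concentration ratio(s), >= 0.
#' @param ... unused.
#' @return predicted area ratio(s) \eqn{a \, x^b}.
#' @export
predict.power_calibration <- function(object, conc_ratio, ...) {
  if (any(conc_ratio < 0)) stop("'conc_ratio' must be >= 0", call. = FALSE)
  object$a * conc_ratio^object$b
}

#' @export
plot.power_calibration <- function(x, conc_range = c(0.01, 30), ...) {
  cc <- exp(seq(log(conc_range[1L]), log(conc_range[2L]), length.out = 200))
  graphics::plot(cc, predict(x, cc), type = "l", log = "xy",
                 xlab = "concentration ratio C/C_IS",
                 ylab = "area ratio A/A_IS",
                 main = sprintf("y = %.4g x^%.4g", x$a, x$b), ...)
  invisible(x)
}

#' Invert the calibration: area ratio to concentration ratio
#'
#' @param curve a [power_calibration].
#' @param area_ratio observed area ratio(s), >= 0 (0 maps to 0).
#' @return concentration ratio(s) \eqn{(y/a)^{1/b}}.
#' @export
invert_calibration <- function(curve, area_ratio) {
  stopifnot(inherits(curve, "power_calibration"))
  if (any(area_ratio < 0))
    stop("'area_ratio' must be >= 0", call. = FALSE)
  (area_ratio / curve$a)^(1 / curve$b)
}

#' Construct an HPLC-ELSD peak table
#'
#' One chromatographic observation of a lipolysis product: the annotated TAG
#' peaks, the internal-standard area, and the sample bookkeeping needed by
#' the quantification equations.
#'
#' @param sample_id sample identifier.
#' @param time_point_min digestion time of the observation (min); 0 for the
#'   pre-digestion sample.
#' @param peaks data frame with columns `retention_min`, `area` and
#'   optionally `annotation` (TAG species label or `"Unknown"`).
#' @param is_area internal-standard (triundecanoin) peak area (> 0).
#' @param m_lp_mg weighed mass of the extracted lipolysis product (mg).
#' @param m_a_mg actual oil mass digested (mg).
#' @param c_s_mg_per_ml injected lipolysis-product concentration (mg/mL;
#'   1 in the standard protocol).
#' @param c_is_mg_per_ml internal-standard concentration (mg/mL; 0.05 in the
#'   standard protocol).
#' @return an object of class `peak_table`.
#' @export
peak_table <- function(sample_id, time_point_min, peaks, is_area,
                       m_lp_mg, m_a_mg,
                       c_s_mg_per_ml = 1, c_is_mg_per_ml = 0.05) {
  stopifnot(is.data.frame(peaks),
            all(c("retention_min", "area") %in% names(peaks)))
  if (!"annotation" %in% names(peaks)) peaks$annotation <- "Unknown"
  peaks <- peaks[order(peaks$retention_min), , drop = FALSE]
  rownames(peaks) <- NULL
  if (any(peaks$area < 0)) stop("peak areas must be >= 0", call. = FALSE)
  if (!is.numeric(is_area) || is_area <= 0)
    stop("'is_area' must be > 0", call. = FALSE)
  vals <- c(m_lp_mg, m_a_mg, c_s_mg_per_ml, c_is_mg_per_ml)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("masses and concentrations must all be > 0", call. = FALSE)
  structure(list(sample_id = sample_id,
                 time_point_min = as.numeric(time_point_min),
                 peaks = peaks, is_area = as.numeric(is_area),
                 m_lp_mg = m_lp_mg, m_a_mg = m_a_mg,
                 c_s_mg_per_ml = c_s_mg_per_ml,
                 c_is_mg_per_ml = c_is_mg_per_ml),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf(
    "<peak_table> %s @ %g min: %d peaks, IS area %.4g, m_LP %.4g mg, m_a %.4g mg\n",
    x$sample_id, x$time_point_min, nrow(x$peaks), x$is_area, x$m_lp_mg,
    x$m_a_mg))
  print(x$peaks, row.names = FALSE)
  invisible(x)
}

# Resolve an area selector against a peak table: "total" sums every TAG peak
# (unknowns included -- they are TAG too, just unannotated); a species label
# sums the peaks carrying that annotation.
select_area <- function(obs, selector) {
  if (identical(selector, "total")) return(sum(obs$peaks$area))
  hit <- obs$peaks$annotation == selector
  if (!any(hit)) return(NA_real_)
  sum(obs$peaks$area[hit])
}

#' Mass of total TAG species in a lipolysis product
#'
#' Inverts the calibration to a concentration ratio and scales it to a mass,
#' normalized to a common amount of starting oil:
#' \deqn{m_{TTGS} = [(A/A_{IS})/a]^{1/b} \; C_{IS} \, m_{LP} / C_S \times
#'   normalize\_to / m_a}
#'
#' @param obs a [peak_table].
#' @param curve a [power_calibration].
#' @param area TAG peak area to quantify; defaults to the sum of all peaks
#'   in `obs`.
#' @param normalize_to reference oil mass (mg) the result is normalized to
#'   (150 in the standard protocol).
#' @return TAG mass in mg (per `normalize_to` mg of starting oil).
#' @export
ttgs_mass <- function(obs, curve, area = NULL, normalize_to = 150) {
  stopifnot(inherits(obs, "peak_table"), inherits(curve, "power_calibration"))
  if (is.null(area)) area <- sum(obs$peaks$area)
  if (!is.numeric(area) || length(area) != 1L || is.na(area) || area < 0)
    stop("'area' must be a single non-negative number", call. = FALSE)
  conc_ratio <- invert_calibration(curve, area / obs$is_area)
  conc_ratio * obs$c_is_mg_per_ml * obs$m_lp_mg / obs$c_s_mg_per_ml *
    normalize_to / obs$m_a_mg
}

#' Lipolysis rate between two time points
#'
#' Fractional loss of TAG mass between the 0-min and t-min observations:
#' \deqn{rate_t(\%) = \left(1 - m_{TTGS}(t)/m_{TTGS}(0)\right) \times 100}
#' with both masses from [ttgs_mass()].  Because the masses enter as a
#' ratio, the coefficient \eqn{a} cancels and only the exponent \eqn{b}
#' matters.  Results outside [0, 100] are reported as-is with a
#' `quality` attribute of `"out_of_range"` and a warning (negative values
#' signal noise or a normalization problem), never clamped.
#'
#' @param obs0 [peak_table] at 0 min.
#' @param obst [peak_table] at t min (same sample lineage).
#' @param curve a [power_calibration] appropriate for `selector`.
#' @param selector `"total"` for the summed TAG area, or a species
#'   annotation label.
#' @param normalize_to reference oil mass in mg (see [ttgs_mass()]).
#' @return lipolysis rate in percent, with a `quality` attribute (`"ok"` or
#'   `"out_of_range"`).
#' @export
lipolysis_rate <- function(obs0, obst, curve, selector = "total",
                           normalize_to = 150) {
  stopifnot(inherits(obs0, "peak_table"), inherits(obst, "peak_table"))
  if (obs0$time_point_min != 0)
    stop("'obs0' must be the 0-min observation", call. = FALSE)
  a0 <- select_area(obs0, selector)
  at <- select_area(obst, selector)
  if (is.na(a0))
    stop(sprintf("selector '%s' matches no peak at 0 min", selector),
         call. = FALSE)
  if (is.na(at)) at <- 0  # species fully hydrolysed below detection
  m0 <- ttgs_mass(obs0, curve, a0, normalize_to)
  if (m0 == 0)
    stop("TAG mass at 0 min is zero; rate undefined", call. = FALSE)
  mt <- ttgs_mass(obst, curve, at, normalize_to)
  rate <- (1 - mt / m0) * 100
  quality <- "ok"
  if (rate < 0 || rate > 100) {
    quality <- "out_of_range"
    warning(sprintf("lipolysis rate %.2f%% outside [0, 100]", rate),
            call. = FALSE)
  }
  structure(rate, quality = quality)
}

#' Per-species lipolysis rates
#'
#' Applies [lipolysis_rate()] to each annotated TAG species with that
#' species' own calibration exponent.
#'
#' @param obs0,obst annotated [peak_table]s at 0 and t min.
#' @param curves named list of [power_calibration]s keyed by species label;
#'   must cover every species requested.
#' @param species labels to quantify; defaults to every non-`"Unknown"`
#'   annotation present at 0 min.
#' @return named numeric vector of rates (%); species absent at 0 min are
#'   skipped with a warning.
#' @export
species_lipolysis_rates <- function(obs0, obst, curves, species = NULL) {
  stopifnot(inherits(obs0, "peak_table"), inherits(obst, "peak_table"))
  if (is.null(species)) {
    species <- unique(c(obs0$peaks$annotation, obst$peaks$annotation))
    species <- setdiff(species, "Unknown")
  }
  present0 <- unique(obs0$peaks$annotation)
  missing0 <- setdiff(species, present0)
  if (length(missing0) > 0L) {
    warning(sprintf("species missing at 0 min skipped: %s",
                    paste(missing0, collapse = ", ")), call. = FALSE)
    species <- setdiff(species, missing0)
  }
  no_curve <- setdiff(species, names(curves))
  if (length(no_curve) > 0L)
    stop(sprintf("no calibration curve for species: %s",
                 paste(no_curve, collapse = ", ")), call. = FALSE)
  out <- vapply(species, function(sp) {
    as.numeric(lipolysis_rate(obs0, obst, curves[[sp]], selector = sp))
  }, 0)
  names(out) <- species
  out
}
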