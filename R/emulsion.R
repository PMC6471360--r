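#' Construct a particle-size distribution
#'
#' @param diameter_um bin diameters in micrometres; strictly increasing, > 0.
#' @param count particle counts or frequencies per bin; >= 0, not all zero.
#' @return an object of class `particle_size_distribution`.
#' @export
particle_size_distribution <- function(diameter_um, count) {
  diameter_um <- as.numeric(diameter_um)
  count <- as.numeric(count)
  if (length(diameter_um) != length(count) || length(count) < 1L)
    stop("'diameter_um' and 'count' must have equal positive length",
         call. = FALSE)
  if (any(diameter_um <= 0) || any(diff(diameter_um) <= 0))
    stop("'diameter_um' must be strictly increasing and positive",
         call. = FALSE)
  if (any(count < 0)) stop("'count' must be non-negative", call. = FALSE)
  if (sum(count) <= 0) stop("all counts are zero", call. = FALSE)
  structure(list(diameter_um = diameter_um, count = count),
            class = "particle_size_distribution")
}

#' Sauter mean diameter
#'
#' Surface-weighted mean droplet diameter
#' \deqn{d_{32} = \sum n_i d_i^3 / \sum n_i d_i^2,}
#' the diameter of a sphere with the same volume-to-surface ratio as the
#' whole distribution.  It is scale-free in the counts and always lies
#' between the smallest and largest diameter present.
#'
#' @param psd a [particle_size_distribution].
#' @return \eqn{d_{32}} in micrometres.
#' @examples
#' sauter_mean_diameter(particle_size_distribution(c(1, 2), c(1, 1)))  # 1.8
#' @export
sauter_mean_diameter <- function(psd) {
  stopifnot(inherits(psd, "particle_size_distribution"))
  sum(psd$count * psd$diameter_um^3) / sum(psd$count * psd$diameter_um^2)
}

#' Construct a backscattering scan
#'
#' A Turbiscan-style kinetic scan: the change in backscattered intensity
#' (delta-BS, %) over the height of the sample cell, repeated over time.
#'
#' @param times_min scan times in minutes, increasing.
#' @param heights_mm scan heights in mm from the cell bottom, increasing.
#' @param dbs matrix of delta-BS values (%), `length(times_min)` rows by
#'   `length(heights_mm)` columns.
#' @return an object of class `backscatter_scan`.
#' @export
backscatter_scan <- function(times_min, heights_mm, dbs) {
  times_min <- as.numeric(times_min)
  heights_mm <- as.numeric(heights_mm)
  dbs <- as.matrix(dbs)
  if (any(diff(times_min) <= 0)) stop("'times_min' must be increasing",
                                      call. = FALSE)
  if (any(diff(heights_mm) <= 0)) stop("'heights_mm' must be increasing",
                                       call. = FALSE)
  if (nrow(dbs) != length(times_min) || ncol(dbs) != length(heights_mm))
    stop("'dbs' must be a times x heights matrix", call. = FALSE)
  structure(list(times_min = times_min, heights_mm = heights_mm, dbs = dbs),
            class = "backscatter_scan")
}

#' @export
print.backscatter_scan <- function(x, ...) {
  cat(sprintf(
    "<backscatter_scan> %d times (0-%g min) x %d heights (%.1f-%.1f mm)\n",
    length(x$times_min), max(x$times_min), length(x$heights_mm),
    min(x$heights_mm), max(x$heights_mm)))
  invisible(x)
}

#' Creaming / clarification rate from a backscattering scan
#'
#' Averages delta-BS over the heights of the chosen zone at each scan time
#' and returns the ordinary-least-squares slope of that zone mean against
#' time, in %/h.  The creaming zone is the top `creaming_depth_mm` of the
#' scanned column (the liquid level is taken as the highest scanned point);
#' the clarification zone is the bottom `clarification_depth_mm`.  A
#' positive creaming rate means droplets are concentrating at the top; a
#' negative clarification rate means the bottom is clearing.
#'
#' @param scan a [backscatter_scan] with at least two time points.
#' @param zone `"creaming"` or `"clarification"`.
#' @param creaming_depth_mm depth of the creaming zone below the liquid
#'   level (default 3 mm).
#' @param clarification_depth_mm height of the clarification zone above the
#'   cell bottom (default 5 mm).
#' @return slope in %/h.
#' @export
backscatter_rate <- function(scan, zone = c("creaming", "clarification"),
                             creaming_depth_mm = 3,
                             clarification_depth_mm = 5) {
  stopifnot(inherits(scan, "backscatter_scan"))
  zone <- match.arg(zone)
  if (length(scan$times_min) < 2L)
    stop("at least two scan times are required", call. = FALSE)
  h <- scan$heights_mm
  sel <- if (zone == "creaming") {
    h >= max(h) - creaming_depth_mm
  } else {
    h <= min(h) + clarification_depth_mm
  }
  if (!any(sel))
    stop(sprintf("%s zone contains no scanned heights", zone), call. = FALSE)
  zone_mean <- rowMeans(scan$dbs[, sel, drop = FALSE])
  fit <- stats::lm(zone_mean ~ scan$times_min)
  unname(stats::coef(fit)[2L]) * 60  # %/min -> %/h
}
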