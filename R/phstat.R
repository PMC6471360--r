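#' Construct a pH-stat titration series
#'
#' Cumulative NaOH consumption recorded while the titrator holds the
#' digestion cell at its target pH.  Consumed titrant tracks the free fatty
#' acids released by lipase.
#'
#' @param times_s sampling times in seconds; strictly increasing, first 0.
#' @param volumes_l cumulative consumed NaOH volume in litres; non-negative,
#'   non-decreasing, starting at 0.
#' @param molarity titrant molarity in mol/L.
#' @param target_ph pH held by the titrator (default 8.1).
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(times_s, volumes_l, molarity, target_ph = 8.1) {
  times_s <- as.numeric(times_s)
  volumes_l <- as.numeric(volumes_l)
  if (length(times_s) != length(volumes_l) || length(times_s) < 1L)
    stop("'times_s' and 'volumes_l' must have equal positive length",
         call. = FALSE)
  if (times_s[1L] != 0 || any(diff(times_s) <= 0))
    stop("'times_s' must be strictly increasing and start at 0",
         call. = FALSE)
  if (volumes_l[1L] != 0 || any(volumes_l < 0) || any(diff(volumes_l) < 0))
    stop("'volumes_l' must be non-negative, non-decreasing and start at 0",
         call. = FALSE)
  if (!is.numeric(molarity) || molarity <= 0)
    stop("'molarity' must be > 0", call. = FALSE)
  structure(list(times_s = times_s, volumes_l = volumes_l,
                 molarity = molarity, target_ph = target_ph),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "<titration_series> %d samples over %.0f s, %.3g M NaOH, pH %.1f, final %.3f mL\n",
    length(x$times_s), max(x$times_s), x$molarity, x$target_ph,
    1000 * x$volumes_l[length(x$volumes_l)]))
  invisible(x)
}

#' Construct a digestion specification
#'
#' The constants of one pH-stat run needed to convert titrant volume into a
#' released-FFA percentage.
#'
#' @param oil_mass_g mass of the oil sample in the cell (g).
#' @param oil_molar_mass mean molar mass of the oil (g/mol), e.g. from
#'   [mean_oil_molar_mass()].
#' @param total_volume_ml total digestion-fluid volume (mL; 36 for the
#'   standard cell).
#' @return an object of class `digestion_spec`.
#' @export
digestion_spec <- function(oil_mass_g, oil_molar_mass, total_volume_ml = 36) {
  vals <- c(oil_mass_g, oil_molar_mass, total_volume_ml)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0))
    stop("oil mass, molar mass and total volume must all be > 0",
         call. = FALSE)
  structure(list(oil_mass_g = oil_mass_g, oil_molar_mass = oil_molar_mass,
                 total_volume_ml = total_volume_ml),
            class = "digestion_spec")
}

#' Released free-fatty-acid percentage over time
#'
#' Converts the cumulative titrant volume into the percentage of titratable
#' fatty acids released:
#' \deqn{FFA(\%) = \frac{V_{NaOH}(t) \, m_{NaOH}}{(w_{lipid}/M_{lipid}) \times 2} \times 100}
#' The factor 2 reflects sn-1,3-specific pancreatic lipase, which liberates
#' two of the three fatty acids per TAG.  Values above 100% are possible
#' (over-titration, DAG hydrolysis) and are reported with a warning rather
#' than truncated.
#'
#' @param ts a [titration_series].
#' @param spec a [digestion_spec].
#' @param fatty_acids_per_tag titratable fatty acids per TAG molecule
#'   (default 2; advanced use only).
#' @return a data frame with columns `time_s` and `ffa_percent`.
#' @examples
#' ts <- titration_series(c(0, 300, 600), c(0, 6.825e-3, 1.365e-2), 0.05)
#' ffa_release_percent(ts, digestion_spec(0.300, 879.4))
#' @export
ffa_release_percent <- function(ts, spec, fatty_acids_per_tag = 2) {
  stopifnot(inherits(ts, "titration_series"), inherits(spec, "digestion_spec"))
  if (fatty_acids_per_tag <= 0)
    stop("'fatty_acids_per_tag' must be > 0", call. = FALSE)
  denom <- spec$oil_mass_g / spec$oil_molar_mass * fatty_acids_per_tag
  ffa <- ts$volumes_l * ts$molarity / denom * 100
  if (any(ffa > 100))
    warning(sprintf("FFA release exceeds 100%% (max %.1f%%)", max(ffa)),
            call. = FALSE)
  data.frame(time_s = ts$times_s, ffa_percent = ffa)
}

#' Initial lipolysis rate from the first minute of titration
#'
#' The micromoles of fatty acid released during the first 60 s (cumulative
#' titrant volume linearly interpolated at 60 s when not sampled exactly),
#' expressed as a concentration increase per second:
#' \deqn{rate\,(mM/s) = \frac{FFA\,(\mu mol\ in\ 60\,s)}{V_{total}\,(mL)} / 60}
#'
#' @param ts a [titration_series] spanning at least 60 s.
#' @param spec a [digestion_spec] (supplies the total digestion volume).
#' @return initial rate in mM/s.
#' @examples
#' ts <- titration_series(c(0, 120), c(0, 2 * 289.4e-6 / 0.05), 0.05)
#' initial_rate(ts, digestion_spec(0.300, 879.4, 36))  # ~0.134 mM/s
#' @export
initial_rate <- function(ts, spec) {
  stopifnot(inherits(ts, "titration_series"), inherits(spec, "digestion_spec"))
  if (max(ts$times_s) < 60)
    stop("titration series must span at least 60 s to define the initial rate",
         call. = FALSE)
  v60 <- stats::approx(ts$times_s, ts$volumes_l, xout = 60)$y
  umol <- v60 * ts$molarity * 1e6
  umol / spec$total_volume_ml / 60
}
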