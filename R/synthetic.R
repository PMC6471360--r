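# Synthetic-data generators: seeded forward models of every analysis stage,
# so each stage can be checked end to end against a known ground truth.
# Each generator is the exact inverse of its analysis operation at zero
# noise: analyze(generate(truth)) == truth.

#' Construct a simulation configuration
#'
#' Bundles the ground truth and nuisance parameters from which every
#' synthetic input type is generated.  See [default_simulation_config()] for
#' a configuration pre-loaded with the study design points.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param oil an [oil_composition].
#' @param kinetics list `(f_max, k)`: first-order FFA release
#'   \eqn{FFA(t) = F_{max}(1 - e^{-kt})} with `f_max` in % and `k` in
#'   1/min.
#' @param targets named list of quantification targets; each element is a
#'   list `(curve, rate, fraction)` with a [power_calibration], the true
#'   lipolysis rate (%) and the mass fraction of the starting oil at 0 min.
#' @param digestion a [digestion_spec] for the pH-stat stage.
#' @param molarity NaOH molarity (mol/L).
#' @param noise_cv multiplicative coefficient of variation applied to all
#'   ELSD areas (lognormal; 0 = noise-free).
#' @param masses list with `m_a_mg` and `m_lp_mg`, each length 2 (0 min,
#'   t min), plus `c_s_mg_per_ml`, `c_is_mg_per_ml`, `is_area` and
#'   `normalize_to`.
#' @param time_point_min digestion time of the second peak table (min).
#' @param titration list `(duration_s, step_s)` for the titration grid.
#' @param psd list `(median_um, gsd, n_particles, n_bins)` for the droplet
#'   size distribution (lognormal diameters).
#' @param scan list `(creaming_rate, clarification_rate, duration_min,
#'   interval_min, height_mm, height_step_mm, noise_sd)`; rates in %/h.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed, oil, kinetics, targets, digestion,
                              molarity = 0.05, noise_cv = 0,
                              masses = list(m_a_mg = c(150, 150),
                                            m_lp_mg = c(150, 140),
                                            c_s_mg_per_ml = 1,
                                            c_is_mg_per_ml = 0.05,
                                            is_area = 4000,
                                            normalize_to = 150),
                              time_point_min = 30,
                              titration = list(duration_s = 600, step_s = 1),
                              psd = list(median_um = 0.3, gsd = 1.3,
                                         n_particles = 20000, n_bins = 60),
                              scan = list(creaming_rate = 7.06,
                                          clarification_rate = -2.12,
                                          duration_min = 180,
                                          interval_min = 5, height_mm = 24,
                                          height_step_mm = 0.5,
                                          noise_sd = 0)) {
  stopifnot(inherits(oil, "oil_composition"),
            inherits(digestion, "digestion_spec"))
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer", call. = FALSE)
  if (!is.numeric(noise_cv) || noise_cv < 0)
    stop("'noise_cv' must be >= 0", call. = FALSE)
  if (kinetics$k <= 0 || kinetics$f_max <= 0)
    stop("kinetics must have f_max > 0 and k > 0", call. = FALSE)
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    if (!inherits(tg$curve, "power_calibration"))
      stop(sprintf("target '%s' has no calibration curve", nm), call. = FALSE)
    if (tg$rate < 0 || tg$rate > 100)
      stop(sprintf("target '%s' rate must be in [0, 100]", nm),
           call. = FALSE)
  }
  structure(list(seed = seed, oil = oil, kinetics = kinetics,
                 targets = targets, digestion = digestion,
                 molarity = molarity, noise_cv = noise_cv, masses = masses,
                 time_point_min = time_point_min, titration = titration,
                 psd = psd, scan = scan),
            class = "simulation_config")
}

# Solve first-order release kinetics F(t) = f_max (1 - exp(-k t)) from two
# anchors: the 1-min release x1 and the 10-min release x10 (both %).
solve_first_order_kinetics <- function(x1, x10) {
  stopifnot(x1 > 0, x10 > x1, 10 * x1 > x10)
  g <- function(k) x1 * (1 - exp(-10 * k)) - x10 * (1 - exp(-k))
  k <- stats::uniroot(g, c(1e-6, 20), tol = 1e-12)$root
  list(f_max = x1 / (1 - exp(-k)), k = k)
}

# Study design points: total-oil and per-species power calibrations
# (coefficient a, exponent b, reported R^2) and true lipolysis rates (%),
# plus pH-stat anchors (initial rate mM/s, 10-min FFA release %) and
# emulsion metrics (d32 um, creaming / clarification dBS slopes %/h).
.design_points <- list(
  SBO = list(cal = c(a = 0.4568, b = 1.4353, r2 = 0.996), rate = 80.4,
             rate0 = 0.134, ffa10 = 93.8, d32 = 0.26,
             creaming = 4.29, clarification = -0.90,
             species = list(
               "L-L-L" = list(a = 67.518, b = 1.4217, r2 = 0.9995,
                              rate = 77.1, fraction = 0.245),
               "L-L-O" = list(a = 77.223, b = 1.4606, r2 = 0.9995,
                              rate = 75.5, fraction = 0.214))),
  PGO = list(cal = c(a = 0.9241, b = 1.4759, r2 = 0.952), rate = 66.5,
             rate0 = 0.094, ffa10 = 71.8, d32 = 0.31,
             creaming = 7.06, clarification = -2.12,
             species = list(
               "CLn-CLn-CLn" = list(a = 443.75, b = 1.336, r2 = 0.9445,
                                    rate = 65.3, fraction = 0.678),
               "CLn-CLn-P" = list(a = 169.09, b = 1.801, r2 = 0.968,
                                  rate = 70.3, fraction = 0.121))),
  PHY = list(cal = c(a = 0.32, b = 1.5251, r2 = 0.994), rate = 74.8,
             rate0 = 0.118, ffa10 = 85.4, d32 = 0.30,
             creaming = 5.5, clarification = -1.39, species = NULL),
  IO  = list(cal = c(a = 0.4538, b = 1.4306, r2 = 0.999), rate = 77.0,
             rate0 = 0.124, ffa10 = 92.2, d32 = 0.30,
             creaming = 6.0, clarification = -1.82, species = NULL))

#' Default simulation configuration for a study oil
#'
#' Returns a [simulation_config] whose ground truth is the set of design
#' points of the four-oil digestion study: the oil-level and species-level
#' power calibrations, total lipolysis rates 80.4 / 66.5 / 74.8 / 77.0 %
#' (SBO / PGO / PHY / IO), species rates (e.g. 77.1 % for L-L-L, 65.3 % for
#' CLn-CLn-CLn), first-order FFA-release kinetics anchored at the measured
#' initial rates (0.094-0.134 mM/s) and 10-min releases (71.8-93.8 %),
#' droplet d32 of 0.26-0.31 um and the measured creaming / clarification
#' backscattering slopes.
#'
#' @param oil `"SBO"`, `"PGO"`, `"PHY"` or `"IO"`.
#' @param seed integer seed.
#' @param level `"total"` for a single aggregate TAG target (analysed with
#'   the `"total"` selector and the oil-level calibration) or `"species"`
#'   for the per-species targets (SBO and PGO only).
#' @param noise_cv multiplicative area noise CV (default 0).
#' @return a [simulation_config].
#' @examples
#' cfg <- default_simulation_config("PGO", seed = 1)
#' cfg$targets$TTGS$rate  # 66.5
#' @export
default_simulation_config <- function(oil = c("SBO", "PGO", "PHY", "IO"),
                                      seed = 1,
                                      level = c("total", "species"),
                                      noise_cv = 0) {
  oil <- match.arg(oil)
  level <- match.arg(level)
  dp <- .design_points[[oil]]
  comp <- oil_composition_fixture(oil)
  mm <- mean_oil_molar_mass(comp)
  spec <- digestion_spec(0.300, mm, 36)
  # 1-min FFA release (%) implied by the printed initial rate
  x1 <- dp$rate0 * spec$total_volume_ml * 60 * 1e-6 /
    (spec$oil_mass_g / mm * 2) * 100
  kin <- solve_first_order_kinetics(x1, dp$ffa10)
  targets <- if (level == "total") {
    list(TTGS = list(
      curve = power_calibration(dp$cal[["a"]], dp$cal[["b"]],
                                r_squared = dp$cal[["r2"]]),
      rate = dp$rate, fraction = 1))
  } else {
    if (is.null(dp$species))
      stop(sprintf("no species-level design points for %s", oil),
           call. = FALSE)
    lapply(dp$species, function(s)
      list(curve = power_calibration(s$a, s$b, r_squared = s$r2),
           rate = s$rate, fraction = s$fraction))
  }
  # lognormal with geometric sd 1.3 whose Sauter mean equals the printed d32
  gsd <- 1.3
  median_um <- dp$d32 / exp(2.5 * log(gsd)^2)
  simulation_config(
    seed = seed, oil = comp, kinetics = kin, targets = targets,
    digestion = spec, noise_cv = noise_cv,
    psd = list(median_um = median_um, gsd = gsd, n_particles = 20000,
               n_bins = 60),
    scan = list(creaming_rate = dp$creaming,
                clarification_rate = dp$clarification,
                duration_min = 180, interval_min = 5, height_mm = 24,
                height_step_mm = 0.5, noise_sd = 0))
}

#' Simulate a pH-stat titration series
#'
#' First-order FFA release \eqn{FFA(t) = F_{max}(1 - e^{-kt})} inverted
#' through the FFA-percentage formula to a cumulative NaOH volume.  The
#' series is deterministic given the configuration.
#'
#' @param cfg a [simulation_config].
#' @return a [titration_series].
#' @export
simulate_titration <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  times <- seq(0, cfg$titration$duration_s, by = cfg$titration$step_s)
  ffa <- cfg$kinetics$f_max * (1 - exp(-cfg$kinetics$k * times / 60))
  volumes <- ffa / 100 *
    (cfg$digestion$oil_mass_g / cfg$digestion$oil_molar_mass * 2) /
    cfg$molarity
  titration_series(times, volumes, cfg$molarity)
}

# one multiplicative lognormal noise draw per area, unit mean
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a pair of HPLC-ELSD peak tables
#'
#' Forward model of the quantification equations: each configured target's
#' true TAG mass at 0 min is `fraction * normalize_to` mg; at t min it is
#' reduced by the true lipolysis rate.  Masses are converted to
#' concentration ratios, pushed through each target's power calibration to
#' peak areas, and multiplied by lognormal noise with CV `noise_cv` (the IS
#' areas included).  At `noise_cv = 0` the analysis recovers every
#' configured rate exactly.
#'
#' @param cfg a [simulation_config].
#' @return list with elements `t0` and `tt`, both [peak_table]s, annotated
#'   with the target names.
#' @export
simulate_peak_tables <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  ms <- cfg$masses
  n <- length(cfg$targets)
  build <- function(tp_index, tp_min) {
    m_a <- ms$m_a_mg[tp_index]
    m_lp <- ms$m_lp_mg[tp_index]
    areas <- numeric(n)
    for (i in seq_len(n)) {
      tg <- cfg$targets[[i]]
      mass0 <- tg$fraction * ms$normalize_to
      mass <- if (tp_index == 1L) mass0 else mass0 * (1 - tg$rate / 100)
      conc_ratio <- mass * ms$c_s_mg_per_ml * m_a /
        (ms$c_is_mg_per_ml * m_lp * ms$normalize_to)
      areas[i] <- predict(tg$curve, conc_ratio) * ms$is_area
    }
    areas <- areas * rlnorm_cv(n, cfg$noise_cv)
    is_area <- ms$is_area * rlnorm_cv(1, cfg$noise_cv)
    peak_table(
      sample_id = cfg$oil$name, time_point_min = tp_min,
      peaks = data.frame(retention_min = 10 + 5 * seq_len(n) - 5,
                         area = areas,
                         annotation = names(cfg$targets)),
      is_area = is_area, m_lp_mg = m_lp, m_a_mg = m_a,
      c_s_mg_per_ml = ms$c_s_mg_per_ml, c_is_mg_per_ml = ms$c_is_mg_per_ml)
  }
  list(t0 = build(1L, 0), tt = build(2L, cfg$time_point_min))
}

#' Simulate a particle-size distribution
#'
#' Lognormal droplet diameters, binned.  A zero-width distribution
#' (`gsd = 1`) collapses to a single bin at the median.
#'
#' @param cfg a [simulation_config].
#' @return a [particle_size_distribution].
#' @export
simulate_psd <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 1L)
  p <- cfg$psd
  if (p$gsd <= 1) {
    return(particle_size_distribution(p$median_um, p$n_particles))
  }
  d <- stats::rlnorm(p$n_particles, meanlog = log(p$median_um),
                     sdlog = log(p$gsd))
  h <- graphics::hist(d, breaks = p$n_bins, plot = FALSE)
  particle_size_distribution(h$mids, h$counts)
}

#' Simulate a backscattering scan
#'
#' Linear delta-BS ramps at the configured creaming and clarification
#' slopes inside their zones (top 3 mm, bottom 5 mm), zero in between, plus
#' optional white noise.
#'
#' @param cfg a [simulation_config].
#' @return a [backscatter_scan].
#' @export
simulate_scan <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed + 2L)
  s <- cfg$scan
  times <- seq(0, s$duration_min, by = s$interval_min)
  heights <- seq(0, s$height_mm, by = s$height_step_mm)
  slope_per_min <- rep(0, length(heights))
  slope_per_min[heights >= max(heights) - 3] <- s$creaming_rate / 60
  slope_per_min[heights <= min(heights) + 5] <- s$clarification_rate / 60
  dbs <- outer(times, slope_per_min)
  if (s$noise_sd > 0)
    dbs <- dbs + matrix(stats::rnorm(length(dbs), sd = s$noise_sd),
                        nrow = length(times))
  backscatter_scan(times, heights, dbs)
}
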