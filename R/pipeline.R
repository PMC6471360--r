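#' Run the full quantification pipeline from a configuration
#'
#' Executes the requested stages in order and collects every result in a
#' single run report together with provenance (input-file MD5 hashes, the
#' configuration, package version).  Stages are independent; any subset may
#' be configured:
#'
#' \describe{
#'   \item{`phstat`}{`list(log, molarity, oil_mass_g, oil_molar_mass,
#'     total_volume_ml)` -- FFA release curve and initial rate from a
#'     titration log.}
#'   \item{`quantify`}{`list(t0, tt, calibration, selector, per_species)` --
#'     total (and optionally per-species) lipolysis rates from two peak
#'     tables and a calibration JSON.  `selector` defaults to `"total"`,
#'     quantified with the curve named `"TTGS"` (or the single curve in the
#'     file); `per_species = TRUE` additionally applies every species curve.}
#'   \item{`emulsion`}{`list(psd, scan)` -- Sauter mean diameter and the
#'     creaming / clarification backscattering rates.}
#' }
#'
#' @param config a named list with the stage sections above, or the path of
#'   a JSON file containing it.
#' @return an object of class `run_report`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  inputs <- character()
  track <- function(path, stage) {
    if (!is.character(path) || !file.exists(path))
      stop(sprintf("%s stage: input file not found: %s", stage, path),
           call. = FALSE)
    inputs[[path]] <<- unname(tools::md5sum(path))
    path
  }
  results <- list()

  if (!is.null(config$phstat)) {
    pc <- config$phstat
    ts <- read_titration_log(track(pc$log, "phstat"), molarity = pc$molarity)
    spec <- digestion_spec(pc$oil_mass_g, pc$oil_molar_mass,
                           if (is.null(pc$total_volume_ml)) 36
                           else pc$total_volume_ml)
    curve <- ffa_release_percent(ts, spec)
    results$phstat <- list(
      ffa_curve = curve,
      ffa_final_percent = curve$ffa_percent[nrow(curve)],
      initial_rate_mm_per_s = initial_rate(ts, spec))
  }

  if (!is.null(config$quantify)) {
    qc <- config$quantify
    obs0 <- read_peak_table(track(qc$t0, "quantify"))
    obst <- read_peak_table(track(qc$tt, "quantify"))
    curves <- read_calibration_json(track(qc$calibration, "quantify"))
    total_curve <- if ("TTGS" %in% names(curves)) curves[["TTGS"]]
                   else if (length(curves) == 1L) curves[[1L]] else NULL
    res <- list()
    if (!is.null(total_curve)) {
      tot <- lipolysis_rate(obs0, obst, total_curve, selector = "total")
      res$total_rate_percent <- as.numeric(tot)
      res$total_rate_quality <- attr(tot, "quality")
    }
    if (isTRUE(qc$per_species)) {
      sp_curves <- curves[setdiff(names(curves), "TTGS")]
      if (length(sp_curves) == 0L)
        stop("quantify stage: per_species requested but the calibration file has no species curves",
             call. = FALSE)
      res$species_rates_percent <-
        as.list(species_lipolysis_rates(obs0, obst, sp_curves,
                                        species = names(sp_curves)))
    }
    if (length(res) == 0L)
      stop("quantify stage: calibration file has no 'TTGS' curve and per_species is not set",
           call. = FALSE)
    results$quantify <- res
  }

  if (!is.null(config$emulsion)) {
    ec <- config$emulsion
    res <- list()
    if (!is.null(ec$psd))
      res$d32_um <- sauter_mean_diameter(read_psd(track(ec$psd, "emulsion")))
    if (!is.null(ec$scan)) {
      scan <- read_scan(track(ec$scan, "emulsion"))
      res$creaming_rate_percent_per_h <- backscatter_rate(scan, "creaming")
      res$clarification_rate_percent_per_h <-
        backscatter_rate(scan, "clarification")
    }
    results$emulsion <- res
  }

  structure(list(
    version = as.character(utils::packageVersion("lipolyzer")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    inputs = as.list(inputs),
    results = results), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> lipolyzer %s, %s; %d input file(s)\n",
              x$version, x$created, length(x$inputs)))
  r <- x$results
  if (!is.null(r$phstat))
    cat(sprintf("  pH-stat : final FFA release %.1f%%, initial rate %.3f mM/s\n",
                r$phstat$ffa_final_percent, r$phstat$initial_rate_mm_per_s))
  if (!is.null(r$quantify)) {
    if (!is.null(r$quantify$total_rate_percent))
      cat(sprintf("  ELSD    : total lipolysis rate %.1f%% (%s)\n",
                  r$quantify$total_rate_percent, r$quantify$total_rate_quality))
    for (sp in names(r$quantify$species_rates_percent))
      cat(sprintf("            %-12s %.1f%%\n", sp,
                  r$quantify$species_rates_percent[[sp]]))
  }
  if (!is.null(r$emulsion)) {
    if (!is.null(r$emulsion$d32_um))
      cat(sprintf("  emulsion: d32 = %.3f um\n", r$emulsion$d32_um))
    if (!is.null(r$emulsion$creaming_rate_percent_per_h))
      cat(sprintf("            creaming %.2f %%/h, clarification %.2f %%/h\n",
                  r$emulsion$creaming_rate_percent_per_h,
                  r$emulsion$clarification_rate_percent_per_h))
  }
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report a `run_report` from [run_pipeline()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
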