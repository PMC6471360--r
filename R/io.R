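# Delimited-text readers and writers for every input type.  All files are
# comma-delimited UTF-8 with a header row; per-observation scalars ride in
# leading "# key: value" comment lines.

read_csv_body <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

check_numeric_column <- function(df, cols, path) {
  for (col in cols) {
    if (!col %in% names(df))
      stop(sprintf("%s: missing column '%s'", path, col), call. = FALSE)
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0L)
      stop(sprintf("%s: non-numeric value in column '%s', row %d ('%s')",
                   path, col, bad[1L], df[[col]][bad[1L]]), call. = FALSE)
    if (anyNA(v))
      stop(sprintf("%s: missing value in column '%s', row %d",
                   path, col, which(is.na(v))[1L]), call. = FALSE)
    df[[col]] <- v
  }
  df
}

#' Read / write a fatty-acid composition table
#'
#' Columns: `code`, `label`, `carbons`, `double_bonds`, `conjugated`,
#' `area_percent`.  A row with code `Unknown` carries the unattributed area
#' percentage.
#'
#' @param path file path.
#' @param comp an [oil_composition].
#' @param name oil name for the read composition; defaults to the file name.
#' @return `read_composition()` returns an [oil_composition];
#'   `write_composition()` returns `path` invisibly.
#' @export
read_composition <- function(path, name = NULL) {
  df <- read_csv_body(path)
  need <- c("code", "label", "carbons", "double_bonds", "conjugated",
            "area_percent")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: composition table needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  unk <- df$code == "Unknown"
  unknown_percent <- if (any(unk)) sum(as.numeric(df$area_percent[unk])) else 0
  df <- df[!unk, , drop = FALSE]
  df <- check_numeric_column(df, c("carbons", "double_bonds", "area_percent"),
                             path)
  acids <- lapply(seq_len(nrow(df)), function(i)
    fatty_acid(df$code[i], df$label[i], df$carbons[i], df$double_bonds[i],
               conjugated = as.logical(df$conjugated[i])))
  oil_composition(if (is.null(name)) basename(path) else name,
                  acids, df$area_percent, unknown_percent)
}

#' @rdname read_composition
#' @export
write_composition <- function(comp, path) {
  stopifnot(inherits(comp, "oil_composition"))
  df <- data.frame(
    code = vapply(comp$acids, `[[`, "", "code"),
    label = names(comp$acids),
    carbons = vapply(comp$acids, `[[`, 0L, "carbons"),
    double_bonds = vapply(comp$acids, `[[`, 0L, "double_bonds"),
    conjugated = vapply(comp$acids, `[[`, TRUE, "conjugated"),
    area_percent = unname(comp$area_percent))
  if (comp$unknown_percent > 0)
    df <- rbind(df, data.frame(code = "Unknown", label = "", carbons = NA,
                               double_bonds = NA, conjugated = NA,
                               area_percent = comp$unknown_percent))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pH-stat titration log
#'
#' Columns: `time_s`, `cumulative_volume_l`.  The titrant molarity is not
#' stored in the log; it is supplied by the caller (instrument metadata).
#'
#' @param path file path.
#' @param molarity titrant molarity (mol/L).
#' @param ts a [titration_series].
#' @param target_ph pH setpoint.
#' @return `read_titration_log()` returns a [titration_series].
#' @export
read_titration_log <- function(path, molarity, target_ph = 8.1) {
  df <- read_csv_body(path)
  df <- check_numeric_column(df, c("time_s", "cumulative_volume_l"), path)
  titration_series(df$time_s, df$cumulative_volume_l, molarity, target_ph)
}

#' @rdname read_titration_log
#' @export
write_titration_log <- function(ts, path) {
  stopifnot(inherits(ts, "titration_series"))
  utils::write.csv(data.frame(time_s = ts$times_s,
                              cumulative_volume_l = ts$volumes_l),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an HPLC-ELSD peak table
#'
#' Peak rows have columns `retention_min`, `area` and optional `annotation`;
#' the per-observation scalars (`sample_id`, `time_point_min`, `is_area`,
#' `m_lp_mg`, `m_a_mg`, `c_s_mg_per_ml`, `c_is_mg_per_ml`) are stored as
#' leading `# key: value` comment lines.
#'
#' @param path file path.
#' @param obs a [peak_table].
#' @return `read_peak_table()` returns a [peak_table].
#' @export
read_peak_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- trimws(sub(":.*$", "", kv))
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  need <- c("sample_id", "time_point_min", "is_area", "m_lp_mg", "m_a_mg")
  if (!all(need %in% names(meta)))
    stop(sprintf("%s: missing '# key: value' header(s): %s", path,
                 paste(setdiff(need, names(meta)), collapse = ", ")),
         call. = FALSE)
  df <- read_csv_body(path)
  if (!"annotation" %in% names(df)) df$annotation <- "Unknown"
  df <- check_numeric_column(df, c("retention_min", "area"), path)
  num <- function(key, default = NULL) {
    if (is.null(meta[[key]])) return(default)
    v <- suppressWarnings(as.numeric(meta[[key]]))
    if (is.na(v))
      stop(sprintf("%s: header '%s' is not numeric ('%s')", path, key,
                   meta[[key]]), call. = FALSE)
    v
  }
  peak_table(sample_id = meta$sample_id,
             time_point_min = num("time_point_min"),
             peaks = df[, c("retention_min", "area", "annotation")],
             is_area = num("is_area"), m_lp_mg = num("m_lp_mg"),
             m_a_mg = num("m_a_mg"),
             c_s_mg_per_ml = num("c_s_mg_per_ml", 1),
             c_is_mg_per_ml = num("c_is_mg_per_ml", 0.05))
}

#' @rdname read_peak_table
#' @export
write_peak_table <- function(obs, path) {
  stopifnot(inherits(obs, "peak_table"))
  meta <- c(sample_id = obs$sample_id,
            time_point_min = obs$time_point_min,
            is_area = obs$is_area, m_lp_mg = obs$m_lp_mg,
            m_a_mg = obs$m_a_mg, c_s_mg_per_ml = obs$c_s_mg_per_ml,
            c_is_mg_per_ml = obs$c_is_mg_per_ml)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(obs$peaks[, c("retention_min", "area", "annotation")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a particle-size distribution
#'
#' Columns: `diameter_um`, `count`.
#'
#' @param path file path.
#' @param psd a [particle_size_distribution].
#' @return `read_psd()` returns a [particle_size_distribution].
#' @export
read_psd <- function(path) {
  df <- read_csv_body(path)
  df <- check_numeric_column(df, c("diameter_um", "count"), path)
  particle_size_distribution(df$diameter_um, df$count)
}

#' @rdname read_psd
#' @export
write_psd <- function(psd, path) {
  stopifnot(inherits(psd, "particle_size_distribution"))
  utils::write.csv(data.frame(diameter_um = psd$diameter_um,
                              count = psd$count),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a backscattering scan (long format)
#'
#' Columns: `time_min`, `height_mm`, `dbs_percent`; one row per
#' (time, height) cell.
#'
#' @param path file path.
#' @param scan a [backscatter_scan].
#' @return `read_scan()` returns a [backscatter_scan].
#' @export
read_scan <- function(path) {
  df <- read_csv_body(path)
  df <- check_numeric_column(df, c("time_min", "height_mm", "dbs_percent"),
                             path)
  times <- sort(unique(df$time_min))
  heights <- sort(unique(df$height_mm))
  dbs <- matrix(NA_real_, length(times), length(heights))
  dbs[cbind(match(df$time_min, times), match(df$height_mm, heights))] <-
    df$dbs_percent
  if (anyNA(dbs))
    stop(sprintf("%s: scan grid is incomplete (missing time x height cells)",
                 path), call. = FALSE)
  backscatter_scan(times, heights, dbs)
}

#' @rdname read_scan
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "backscatter_scan"))
  grid <- expand.grid(height_mm = scan$heights_mm, time_min = scan$times_min)
  utils::write.csv(data.frame(time_min = grid$time_min,
                              height_mm = grid$height_mm,
                              dbs_percent = as.vector(t(scan$dbs))),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write calibration curves as JSON
#'
#' The JSON maps target names (`"TTGS"`, species labels, ...) to objects
#' with fields `a`, `b` and optional `r_squared`.
#'
#' @param path file path.
#' @param curves named list of [power_calibration]s.
#' @return `read_calibration_json()` returns a named list of
#'   [power_calibration]s.
#' @export
read_calibration_json <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(x)
    power_calibration(x$a, x$b,
                      r_squared = if (is.null(x$r_squared)) NA_real_
                                  else x$r_squared))
}

#' @rdname read_calibration_json
#' @export
write_calibration_json <- function(curves, path) {
  stopifnot(all(vapply(curves, inherits, TRUE, "power_calibration")))
  jsonlite::write_json(
    lapply(curves, function(cv)
      list(a = cv$a, b = cv$b, r_squared = cv$r_squared)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write every simulated input file for a configuration
#'
#' Generates the titration log, the 0-min and t-min peak tables, the
#' calibration JSON, the particle-size distribution, the backscattering
#' scan and the composition table, in the formats the analysis functions
#' read.
#'
#' @param cfg a [simulation_config].
#' @param dir output directory (created if needed).
#' @return named character vector of the files written.
#' @export
simulate_to_files <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  tabs <- simulate_peak_tables(cfg)
  write_titration_log(simulate_titration(cfg), p("titration.csv"))
  write_peak_table(tabs$t0, p("peaks_t0.csv"))
  write_peak_table(tabs$tt, p("peaks_tt.csv"))
  write_calibration_json(lapply(cfg$targets, `[[`, "curve"),
                         p("calibration.json"))
  write_psd(simulate_psd(cfg), p("psd.csv"))
  write_scan(simulate_scan(cfg), p("scan.csv"))
  write_composition(cfg$oil, p("composition.csv"))
  c(titration = p("titration.csv"), peaks_t0 = p("peaks_t0.csv"),
    peaks_tt = p("peaks_tt.csv"), calibration = p("calibration.json"),
    psd = p("psd.csv"), scan = p("scan.csv"),
    composition = p("composition.csv"))
}
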