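#' Read power profiles from delimited text
#'
#' Reads radial power profiles from a CSV/TSV file in the long layout
#' exported by optical-mapping instruments: one row per (lens, repetition,
#' radius). Required columns are the radius and power; lens metadata columns
#' are optional and default to a single generic lens. The delimiter is
#' sniffed from the header line (comma or tab).
#'
#' @param path Path to a delimited text file.
#' @param dialect Named list mapping roles to column names. Defaults:
#'   `radius = "radius_mm"`, `power = "power_D"`, `family = "family"`,
#'   `add = "add"`, `distance_power = "distance_power_D"`, `rep = "rep"`.
#' @param metadata Optional named list of fallback metadata (`family`,
#'   `add_label`, `distance_power_D`, `repetition`) used when the
#'   corresponding columns are absent, e.g. loaded from a YAML sidecar.
#' @return A list of [power_profile()] objects, one per (lens, repetition).
#' @export
read_profiles <- function(path, dialect = list(), metadata = list()) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  d <- utils::modifyList(
    list(radius = "radius_mm", power = "power_D", family = "family",
         add = "add", distance_power = "distance_power_D", rep = "rep"),
    dialect)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) format_error("cannot parse '%s': %s", path, conditionMessage(e)))
  for (role in c("radius", "power")) {
    if (!d[[role]] %in% names(df))
      format_error("missing required column '%s' in %s", d[[role]], path)
  }
  get_meta <- function(col, fallback) {
    if (col %in% names(df)) df[[col]] else rep(fallback, nrow(df))
  }
  fam <- as.character(get_meta(d$family, metadata$family %||% "generic"))
  add <- as.character(get_meta(d$add, metadata$add_label %||% "Low"))
  dp  <- as.numeric(get_meta(d$distance_power, metadata$distance_power_D %||% 0))
  rp  <- as.integer(get_meta(d$rep, metadata$repetition %||% 1L))
  key <- paste(fam, add, format(dp), rp, sep = "\r")
  out <- lapply(unique(key), function(k) {
    i <- which(key == k)
    power_profile(radii_mm = as.numeric(df[[d$radius]][i]),
                  powers_D = as.numeric(df[[d$power]][i]),
                  family = fam[i[1L]], add_label = add[i[1L]],
                  distance_power_D = dp[i[1L]], repetition = rp[i[1L]])
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write power profiles to CSV
#'
#' Long-format CSV with columns `family, add, distance_power_D, rep,
#' radius_mm, power_D`; the inverse of [read_profiles()].
#'
#' @param profiles A [power_profile()] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "power_profile")) profiles <- list(profiles)
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(family = p$family, add = p$add_label,
               distance_power_D = p$distance_power_D, rep = p$repetition,
               radius_mm = p$radii_mm, power_D = p$powers_D,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write / read a through-focus curve
#'
#' A [tf_curve()] is stored as a two-column CSV (`focus_D,value`) with a JSON
#' metadata sidecar (`<path>.json`) carrying the metric kind, pupil diameter
#' and, when available, the optics configuration (wavelength, grid, CSF
#' constants) the curve was computed with.
#'
#' @param tf A [tf_curve()].
#' @param path CSV output path.
#' @param cfg Optional [optics_config()] recorded in the sidecar.
#' @return `path` invisibly (`write_tfcurve`); a [tf_curve()]
#'   (`read_tfcurve`).
#' @export
write_tfcurve <- function(tf, path, cfg = NULL) {
  stopifnot(inherits(tf, "tf_curve"))
  utils::write.csv(data.frame(focus_D = tf$focus_D, value = tf$values),
                   path, row.names = FALSE, quote = FALSE)
  meta <- list(metric_kind = tf$metric_kind, pupil_diameter_mm = tf$pupil_diameter_mm)
  if (!is.null(cfg)) {
    meta$wavelength_nm <- cfg$wavelength_nm
    meta$grid_n <- cfg$grid_n
    meta$pad_factor <- cfg$pad_factor
    meta$max_freq_cpd <- cfg$max_freq_cpd
    meta$csf_params <- cfg$csf_params
  }
  write_sidecar(meta, path)
  invisible(path)
}

#' @rdname write_tfcurve
#' @export
read_tfcurve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("focus_D", "value") %in% names(df)))
    format_error("not a TF-curve file (need focus_D,value columns): %s", path)
  meta <- read_sidecar(path)
  tf_curve(df$focus_D, df$value,
           metric_kind = meta$metric_kind %||% "VS",
           pupil_diameter_mm = meta$pupil_diameter_mm %||% NA_real_)
}

#' Write / read a temporal-multiplexing program
#'
#' A [temporal_program()] is stored as CSV (`focus_D,coefficient`) with a
#' JSON sidecar for fit metadata (pupil, fit range, achieved RMSE).
#'
#' @param prog A [temporal_program()].
#' @param path CSV output path.
#' @param meta Optional named list merged into the sidecar.
#' @return `path` invisibly (`write_program`); a [temporal_program()]
#'   (`read_program`).
#' @export
write_program <- function(prog, path, meta = list()) {
  stopifnot(inherits(prog, "temporal_program"))
  utils::write.csv(data.frame(focus_D = prog$focus_steps_D,
                              coefficient = prog$coefficients),
                   path, row.names = FALSE, quote = FALSE)
  fit <- attr(prog, "fit")
  if (!is.null(fit)) meta <- utils::modifyList(fit, meta)
  write_sidecar(meta, path)
  invisible(path)
}

#' @rdname write_program
#' @export
read_program <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("focus_D", "coefficient") %in% names(df)))
    format_error("not a temporal-program file (need focus_D,coefficient): %s", path)
  temporal_program(df$focus_D, df$coefficient)
}

#' Write a design profile
#'
#' CSV (`radius_mm,rel_power_D`) plus a JSON sidecar with the design labels.
#'
#' @param design A [design_profile()].
#' @param path CSV output path.
#' @return `path` invisibly; `read_design` returns a [design_profile()].
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_profile"))
  utils::write.csv(data.frame(radius_mm = design$radii_mm,
                              rel_power_D = design$rel_powers_D),
                   path, row.names = FALSE, quote = FALSE)
  write_sidecar(list(family = design$family, add_label = design$add_label,
                     n_distance_powers = design$n_distance_powers), path)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("radius_mm", "rel_power_D") %in% names(df)))
    format_error("not a design-profile file (need radius_mm,rel_power_D): %s", path)
  meta <- read_sidecar(path)
  design_profile(df$radius_mm, df$rel_power_D,
                 family = meta$family %||% "generic",
                 add_label = meta$add_label %||% "Low",
                 n_distance_powers = meta$n_distance_powers %||% 1L)
}
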