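#' Pipeline run configuration
#'
#' Bundles the optics configuration, temporal-fit settings and I/O options
#' of a full pipeline run. Serializable to and from a single YAML document;
#' unknown keys are rejected to catch typos.
#'
#' @param optics An [optics_config()].
#' @param fit List with `fit_range_D`, `step_span_D` and `seed`.
#' @param io List with `out_dir` (output directory).
#' @param log_level One of `"quiet"`, `"info"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(optics = optics_config(),
                       fit = list(fit_range_D = c(-1, 4),
                                  step_span_D = c(-0.5, 4), seed = 1L),
                       io = list(out_dir = "mclsim-out"),
                       log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  stopifnot(inherits(optics, "optics_config"))
  fit <- utils::modifyList(list(fit_range_D = c(-1, 4),
                                step_span_D = c(-0.5, 4), seed = 1L), fit)
  io <- utils::modifyList(list(out_dir = "mclsim-out"), io)
  structure(list(optics = optics, fit = fit, io = io, log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML document with (optional) top-level keys
#'   `optics`, `fit`, `io`, `log_level`; unknown keys at the top or optics
#'   level raise an error.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  known <- c("optics", "fit", "io", "log_level")
  extra <- setdiff(names(doc), known)
  if (length(extra) > 0L)
    format_error("unknown configuration key(s): %s", paste(extra, collapse = ", "))
  opt_args <- doc$optics %||% list()
  extra_opt <- setdiff(names(opt_args), names(formals(optics_config)))
  if (length(extra_opt) > 0L)
    format_error("unknown optics key(s): %s", paste(extra_opt, collapse = ", "))
  run_config(optics = do.call(optics_config, opt_args),
             fit = doc$fit %||% list(),
             io = doc$io %||% list(),
             log_level = doc$log_level %||% "info")
}

pipeline_log <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info")) message(sprintf(fmt, ...))
}

#' Run the full simulation pipeline
#'
#' Executes the complete chain on a set of measured power-profile files:
#' smoothing (window 5) and repetition averaging per lens, distance-power
#' subtraction, design-level averaging across distance powers, through-focus
#' Visual Strehl per configured pupil diameter, temporal-program fitting,
#' program simulation and bench validation. All artifacts (design profiles,
#' TF-VS curves, programs, bench reports) are written under the configured
#' output directory together with a machine-readable run manifest listing
#' every output file with its MD5 checksum.
#'
#' @param profile_files Character vector of profile CSV paths (see
#'   [read_profiles()]).
#' @param cfg A [run_config()].
#' @return Invisibly, a list with one entry per design, each containing the
#'   `design_profile`, and per pupil the target `tf_curve`, fitted
#'   `temporal_program`, simulated `tf_curve` and `bench_report`; plus the
#'   manifest.
#' @export
run_pipeline <- function(profile_files, cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  if (length(profile_files) == 0L)
    validation_error("no input profile files given")
  profiles <- unlist(lapply(profile_files, read_profiles), recursive = FALSE)
  if (length(profiles) == 0L) validation_error("no profiles parsed from input")

  out_dir <- cfg$io$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, name, ...) {
    p <- file.path(out_dir, name)
    writer(obj, p, ...)
    written <<- c(written, p, if (file.exists(sidecar_path(p))) sidecar_path(p))
    p
  }

  # per-lens: smooth each repetition, average, subtract distance power
  lens_key <- vapply(profiles, function(p)
    paste(p$family, p$add_label, format(p$distance_power_D), sep = "\r"), "")
  rel_by_lens <- lapply(split(profiles, lens_key), function(reps) {
    relative_profile(average_repetitions(lapply(reps, smooth_profile)))
  })

  # per-design: average relative profiles across distance powers
  design_key <- vapply(rel_by_lens, function(p)
    paste(p$family, p$add_label, sep = "\r"), "")
  designs <- lapply(split(rel_by_lens, design_key),
                    function(ps) average_design(unname(ps)))

  results <- list()
  for (dkey in names(designs)) {
    design <- designs[[dkey]]
    slug <- gsub("[^A-Za-z0-9._-]+", "_",
                 paste(design$family, design$add_label, sep = "_"))
    pipeline_log(cfg, "design %s/%s (%d distance powers)",
                 design$family, design$add_label, design$n_distance_powers)
    emit(write_design, design, sprintf("%s_design.csv", slug))
    per_pupil <- list()
    for (pd in cfg$optics$pupil_diameters_mm) {
      target <- tf_vs(design, pd, cfg$optics)
      prog <- fit_temporal_coefficients(
        target, pd, cfg$optics,
        fit_range_D = cfg$fit$fit_range_D,
        step_span_D = cfg$fit$step_span_D,
        seed = cfg$fit$seed)
      sim <- program_tf_vs(prog, pd, cfg$optics)
      bench <- validate_bench(target, sim, cfg$fit$fit_range_D)
      pipeline_log(cfg, "  pupil %.1f mm: RMSE %.4f, peak shift %.3f D (%s)",
                   pd, bench$rmse, bench$peak_shift_D,
                   if (bench$passed) "pass" else "FAIL")
      tag <- sprintf("%s_p%.1fmm", slug, pd)
      emit(write_tfcurve, target, sprintf("%s_tfvs.csv", tag), cfg = cfg$optics)
      emit(write_program, prog, sprintf("%s_program.csv", tag))
      emit(write_tfcurve, sim, sprintf("%s_tfvs_sim.csv", tag), cfg = cfg$optics)
      bp <- file.path(out_dir, sprintf("%s_bench.json", tag))
      jsonlite::write_json(unclass(bench), bp, auto_unbox = TRUE, digits = NA)
      written <- c(written, bp)
      per_pupil[[sprintf("%.1f", pd)]] <-
        list(target = target, program = prog, simulated = sim, bench = bench)
    }
    results[[dkey]] <- list(design = design, pupils = per_pupil)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mclsim")),
    inputs = lapply(profile_files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))),
    config = list(
      wavelength_nm = cfg$optics$wavelength_nm, grid_n = cfg$optics$grid_n,
      pad_factor = cfg$optics$pad_factor,
      focus_grid_D = range(cfg$optics$focus_grid_D),
      pupil_diameters_mm = cfg$optics$pupil_diameters_mm,
      max_freq_cpd = cfg$optics$max_freq_cpd,
      csf_params = cfg$optics$csf_params,
      fit = cfg$fit[c("fit_range_D", "step_span_D", "seed")]),
    outputs = lapply(sort(unique(written)), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
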