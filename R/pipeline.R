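#' Pipeline configuration
#'
#' Bundles a [study_config()] with the analysis settings of the resonance and
#' statistics stages. Validated on construction; [read_pipeline_config()]
#' applies the same validation to configurations loaded from JSON (the schema
#' shipped at `inst/schema/pipeline-config.json` documents the file layout).
#'
#' @param study a [study_config()].
#' @param n_points resonance-curve grid size per record.
#' @param window_cycles RMS envelope window, in periods of the local
#'   frequency.
#' @param alpha per-comparison significance level of the statistics stage.
#' @param adjust `"none"` or `"holm"` (see [run_comparisons()]).
#' @param contrast_plan optional explicit plan (see
#'   [default_contrast_plan()]); `NULL` derives it from the data.
#' @param seed integer seed for the simulation stage (overrides the study
#'   seed so one flag reseeds the whole pipeline).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(study = study_config(), n_points = 201,
                            window_cycles = 3, alpha = 0.05,
                            adjust = c("none", "holm"), contrast_plan = NULL,
                            seed = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(study, "study_config"))
  if (!is.null(seed)) study$seed <- as.integer(seed)
  if (n_points < 20L) stop("n_points must be at least 20")
  if (window_cycles <= 0) stop("window_cycles must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(contrast_plan)) {
    need <- c("type", "groupA", "stageA", "groupB", "stageB")
    if (!all(need %in% names(contrast_plan)))
      stop("contrast_plan needs columns: ", paste(need, collapse = ", "))
    bad <- setdiff(unique(c(contrast_plan$stageA, contrast_plan$stageB)),
                   treatment_stages())
    if (length(bad))
      stop("unknown stage label(s) in contrast plan: ",
           paste(bad, collapse = ", "))
  }
  structure(list(study = study, n_points = n_points,
                 window_cycles = window_cycles, alpha = alpha,
                 adjust = adjust, contrast_plan = contrast_plan),
            class = "pipeline_config")
}

# md5 of the canonical JSON serialisation; stamped on every artifact
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE, digits = 12)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Read and validate a pipeline configuration from JSON
#'
#' Reads a JSON file with optional top-level fields `study` (group sizes,
#' stages, ring masses, mask mass, geometry, effect model, variance
#' components, sweep settings, seed) and `analysis` (`n_points`,
#' `window_cycles`, `alpha`, `adjust`, `contrast_plan`); all omitted fields
#' take the package defaults. Validation errors name the offending field.
#'
#' @param path path to the JSON configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  s <- raw$study %||% list()
  geometry <- if (is.null(s$geometry)) strip_geometry() else
    do.call(strip_geometry, s$geometry[setdiff(names(s$geometry), "S")])
  effect_model <- if (is.null(s$effect_model)) default_effect_model() else
    as.data.frame(s$effect_model, stringsAsFactors = FALSE)
  sweep_defaults <- list(r_lo = 0.6, r_hi = 1.5, rate_factor = 0.05,
                         settle_time = 2, oversample = 12)
  sw <- utils::modifyList(sweep_defaults, as.list(s$sweep %||% list()))
  study <- study_config(
    n_sham = s$n_sham %||% 3, n_pin = s$n_pin %||% 4,
    stages = s$stages %||% treatment_stages(),
    ring_masses = s$ring_masses %||% default_ring_masses(),
    mask_mass = s$mask_mass %||% 0.0015, geometry = geometry,
    effect_model = effect_model, zeta = s$zeta %||% 0.08,
    subject_sd = s$subject_sd %||% 0.10,
    f0_noise_sd = s$f0_noise_sd %||% 0.12,
    noise_sigma = s$noise_sigma %||% 0.01, sweep = sw, seed = s$seed %||% 1L)
  a <- raw$analysis %||% list()
  plan <- if (!is.null(a$contrast_plan))
    as.data.frame(a$contrast_plan, stringsAsFactors = FALSE) else NULL
  pipeline_config(study = study, n_points = a$n_points %||% 201,
                  window_cycles = a$window_cycles %||% 3,
                  alpha = a$alpha %||% 0.05, adjust = a$adjust %||% "none",
                  contrast_plan = plan)
}

fo_log <- function(level, fmt, ..., min_level = getOption("forcedosc.log_level", "info")) {
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[level]] >= ranks[[min_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

write_provenance_csv <- function(d, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# forcedosc %s config_hash=%s",
                     as.character(utils::packageVersion("forcedosc")), hash),
             con)
  write.csv(d, con, row.names = FALSE)
}

read_provenance_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a generated study to a directory
#'
#' Lays the study out as one signal file per measurement
#' (`signals/<subject>/<stage>_m<k>.tsv`, tab-separated `time_s`,
#' `excitation`, `response`), a study manifest `manifest.json` (subjects,
#' stages, per-measurement load and sweep metadata, geometry, seed, config
#' hash) and, for synthetic studies, `ground_truth.json`.
#'
#' @param study an `fo_study` generated with `signals = TRUE`.
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "fo_study"))
  if (is.null(study$records))
    stop("study carries no signal records; regenerate with signals = TRUE")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(study$config)
  ids <- names(study$records)
  for (j in seq_along(study$records)) {
    rec <- study$records[[j]]
    sub_dir <- file.path(dir, "signals", rec$metadata$subject)
    dir.create(sub_dir, recursive = TRUE, showWarnings = FALSE)
    f <- file.path(sub_dir, paste0(sub("^[^_]*_", "", ids[j]), ".tsv"))
    d <- data.frame(time_s = sprintf("%.9g", rec$time),
                    excitation = sprintf("%.9g", rec$excitation),
                    response = sprintf("%.9g", rec$response))
    write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("forcedosc")),
    config_hash = hash, seed = study$config$seed,
    geometry = unclass(study$config$geometry),
    stages = study$config$stages,
    subjects = study$subjects[, c("subject", "group")],
    measurements = cbind(study$manifest,
                         file = file.path("signals", study$manifest$subject,
                                          paste0(sub("^[^_]*_", "", ids),
                                                 ".tsv"))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  jsonlite::write_json(list(config_hash = hash,
                            ground_truth = study$ground_truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(dir)
}

read_study_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Read one oscillation record written by the pipeline
#'
#' @param path the 3-column tab-separated signal file.
#' @param sweep a [sweep_spec()] describing the record's sweep.
#' @param metadata named list attached to the record.
#' @return An `oscillation_record`.
#' @export
read_oscillation_record <- function(path, sweep, metadata = list()) {
  if (!file.exists(path)) stop("signal file not found: ", path)
  d <- read.csv(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("time_s", "excitation", "response")
  if (!all(need %in% names(d)))
    stop("signal file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  dt <- diff(d$time_s)
  if (any(dt <= 0) ||
      max(abs(dt - 1 / sweep$sampling_rate)) > 1e-4 / sweep$sampling_rate)
    stop("time base of ", path, " is not the uniform grid of its sweep")
  structure(list(time = d$time_s, excitation = d$excitation,
                 response = d$response, sweep = sweep, metadata = metadata),
            class = "oscillation_record")
}

analyze_measurements <- function(manifest, config) {
  meas <- manifest$measurements
  rows <- vector("list", nrow(meas))
  n_fail <- 0L
  for (j in seq_len(nrow(meas))) {
    m <- meas[j, ]
    spec <- sweep_spec(m$f_start, m$f_end, m$sweep_rate,
                       direction = m$direction,
                       sampling_rate = m$sampling_rate,
                       settle_time = m$settle_time)
    rec <- read_oscillation_record(file.path(manifest$dir, m$file), spec)
    feat <- tryCatch({
      curve <- extract_resonance_curve(rec, n_points = config$n_points,
                                       window_cycles = config$window_cycles)
      resonance_features(curve, sweep_rate = spec$sweep_rate)
    }, error = function(e) e)
    if (inherits(feat, "error")) {
      n_fail <- n_fail + 1L
      fo_log("debug", "measurement %s/%s/m%d failed QC: %s", m$subject,
             m$stage, m$mass_index, conditionMessage(feat))
      fd <- data.frame(f0_Hz = NA_real_, peak_amp = NA_real_,
                       bw3db_Hz = NA_real_, octave_len = NA_real_,
                       zeta = NA_real_, qc_flags = "analysis_failed",
                       stringsAsFactors = FALSE)
    } else {
      fd <- as.data.frame(feat)
      fo_log("debug", "measurement %s/%s/m%d: f0 = %.3f Hz%s", m$subject,
             m$stage, m$mass_index, fd$f0_Hz,
             if (nzchar(fd$qc_flags)) paste0(" [", fd$qc_flags, "]") else "")
    }
    rows[[j]] <- cbind(data.frame(subject = m$subject, group = m$group,
                                  stage = m$stage, mass_index = m$mass_index,
                                  stringsAsFactors = FALSE), fd)
  }
  fo_log("info", "analyzed %d records, %d QC failure(s)", nrow(meas), n_fail)
  do.call(rbind, rows)
}

#' Run the forced-oscillation pipeline
#'
#' Orchestrates the stages on a working directory: `"simulate"` generates the
#' configured synthetic study and writes its signal files, manifest and
#' ground truth; `"analyze"` reads the signal files, extracts resonance
#' features (`features.csv`) and assembles the tidy viscoelastic points table
#' (`points.csv`); `"stats"` fits the per-cell regressions and runs the
#' planned comparisons (`fits.csv`, `report.csv`, `report.json`); `"all"`
#' chains the three. All outputs carry the configuration hash; given the same
#' seed, re-running reproduces them byte for byte.
#'
#' @param config a [pipeline_config()] (or a path to a JSON configuration,
#'   which is passed through [read_pipeline_config()]).
#' @param mode one of `"all"`, `"simulate"`, `"analyze"`, `"stats"`.
#' @param out_dir working directory for all artifacts.
#' @param log_level `"debug"`, `"info"` or `"quiet"`.
#' @return Invisibly, a list with the paths of the artifacts produced and
#'   (when computed) the points table and the comparison report.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         mode = c("all", "simulate", "analyze", "stats"),
                         out_dir, log_level = "info") {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  old_opt <- options(forcedosc.log_level = log_level)
  on.exit(options(old_opt))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  out <- list(dir = out_dir, config_hash = hash)

  if (mode %in% c("all", "simulate")) {
    fo_log("info", "simulating study (seed %d)", config$study$seed)
    study <- generate_study(config$study, signals = TRUE)
    write_study(study, out_dir)
    fo_log("info", "wrote %d signal records to %s", length(study$records),
           out_dir)
    out$manifest <- file.path(out_dir, "manifest.json")
  }

  if (mode %in% c("all", "analyze")) {
    manifest <- read_study_manifest(out_dir)
    manifest$dir <- out_dir
    features <- analyze_measurements(manifest, config)
    write_provenance_csv(features, file.path(out_dir, "features.csv"), hash)
    geom <- do.call(strip_geometry,
                    manifest$geometry[setdiff(names(manifest$geometry), "S")])
    points <- assemble_points(features, geom, manifest$measurements)
    write_provenance_csv(points, file.path(out_dir, "points.csv"), hash)
    fo_log("info", "assembled %d viscoelastic points", nrow(points))
    out$features <- file.path(out_dir, "features.csv")
    out$points_file <- file.path(out_dir, "points.csv")
    out$points <- points
  }

  if (mode %in% c("all", "stats")) {
    points <- out$points %||% {
      f <- file.path(out_dir, "points.csv")
      if (!file.exists(f)) stop("points table not found: ", f,
                                " (run the analyze stage first)")
      read_provenance_csv(f)
    }
    report <- run_comparisons(points, plan = config$contrast_plan,
                              alpha = config$alpha, adjust = config$adjust)
    write_provenance_csv(report$results, file.path(out_dir, "report.csv"),
                         hash)
    if (!is.null(report$fits))
      write_provenance_csv(report$fits, file.path(out_dir, "fits.csv"), hash)
    jsonlite::write_json(
      list(config_hash = hash, alpha = report$alpha, adjust = report$adjust,
           results = report$results, skipped = report$skipped),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = 12,
      pretty = TRUE)
    fo_log("info", "ran %d comparison test(s), %d significant, %d skipped",
           nrow(report$results), sum(report$results$significant),
           nrow(report$skipped))
    out$report_file <- file.path(out_dir, "report.csv")
    out$report <- report
  }
  invisible(out)
}
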