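#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration that drives
#' [run_pipeline()]: data/output directories, the raw-CSV column schema,
#' kinematics settings (filter gain, mounting up-axis, optional
#' prefilter), phase window offsets, cleaning settings and the
#' simulation block. Phase durations are deliberately configuration,
#' not constants: alternative phase theories can be re-processed by
#' editing the offsets and rerunning.
#'
#' @param path Optional YAML file; entries override the defaults.
#' @param ... Named overrides applied after the file (same structure).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(
    paths = list(data_dir = "data", out_dir = "out", features_csv = NULL),
    schema = list(time = "t", accel = c("ax", "ay", "az"),
                  gyro = c("gx", "gy", "gz"),
                  accel_unit = "mps2", gyro_unit = "dps"),
    kinematics = list(gain = 0.02, up_axis = "+z", prefilter = NULL),
    phases = list(pre = 23, peri = 3, post = 23),
    cleaning = list(winsor_fraction = 0.05, kurtosis = "excess"),
    simulation = list(),
    seed = 1L
  )
  merge_in <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
        merge_in(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  if (!is.null(path)) cfg <- merge_in(cfg, yaml::read_yaml(path))
  cfg <- merge_in(cfg, list(...))
  stopifnot(all(unlist(cfg$phases) > 0))
  class(cfg) <- "pipeline_config"
  cfg
}

config_offsets <- function(config) {
  c(pre = config$phases$pre, peri = config$phases$peri,
    post = config$phases$post)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config), identity, how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(config, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  message(msg)
  log_file <- file.path(config$paths$out_dir, "run.log")
  if (dir.exists(dirname(log_file)))
    cat(msg, "\n", file = log_file, append = TRUE)
}

stage_simulate <- function(config) {
  sim_args <- config$simulation
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(sim_config, sim_args)
  simulate_cohort(cfg, dir = config$paths$data_dir)
  invisible(config$paths$data_dir)
}

stage_extract <- function(config) {
  dd <- config$paths$data_dir
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pre <- config$paths$features_csv
  if (!is.null(pre)) {
    # derived per-phase features supplied directly; pass through
    feats <- read_feature_table(pre)
    write_feature_table(feats, file.path(out, "feature_table.csv"),
                        overwrite = TRUE)
    return(invisible(file.path(out, "feature_table.csv")))
  }
  ann_path <- file.path(dd, "annotations.csv")
  if (!file.exists(ann_path))
    stop("extract: annotation file not found: ", ann_path)
  ann <- read_startle_annotations(ann_path)
  schema <- do.call(imu_schema, config$schema)
  imu_files <- list.files(file.path(dd, "imu"), pattern = "\\.csv$",
                          full.names = TRUE)
  if (length(imu_files) == 0)
    stop("extract: no IMU CSV files under ", file.path(dd, "imu"))
  recs <- lapply(imu_files, read_imu_csv, schema = schema)
  res <- compute_cohort_features(
    recs, ann, gain = config$kinematics$gain,
    up_axis = config$kinematics$up_axis,
    prefilter = config$kinematics$prefilter,
    offsets = config_offsets(config))
  if (is.null(res$features))
    stop("extract: no subject passed phase-coverage checks")
  write_feature_table(res$features, file.path(out, "feature_table.csv"),
                      overwrite = TRUE)
  write.csv(res$phase_table, file.path(out, "phase_windows.csv"),
            row.names = FALSE)
  write.csv(res$exclusions, file.path(out, "exclusions.csv"),
            row.names = FALSE)
  if (nrow(res$exclusions))
    pipeline_log(config, "extract: excluded ", nrow(res$exclusions),
                 " subject(s); see exclusions.csv")
  invisible(file.path(out, "feature_table.csv"))
}

stage_score <- function(config) {
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  ev_path <- file.path(config$paths$data_dir, "events.csv")
  if (!file.exists(ev_path))
    stop("score: events file not found: ", ev_path)
  scores <- score_fear_events(read_code_events(ev_path))
  write.csv(scores, file.path(out, "code_scores.csv"), row.names = FALSE)
  invisible(file.path(out, "code_scores.csv"))
}

stage_analyze <- function(config) {
  out <- config$paths$out_dir
  feats <- read_feature_table(file.path(out, "feature_table.csv"))
  scores_path <- file.path(out, "code_scores.csv")
  scores <- if (file.exists(scores_path))
    read.csv(scores_path, stringsAsFactors = FALSE) else NULL
  meta_path <- file.path(config$paths$data_dir, "meta.csv")
  meta <- if (file.exists(meta_path)) read_subject_meta(meta_path) else NULL
  cohort <- build_cohort_table(feats, scores, meta)
  fc <- clean_cohort(cohort,
                     winsor_fraction = config$cleaning$winsor_fraction,
                     kurtosis = config$cleaning$kurtosis)
  ana <- analyze_cohort(fc)
  tables <- list(descriptives = ana$descriptives,
                 phase_tests = ana$phase_tests,
                 modality_correlations = ana$modality_correlations,
                 symptom_correlations = ana$symptom_correlations$symptoms,
                 covariate_screen = ana$symptom_correlations$covariates,
                 diagnosis_tests = ana$diagnosis_tests,
                 diagnosis_tests_sensitivity = ana$diagnosis_tests_sensitivity)
  for (nm in names(tables))
    if (!is.null(tables[[nm]]))
      write.csv(tables[[nm]], file.path(out, paste0(nm, ".csv")),
                row.names = FALSE)
  report <- c(list(provenance = list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fearmotion")),
    n_subjects = ana$n_subjects)),
    tables,
    list(cleaning = ana$provenance))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  invisible(file.path(out, "report.json"))
}

stage_report <- function(config) {
  out <- config$paths$out_dir
  rp <- file.path(out, "report.json")
  if (!file.exists(rp)) stop("report: no report.json; run analyze first")
  rep <- jsonlite::read_json(rp, simplifyVector = TRUE)
  validate_report(rep)
  lines <- c(
    sprintf("fearmotion pipeline report (package %s)",
            rep$provenance$package_version),
    sprintf("config %s, seed %s, %d subjects", rep$provenance$config_hash,
            rep$provenance$seed, rep$provenance$n_subjects),
    "",
    "Phase contrasts (paired t, first minus second phase):",
    utils::capture.output(print(rep$phase_tests, digits = 3)))
  if (!is.null(rep$diagnosis_tests))
    lines <- c(lines, "", "Diagnosis-group comparisons:",
               utils::capture.output(print(rep$diagnosis_tests, digits = 3)))
  excl_path <- file.path(out, "exclusions.csv")
  if (file.exists(excl_path)) {
    excl <- read.csv(excl_path)
    lines <- c(lines, "", sprintf("Exclusions: %d", nrow(excl)),
               if (nrow(excl)) utils::capture.output(print(excl)))
  }
  writeLines(lines, file.path(out, "summary.txt"))
  invisible(file.path(out, "summary.txt"))
}

#' Check a pipeline report against the shipped schema
#'
#' Light structural validation of a `report.json` produced by the
#' analyze stage against the JSON schema shipped at
#' `system.file("schema", "report-schema.json", package = "fearmotion")`:
#' required top-level members, required provenance fields and required
#' columns of each result table.
#'
#' @param report Parsed report list (from [jsonlite::read_json()]).
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "fearmotion"),
                                simplifyVector = TRUE)
  for (req in schema$required)
    if (is.null(report[[req]]))
      stop("report schema violation: missing required member '", req, "'")
  for (req in schema$properties$provenance$required)
    if (is.null(report$provenance[[req]]))
      stop("report schema violation: provenance missing '", req, "'")
  for (tab in names(schema$table_columns)) {
    if (is.null(report[[tab]])) next
    cols <- schema$table_columns[[tab]]
    have <- names(as.data.frame(report[[tab]]))
    miss <- setdiff(cols, have)
    if (length(miss))
      stop("report schema violation: table '", tab, "' missing column(s) ",
           paste(miss, collapse = ", "))
  }
  invisible(TRUE)
}

#' Run the analysis pipeline
#'
#' Orchestrates the end-to-end pipeline over a data directory:
#' `simulate` writes a synthetic cohort file set, `extract` computes the
#' per-phase feature table from raw IMU CSVs (or passes through a
#' supplied derived-feature table), `score` computes
#' intensity-weighted behavioral code scores, `analyze` runs the full
#' statistical battery (CSV tables plus a `report.json` with a
#' provenance header), `report` renders a human-readable summary, and
#' `all` runs everything in order. Each stage is deterministic given
#' unchanged inputs and the configured seed. A failing stage signals an
#' error naming the stage and leaves a `FAILED` marker next to any
#' partial artifacts.
#'
#' @param config A [pipeline_config()] (or a YAML path for one).
#' @param subcommand One of `"simulate"`, `"extract"`, `"score"`,
#'   `"analyze"`, `"report"`, `"all"`.
#' @return Invisibly, the primary artifact path of the last stage run.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         subcommand = c("all", "simulate", "extract",
                                        "score", "analyze", "report")) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  subcommand <- match.arg(subcommand)
  stages <- if (subcommand == "all")
    c("simulate", "extract", "score", "analyze", "report") else subcommand
  dir.create(config$paths$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- NULL
  for (st in stages) {
    pipeline_log(config, "stage ", st, " started")
    res <- tryCatch(
      switch(st,
             simulate = stage_simulate(config),
             extract = stage_extract(config),
             score = stage_score(config),
             analyze = stage_analyze(config),
             report = stage_report(config)),
      error = function(e) {
        writeLines(paste0("stage ", st, " failed: ", conditionMessage(e)),
                   file.path(config$paths$out_dir, "FAILED"))
        stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    pipeline_log(config, "stage ", st, " done")
  }
  marker <- file.path(config$paths$out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  invisible(res)
}
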