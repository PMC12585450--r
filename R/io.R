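# Delimited-text trial schema and results writing. Degrees and newtons in
# files; time in seconds. A JSON sidecar carries the generating config and
# seed so a simulated trial round-trips with its provenance.

trial_schema <- list(
  kinematic = c("time_s", "hip_deg", "knee_deg", "ankle_deg"),
  grf = c("time_s", "grf_N")
)

#' Write a trial to a directory as delimited text
#'
#' Writes `kinematic.csv` (`time_s`, `hip_deg`, `knee_deg`, `ankle_deg`),
#' `grf.csv` (`time_s`, `grf_N`) and a `meta.json` sidecar holding the
#' generator config/seed and any subject labels.
#'
#' @param trial A `gait_trial` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  if (!inherits(trial, "gait_trial")) {
    stop("write_trial(): not a gait_trial", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(trial$angles, file.path(dir, "kinematic.csv"))
  readr::write_csv(trial$grf, file.path(dir, "grf.csv"))
  cfg <- trial$meta$config
  meta <- list(
    config = cfg[setdiff(names(cfg), "joint_waveforms")],
    joint_waveforms = cfg$joint_waveforms,
    kinematic_rate = cfg$kinematic_rate,
    grf_rate = cfg$grf_rate,
    labels = trial$meta[setdiff(names(trial$meta), c("config", "truth"))]
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

read_numeric_column <- function(df, col, file) {
  raw <- df[[col]]
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) & !is.na(raw) & raw != "NA" & raw != "")
  if (length(bad)) {
    stop("read_trial(): non-numeric value in column '", col, "' of ", file,
         " at data row ", bad[1], " ('", raw[bad[1]], "')", call. = FALSE)
  }
  out
}

#' Read a trial written by [write_trial()]
#'
#' Validates the schema (missing columns, non-numeric values with their row
#' number, non-monotone time) and rebuilds the `gait_trial` object. Sampling
#' rates come from `meta.json` when present, otherwise from the median time
#' step.
#'
#' @param dir Directory containing `kinematic.csv` and `grf.csv`.
#' @return A `gait_trial` object.
#' @export
read_trial <- function(dir) {
  read_one <- function(file, cols) {
    path <- file.path(dir, file)
    if (!file.exists(path)) {
      stop("read_trial(): missing file ", path, call. = FALSE)
    }
    df <- readr::read_csv(path, col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE)
    missing <- setdiff(cols, names(df))
    if (length(missing)) {
      stop("read_trial(): ", file, " is missing column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- tibble::as_tibble(
      lapply(stats::setNames(cols, cols), function(cc)
        read_numeric_column(df, cc, file))
    )
    if (any(diff(out$time_s) <= 0)) {
      stop("read_trial(): time_s is not strictly increasing in ", file,
           call. = FALSE)
    }
    out
  }
  angles <- read_one("kinematic.csv", trial_schema$kinematic)
  grf <- read_one("grf.csv", trial_schema$grf)
  meta <- list()
  meta_path <- file.path(dir, "meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  }
  rate_from <- function(t) 1 / stats::median(diff(t))
  structure(
    list(angles = angles, grf = grf,
         meta = list(
           config = meta$config,
           kinematic_rate = meta$kinematic_rate %||% rate_from(angles$time_s),
           grf_rate = meta$grf_rate %||% rate_from(grf$time_s),
           labels = meta$labels
         )),
    class = "gait_trial"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a pipeline report bundle to disk
#'
#' Writes the tidy per-subject results (`results.csv`), the ANOVA table
#' (`anova.csv`), the group x time summary tables (`summary.csv`) and the
#' machine-readable run log (`log.json`).
#'
#' @param report A `coordgait_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(report, dir) {
  if (!inherits(report, "coordgait_report")) {
    stop("write_results(): not a coordgait_report", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$results, file.path(dir, "results.csv"))
  readr::write_csv(report$anova, file.path(dir, "anova.csv"))
  readr::write_csv(report$summary, file.path(dir, "summary.csv"))
  jsonlite::write_json(report$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
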