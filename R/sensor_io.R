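#' Column schema for raw IMU CSV files
#'
#' Describes how the columns of a raw IMU CSV map onto the canonical
#' recording fields, and in which units the file stores them. The reader
#' converts everything to the package's canonical units: m/s^2 for
#' acceleration, deg/s for angular rate, seconds for time.
#'
#' @param time Name of the time column (seconds from recording start).
#' @param accel Character vector of the three accelerometer column names
#'   (x, y, z order in the sensor frame).
#' @param gyro Character vector of the three gyroscope column names.
#' @param accel_unit `"mps2"` (m/s^2) or `"g"` (multiples of standard
#'   gravity, 9.80665 m/s^2).
#' @param gyro_unit `"dps"` (deg/s) or `"rps"` (rad/s).
#' @param sample_rate Optional sampling rate in Hz; when `NULL` it is
#'   inferred from the median time step.
#' @return An object of class `imu_schema`.
#' @export
#' @examples
#' imu_schema(accel_unit = "g")
imu_schema <- function(time = "t",
                       accel = c("ax", "ay", "az"),
                       gyro = c("gx", "gy", "gz"),
                       accel_unit = c("mps2", "g"),
                       gyro_unit = c("dps", "rps"),
                       sample_rate = NULL) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  stopifnot(length(time) == 1, length(accel) == 3, length(gyro) == 3)
  if (!is.null(sample_rate)) stopifnot(sample_rate > 0)
  structure(
    list(time = time, accel = accel, gyro = gyro,
         accel_unit = accel_unit, gyro_unit = gyro_unit,
         sample_rate = sample_rate),
    class = "imu_schema"
  )
}

#' Construct an IMU recording
#'
#' Canonical container for one subject's raw inertial time series:
#' timestamps, tri-axial acceleration (m/s^2) and tri-axial angular rate
#' (deg/s), all in the sensor frame.
#'
#' @param subject_id Subject identifier.
#' @param t Numeric vector of sample times in seconds, monotone
#'   nondecreasing.
#' @param accel N x 3 matrix of accelerations, m/s^2.
#' @param gyro N x 3 matrix of angular rates, deg/s.
#' @param sample_rate Sampling rate in Hz; inferred from the median time
#'   step when `NULL`. The time vector must be consistent with it to
#'   within 1%.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(subject_id, t, accel, gyro, sample_rate = NULL) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  n <- length(t)
  if (n < 2) stop("an IMU recording needs at least 2 samples")
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3 || ncol(gyro) != 3)
    stop("accel and gyro must be N x 3 with N matching length(t)")
  if (any(diff(t) < 0))
    stop("IMU data error: time vector is not monotone nondecreasing")
  dt_med <- median(diff(t))
  if (dt_med <= 0) stop("degenerate time vector: median step is not positive")
  if (is.null(sample_rate)) sample_rate <- 1 / dt_med
  if (abs(dt_med - 1 / sample_rate) > 0.01 / sample_rate)
    stop("time spacing inconsistent with sample_rate (deviation > 1%)")
  dimnames(accel) <- list(NULL, c("ax", "ay", "az"))
  dimnames(gyro) <- list(NULL, c("gx", "gy", "gz"))
  structure(
    list(subject_id = as.character(subject_id), sample_rate = sample_rate,
         t = as.numeric(t), accel = accel, gyro = gyro),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> subject %s: %d samples @ %.6g Hz (%.1f s)\n",
              x$subject_id, length(x$t), x$sample_rate,
              x$t[length(x$t)] - x$t[1]))
  invisible(x)
}

# interpolate NA runs of length <= max_gap per column; error on longer runs
interpolate_gaps <- function(t, m, max_gap = 3L) {
  n_fixed <- 0L
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (!any(na)) next
    r <- rle(na)
    if (any(r$values & r$lengths > max_gap))
      stop("IMU data error: missing-sample gap longer than ", max_gap,
           " samples in column ", j)
    if (na[1] || na[length(na)])
      stop("IMU data error: missing samples at recording boundary")
    m[na, j] <- approx(t[!na], m[!na, j], xout = t[na])$y
    n_fixed <- n_fixed + sum(na)
  }
  attr(m, "n_interpolated") <- n_fixed
  m
}

#' Read a raw IMU CSV file
#'
#' Reads one row per sample and returns a canonical-unit
#' [imu_recording()]. Unit conversion (g to m/s^2, rad/s to deg/s) is
#' applied per the schema; reading data already in canonical units leaves
#' every value unchanged. Missing sensor values in gaps of up to 3
#' samples are linearly interpolated (with a reported count); longer
#' gaps, more than 5% affected rows, or non-monotone time are errors.
#'
#' @param path CSV file path.
#' @param schema An [imu_schema()] describing columns and units.
#' @param subject_id Subject identifier; defaults to the file name
#'   without extension.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, schema = imu_schema(), subject_id = NULL) {
  if (!file.exists(path)) stop("IMU file not found: ", path)
  stopifnot(inherits(schema, "imu_schema"))
  df <- read.csv(path, check.names = FALSE)
  need <- c(schema$time, schema$accel, schema$gyro)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("IMU schema error: missing columns: ", paste(miss, collapse = ", "))
  t <- as.numeric(df[[schema$time]])
  if (anyNA(t)) stop("IMU data error: missing timestamps")
  if (any(diff(t) < 0))
    stop("IMU data error: time column is not monotone nondecreasing")
  m <- as.matrix(df[c(schema$accel, schema$gyro)])
  storage.mode(m) <- "double"
  n_bad <- sum(!complete.cases(m))
  if (n_bad > 0.05 * nrow(m))
    stop("IMU data error: more than 5% of rows have missing samples (",
         n_bad, " of ", nrow(m), ")")
  m <- interpolate_gaps(t, m)
  if (attr(m, "n_interpolated") > 0)
    message("read_imu_csv: interpolated ", attr(m, "n_interpolated"),
            " missing values in ", basename(path))
  accel <- m[, 1:3, drop = FALSE]
  gyro <- m[, 4:6, drop = FALSE]
  if (schema$accel_unit == "g") accel <- accel * .g0
  if (schema$gyro_unit == "rps") gyro <- gyro * 180 / pi
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  imu_recording(subject_id, t, accel, gyro, sample_rate = schema$sample_rate)
}

#' Write an IMU recording as a canonical-unit CSV
#'
#' @param rec An [imu_recording()].
#' @param path Output path.
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path, overwrite = FALSE) {
  stopifnot(inherits(rec, "imu_recording"))
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path)
  df <- data.frame(t = rec$t, rec$accel, rec$gyro)
  write_csv_full_precision(df, path)
  invisible(path)
}

# write numeric columns at full double precision so round trips are exact
write_csv_full_precision <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read startle annotations
#'
#' One row per subject giving the manually identified startle instant, in
#' seconds on the recording clock.
#'
#' @param path CSV with columns `subject_id`, `t_startle`.
#' @return A data frame with one row per subject.
#' @export
read_startle_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "t_startle")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file missing columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$t_startle <- as.numeric(df$t_startle)
  if (anyNA(df$t_startle)) stop("annotation file has missing startle times")
  df
}

code_enum_levels <- function() {
  list(phase = c("PotentialThreat", "AcuteThreat"),
       valence = c("fear", "anger", "sadness", "positivity"),
       channel = c("verbal", "nonverbal"),
       intensity = c("low", "moderate", "high"))
}

#' Validate a table of behavioral code events
#'
#' @param events Data frame with columns `subject_id`, `phase`,
#'   `valence`, `channel`, `intensity`, `duration`.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_code_events <- function(events) {
  need <- c("subject_id", "phase", "valence", "channel", "intensity", "duration")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("code events missing columns: ", paste(miss, collapse = ", "))
  lv <- code_enum_levels()
  for (col in c("phase", "valence", "channel", "intensity")) {
    bad <- which(!(events[[col]] %in% lv[[col]]))
    if (length(bad))
      stop(sprintf("code event validation error: row %d has invalid %s '%s'",
                   bad[1], col, events[[col]][bad[1]]))
  }
  if (any(!is.finite(events$duration) | events$duration <= 0)) {
    bad <- which(!is.finite(events$duration) | events$duration <= 0)[1]
    stop("code event validation error: row ", bad, " has non-positive duration")
  }
  events$subject_id <- as.character(events$subject_id)
  events
}

#' Read behavioral code events
#'
#' Each row is one coded behavior interval: phase
#' (PotentialThreat/AcuteThreat), valence (fear/anger/sadness/positivity),
#' channel (verbal/nonverbal), intensity (low/moderate/high) and interval
#' duration in seconds. Unknown enum values are rejected with the
#' offending row named.
#'
#' @param path CSV file path.
#' @return Validated data frame of events (possibly zero rows).
#' @export
read_code_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    need <- c("subject_id", "phase", "valence", "channel", "intensity", "duration")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("code events missing columns: ", paste(miss, collapse = ", "))
    return(df)
  }
  validate_code_events(df)
}

#' Read subject metadata
#'
#' @param path CSV with columns `subject_id`, `age`, `gender`,
#'   `cbcl_internalizing`, `cbcl_externalizing`, `internalizing_dx`
#'   (none/past/current), `externalizing_dx` (logical). CBCL T scores
#'   must lie in \[20, 110\] (NA allowed for unassessed subjects).
#' @return Validated data frame.
#' @export
read_subject_meta <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age", "gender", "cbcl_internalizing",
            "cbcl_externalizing", "internalizing_dx", "externalizing_dx")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata file missing columns: ", paste(miss, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  for (col in c("cbcl_internalizing", "cbcl_externalizing")) {
    x <- df[[col]]
    if (any(!is.na(x) & (x < 20 | x > 110)))
      stop("metadata error: ", col, " outside [20, 110]")
  }
  bad <- !is.na(df$internalizing_dx) &
    !(df$internalizing_dx %in% c("none", "past", "current"))
  if (any(bad))
    stop("metadata error: internalizing_dx must be none/past/current, got '",
         df$internalizing_dx[which(bad)[1]], "'")
  df$externalizing_dx <- as.logical(df$externalizing_dx)
  df
}

#' Write the per-subject feature table as a long-format CSV
#'
#' One row per subject x phase x variable, with value at full double
#' precision plus any per-subject metadata columns repeated on each row,
#' so that [read_feature_table()] reconstructs the wide table losslessly.
#'
#' @param features Wide data frame: `subject_id` plus the 18
#'   `<variable>_<phase>` motion columns and optional extra columns
#'   (fear codes, metadata).
#' @param path Output path.
#' @param overwrite Overwrite an existing file?
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, overwrite = FALSE) {
  if (is.null(features) || nrow(features) == 0)
    stop("cannot write an empty feature table")
  if (file.exists(path) && !overwrite)
    stop("refusing to overwrite existing file: ", path)
  stopifnot("subject_id" %in% names(features))
  fcols <- intersect(feature_columns(), names(features))
  if (length(fcols) == 0) stop("no motion feature columns found")
  meta_cols <- setdiff(names(features), c("subject_id", fcols))
  long <- do.call(rbind, lapply(fcols, function(cn) {
    parts <- regmatches(cn, regexpr("_(pt|s|rm)$", cn))
    data.frame(subject_id = features$subject_id,
               phase = toupper(sub("^_", "", parts)),
               variable = sub("_(pt|s|rm)$", "", cn),
               value = features[[cn]],
               stringsAsFactors = FALSE)
  }))
  if (length(meta_cols))
    long <- cbind(long, features[match(long$subject_id, features$subject_id),
                                 meta_cols, drop = FALSE])
  long <- long[order(long$subject_id, long$phase, long$variable), ]
  write_csv_full_precision(long, path)
  invisible(path)
}

#' Read a long-format feature table back into wide form
#'
#' Inverse of [write_feature_table()]; also ingests externally derived
#' per-phase summary measures directly (the pipeline does not require raw
#' samples when features are already available).
#'
#' @param path CSV written by [write_feature_table()] or in the same
#'   layout (`subject_id`, `phase`, `variable`, `value`, extra metadata
#'   columns constant within subject).
#' @return Wide data frame, one row per subject.
#' @export
read_feature_table <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "phase", "variable", "value")
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop("feature table missing columns: ", paste(miss, collapse = ", "))
  long$subject_id <- as.character(long$subject_id)
  long$col <- paste(long$variable, tolower(long$phase), sep = "_")
  ids <- unique(long$subject_id)
  wide <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (cn in unique(long$col)) {
    sub <- long[long$col == cn, ]
    wide[[cn]] <- sub$value[match(ids, sub$subject_id)]
  }
  meta_cols <- setdiff(names(long), c(need, "col"))
  for (mc in meta_cols)
    wide[[mc]] <- long[[mc]][match(ids, long$subject_id)]
  wide
}
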