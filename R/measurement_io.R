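## Device-dialect JSON I/O and cohort assembly.
##
## The device stores one JSON file per measurement: subject metadata plus,
## for every sensor in the 26-sensor array, the raw response to room air
## (baseline phase) and to the exhaled breath. The dialect used here is
## versioned and explicit:
##   {schema_version, measurement_id, label, metadata{}, sensors:[
##      {sensor_id, family, sampling_interval_s, baseline:[...], breath:[...]}]}

SCHEMA_VERSION <- "1.0"
SENSOR_FAMILIES <- c("GNP", "MOXA", "MOXD")
CLASS_LABELS <- c("cancer", "control", "unknown")

#' Construct a raw sensor trace
#'
#' One sensor's raw record for a single measurement: the room-air baseline
#' phase and the breath phase, in raw signal units.
#'
#' @param sensor_id character scalar, unique within a measurement.
#' @param family sensor family: `"GNP"` (gold-nanoparticle chemiresistor),
#'   `"MOXA"` (analogue metal-oxide) or `"MOXD"` (digital metal-oxide).
#' @param baseline,breath numeric vectors of raw signal values; both must be
#'   non-empty and finite for a valid trace.
#' @param sampling_interval_s sampling interval in seconds (> 0).
#' @return An object of class `raw_sensor_trace`.
#' @export
raw_sensor_trace <- function(sensor_id, family, baseline, breath,
                             sampling_interval_s = 1) {
  if (!is.character(sensor_id) || length(sensor_id) != 1L || !nzchar(sensor_id))
    stop("sensor_id must be a non-empty string")
  family <- match.arg(family, SENSOR_FAMILIES)
  baseline <- as.numeric(baseline)
  breath <- as.numeric(breath)
  if (!is.numeric(sampling_interval_s) || sampling_interval_s <= 0)
    stop("sampling_interval_s must be > 0")
  structure(
    list(sensor_id = sensor_id, family = family, baseline = baseline,
         breath = breath, sampling_interval_s = as.numeric(sampling_interval_s)),
    class = "raw_sensor_trace")
}

# A trace is *valid* (usable downstream) when both phases are non-empty and
# all values finite; screen_cohort() excludes measurements with invalid traces.
trace_is_valid <- function(tr) {
  length(tr$baseline) > 0L && length(tr$breath) > 0L &&
    all(is.finite(tr$baseline)) && all(is.finite(tr$breath))
}

check_series <- function(x, what, sensor_id) {
  if (length(x) == 0L) return(invisible(TRUE)) # emptiness handled by screening
  bad <- which(!is.finite(x))
  if (length(bad))
    stop(sprintf("non-numeric or non-finite value in %s of sensor '%s' at index %d",
                 what, sensor_id, bad[1L]))
  invisible(TRUE)
}

#' Construct a breath measurement
#'
#' @param measurement_id character scalar.
#' @param sensors list of [raw_sensor_trace()] objects; sensor ids must be
#'   unique.
#' @param class_label `"cancer"`, `"control"` or `"unknown"`. `"unknown"` is
#'   permitted only for prediction-time records, never in training sets.
#' @param metadata named character list/vector (age, sex, timestamp, ...).
#' @param excluded logical; has this measurement been excluded by screening?
#' @param exclusion_reason character reason, `""` when not excluded.
#' @return An object of class `breath_measurement`.
#' @export
breath_measurement <- function(measurement_id, sensors,
                               class_label = "unknown", metadata = list(),
                               excluded = FALSE, exclusion_reason = "") {
  if (!is.character(measurement_id) || length(measurement_id) != 1L ||
      !nzchar(measurement_id))
    stop("measurement_id must be a non-empty string")
  class_label <- match.arg(class_label, CLASS_LABELS)
  if (!is.list(sensors) || length(sensors) == 0L)
    stop("sensors must be a non-empty list of raw_sensor_trace objects")
  ids <- vapply(sensors, function(s) s$sensor_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sensor_id within measurement: ", ids[duplicated(ids)][1L])
  names(sensors) <- ids
  metadata <- lapply(as.list(metadata), as.character)
  structure(
    list(measurement_id = measurement_id, class_label = class_label,
         metadata = metadata, sensors = sensors,
         excluded = isTRUE(excluded),
         exclusion_reason = as.character(exclusion_reason)),
    class = "breath_measurement")
}

#' Construct a cohort of breath measurements
#'
#' @param measurements list of [breath_measurement()] objects.
#' @param schema_version dialect version string.
#' @return An object of class `breath_cohort`.
#' @export
breath_cohort <- function(measurements, schema_version = SCHEMA_VERSION) {
  if (!is.list(measurements))
    stop("measurements must be a list")
  ids <- vapply(measurements, function(m) m$measurement_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate measurement_id in cohort: ", ids[duplicated(ids)][1L])
  names(measurements) <- ids
  structure(list(measurements = measurements,
                 schema_version = schema_version),
            class = "breath_cohort")
}

#' @export
print.breath_cohort <- function(x, ...) {
  kept <- !vapply(x$measurements, function(m) m$excluded, logical(1))
  labs <- vapply(x$measurements, function(m) m$class_label, character(1))
  cat(sprintf("breath_cohort: %d measurements (%d kept, %d excluded)\n",
              length(x$measurements), sum(kept), sum(!kept)))
  print(table(label = labs[kept]))
  invisible(x)
}

#' @export
print.breath_measurement <- function(x, ...) {
  cat(sprintf("breath_measurement '%s' [%s]%s: %d sensors\n",
              x$measurement_id, x$class_label,
              if (x$excluded) paste0(" (excluded: ", x$exclusion_reason, ")") else "",
              length(x$sensors)))
  invisible(x)
}

require_key <- function(rec, key, where) {
  if (is.null(rec[[key]]))
    stop(sprintf("schema error: missing required key '%s' in %s", key, where))
  rec[[key]]
}

#' Read one measurement from a device-dialect JSON file
#'
#' Parses and validates a single-measurement JSON record. Unparseable or
#' schema-violating files raise an error naming the offending key or sensor;
#' they are never silently skipped.
#'
#' @param path path to a JSON file.
#' @return A [breath_measurement()].
#' @export
read_measurement <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  mid <- require_key(rec, "measurement_id", path)
  label <- if (is.null(rec$label)) "unknown" else rec$label
  if (!label %in% CLASS_LABELS)
    stop("schema error: unknown class label '", label, "' in ", path)
  sensors_raw <- require_key(rec, "sensors", path)
  if (length(sensors_raw) == 0L)
    stop("schema error: empty sensors list in ", path)
  sensors <- lapply(sensors_raw, function(s) {
    sid <- require_key(s, "sensor_id", path)
    fam <- require_key(s, "family", paste0("sensor '", sid, "'"))
    for (key in c("baseline", "breath", "sampling_interval_s")) {
      if (is.null(s[[key]]))
        stop(sprintf("schema error: missing required key '%s' for sensor '%s' in %s",
                     key, sid, path))
    }
    bl <- suppressWarnings(as.numeric(unlist(s$baseline)))
    br <- suppressWarnings(as.numeric(unlist(s$breath)))
    check_series(bl, "baseline", sid)
    check_series(br, "breath", sid)
    raw_sensor_trace(sid, fam, bl, br, s$sampling_interval_s)
  })
  md <- if (is.null(rec$metadata)) list() else rec$metadata
  breath_measurement(mid, sensors, class_label = label, metadata = md)
}

#' Write one measurement to a device-dialect JSON file
#'
#' Serializes at full double precision so that
#' `read_measurement(write_measurement(m, f))` reproduces `m` exactly.
#'
#' @param m a [breath_measurement()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_measurement <- function(m, path) {
  stopifnot(inherits(m, "breath_measurement"))
  if (length(m$sensors) == 0L)
    stop("schema error: refusing to write measurement with empty sensors map")
  rec <- list(
    schema_version = SCHEMA_VERSION,
    measurement_id = m$measurement_id,
    label = m$class_label,
    metadata = m$metadata,
    sensors = lapply(unname(m$sensors), function(s) {
      list(sensor_id = s$sensor_id, family = s$family,
           sampling_interval_s = s$sampling_interval_s,
           baseline = s$baseline, breath = s$breath)
    }))
  # 17 significant digits: the shortest length that round-trips any double
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = 17,
                       pretty = FALSE)
  invisible(path)
}

#' Read a whole cohort from a manifest or directory
#'
#' @param paths character vector of JSON file paths, a directory containing
#'   `*.json` files, or a manifest JSON file holding a list of paths.
#' @param sample_sheet optional path to a 2-column CSV
#'   (`measurement_id,label`) supplying class labels, overriding any labels
#'   stored in the device files.
#' @return A [breath_cohort()].
#' @export
read_cohort <- function(paths, sample_sheet = NULL) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.json$", full.names = TRUE))
    paths <- paths[basename(paths) != "manifest.json"]
  } else if (length(paths) == 1L && grepl("\\.json$", paths) &&
           file.exists(paths) && !dir.exists(paths)) {
    head_chars <- readChar(paths, nchars = 64L)
    if (grepl("^\\s*\\[", head_chars)) # manifest: JSON array of file paths
      paths <- unlist(jsonlite::fromJSON(paths))
  }
  ms <- lapply(paths, read_measurement)
  cohort <- breath_cohort(ms)
  if (!is.null(sample_sheet)) cohort <- apply_sample_sheet(cohort, sample_sheet)
  cohort
}

#' Attach class labels from a sample sheet
#'
#' The device file cannot know histology; deployments supply labels
#' separately as a CSV with header `measurement_id,label`.
#'
#' @param cohort a [breath_cohort()].
#' @param path sample-sheet CSV path.
#' @return The relabelled cohort.
#' @export
apply_sample_sheet <- function(cohort, path) {
  sheet <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("measurement_id", "label") %in% names(sheet)))
    stop("sample sheet must have columns 'measurement_id' and 'label'")
  lut <- setNames(sheet$label, sheet$measurement_id)
  cohort$measurements <- lapply(cohort$measurements, function(m) {
    if (m$measurement_id %in% names(lut)) {
      lab <- lut[[m$measurement_id]]
      if (!lab %in% CLASS_LABELS) stop("unknown label in sample sheet: ", lab)
      m$class_label <- lab
    }
    m
  })
  cohort
}

#' Screen a cohort for missing or empty sensor traces
#'
#' Measurements that lack any required sensor, or whose trace for a required
#' sensor is empty or non-finite, are marked excluded with reason
#' `"missing_sensor:<id>"`. Exclusion never looks at the class label.
#' Screening is idempotent.
#'
#' @param cohort a [breath_cohort()].
#' @param required_sensors character vector of sensor ids every measurement
#'   must carry; defaults to the union of sensor ids seen in the cohort.
#' @return The cohort with exclusion flags set; kept/excluded counts are
#'   reported via `message()`.
#' @export
screen_cohort <- function(cohort, required_sensors = NULL) {
  stopifnot(inherits(cohort, "breath_cohort"))
  if (is.null(required_sensors)) {
    required_sensors <- unique(unlist(lapply(cohort$measurements, function(m)
      names(m$sensors))))
  }
  if (length(required_sensors) == 0L) stop("required_sensors must be non-empty")
  cohort$measurements <- lapply(cohort$measurements, function(m) {
    if (m$excluded) return(m)
    for (sid in required_sensors) {
      tr <- m$sensors[[sid]]
      if (is.null(tr) || !trace_is_valid(tr)) {
        m$excluded <- TRUE
        m$exclusion_reason <- paste0("missing_sensor:", sid)
        return(m)
      }
    }
    m
  })
  kept <- sum(!vapply(cohort$measurements, function(m) m$excluded, logical(1)))
  excl <- length(cohort$measurements) - kept
  if (kept == 0L) stop("empty cohort after screening")
  message(sprintf("screen_cohort: %d kept, %d excluded", kept, excl))
  cohort
}

#' Kept (non-excluded) measurements of a cohort
#' @param cohort a [breath_cohort()].
#' @return List of measurements with `excluded = FALSE`.
#' @export
kept_measurements <- function(cohort) {
  Filter(function(m) !m$excluded, cohort$measurements)
}

#' Class labels of the kept measurements
#' @param cohort a [breath_cohort()].
#' @return Named character vector (names are measurement ids).
#' @export
cohort_labels <- function(cohort) {
  ms <- kept_measurements(cohort)
  vapply(ms, function(m) m$class_label, character(1))
}

# Training-set guard: at least 2 measurements per class, no "unknown".
assert_training_labels <- function(labels) {
  if (any(labels == "unknown"))
    stop("class label 'unknown' not permitted in training data")
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least 2 measurements per class for training")
  invisible(TRUE)
}
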