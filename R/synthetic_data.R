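## Synthetic breath-analyzer cohorts. Each sensor's breath-phase response is
## emulated as a rise-plateau-decay curve (rapid reaction to the breath
## pulse, a plateau, then slow recovery), expressed in ratio-normalized units
## around 1; raw traces are reconstructed by multiplying with the sensor's
## stabilized room-air level. Class signal is carried by curve *shape*:
## informative sensors draw class-specific prototypes. Faulty measurements
## (missing sensor traces), gross outliers (10x amplitude), extra leading
## time points and gaussian noise are injected at configurable rates.

#' Simulation configuration
#'
#' @param n_cancer,n_control class sizes (defaults 54 and 85, a typical
#'   two-class gastric-cancer screening cohort).
#' @param n_sensors number of sensors (default 26, split 8 GNP / 8 analogue
#'   MOX / 10 digital MOX as in the full array).
#' @param T breath-phase length in time points (default 120).
#' @param baseline_T baseline-phase length (default 60).
#' @param g_prototypes shape prototypes per class per sensor (default 2).
#' @param shape_signal fraction of sensors whose prototypes differ by class
#'   (default 0.5).
#' @param separation minimum pairwise prototype distance, as a multiple of
#'   `noise_sd` per time point (default 5).
#' @param noise_sd per-point gaussian noise on the normalized curve
#'   (default 0.05).
#' @param baseline_level stabilized room-air signal level in raw units
#'   (default 10).
#' @param baseline_drift linear drift across the baseline phase, as a
#'   fraction of `baseline_level` (default 0.005).
#' @param outlier_rate probability a measurement is a gross outlier (10x
#'   amplitude on every sensor); default 0.
#' @param missing_sensor_rate probability a measurement loses one sensor
#'   trace to a technical fault; default 0.
#' @param length_jitter maximum number of spurious extra time points
#'   prepended to a breath trace (default 3).
#' @param seed integer RNG seed.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(n_cancer = 54L, n_control = 85L, n_sensors = 26L,
                       T = 120L, baseline_T = 60L, g_prototypes = 2L,
                       shape_signal = 0.5, separation = 5,
                       noise_sd = 0.05, baseline_level = 10,
                       baseline_drift = 0.005, outlier_rate = 0,
                       missing_sensor_rate = 0, length_jitter = 3L,
                       seed = 1L) {
  cfg <- list(n_cancer = as.integer(n_cancer), n_control = as.integer(n_control),
              n_sensors = as.integer(n_sensors), T = as.integer(T),
              baseline_T = as.integer(baseline_T),
              g_prototypes = as.integer(g_prototypes),
              shape_signal = shape_signal, separation = separation,
              noise_sd = noise_sd, baseline_level = baseline_level,
              baseline_drift = baseline_drift, outlier_rate = outlier_rate,
              missing_sensor_rate = missing_sensor_rate,
              length_jitter = as.integer(length_jitter), seed = as.integer(seed))
  if (cfg$n_cancer < 2L || cfg$n_control < 2L)
    stop("need at least 2 measurements per class")
  for (r in c("shape_signal", "outlier_rate", "missing_sensor_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must lie in [0, 1]")
  if (cfg$T < 30L) stop("T too short for a rise-plateau-decay curve")
  structure(cfg, class = "sim_config")
}

# One rise-plateau-decay curve in normalized units (baseline level == 1):
# logistic onset at t_on with rise constant tau_r, exponential recovery with
# constant tau_d after t_off, peak excursion amp above baseline.
rpd_curve <- function(T, amp, t_on, tau_r, t_off, tau_d) {
  t <- seq_len(T)
  rise <- 1 / (1 + exp(-(t - t_on) / tau_r))
  decay <- exp(-pmax(0, t - t_off) / tau_d)
  1 + amp * rise * decay
}

# Build n_proto prototype curves with min pairwise per-point RMS distance
# >= target_rms, by spreading amplitudes and onset times over a grid and
# widening the amplitude spacing until the separation target holds.
make_prototypes <- function(n_proto, T, target_rms) {
  step <- max(0.3, 2 * target_rms)
  for (iter in 1:25) {
    protos <- t(vapply(seq_len(n_proto) - 1L, function(i) {
      rpd_curve(T,
                amp = 1 + i * step,
                t_on = T * 0.10 + (i %% 2L) * T * 0.05,
                tau_r = T * 0.02,
                t_off = T * (0.45 + 0.05 * (i %% 3L)),
                tau_d = T * (0.20 + 0.08 * (i %% 2L)))
    }, numeric(T)))
    if (n_proto == 1L) return(protos)
    dmin <- min(stats::dist(protos)) / sqrt(T) # per-point RMS
    if (dmin >= target_rms) return(protos)
    step <- step * max(1.2, target_rms / max(dmin, 1e-12))
  }
  stop("could not achieve the requested prototype separation")
}

sensor_ids_for <- function(n_sensors) {
  if (n_sensors == 26L) counts <- c(GNP = 8L, MOXA = 8L, MOXD = 10L)
  else {
    base <- n_sensors %/% 3L
    counts <- c(GNP = base, MOXA = base, MOXD = n_sensors - 2L * base)
  }
  unlist(lapply(names(counts), function(f)
    sprintf("%s%02d", f, seq_len(counts[[f]]))), use.names = FALSE)
}

sensor_family_of <- function(sid) sub("[0-9]+$", "", sid)

# Shared cohort assembly given per-(sensor, class) prototype matrices.
assemble_cohort <- function(cfg, protos_by_sensor) {
  n <- cfg$n_cancer + cfg$n_control
  classes <- sample(c(rep("cancer", cfg$n_cancer),
                      rep("control", cfg$n_control)))
  ids <- sprintf("M%03d", seq_len(n))
  g <- nrow(protos_by_sensor[[1L]]$cancer)
  proto_idx <- sample.int(g, n, replace = TRUE)
  is_outlier <- runif(n) < cfg$outlier_rate
  lose_sensor <- ifelse(runif(n) < cfg$missing_sensor_rate,
                        sample(names(protos_by_sensor), n, replace = TRUE),
                        NA_character_)

  bt <- seq_len(cfg$baseline_T)
  measurements <- lapply(seq_len(n), function(i) {
    sensors <- lapply(names(protos_by_sensor), function(sid) {
      if (identical(lose_sensor[i], sid)) return(NULL)
      level <- cfg$baseline_level * (1 + 0.2 * (match(sid, names(protos_by_sensor)) - 1L) / cfg$n_sensors)
      baseline <- level * (1 + cfg$baseline_drift * (bt - 1) / cfg$baseline_T) +
        rnorm(cfg$baseline_T, 0, cfg$noise_sd * level * 0.05)
      ref <- mean(tail(baseline, 10L))
      proto <- protos_by_sensor[[sid]][[classes[i]]][proto_idx[i], ]
      curve <- proto + rnorm(cfg$T, 0, cfg$noise_sd)
      breath <- ref * curve
      if (is_outlier[i]) breath <- breath * 10
      extra <- sample.int(cfg$length_jitter + 1L, 1L) - 1L
      if (extra > 0L) breath <- c(rep(breath[1L], extra), breath)
      raw_sensor_trace(sid, sensor_family_of(sid), baseline, breath,
                       sampling_interval_s = 1)
    })
    sensors <- Filter(Negate(is.null), sensors)
    breath_measurement(ids[i], sensors, class_label = classes[i],
                       metadata = list(age = as.character(40L + (i %% 40L)),
                                       sex = c("f", "m")[1L + i %% 2L]))
  })

  cohort <- breath_cohort(measurements)
  attr(cohort, "truth") <- data.frame(
    measurement_id = ids, class = classes, prototype_id = proto_idx,
    outlier = is_outlier, missing_sensor = lose_sensor,
    stringsAsFactors = FALSE)
  attr(cohort, "prototypes") <- protos_by_sensor
  cohort
}

#' Simulate a two-class breath cohort with shape-borne class signal
#'
#' For each informative sensor (the first `ceiling(shape_signal * n_sensors)`
#' sensors), the two classes draw from disjoint prototype sets of
#' `g_prototypes` rise-plateau-decay curves, all pairwise separated by at
#' least `separation * noise_sd` per time point; uninformative sensors share
#' one prototype set across classes. Ground truth (class, prototype index,
#' injected outlier/missing-sensor flags) is stored in `attr(cohort,
#' "truth")`, and the prototype curves in `attr(cohort, "prototypes")`.
#'
#' @param cfg a [sim_config()].
#' @return A [breath_cohort()] with truth attributes.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sids <- sensor_ids_for(cfg$n_sensors)
  n_inf <- ceiling(cfg$shape_signal * cfg$n_sensors)
  target <- cfg$separation * cfg$noise_sd
  g <- cfg$g_prototypes

  protos_by_sensor <- lapply(seq_along(sids), function(s) {
    if (s <= n_inf) {
      both <- make_prototypes(2L * g, cfg$T, target)
      list(cancer = both[seq_len(g), , drop = FALSE],
           control = both[g + seq_len(g), , drop = FALSE])
    } else {
      shared <- make_prototypes(g, cfg$T, target)
      list(cancer = shared, control = shared)
    }
  })
  names(protos_by_sensor) <- sids
  assemble_cohort(cfg, protos_by_sensor)
}

# arrange values unimodally: ascending odd order statistics, then the even
# ones descending ("organ-pipe" order)
unimodal_arrangement <- function(v) {
  s <- sort(v)
  c(s[seq(1L, length(s), 2L)], rev(s[seq(2L, length(s), 2L)]))
}

#' Simulate a cohort where only curve shape separates the classes
#'
#' Each sensor has one cancer prototype (a single rise-plateau-decay response
#' pulse) and one control prototype that is an exact time-permutation of the
#' same values: the pulse's value multiset is split by alternating order
#' statistics into two halves, each arranged unimodally, giving a curve with
#' two separated response pulses. Because the control curve contains exactly
#' the same values (and the same baseline pads at both ends), the minimum,
#' maximum, average, trapezoidal AUC and end mean of the noisy curves are
#' identically distributed across classes, while the Euclidean and DTW
#' distances between the prototypes are large -- DTW in particular must pay
#' for the inter-pulse valley, which no time-warp of a single pulse creates.
#' The generator verifies the summary-match property on its emitted
#' prototypes (class difference of every common feature below `noise_sd / 2`)
#' and errors if it cannot be satisfied.
#'
#' @param cfg a [sim_config()]; one prototype per class and every sensor
#'   carries the shape signal.
#' @return A [breath_cohort()] with truth attributes.
#' @export
simulate_shape_only_cohort <- function(cfg = sim_config(shape_signal = 1)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$T < 60L) stop("cannot satisfy summary-match for requested T")
  set.seed(cfg$seed)
  sids <- sensor_ids_for(cfg$n_sensors)
  pad <- 12L # longer than the 10-point end window, shared by both classes
  m <- cfg$T - 2L * pad

  protos_by_sensor <- lapply(seq_along(sids), function(s) {
    amp <- 3.3 + 0.15 * ((s - 1L) %% 5L)
    core <- rpd_curve(m, amp = amp, t_on = m * 0.10, tau_r = m * 0.02,
                      t_off = m * 0.55, tau_d = m * 0.15)
    rk <- rank(core, ties.method = "first")
    bimodal <- c(unimodal_arrangement(core[rk %% 2L == 1L]),
                 unimodal_arrangement(core[rk %% 2L == 0L]))
    fwd <- c(rep(1, pad), core, rep(1, pad))
    alt <- c(rep(1, pad), bimodal, rep(1, pad))
    list(cancer = matrix(fwd, 1L), control = matrix(alt, 1L))
  })
  names(protos_by_sensor) <- sids

  cohort <- assemble_cohort(cfg, protos_by_sensor)

  # summary-match self-check on the emitted prototypes
  tol <- max(cfg$noise_sd / 2, 1e-8)
  for (pp in protos_by_sensor) {
    fa <- extract_common(pp$cancer[1L, ])
    fb <- extract_common(pp$control[1L, ])
    if (any(abs(fa - fb) > tol))
      stop("cannot satisfy summary-match for requested T")
  }
  cohort
}

#' Write a cohort as device-dialect files
#'
#' Emits one JSON file per measurement plus `sample_sheet.csv`
#' (`measurement_id,label`), `manifest.json` (list of file paths) and, when
#' ground truth is attached, `ground_truth.csv`.
#'
#' @param cohort a [breath_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$measurements, function(m) {
    p <- file.path(dir, paste0(m$measurement_id, ".json"))
    write_measurement(m, p)
    p
  }, character(1))
  labs <- vapply(cohort$measurements, function(m) m$class_label, character(1))
  write.csv(data.frame(measurement_id = names(labs), label = unname(labs)),
            file.path(dir, "sample_sheet.csv"), row.names = FALSE)
  jsonlite::write_json(unname(paths), file.path(dir, "manifest.json"))
  truth <- attr(cohort, "truth")
  if (!is.null(truth))
    write.csv(truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
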