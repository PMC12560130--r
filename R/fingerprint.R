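#' Column names of the 24 shift columns in a fingerprint matrix
#' @return Character vector `s01`..`s24`.
#' @export
sensor_columns <- function() sprintf("s%02d", 1:24)

#' Measurement schedule for a liquid class
#'
#' Every sample is read repeatedly after introduction to capture
#' kinetic development: 10 readings at 30 s intervals for all classes
#' except beer, which gets 20 readings (its surface interaction
#' develops for several minutes). The rolling deionised-water baseline
#' averages the preceding 10 DI readings.
#'
#' @param class_label a known liquid class (see [liquid_sample()]).
#' @param n_readings,interval_s,baseline_window explicit overrides; any
#'   non-`NULL` value replaces the class default (required for
#'   `custom`).
#' @return List with `n_readings`, `interval_s`, `baseline_window`.
#' @export
schedule_for_class <- function(class_label, n_readings = NULL,
                               interval_s = NULL, baseline_window = NULL) {
  known <- c("mineral_water", "beer", "white_wine", "whiskey", "vodka",
             "gin", "di_water", "custom")
  if (!class_label %in% known)
    stop("unknown class label: ", class_label)
  if (class_label == "custom" && is.null(n_readings))
    stop("class 'custom' requires an explicit n_readings override")
  n <- if (!is.null(n_readings)) n_readings
       else if (class_label == "beer") 20L else 10L
  out <- list(n_readings = as.integer(n),
              interval_s = if (is.null(interval_s)) 30 else interval_s,
              baseline_window = if (is.null(baseline_window)) 10L
                                else as.integer(baseline_window))
  stopifnot(out$n_readings >= 1, out$interval_s > 0,
            out$baseline_window >= 1)
  out
}

#' Rolling deionised-water baseline
#'
#' The per-sensor baseline is the mean of the most recent `window`
#' (default 10) DI-water minimum readings. With fewer than `window`
#' readings available all of them are used and a warning is attached —
#' refusing would block a cold start.
#'
#' @param di_reading_history numeric matrix, one row per DI reading,
#'   24 columns of lambda_min (nm), oldest first.
#' @param window number of most recent readings averaged (default 10).
#' @return Numeric vector of 24 baseline wavelengths, with attributes
#'   `n_used` and `short_history` (logical).
#' @export
update_baseline <- function(di_reading_history, window = 10L) {
  h <- as.matrix(di_reading_history)
  if (nrow(h) < 1) stop("empty DI reading history: no baseline possible")
  if (ncol(h) != 24) stop("history must have 24 sensor columns")
  n_used <- min(window, nrow(h))
  recent <- h[seq(nrow(h) - n_used + 1, nrow(h)), , drop = FALSE]
  out <- colMeans(recent)
  attr(out, "n_used") <- n_used
  attr(out, "short_history") <- n_used < window
  if (n_used < window)
    warning("baseline computed from only ", n_used, " DI readings")
  out
}

#' Assemble one fingerprint from 24 sensor readings and a baseline
#'
#' The fingerprint is the vector of 24 resonance shifts
#' \eqn{\Delta\lambda_i = \lambda_{min,i} - baseline_i}. A missing
#' sensor reading is an error — no silent imputation.
#'
#' @param readings_24 list of 24 `sensor_reading` objects (any order;
#'   all sensor ids 1..24 present, sharing one `time_s`), or a named
#'   numeric vector of 24 lambda_min values indexed by sensor id.
#' @param baseline numeric vector of 24 baseline wavelengths (nm).
#' @param sample_id,class_label,replicate metadata carried on the result.
#' @return Object of class `fingerprint`: list with `delta_lambda`
#'   (length 24), `time_s`, metadata and `flags`.
#' @export
compute_fingerprint <- function(readings_24, baseline, sample_id = NA,
                                class_label = NA, replicate = NA) {
  if (length(baseline) != 24) stop("baseline must have 24 entries")
  flags <- character(0)
  if (is.list(readings_24)) {
    ids <- vapply(readings_24, `[[`, 0L, "sensor_id")
    if (!setequal(ids, 1:24) || length(ids) != 24)
      stop("need exactly one reading per sensor 1..24")
    ts <- unique(vapply(readings_24, `[[`, 0, "time_s"))
    if (length(ts) != 1) stop("readings must share one time_s")
    lam <- numeric(24)
    lam[ids] <- vapply(readings_24, `[[`, 0, "lambda_min")
    flags <- unique(unlist(lapply(readings_24, `[[`, "flags")))
    time_s <- ts
  } else {
    if (length(readings_24) != 24) stop("need 24 lambda_min values")
    lam <- as.numeric(readings_24)
    time_s <- NA
  }
  dl <- lam - as.numeric(baseline)
  if (any(!is.finite(dl))) stop("non-finite fingerprint entries")
  structure(list(sample_id = sample_id, class_label = class_label,
                 replicate = replicate, time_s = time_s,
                 delta_lambda = dl, flags = flags),
            class = "fingerprint")
}

# signal-level simulated reading: vector of 24 lambda_min for `sample`
# at time t after introduction, plus carryover residual and drift
simulate_reading <- function(chem, sample, model, t,
                             residual = numeric(24), drift_nm = 0) {
  lam <- vapply(1:24, function(i) {
    ch <- chem[i, ]
    ch$resonance_water + shift_at_time(ch, sample, t, model)
  }, numeric(1))
  lam <- lam + residual + drift_nm
  if (model$lambda_noise_sd > 0)
    lam <- lam + stats::rnorm(24, 0, model$lambda_noise_sd)
  lam
}

# adsorption-only part of the equilibrium shift (no bulk term); this is
# what can persist on the surface after an incomplete rinse
adsorption_shift <- function(chem, sample) {
  feats <- analyte_features()
  conc <- unclass(sample$composition)[feats]
  vapply(1:24, function(i) {
    aff <- as.numeric(chem[i, paste0("aff_", feats)])
    ks <- as.numeric(chem[i, paste0("k_", feats)])
    sum(aff * ifelse(conc > 0, conc / (ks + conc), 0))
  }, numeric(1))
}

# full-optical reading: render a frame at the current dip centres and
# push it through section -> normalise -> spline extraction
simulate_reading_optical <- function(chem, sample, model, t, layout,
                                     calibration, seed,
                                     residual = numeric(24), drift_nm = 0) {
  centers <- vapply(1:24, function(i) {
    ch <- chem[i, ]
    ch$resonance_water + shift_at_time(ch, sample, t, model)
  }, numeric(1)) + residual + drift_nm
  frame <- render_frame(layout, centers, model, calibration, seed = seed)
  spectra <- frame_to_spectra(frame)
  readings <- lapply(spectra, find_minimum)
  vapply(readings, `[[`, 0, "lambda_min")
}

#' Run a full measurement session over a sample catalogue
#'
#' Reproduces the acquisition protocol: liquid classes are visited in
#' turn; within a class, the sample-by-replicate introductions (3
#' replicates each) are measured in seeded random order; 10 DI-water
#' readings are taken before each class block to refresh the rolling
#' baseline; each introduction is read on its class schedule (10
#' readings, or 20 for beer, every 30 s) with adsorption kinetics
#' evaluated at each time point. Every reading becomes one fingerprint
#' row.
#'
#' @param catalog list of `liquid_sample` objects (a DI standard, if
#'   present, is used for baselines and excluded from the rows).
#' @param chemistries a [default_chemistries()] table.
#' @param model a [response_model()].
#' @param seed integer seed driving order randomisation and noise.
#' @param replicates introductions per sample (default 3).
#' @param source `"signal"` (fast: noise injected in the wavelength
#'   domain) or `"optical"` (every reading renders a hyperspectral
#'   frame and runs the full readout + spline pipeline).
#' @param layout,calibration optics used when `source = "optical"`.
#' @param schedule_override if non-`NULL`, overrides every class's
#'   `n_readings` (useful for short diagnostic sessions).
#' @return A `fingerprint_matrix`: data.frame with metadata columns
#'   (`sample_id`, `class_label`, `replicate`, `time_s`, `status`) and
#'   shift columns `s01`..`s24` (nm).
#' @examples
#' \donttest{
#' fm <- run_session(default_catalog(42), seed = 1)
#' nrow(fm)  # (29 x 3 x 10) + (6 x 3 x 20) = 1230
#' }
#' @export
run_session <- function(catalog, chemistries = default_chemistries(),
                        model = response_model(), seed = 1L,
                        replicates = 3L, source = c("signal", "optical"),
                        layout = default_layout(),
                        calibration = default_calibration(),
                        schedule_override = NULL) {
  source <- match.arg(source)
  di <- Filter(function(s) s$class_label == "di_water", catalog)
  di <- if (length(di)) di[[1]] else
    liquid_sample("DI", "di_water", analyte_composition())
  beverages <- Filter(function(s) s$class_label != "di_water", catalog)
  classes <- unique(vapply(beverages, `[[`, "", "class_label"))

  rows <- list()
  withr::with_seed(as.integer(seed), {
    di_history <- NULL
    clock_s <- 0
    residual <- numeric(24)
    frame_seed <- 0L
    read_one <- function(sample, t) {
      drift <- model$baseline_drift_rate * clock_s / 3600
      if (source == "signal") {
        simulate_reading(chemistries, sample, model, t, residual, drift)
      } else {
        frame_seed <<- frame_seed + 1L
        simulate_reading_optical(chemistries, sample, model, t, layout,
                                 calibration,
                                 seed = as.integer(seed) + frame_seed,
                                 residual = residual, drift_nm = drift)
      }
    }
    for (cls in classes) {
      # refresh the rolling DI baseline before the class block
      for (j in 1:10) {
        clock_s <- clock_s + 30
        di_history <- rbind(di_history, read_one(di, t = 600))
      }
      baseline <- suppressWarnings(update_baseline(di_history))
      members <- Filter(function(s) s$class_label == cls, beverages)
      intro <- expand.grid(sample = seq_along(members),
                           replicate = seq_len(replicates))
      intro <- intro[sample.int(nrow(intro)), , drop = FALSE]
      sched <- schedule_for_class(cls, n_readings = schedule_override)
      for (r in seq_len(nrow(intro))) {
        s <- members[[intro$sample[r]]]
        for (j in seq_len(sched$n_readings)) {
          t <- j * sched$interval_s
          clock_s <- clock_s + sched$interval_s
          lam <- read_one(s, t)
          status <- if (all(is.finite(lam))) "ok" else "flagged"
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s$sample_id, class_label = s$class_label,
            replicate = intro$replicate[r], time_s = t, status = status,
            as.list(stats::setNames(lam - baseline, sensor_columns())),
            stringsAsFactors = FALSE)
        }
        residual <- model$carryover_fraction * adsorption_shift(chemistries, s)
      }
    }
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("fingerprint_matrix", "data.frame")
  out
}

#' Extract the 24-column shift matrix from a fingerprint matrix
#'
#' @param fm a `fingerprint_matrix` (or any data.frame with the
#'   `s01`..`s24` columns).
#' @param ok_only drop rows whose `status` is not `"ok"` (default TRUE).
#' @return Numeric matrix, rows x 24.
#' @export
fingerprint_values <- function(fm, ok_only = TRUE) {
  if (ok_only && "status" %in% names(fm)) fm <- fm[fm$status == "ok", ]
  as.matrix(fm[, sensor_columns()])
}

#' Write / read a fingerprint matrix CSV
#'
#' The CSV is the contract between acquisition and chemometrics:
#' metadata columns then `s01`..`s24`.
#'
#' @param fm a `fingerprint_matrix`.
#' @param file path.
#' @return `write_fingerprints()` returns `file` invisibly;
#'   `read_fingerprints()` returns the `fingerprint_matrix`.
#' @export
write_fingerprints <- function(fm, file) {
  utils::write.csv(fm, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(file) {
  out <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing <- setdiff(sensor_columns(), names(out))
  if (length(missing))
    stop("not a fingerprint matrix: missing ", paste(missing, collapse = ", "))
  class(out) <- c("fingerprint_matrix", "data.frame")
  out
}

#' Rinse quality control: has the chip reverted to its DI baseline?
#'
#' After rinsing, a DI-water fingerprint should be flat: each sensor
#' passes iff its |shift| is within the tolerance (default 0.2 nm,
#' twice the instrument resolution); the chip passes iff all 24 do.
#'
#' @param post_rinse_fingerprint numeric vector of 24 shifts (nm)
#'   measured on DI water after rinsing, or a `fingerprint`.
#' @param tolerance_nm per-sensor pass tolerance (nm).
#' @return List with logical `sensor_pass` (length 24) and scalar `pass`.
#' @export
check_baseline_reversion <- function(post_rinse_fingerprint,
                                     tolerance_nm = 0.2) {
  dl <- if (inherits(post_rinse_fingerprint, "fingerprint"))
    post_rinse_fingerprint$delta_lambda else as.numeric(post_rinse_fingerprint)
  if (length(dl) != 24) stop("need 24 shift values")
  sensor_pass <- abs(dl) <= tolerance_nm
  list(sensor_pass = sensor_pass, pass = all(sensor_pass))
}

#' Simulate a post-rinse DI fingerprint with surface carryover
#'
#' With a nonzero `carryover_fraction`, a fraction of the previous
#' sample's chemistry-specific adsorption shift persists through the
#' rinse; failures therefore concentrate on the high-affinity sensors.
#'
#' @param chemistries a [default_chemistries()] table.
#' @param previous_sample the `liquid_sample` measured before the rinse.
#' @param model a [response_model()] with `carryover_fraction` set.
#' @param seed integer seed for measurement noise.
#' @return Numeric vector of 24 post-rinse DI shifts (nm).
#' @export
simulate_rinse_residual <- function(chemistries, previous_sample,
                                    model = response_model(),
                                    seed = 1L) {
  res <- model$carryover_fraction * adsorption_shift(chemistries,
                                                     previous_sample)
  withr::with_seed(as.integer(seed),
                   res + stats::rnorm(24, 0, model$lambda_noise_sd))
}
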