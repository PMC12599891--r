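#' Class-dependent gait generator parameters
#'
#' Bundles the knobs through which substance-induced impairment is expressed
#' in the synthetic gait model: cadence (`step_rate_hz`), stride-time
#' variability (`stride_time_cv`, the coefficient of variation of the
#' lognormal step-duration distribution), medio-lateral sway amplitude
#' (`sway_amp`, a stride-locked quadrature component on the ML axis, m/s^2),
#' the per-harmonic amplitudes of the within-cycle waveform
#' (`harmonic_weights`), and the additive white-noise level (`noise_sd`).
#'
#' @param label one of `"sober"`, `"alcohol"`, `"marijuana"`.
#' @param step_rate_hz steps per second; must be > 0.
#' @param stride_time_cv coefficient of variation of step duration, >= 0.
#' @param sway_amp medio-lateral sway amplitude in m/s^2, >= 0.
#' @param harmonic_weights numeric vector of per-harmonic amplitudes of the
#'   stride-locked waveform (harmonic 1 = stride frequency, harmonic 2 =
#'   step frequency, ...). All entries >= 0.
#' @param noise_sd standard deviation of additive i.i.d. Gaussian sensor
#'   noise (m/s^2), >= 0.
#' @return an object of class `gait_class_params`.
#' @seealso [class_presets()] for the default per-class parameter sets.
#' @export
gait_class_params <- function(label = c("sober", "alcohol", "marijuana"),
                              step_rate_hz = 1.9,
                              stride_time_cv = 0.03,
                              sway_amp = 0.3,
                              harmonic_weights = c(0.5, 1.0, 0.25),
                              noise_sd = 0.3) {
  label <- match.arg(label)
  stopifnot(is.numeric(step_rate_hz), length(step_rate_hz) == 1L)
  if (!(step_rate_hz > 0)) stop("step_rate_hz must be > 0")
  if (stride_time_cv < 0) stop("stride_time_cv must be >= 0")
  if (sway_amp < 0) stop("sway_amp must be >= 0")
  if (any(harmonic_weights < 0)) stop("harmonic_weights must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(
    list(label = label, step_rate_hz = step_rate_hz,
         stride_time_cv = stride_time_cv, sway_amp = sway_amp,
         harmonic_weights = as.numeric(harmonic_weights),
         noise_sd = noise_sd),
    class = "gait_class_params")
}

#' Default per-class gait parameter presets
#'
#' The sober preset is a regular gait; alcohol increases medio-lateral sway
#' and lowers cadence; marijuana increases stride-time variability. These are
#' deliberately separable stand-ins for real pharmacological signatures (the
#' methods vignette discusses what they do and do not emulate).
#'
#' @return named list of [gait_class_params()] objects
#'   (`sober`, `alcohol`, `marijuana`).
#' @export
class_presets <- function() {
  list(
    sober = gait_class_params("sober", step_rate_hz = 1.9,
                              stride_time_cv = 0.03, sway_amp = 0.3),
    alcohol = gait_class_params("alcohol", step_rate_hz = 1.6,
                                stride_time_cv = 0.05, sway_amp = 1.4),
    marijuana = gait_class_params("marijuana", step_rate_hz = 1.8,
                                  stride_time_cv = 0.14, sway_amp = 0.4)
  )
}

# Per-axis base amplitudes (m/s^2) of the stride-locked waveform and the
# phase offsets (radians) per axis x harmonic. x = medio-lateral,
# y = vertical (carries gravity), z = antero-posterior.
.axis_amp <- c(x = 0.4, y = 1.0, z = 0.6)
.axis_phase <- matrix(
  c(0.0, 1.1, 2.3,    # x, harmonics 1..3...
    0.7, 0.0, 1.9,    # y
    1.4, 0.5, 0.0),   # z
  nrow = 3, byrow = TRUE, dimnames = list(c("x", "y", "z"), NULL))
.gravity <- 9.81

# Continuous stride phase at sample times: steps have lognormal durations
# with CV = cv around 1/step_rate; phase advances by pi per step (2*pi per
# gait cycle = 2 steps).
.stride_phase <- function(n, fs, step_rate, cv) {
  t <- (seq_len(n) - 1L) / fs
  dur_total <- n / fs
  n_steps <- ceiling(dur_total * step_rate) + 8L
  mu <- 1 / step_rate
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(mu) - sdlog^2 / 2
    d <- stats::rlnorm(n_steps, meanlog, sdlog)
  } else {
    d <- rep(mu, n_steps)
  }
  edges <- c(0, cumsum(d))
  while (edges[length(edges)] < dur_total) {        # rare underrun
    extra <- if (cv > 0) stats::rlnorm(8L, log(mu) - log(1 + cv^2) / 2,
                                       sqrt(log(1 + cv^2))) else rep(mu, 8L)
    edges <- c(edges, edges[length(edges)] + cumsum(extra))
  }
  step_idx <- findInterval(t, edges, rightmost.closed = FALSE)
  frac <- (t - edges[step_idx]) / (edges[step_idx + 1L] - edges[step_idx])
  pi * (step_idx - 1L + frac)                       # pi per step
}

#' Generate one synthetic walking-bout recording
#'
#' Simulates a smartphone inertial recording of one walking bout. Each axis
#' is a sum of harmonics of the stride frequency, phase-locked to a step
#' train whose step durations are lognormal with coefficient of variation
#' `params$stride_time_cv`; the medio-lateral axis additionally carries a
#' stride-locked quadrature sway component of amplitude `params$sway_amp`;
#' vertical acceleration is offset by gravity; i.i.d. Gaussian noise of sd
#' `params$noise_sd` is added per channel. Gyroscope channels are
#' phase-shifted copies of the accelerometer harmonics with independent
#' noise. Fully reproducible from `seed`.
#'
#' @param params a [gait_class_params()] object.
#' @param duration_s bout duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param subject_offset list with per-subject random effects: `gain`
#'   (multiplicative amplitude factor) and `cadence` (additive step-rate
#'   offset, Hz). Default: no offset.
#' @param seed integer seed.
#' @param subject_id,recording_id identifier strings.
#' @param gyro logical; also synthesize gyroscope channels.
#' @return an object of class `sensor_recording`: list with `t`, `ax`, `ay`,
#'   `az` (and `gx`,`gy`,`gz` if `gyro`), `fs`, `subject_id`, `label`, `id`.
#' @export
generate_recording <- function(params, duration_s = 30, fs = 50,
                               subject_offset = list(gain = 1, cadence = 0),
                               seed = 1L, subject_id = "s01",
                               recording_id = NULL, gyro = TRUE) {
  stopifnot(inherits(params, "gait_class_params"))
  if (!(duration_s > 0)) stop("duration_s must be > 0")
  if (!(fs > 0)) stop("fs must be > 0")
  n <- round(duration_s * fs)
  step_rate <- params$step_rate_hz + subject_offset$cadence
  if (!(step_rate > 0)) stop("effective step rate must be > 0")
  gain <- subject_offset$gain
  withr::with_seed(as.integer(seed), {
    phase <- .stride_phase(n, fs, step_rate, params$stride_time_cv)
    w <- params$harmonic_weights
    mk_axis <- function(axis, phase_shift = 0) {
      s <- numeric(n)
      for (h in seq_along(w)) {
        s <- s + w[h] * .axis_amp[axis] *
          sin(h * phase + .axis_phase[axis, min(h, ncol(.axis_phase))] +
                phase_shift)
      }
      s * gain
    }
    ax <- mk_axis("x") +
      gain * params$sway_amp * sin(phase + pi / 2)   # quadrature sway, ML
    ay <- mk_axis("y") + .gravity
    az <- mk_axis("z")
    noise <- function() if (params$noise_sd > 0)
      stats::rnorm(n, 0, params$noise_sd) else numeric(n)
    ax <- ax + noise(); ay <- ay + noise(); az <- az + noise()
    rec <- list(t = (seq_len(n) - 1L) / fs,
                ax = ax, ay = ay, az = az,
                fs = fs, subject_id = subject_id,
                label = params$label,
                id = recording_id %||%
                  sprintf("%s_%s", subject_id, params$label))
    if (gyro) {
      rec$gx <- mk_axis("x", pi / 3) + noise()
      rec$gy <- mk_axis("y", pi / 3) + noise()
      rec$gz <- mk_axis("z", pi / 3) + noise()
    }
    structure(rec, class = "sensor_recording")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %s  subject=%s  label=%s  fs=%g Hz  n=%d\n",
              x$id, x$subject_id, x$label, x$fs, length(x$ax)))
  invisible(x)
}

#' Generate a labeled synthetic gait dataset
#'
#' Draws per-subject random effects once per subject (lognormal gain, sd 0.1
#' on the log scale; Gaussian cadence offset, sd 0.05 Hz) and generates
#' `bouts_per_subject` walking bouts for each subject of each class.
#' Deterministic under a fixed seed; subject ids are unique across classes.
#'
#' @param class_mix named integer vector or list, label -> number of
#'   subjects (labels among sober/alcohol/marijuana; counts >= 0).
#' @param bouts_per_subject recordings per subject.
#' @param params_by_class named list of [gait_class_params()]; defaults to
#'   [class_presets()].
#' @param duration_s,fs,gyro passed to [generate_recording()].
#' @param seed integer master seed; all per-recording seeds derive from it.
#' @return list of `sensor_recording` objects.
#' @export
generate_dataset <- function(class_mix, bouts_per_subject = 1L,
                             params_by_class = class_presets(),
                             duration_s = 30, fs = 50, seed = 1L,
                             gyro = FALSE) {
  class_mix <- unlist(class_mix)
  if (length(class_mix) == 0L) return(list())
  if (any(class_mix < 0)) stop("subject counts must be >= 0")
  if (is.null(names(class_mix)) ||
      !all(names(class_mix) %in% c("sober", "alcohol", "marijuana")))
    stop("class_mix must be named with sober/alcohol/marijuana")
  recs <- list()
  seed <- as.integer(seed)
  for (lab in names(class_mix)) {
    n_subj <- class_mix[[lab]]
    if (n_subj == 0L) next
    params <- params_by_class[[lab]]
    if (is.null(params)) stop("no parameters for class ", lab)
    for (s in seq_len(n_subj)) {
      sid <- sprintf("%s_s%02d", lab, s)
      subj_seed <- derive_seed(seed, paste0("subj_", sid))
      off <- withr::with_seed(subj_seed, list(
        gain = stats::rlnorm(1, 0, 0.1),
        cadence = stats::rnorm(1, 0, 0.05)))
      for (b in seq_len(bouts_per_subject)) {
        rid <- sprintf("%s_b%02d", sid, b)
        recs[[rid]] <- generate_recording(
          params, duration_s = duration_s, fs = fs, subject_offset = off,
          seed = derive_seed(seed, paste0("rec_", rid)),
          subject_id = sid, recording_id = rid, gyro = gyro)
      }
    }
  }
  recs
}

#' Derive a stage seed from a global seed
#'
#' Deterministic 31-bit seed derivation so that every stage / object of a
#' pipeline run gets its own reproducible RNG stream from one master seed.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer.
#' @return integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h * 8191) %% 2147483647)
}

#' Write recordings as CSV files plus a manifest
#'
#' One CSV per recording (columns `t,ax,ay,az[,gx,gy,gz]`) and a
#' `manifest.csv` (`file,subject_id,label,fs`) in `dir`.
#'
#' @param recs list of `sensor_recording`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest data.frame.
#' @export
write_recordings_csv <- function(recs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(file = character(0), subject_id = character(0),
                    label = character(0), fs = numeric(0))
  for (r in recs) {
    df <- data.frame(t = r$t, ax = r$ax, ay = r$ay, az = r$az)
    if (!is.null(r$gx)) { df$gx <- r$gx; df$gy <- r$gy; df$gz <- r$gz }
    f <- paste0(r$id, ".csv")
    utils::write.csv(df, file.path(dir, f), row.names = FALSE)
    man <- rbind(man, data.frame(file = f, subject_id = r$subject_id,
                                 label = r$label, fs = r$fs))
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Read recordings written by [write_recordings_csv()]
#'
#' @param dir directory containing per-recording CSVs and `manifest.csv`.
#' @return list of `sensor_recording`.
#' @export
read_recordings_csv <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!dir.exists(dir)) stop("input directory does not exist: ", dir)
  if (!file.exists(mf)) stop("manifest.csv not found in ", dir)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  recs <- list()
  for (i in seq_len(nrow(man))) {
    df <- utils::read.csv(file.path(dir, man$file[i]))
    r <- list(t = df$t, ax = df$ax, ay = df$ay, az = df$az,
              fs = man$fs[i], subject_id = man$subject_id[i],
              label = man$label[i],
              id = sub("\\.csv$", "", man$file[i]))
    if (!is.null(df$gx)) { r$gx <- df$gx; r$gy <- df$gy; r$gz <- df$gz }
    recs[[r$id]] <- structure(r, class = "sensor_recording")
  }
  recs
}
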