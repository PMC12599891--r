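#' Segmentation configuration
#'
#' Numeric choices of the preprocessing chain. Defaults: 4th-order 10 Hz
#' zero-phase low-pass (human gait energy lies below 10 Hz), Hampel outlier
#' filter (window 11, 3 sigma), candidate-cycle duration gate
#' `[min_cycle_s, max_cycle_s]`, NCC acceptance threshold, and the fixed
#' per-cycle resampling length (side length of the downstream GAF image).
#'
#' @param lowpass_cutoff_hz low-pass cutoff (Hz).
#' @param filter_order Butterworth order (attenuation exponent).
#' @param hampel_window odd window length (samples) of the outlier filter.
#' @param hampel_nsigma outlier threshold in robust sigmas.
#' @param min_cycle_s,max_cycle_s admissible cycle duration range (s),
#'   `0 < min < max`.
#' @param ncc_threshold minimum normalized cross-correlation with the
#'   per-recording template, in `[-1, 1]`.
#' @param resample_len fixed per-cycle length after resampling (>= 2).
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(lowpass_cutoff_hz = 10, filter_order = 4L,
                                hampel_window = 11L, hampel_nsigma = 3,
                                min_cycle_s = 0.5, max_cycle_s = 2.0,
                                ncc_threshold = 0.6, resample_len = 500L) {
  if (!(min_cycle_s > 0 && min_cycle_s < max_cycle_s))
    stop("need 0 < min_cycle_s < max_cycle_s")
  if (ncc_threshold < -1 || ncc_threshold > 1)
    stop("ncc_threshold must be in [-1, 1]")
  if (resample_len < 2) stop("resample_len must be >= 2")
  if (hampel_window %% 2 == 0 || hampel_window < 3)
    stop("hampel_window must be odd and >= 3")
  structure(list(lowpass_cutoff_hz = lowpass_cutoff_hz,
                 filter_order = as.integer(filter_order),
                 hampel_window = as.integer(hampel_window),
                 hampel_nsigma = hampel_nsigma,
                 min_cycle_s = min_cycle_s, max_cycle_s = max_cycle_s,
                 ncc_threshold = ncc_threshold,
                 resample_len = as.integer(resample_len)),
            class = "segmentation_config")
}

# Butterworth low-pass design via bilinear transform, as a cascade of
# biquad sections. Each section is normalized to unit DC gain, so the
# cascade's DC gain is exactly 1. Returns a list of (b, a) coefficient
# pairs (odd orders get one first-order section).
.butter_sections <- function(order, cutoff_hz, fs) {
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)        # prewarped analog cutoff
  k <- seq_len(order)
  poles <- wc * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  zp <- (2 * fs + poles) / (2 * fs - poles)      # bilinear map
  secs <- list()
  used <- rep(FALSE, order)
  for (i in seq_len(order)) {
    if (used[i]) next
    if (abs(Im(zp[i])) < 1e-12) {                # real pole: 1st order
      a1 <- -Re(zp[i])
      g <- (1 + a1) / 2
      secs[[length(secs) + 1L]] <- list(b = g * c(1, 1), a = c(1, a1))
      used[i] <- TRUE
    } else {                                     # conjugate pair: biquad
      j <- which(!used & abs(zp - Conj(zp[i])) < 1e-9)[1]
      a1 <- -2 * Re(zp[i]); a2 <- Mod(zp[i])^2
      g <- (1 + a1 + a2) / 4
      secs[[length(secs) + 1L]] <- list(b = g * c(1, 2, 1),
                                        a = c(1, a1, a2))
      used[c(i, j)] <- TRUE
    }
  }
  secs
}

# single-direction IIR section: MA part by convolution, AR part recursive
.iir_apply <- function(x, b, a) {
  u <- as.numeric(stats::filter(c(rep(0, length(b) - 1L), x), b,
                                method = "convolution", sides = 1))
  u <- u[-seq_len(length(b) - 1L)]
  if (length(a) > 1L)
    u <- as.numeric(stats::filter(u, -a[-1], method = "recursive"))
  u
}

#' Zero-phase Butterworth low-pass filter
#'
#' Standard forward-backward (zero-phase) Butterworth filtering: the filter
#' is designed by the bilinear transform, applied as a cascade of unit-DC
#' biquad sections forward and then backward over the time-reversed signal,
#' which squares the magnitude response
#' (`1 / (1 + (f/fc)^(2*order))`) and cancels the phase. Edge transients
#' are suppressed by odd-reflection padding at both ends. Length is
#' preserved and the DC gain is exactly 1.
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz cutoff frequency, `0 < cutoff_hz < fs/2`.
#' @param order Butterworth order (default 4).
#' @return filtered numeric vector, same length as `x`.
#' @export
lowpass_filter <- function(x, fs, cutoff_hz, order = 4L) {
  if (!(cutoff_hz > 0 && cutoff_hz < fs / 2))
    stop("cutoff_hz must satisfy 0 < cutoff_hz < fs/2 (Nyquist)")
  n <- length(x)
  if (n < 4) return(x)
  secs <- .butter_sections(order, cutoff_hz, fs)
  pad <- min(n - 1L, 24L * order)
  xp <- c(2 * x[1] - x[(pad + 1L):2L],             # odd reflection
          x,
          2 * x[n] - x[(n - 1L):(n - pad)])
  for (s in secs) xp <- .iir_apply(xp, s$b, s$a)   # forward
  xp <- rev(xp)
  for (s in secs) xp <- .iir_apply(xp, s$b, s$a)   # backward
  rev(xp)[pad + seq_len(n)]
}

#' Hampel outlier filter
#'
#' Replaces samples deviating from the centered rolling median by more than
#' `nsigma * 1.4826 * MAD` (MAD = rolling median absolute deviation from
#' that median) with the rolling median; all other samples are unchanged.
#' The first and last half-window samples have no centered window and pass
#' through untouched (the usual Hampel convention; a truncated one-sided
#' window would flag legitimate edge slopes). A locally constant window has
#' MAD 0 and deviation 0, which never exceeds the threshold, so constant
#' stretches pass through unchanged.
#'
#' @param x numeric vector.
#' @param window odd window length >= 3, not larger than `length(x)`.
#' @param nsigma threshold in robust standard deviations.
#' @return numeric vector with outliers replaced.
#' @export
remove_outliers <- function(x, window = 11L, nsigma = 3) {
  n <- length(x)
  if (window %% 2 == 0 || window < 3) stop("window must be odd and >= 3")
  if (window > n) stop("window larger than sequence")
  half <- (window - 1L) %/% 2L
  out <- x
  if (n < 2L * half + 1L) return(out)
  for (i in (half + 1L):(n - half)) {
    w <- x[(i - half):(i + half)]
    med <- stats::median(w)
    mad0 <- stats::median(abs(w - med))
    if (abs(x[i] - med) > nsigma * 1.4826 * mad0) out[i] <- med
  }
  out
}

#' Signal vector magnitude (SVM1)
#'
#' Per-sample root-sum-of-squares of the three accelerometer axes,
#' `sqrt(ax^2 + ay^2 + az^2)`. (Not a Support Vector Machine.)
#'
#' @param ax,ay,az equal-length numeric vectors.
#' @return nonnegative numeric vector.
#' @export
compute_svm1 <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop("axis length mismatch")
  sqrt(ax^2 + ay^2 + az^2)
}

#' Detect salient points (local minima) of the SVM1 series
#'
#' Salient points are strict interior local minima
#' (`x[i-1] > x[i] < x[i+1]`). When two minima are closer than
#' `min_separation` samples, the deeper (smaller-valued) one is kept, ties
#' broken toward the earlier index; the returned ascending indices are
#' pairwise at least `min_separation` apart.
#'
#' @param svm1 numeric vector.
#' @param min_separation minimum index distance between kept minima (>= 1).
#' @return integer vector of 1-based indices (possibly empty).
#' @export
detect_salient_points <- function(svm1, min_separation = 1L) {
  if (min_separation < 1) stop("min_separation must be >= 1")
  n <- length(svm1)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1L)
  cand <- i[svm1[i - 1L] > svm1[i] & svm1[i] < svm1[i + 1L]]
  if (length(cand) == 0L || min_separation == 1L) return(cand)
  ord <- cand[order(svm1[cand], cand)]    # by depth, ties -> earlier index
  kept <- integer(0)
  for (j in ord) {
    if (all(abs(kept - j) >= min_separation)) kept <- c(kept, j)
  }
  sort(kept)
}

#' Candidate gait cycles from consecutive salient points
#'
#' Consecutive salient-point pairs define half-open candidate cycles
#' `[start, end)` (1-based start index, exclusive end). Candidates whose
#' duration `(end - start)/fs` falls outside
#' `[min_cycle_s, max_cycle_s]` are dropped.
#'
#' @param salient_points ascending integer indices.
#' @param fs sampling rate (Hz).
#' @param config a [segmentation_config()].
#' @return two-column integer matrix (`start`, `end`), zero rows if fewer
#'   than two salient points survive.
#' @export
segment_cycles <- function(salient_points, fs, config = segmentation_config()) {
  if (is.unsorted(salient_points, strictly = TRUE))
    stop("salient points must be strictly ascending")
  m <- length(salient_points)
  if (m < 2L)
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  start <- salient_points[-m]
  end <- salient_points[-1L]
  dur <- (end - start) / fs
  keep <- dur >= config$min_cycle_s & dur <= config$max_cycle_s
  cbind(start = start[keep], end = end[keep])
}

#' Normalized cross-correlation
#'
#' Pearson-type similarity
#' `sum((t - mean(t)) * (c - mean(c))) / (||t - mean(t)|| * ||c - mean(c)||)`
#' in `[-1, 1]`; invariant under positive affine maps of either argument.
#'
#' @param template,candidate equal-length, non-constant numeric vectors.
#' @return scalar in `[-1, 1]`.
#' @export
ncc <- function(template, candidate) {
  if (length(template) != length(candidate)) stop("length mismatch")
  tc <- template - mean(template)
  cc <- candidate - mean(candidate)
  nt <- sqrt(sum(tc^2)); ncd <- sqrt(sum(cc^2))
  if (nt == 0 || ncd == 0) stop("constant input: NCC undefined (zero norm)")
  max(-1, min(1, sum(tc * cc) / (nt * ncd)))
}

#' Resample a multichannel cycle window to a fixed length
#'
#' Per-row linear interpolation onto `target_len` equally spaced points
#' spanning the original support; endpoints are preserved exactly.
#'
#' @param window numeric matrix, channels x m with m >= 2.
#' @param target_len output length >= 2.
#' @return channels x `target_len` matrix.
#' @export
resample_cycle <- function(window, target_len) {
  if (!is.matrix(window) || ncol(window) < 2)
    stop("window must be a matrix with at least 2 columns")
  if (target_len < 2) stop("target_len must be >= 2")
  m <- ncol(window)
  xout <- seq(1, m, length.out = target_len)
  t(apply(window, 1, function(r) stats::approx(seq_len(m), r, xout)$y))
}

#' Validate candidate cycles against the per-recording template by NCC
#'
#' The template is the SVM1 profile of the median-duration candidate,
#' resampled to `config$resample_len`. Every candidate's resampled SVM1
#' profile is scored against it by [ncc()]; candidates scoring at least
#' `config$ncc_threshold` are kept and returned as `gait_cycle` objects
#' holding the resampled triaxial window.
#'
#' @param axes 3 x n numeric matrix of (filtered, cleaned) accelerometer
#'   axes.
#' @param svm1 the corresponding SVM1 series.
#' @param segments matrix from [segment_cycles()].
#' @param fs sampling rate (Hz).
#' @param config a [segmentation_config()].
#' @param source_id,label,subject_id metadata attached to emitted cycles.
#' @return list of `gait_cycle` objects (possibly empty).
#' @export
validate_cycles <- function(axes, svm1, segments, fs,
                            config = segmentation_config(),
                            source_id = "rec", label = "sober",
                            subject_id = "s01") {
  if (nrow(segments) == 0L) return(list())
  dur <- segments[, "end"] - segments[, "start"]
  med_i <- which.min(abs(dur - stats::median(dur)))
  prof <- function(i) {
    idx <- segments[i, "start"]:(segments[i, "end"] - 1L)
    resample_cycle(matrix(svm1[idx], nrow = 1), config$resample_len)[1, ]
  }
  template <- prof(med_i)
  out <- list()
  for (i in seq_len(nrow(segments))) {
    cand <- prof(i)
    score <- tryCatch(ncc(template, cand), error = function(e) -Inf)
    if (score >= config$ncc_threshold) {
      idx <- segments[i, "start"]:(segments[i, "end"] - 1L)
      win <- resample_cycle(axes[, idx, drop = FALSE], config$resample_len)
      cyc <- structure(
        list(source_id = source_id,
             cycle_id = sprintf("%s_c%03d", source_id, i),
             start_idx = segments[i, "start"],
             end_idx = segments[i, "end"],
             window = win, ncc_score = score,
             label = label, subject_id = subject_id),
        class = "gait_cycle")
      out[[cyc$cycle_id]] <- cyc
    }
  }
  out
}

#' Preprocess one recording into validated gait cycles
#'
#' Full chain: per-axis zero-phase low-pass filter, Hampel outlier removal,
#' SVM1 computation, salient-point detection (minimum separation
#' `round(min_cycle_s * fs)` samples), consecutive-pair segmentation with
#' the duration gate, and NCC template validation.
#'
#' @param rec a `sensor_recording`.
#' @param config a [segmentation_config()].
#' @return list of `gait_cycle` objects.
#' @export
preprocess_recording <- function(rec, config = segmentation_config()) {
  stopifnot(inherits(rec, "sensor_recording"))
  filt <- function(x)
    remove_outliers(
      lowpass_filter(x, rec$fs, config$lowpass_cutoff_hz,
                     config$filter_order),
      config$hampel_window, config$hampel_nsigma)
  axes <- rbind(x = filt(rec$ax), y = filt(rec$ay), z = filt(rec$az))
  svm1 <- compute_svm1(axes[1, ], axes[2, ], axes[3, ])
  sp <- detect_salient_points(svm1,
                              max(1L, round(config$min_cycle_s * rec$fs)))
  segs <- segment_cycles(sp, rec$fs, config)
  validate_cycles(axes, svm1, segs, rec$fs, config,
                  source_id = rec$id, label = rec$label,
                  subject_id = rec$subject_id)
}

#' Preprocess a list of recordings
#'
#' @param recs list of `sensor_recording`.
#' @param config a [segmentation_config()].
#' @return a `cycle_set`: list with `cycles` (flat list of `gait_cycle`)
#'   and the `config` used.
#' @export
preprocess_dataset <- function(recs, config = segmentation_config()) {
  cycles <- list()
  for (r in recs) cycles <- c(cycles, preprocess_recording(r, config))
  structure(list(cycles = cycles, config = config), class = "cycle_set")
}

#' @export
print.cycle_set <- function(x, ...) {
  labs <- vapply(x$cycles, function(c) c$label, character(1))
  cat(sprintf("<cycle_set> %d cycles (resample_len=%d): %s\n",
              length(x$cycles), x$config$resample_len,
              paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                    collapse = ", ")))
  invisible(x)
}

#' Cycle-level summary table
#'
#' @param cs a `cycle_set`.
#' @return data.frame with one row per cycle (ids, indices, NCC score,
#'   label).
#' @export
cycle_report <- function(cs) {
  do.call(rbind, lapply(cs$cycles, function(c) data.frame(
    cycle_id = c$cycle_id, source_id = c$source_id,
    subject_id = c$subject_id, start_idx = c$start_idx,
    end_idx = c$end_idx, ncc_score = c$ncc_score, label = c$label,
    stringsAsFactors = FALSE)))
}
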