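#' Synthetic ECG trace with known R-peak times
#'
#' Template-based generator: each beat is a narrow positive R deflection with
#' smaller P and T humps (Gaussian bumps at -0.20 s and +0.30 s relative to
#' the R apex), repeated at jittered RR intervals with optional additive
#' Gaussian noise. Beat apices are snapped to the sample grid and recorded as
#' ground truth.
#'
#' @param duration seconds.
#' @param hr_bpm mean heart rate, in (30, 200).
#' @param hr_jitter_sd sd of the Gaussian RR-interval jitter (seconds).
#' @param noise_sd sd of the additive sample noise.
#' @param seed optional integer seed.
#' @param sample_rate Hz (default 500, the acquisition rate of the original
#'   system).
#' @param amplitude scale of the whole template (R apex height).
#' @param first_peak time of the first R apex (seconds).
#' @return `ecg_trace` list: `sample_rate`, `samples`, `true_r_times`.
#' @export
synth_ecg <- function(duration, hr_bpm = 60, hr_jitter_sd = 0, noise_sd = 0,
                      seed = NULL, sample_rate = 500, amplitude = 1,
                      first_peak = 0.5) {
  stopifnot(duration > 0, sample_rate > 0)
  if (hr_bpm <= 30 || hr_bpm >= 200) {
    stop("hr_bpm must lie in (30, 200)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rr <- 60 / hr_bpm
  beats <- numeric(0)
  t <- first_peak
  while (t <= duration) {
    beats <- c(beats, t)
    step <- rr + if (hr_jitter_sd > 0) rnorm(1, 0, hr_jitter_sd) else 0
    t <- t + max(step, 0.3)  # floor keeps RR physiological under jitter
  }
  beats <- round(beats * sample_rate) / sample_rate  # snap apices to samples
  n <- floor(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  x <- numeric(n)
  bump <- function(center, amp, width) {
    idx <- which(tt >= center - 4 * width & tt <= center + 4 * width)
    x[idx] <<- x[idx] + amp * exp(-0.5 * ((tt[idx] - center) / width)^2)
  }
  for (b in beats) {
    bump(b - 0.20, 0.15 * amplitude, 0.040)  # P
    bump(b, 1.00 * amplitude, 0.012)          # R
    bump(b + 0.30, 0.30 * amplitude, 0.060)  # T
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  structure(list(sample_rate = sample_rate, samples = x,
                 true_r_times = beats[beats <= (n - 1) / sample_rate]),
            class = "ecg_trace")
}

ecg_duration <- function(trace) length(trace$samples) / trace$sample_rate

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward application of a low-pass Butterworth filter (default
#' fourth order), giving zero phase shift and an effective doubling of the
#' magnitude response order. Output length equals input length.
#'
#' @param trace `ecg_trace`.
#' @param order filter order (default 4).
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency.
#' @return filtered `ecg_trace` (ground-truth peak times carried over).
#' @export
lowpass_zero_phase <- function(trace, order = 4, cutoff = 25) {
  stopifnot(inherits(trace, "ecg_trace"))
  nyq <- trace$sample_rate / 2
  if (cutoff <= 0 || cutoff >= nyq) {
    stop("cutoff must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  trace$samples <- as.numeric(signal::filtfilt(bf, trace$samples))
  trace
}

#' Calibrate the R-peak threshold from a priming window
#'
#' The detector is primed on the first stretch of the filtered signal
#' (default 10 s): the threshold is a fraction (default 0.6) of a high
#' quantile of the amplitude observed in that window. The default 99.5th
#' percentile is a robust stand-in for the R-apex amplitude (the signal
#' spends well under 0.5% of its time near the apex at any plausible heart
#' rate), so the threshold lands at about 60% of the R height - strictly
#' between the T-wave and R-wave amplitudes of a clean trace. Lower
#' quantiles (e.g. 0.95) sit on the T-wave shoulder and misfire on T waves.
#'
#' @param filtered filtered `ecg_trace`.
#' @param priming_duration seconds (> 0).
#' @param fraction multiplier on the reference amplitude.
#' @param quantile_prob quantile of the priming-window amplitude used as the
#'   reference (default 0.995).
#' @return list with `threshold`, `priming_duration`, `fraction`,
#'   `quantile_prob`.
#' @export
calibrate_threshold <- function(filtered, priming_duration = 10,
                                fraction = 0.6, quantile_prob = 0.995) {
  stopifnot(inherits(filtered, "ecg_trace"), priming_duration > 0,
            quantile_prob > 0, quantile_prob <= 1)
  if (ecg_duration(filtered) < priming_duration) {
    stop("trace is shorter than the priming window", call. = FALSE)
  }
  nwin <- floor(priming_duration * filtered$sample_rate)
  win <- filtered$samples[seq_len(nwin)]
  list(threshold = fraction * unname(quantile(win, quantile_prob)),
       priming_duration = priming_duration, fraction = fraction,
       quantile_prob = quantile_prob)
}

#' Detect R peaks by threshold plus derivative turn
#'
#' Single left-to-right pass over the filtered samples: while the signal is
#' above the threshold and the detector is armed, a peak is flagged at the
#' sample where the first difference falls to zero or changes sign from
#' positive (the apex); the detector then disarms for the refractory
#' interval. Peaks inside the priming window (`exclude_before`) are not
#' reported.
#'
#' @param filtered filtered `ecg_trace`.
#' @param threshold amplitude threshold (see [calibrate_threshold()]).
#' @param refractory seconds the detector stays disarmed after a peak
#'   (default 0.25).
#' @param exclude_before suppress events before this time (seconds),
#'   typically the priming duration.
#' @return data frame with `sample_index` (1-based) and `time` (seconds,
#'   `(sample_index - 1) / sample_rate`).
#' @export
detect_rpeaks <- function(filtered, threshold, refractory = 0.25,
                          exclude_before = 0) {
  stopifnot(inherits(filtered, "ecg_trace"), refractory >= 0)
  x <- filtered$samples
  n <- length(x)
  fs <- filtered$sample_rate
  if (n < 3) return(data.frame(sample_index = integer(0), time = numeric(0)))
  dx <- diff(x)
  # apex candidates: previous difference positive, current zero or negative,
  # amplitude above threshold
  apex <- which(dx[-1] <= 0 & dx[-(n - 1)] > 0 & x[2:(n - 1)] > threshold) + 1L
  keep <- logical(length(apex))
  last_time <- -Inf
  for (j in seq_along(apex)) {
    tj <- (apex[j] - 1) / fs
    if (tj - last_time >= refractory) {
      keep[j] <- TRUE
      last_time <- tj
    }
  }
  apex <- apex[keep]
  times <- (apex - 1) / fs
  sel <- times >= exclude_before
  data.frame(sample_index = apex[sel], time = times[sel])
}

#' Fixed-timestep opacity and particle schedule
#'
#' Emulates the renderer's fixed 50 Hz loop: at each timestep boundary, if at
#' least one R-peak flag arrived since the previous boundary the body image
#' is set to full opacity and a particle pulse is released; otherwise the
#' opacity decays (by default subtractively, 2 percentage points of full
#' scale per step, floored at 0) and the particle intensity fades linearly to
#' zero over `particle_fade` seconds. A flag raised exactly on a boundary is
#' consumed at the next boundary.
#'
#' @param event_times R-peak flag times in seconds.
#' @param duration schedule length in seconds.
#' @param timestep seconds per frame (default 0.02).
#' @param decay_per_step opacity lost per non-reset step (default 0.02).
#' @param particle_fade particle fade-out time in seconds (default 0.5).
#' @param decay_mode `"subtract"` (default) or `"multiply"` (opacity scaled
#'   by `1 - decay_per_step` per step).
#' @param initial_opacity opacity before the first event (default 1).
#' @return data frame with `time`, `opacity`, `particle_intensity`, `reset`
#'   (logical flag-consumption marker), one row per timestep boundary.
#' @export
schedule_frames <- function(event_times, duration, timestep = 0.02,
                            decay_per_step = 0.02, particle_fade = 0.5,
                            decay_mode = c("subtract", "multiply"),
                            initial_opacity = 1) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(timestep > 0, decay_per_step >= 0, particle_fade > 0,
            duration > 0)
  n_frames <- floor(duration / timestep + 1e-6)
  eps <- 1e-6
  frame_of <- floor(event_times / timestep + eps) + 1L
  has_event <- tabulate(frame_of[frame_of >= 1 & frame_of <= n_frames],
                        nbins = n_frames) > 0
  op <- numeric(n_frames)
  pi_ <- numeric(n_frames)
  cur <- initial_opacity
  last_release <- -Inf
  for (i in seq_len(n_frames)) {
    ti <- i * timestep
    if (has_event[i]) {
      cur <- 1
      last_release <- ti
    } else {
      cur <- if (decay_mode == "subtract") max(0, cur - decay_per_step) else
        cur * (1 - decay_per_step)
    }
    op[i] <- cur
    pi_[i] <- max(0, 1 - (ti - last_release) / particle_fade)
  }
  data.frame(time = seq_len(n_frames) * timestep, opacity = op,
             particle_intensity = pi_, reset = has_event)
}

#' Flash-latency audit against ground truth
#'
#' Matches each ground-truth R-peak time to the first opacity-reset frame
#' within `match_window` after it. Latency is frame time minus true peak
#' time; true peaks with no matching reset count as missed, and reset frames
#' matching no true peak count as spurious. Peaks and resets before
#' `exclude_before` (typically the priming window) are ignored.
#'
#' @param true_r_times ground-truth R-peak times (seconds).
#' @param schedule frame schedule from [schedule_frames()].
#' @param match_window maximum accepted latency in seconds (default 0.06).
#' @param exclude_before seconds to drop from the start.
#' @return `fbi_latency` list: `per_peak_latency_ms`, `matched`, `missed`,
#'   `spurious`, `median_ms`, `min_ms`, `max_ms`, plus sensitivity and
#'   precision.
#' @export
latency_report <- function(true_r_times, schedule, match_window = 0.06,
                           exclude_before = 0) {
  if (length(true_r_times) == 0) {
    stop("no ground-truth R-peak times supplied", call. = FALSE)
  }
  peaks <- true_r_times[true_r_times >= exclude_before]
  resets <- schedule$time[schedule$reset & schedule$time >= exclude_before]
  used <- logical(length(resets))
  lat <- numeric(0)
  missed <- 0L
  for (tp in peaks) {
    j <- which(!used & resets >= tp - 1e-9 &
                 resets <= tp + match_window + 1e-9)
    if (length(j) == 0) {
      missed <- missed + 1L
    } else {
      used[j[1]] <- TRUE
      # snap to whole microseconds: the times are grid multiples and the
      # subtraction otherwise leaks float dust into the millisecond report
      lat <- c(lat, round((resets[j[1]] - tp) * 1e6) / 1e6)
    }
  }
  matched <- length(lat)
  structure(list(
    per_peak_latency_ms = lat * 1000,
    matched = matched, missed = missed, spurious = sum(!used),
    median_ms = if (matched > 0) stats::median(lat) * 1000 else NA_real_,
    min_ms = if (matched > 0) min(lat) * 1000 else NA_real_,
    max_ms = if (matched > 0) max(lat) * 1000 else NA_real_,
    sensitivity = matched / length(peaks),
    precision = if (matched + sum(!used) > 0)
      matched / (matched + sum(!used)) else NA_real_),
    class = "fbi_latency")
}

#' @export
print.fbi_latency <- function(x, ...) {
  cat(sprintf(
    "<fbi_latency> matched %d, missed %d, spurious %d; latency ms: median %.1f [%.1f, %.1f]\n",
    x$matched, x$missed, x$spurious, x$median_ms, x$min_ms, x$max_ms))
  invisible(x)
}

#' Full cardio-visual synchrony pipeline
#'
#' Runs the offline emulation of the real-time system end to end: zero-phase
#' low-pass filtering, threshold calibration on the priming window, R-peak
#' detection, block-wise flag availability (detections become visible to the
#' renderer at the end of their processing block, emulating the real-time
#' constraint that a non-causal zero-phase filter cannot look ahead), frame
#' scheduling, and a latency audit against the trace's ground truth.
#'
#' With the default 0.02 s block and 0.02 s timestep each flash lands 20-40
#' ms after the true R apex: up to one block for the flag to surface plus one
#' timestep for the renderer to consume it.
#'
#' @param trace `ecg_trace` with ground-truth peak times.
#' @param cutoff,order filter parameters (see [lowpass_zero_phase()]).
#' @param priming_duration,threshold_fraction calibration parameters.
#' @param refractory detector refractory interval in seconds.
#' @param block processing-block length in seconds (default one timestep).
#' @param timestep,decay_per_step,particle_fade renderer parameters.
#' @param match_window latency audit window in seconds.
#' @return list with `filtered`, `threshold`, `events`, `available_times`,
#'   `schedule`, `report`.
#' @export
sync_pipeline <- function(trace, cutoff = 25, order = 4,
                          priming_duration = 10, threshold_fraction = 0.6,
                          refractory = 0.25, block = 0.02, timestep = 0.02,
                          decay_per_step = 0.02, particle_fade = 0.5,
                          match_window = 0.06) {
  stopifnot(inherits(trace, "ecg_trace"))
  if (is.null(trace$true_r_times)) {
    stop("trace has no ground-truth R-peak times", call. = FALSE)
  }
  filtered <- lowpass_zero_phase(trace, order = order, cutoff = cutoff)
  cal <- calibrate_threshold(filtered, priming_duration = priming_duration,
                             fraction = threshold_fraction)
  events <- detect_rpeaks(filtered, cal$threshold, refractory = refractory,
                          exclude_before = priming_duration)
  avail <- ceiling(events$time / block - 1e-6) * block
  schedule <- schedule_frames(avail, duration = ecg_duration(trace),
                              timestep = timestep,
                              decay_per_step = decay_per_step,
                              particle_fade = particle_fade)
  report <- latency_report(trace$true_r_times, schedule,
                           match_window = match_window,
                           exclude_before = priming_duration)
  list(filtered = filtered, threshold = cal$threshold, events = events,
       available_times = avail, schedule = schedule, report = report)
}

#' Read/write ECG traces and frame schedules
#'
#' Traces are two-column CSV files (`time_s`, `amplitude`) with an optional
#' ground-truth sidecar (one `r_time_s` column); schedules are CSV with
#' `time_s`, `opacity`, `particle_intensity`.
#'
#' @param trace `ecg_trace`.
#' @param path output CSV path.
#' @param sidecar optional path for the ground-truth peak times.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(trace, path, sidecar = NULL) {
  stopifnot(inherits(trace, "ecg_trace"))
  tt <- (seq_along(trace$samples) - 1) / trace$sample_rate
  write.csv(data.frame(time_s = tt, amplitude = trace$samples), path,
            row.names = FALSE)
  if (!is.null(sidecar)) {
    write.csv(data.frame(r_time_s = trace$true_r_times), sidecar,
              row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ecg
#' @export
read_ecg <- function(path, sidecar = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "amplitude") %in% names(df)))
  dt <- diff(df$time_s)
  fs <- 1 / stats::median(dt)
  truth <- if (!is.null(sidecar)) read.csv(sidecar)$r_time_s else NULL
  structure(list(sample_rate = fs, samples = df$amplitude,
                 true_r_times = truth), class = "ecg_trace")
}
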