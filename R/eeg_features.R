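# Canonical band edges (Hz). Gamma is capped at the 50 Hz filter ceiling.
EEG_BANDS <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                  beta = c(13, 30), gamma = c(30, 50))

# Default aggregation sets: frontal-midline theta, frontal-parietal gamma.
THETA_CHANNELS <- c("Fz", "FCz", "Cz")
GAMMA_CHANNELS <- c("F3", "F4", "Fz", "P3", "P4", "Pz")

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fourth-order Butterworth band-pass (default 1--50 Hz)
#' forward-backward per channel. Forward-backward filtering cancels phase
#' distortion (band power is phase-blind but epoch alignment is not) at the
#' cost of doubling the effective filter order.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param order Butterworth order of the underlying one-pass design.
#' @return A filtered `eeg_recording` of identical shape.
#' @export
bandpass_filter <- function(recording, low = 1, high = 50, order = 4) {
  stopifnot(inherits(recording, "eeg_recording"))
  nyq <- recording$fs / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("band edges must satisfy 0 < low < high < fs/2 = %g Hz", nyq),
         call. = FALSE)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filtered <- t(apply(recording$samples, 1L, function(x) signal::filtfilt(bf, x)))
  if (ncol(recording$samples) == 1L) filtered <- t(filtered)
  eeg_recording(filtered, recording$fs, recording$channel_labels,
                recording$condition)
}

#' Split a recording into non-overlapping epochs
#'
#' Cuts the recording into `floor(T / epoch_seconds)` consecutive
#' half-open windows; a trailing remainder shorter than one epoch is
#' dropped.
#'
#' @param recording An [eeg_recording()].
#' @param epoch_seconds Epoch length in seconds.
#' @return A list of channels-by-samples matrices, each carrying the
#'   channel labels as row names.
#' @export
epoch_recording <- function(recording, epoch_seconds = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  len <- floor(epoch_seconds * recording$fs)
  n <- ncol(recording$samples)
  if (len < 1L || n < len)
    stop(sprintf("recording too short: %d samples, need at least %d for one epoch",
                 n, len), call. = FALSE)
  k <- n %/% len
  lapply(seq_len(k), function(i) {
    ep <- recording$samples[, ((i - 1L) * len + 1L):(i * len), drop = FALSE]
    rownames(ep) <- recording$channel_labels
    ep
  })
}

#' Per-channel mean removal within an epoch
#'
#' The minimal baseline correction available for continuous sessions
#' without a pre-stimulus interval: subtract each channel's epoch mean, so
#' slow offsets do not leak into low-frequency power.
#'
#' @param epoch Channels-by-samples matrix.
#' @return The demeaned epoch (channel means zero to within 1e-10).
#' @export
baseline_correct <- function(epoch) {
  epoch <- as.matrix(epoch)
  sweep(epoch, 1L, rowMeans(epoch))
}

#' Welch power spectral density of one epoch
#'
#' FFT-based one-sided PSD per channel: Hann-windowed 1-second segments
#' with 50% overlap, averaged (Welch). For epochs shorter than one second
#' the whole epoch forms a single segment. Scaling is such that the
#' integral of the PSD over frequency approximates the signal variance
#' (Parseval).
#'
#' @param epoch Channels-by-samples matrix (>= 2 samples).
#' @param fs Sampling rate, Hz.
#' @return An object of class `psd_spectrum`: `frequencies` (Hz, strictly
#'   increasing) and `power` (channels-by-frequencies matrix, uV^2/Hz).
#' @export
compute_psd <- function(epoch, fs) {
  epoch <- as.matrix(epoch)
  n <- ncol(epoch)
  if (n < 2L) stop("epoch must contain at least 2 samples", call. = FALSE)
  seg <- min(as.integer(round(fs)), n)
  step <- max(1L, seg %/% 2L)
  starts <- seq(1L, n - seg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(seg) - 1) / seg)  # periodic Hann
  u <- sum(w^2)
  n_freq <- seg %/% 2L + 1L
  freqs <- (seq_len(n_freq) - 1) * fs / seg
  scale <- rep(2, n_freq)               # one-sided doubling ...
  scale[1L] <- 1                        # ... except DC
  if (seg %% 2L == 0L) scale[n_freq] <- 1  # ... and Nyquist
  power <- matrix(0, nrow(epoch), n_freq)
  for (s0 in starts) {
    segm <- epoch[, s0:(s0 + seg - 1L), drop = FALSE]
    ft <- t(apply(segm, 1L, function(x) stats::fft(x * w)[seq_len(n_freq)]))
    if (nrow(epoch) == 1L) ft <- matrix(ft, 1L)
    power <- power + sweep(Mod(ft)^2, 2L, scale, `*`) / (fs * u)
  }
  power <- power / length(starts)
  rownames(power) <- rownames(epoch)
  structure(list(frequencies = freqs, power = power), class = "psd_spectrum")
}

#' Band power by trapezoidal integration of a PSD
#'
#' Integrates the PSD over `[low, high]` per channel, linearly
#' interpolating the band edges onto the frequency grid so that adjacent
#' bands are exactly additive: `band_power(a, b) + band_power(b, c) =
#' band_power(a, c)`.
#'
#' @param psd A `psd_spectrum` from [compute_psd()].
#' @param band Numeric `c(low, high)` in Hz, inside the PSD's range.
#' @return Named numeric vector of per-channel powers (uV^2).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd_spectrum"))
  low <- band[[1]]; high <- band[[2]]
  f <- psd$frequencies
  if (!(low < high)) stop("empty frequency band", call. = FALSE)
  if (low < f[1L] || high > f[length(f)])
    stop(sprintf("band [%g, %g] outside PSD range [%g, %g]",
                 low, high, f[1L], f[length(f)]), call. = FALSE)
  apply(psd$power, 1L, function(p) {
    inner <- f > low & f < high
    knots <- c(low, f[inner], high)
    vals <- c(stats::approx(f, p, xout = low)$y, p[inner],
              stats::approx(f, p, xout = high)$y)
    sum(diff(knots) * (utils::head(vals, -1L) + utils::tail(vals, -1L)) / 2)
  })
}

#' Time-domain descriptors of an epoch
#'
#' Per-channel mean, standard deviation, skewness and excess kurtosis
#' (population moment definitions). Descriptive only: downstream modelling
#' uses spectral features. For constant channels (sd = 0) the shape
#' moments are undefined and returned as `NA`.
#'
#' @param epoch Channels-by-samples matrix with at least 4 samples.
#' @return `data.frame` with columns `channel`, `mean`, `sd`, `skewness`,
#'   `kurtosis` (excess).
#' @export
time_domain_descriptors <- function(epoch) {
  epoch <- as.matrix(epoch)
  if (ncol(epoch) < 4L) stop("need at least 4 samples per channel", call. = FALSE)
  labels <- rownames(epoch)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(epoch)))
  out <- t(apply(epoch, 1L, function(x) {
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) return(c(m, 0, NA_real_, NA_real_))
    z <- (x - m) / (stats::sd(x) * sqrt((length(x) - 1) / length(x)))
    c(m, s, mean(z^3), mean(z^4) - 3)
  }))
  data.frame(channel = labels, mean = out[, 1L], sd = out[, 2L],
             skewness = out[, 3L], kurtosis = out[, 4L],
             row.names = NULL, stringsAsFactors = FALSE)
}

# Filter -> epoch -> baseline-correct -> Welch PSD -> band power,
# averaged over epochs; returns the per-channel mean band power.
recording_band_power <- function(recording, band, epoch_seconds = 2,
                                 filter_low = 1, filter_high = 50) {
  filtered <- bandpass_filter(recording, filter_low, filter_high)
  epochs <- epoch_recording(filtered, epoch_seconds)
  per_epoch <- vapply(epochs, function(ep) {
    band_power(compute_psd(baseline_correct(ep), recording$fs), band)
  }, numeric(nrow(recording$samples)))
  if (nrow(recording$samples) == 1L)
    per_epoch <- matrix(per_epoch, 1L, dimnames = list(recording$channel_labels))
  stats::setNames(rowMeans(per_epoch), recording$channel_labels)
}

#' Raw pre-to-post band-power change scores
#'
#' Runs the full spectral pipeline (band-pass filter, 2-s epochs, baseline
#' correction, Welch PSD, band-power integration, epoch averaging) on both
#' recordings, averages over the named channel sets, and returns the raw
#' post-minus-pre differences. Change scores are deliberately left
#' unstandardized.
#'
#' @param pre,post [eeg_recording()] objects sharing labels and sampling
#'   rate.
#' @param theta_channels Channel set averaged for the theta (4--8 Hz)
#'   score; defaults to the frontal-midline set.
#' @param gamma_channels Channel set for the gamma (30--50 Hz) score;
#'   defaults to the frontal-parietal set.
#' @param epoch_seconds Epoch length for the spectral pipeline.
#' @return List of class `change_scores`: `theta_change`, `gamma_change`
#'   (uV^2 differences).
#' @examples
#' pair <- generate_eeg_pair(duration = 8, theta_multiplier = 1.5, seed = 7)
#' change_scores(pair$pre, pair$post)
#' @export
change_scores <- function(pre, post,
                          theta_channels = THETA_CHANNELS,
                          gamma_channels = GAMMA_CHANNELS,
                          epoch_seconds = 2) {
  stopifnot(inherits(pre, "eeg_recording"), inherits(post, "eeg_recording"))
  if (!identical(pre$channel_labels, post$channel_labels) || pre$fs != post$fs)
    stop("pre and post recordings must share channel labels and sampling rate",
         call. = FALSE)
  for (set_name in c("theta_channels", "gamma_channels")) {
    wanted <- get(set_name)
    missing_ch <- setdiff(wanted, pre$channel_labels)
    if (length(missing_ch) > 0L)
      stop(sprintf("%s not found in recording: %s", set_name,
                   paste(missing_ch, collapse = ", ")), call. = FALSE)
  }
  band_change <- function(band, chans) {
    post_p <- recording_band_power(post, band, epoch_seconds)
    pre_p <- recording_band_power(pre, band, epoch_seconds)
    mean(post_p[chans]) - mean(pre_p[chans])
  }
  structure(list(theta_change = band_change(EEG_BANDS$theta, theta_channels),
                 gamma_change = band_change(EEG_BANDS$gamma, gamma_channels)),
            class = "change_scores")
}

#' Full band-power summary for one recording
#'
#' Per-channel absolute power in each canonical band (delta, theta, alpha,
#' beta, gamma), plus the two aggregate scores used downstream.
#'
#' @inheritParams change_scores
#' @param recording An [eeg_recording()].
#' @return List of class `band_power_summary`: `per_band` (bands-by-channel
#'   matrix), `aggregate_theta`, `aggregate_gamma`.
#' @export
band_power_summary <- function(recording,
                               theta_channels = THETA_CHANNELS,
                               gamma_channels = GAMMA_CHANNELS,
                               epoch_seconds = 2) {
  stopifnot(inherits(recording, "eeg_recording"))
  per_band <- t(vapply(EEG_BANDS, function(b) {
    recording_band_power(recording, b, epoch_seconds)
  }, numeric(nrow(recording$samples))))
  colnames(per_band) <- recording$channel_labels
  structure(list(
    per_band = per_band,
    aggregate_theta = mean(per_band["theta", intersect(theta_channels, colnames(per_band))]),
    aggregate_gamma = mean(per_band["gamma", intersect(gamma_channels, colnames(per_band))]),
    condition = recording$condition
  ), class = "band_power_summary")
}
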