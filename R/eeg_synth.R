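# 32-channel 10-20-style montage used by the synthetic generator; includes
# the frontal-midline (Fz, FCz, Cz) and frontal-parietal (F3/F4/P3/P4/Pz)
# sites the default aggregation sets need.
EEG_MONTAGE_32 <- c(
  "Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
  "FC5", "FC1", "FCz", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
  "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
  "PO3", "PO4", "O1", "O2"
)

#' EEG recording container
#'
#' @param samples Channels-by-time numeric matrix (microvolts).
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels One label per row of `samples`.
#' @param condition `"pre"` or `"post"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, channel_labels, condition = c("pre", "post")) {
  condition <- match.arg(condition)
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples))
    stop("'samples' must be a numeric matrix without missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("'fs' must be a single positive sampling rate", call. = FALSE)
  if (length(channel_labels) != nrow(samples))
    stop("need one channel label per row of 'samples'", call. = FALSE)
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$condition, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

# Band-limited Gaussian noise: white noise FFT-masked to [low, high] Hz and
# rescaled to the target standard deviation.
band_limited_noise <- function(n, fs, low, high, sd_target) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  mask <- f >= low & f <= high
  spec <- stats::fft(x)
  spec[!mask] <- 0
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y / s * sd_target
}

# 1/f-weighted ("pink") background noise, rescaled to the target sd.
pink_noise <- function(n, fs, sd_target) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  w <- ifelse(f > 0, 1 / sqrt(pmax(f, 1 / n)), 0)
  spec <- stats::fft(x) * w
  y <- Re(stats::fft(spec, inverse = TRUE)) / n
  y / stats::sd(y) * sd_target
}

#' Generate a matched pre/post pair of synthetic EEG recordings
#'
#' Each channel is 1/f-weighted background noise plus band-limited theta
#' (4--8 Hz) and gamma (30--50 Hz) components. The post recording shares
#' every component with the pre recording, but its theta and gamma
#' component amplitudes are scaled by the square root of the corresponding
#' multiplier, so band *power* scales by the multiplier itself. A
#' multiplier of 1 therefore leaves the band unchanged, above 1 raises its
#' post-session power, below 1 lowers it.
#'
#' @param channels Number of channels (1--32; labelled from the fixed
#'   10-20-style montage).
#' @param fs Sampling rate, Hz (>= 128).
#' @param duration Recording length in seconds (>= 4, i.e. at least two
#'   analysis epochs).
#' @param theta_multiplier,gamma_multiplier Positive post/pre band-power
#'   ratios.
#' @param seed Integer seed.
#' @param background_sd,theta_sd,gamma_sd Component amplitudes in
#'   microvolts (defaults approximate resting scalp EEG proportions).
#' @return `list(pre = , post = )` of [eeg_recording()] objects.
#' @examples
#' pair <- generate_eeg_pair(channels = 4, duration = 6, seed = 1)
#' pair$pre
#' @export
generate_eeg_pair <- function(channels = 32L, fs = 128, duration = 30,
                              theta_multiplier = 1, gamma_multiplier = 1,
                              seed = 42L,
                              background_sd = 10, theta_sd = 5, gamma_sd = 3) {
  if (fs < 128) stop("'fs' must be at least 128 Hz", call. = FALSE)
  if (duration < 4) stop("'duration' must be at least 4 s (two epochs)", call. = FALSE)
  if (theta_multiplier <= 0 || gamma_multiplier <= 0)
    stop("band-power multipliers must be positive", call. = FALSE)
  channels <- as.integer(channels)
  if (channels < 1L || channels > length(EEG_MONTAGE_32))
    stop("'channels' must be between 1 and ", length(EEG_MONTAGE_32), call. = FALSE)
  labels <- EEG_MONTAGE_32[seq_len(channels)]
  n <- round(fs * duration)

  local_seed(as.integer(seed) %% .Machine$integer.max, {
    pre <- matrix(0, channels, n)
    post <- matrix(0, channels, n)
    for (ch in seq_len(channels)) {
      bg <- pink_noise(n, fs, background_sd)
      th <- band_limited_noise(n, fs, 4, 8, theta_sd)
      gm <- band_limited_noise(n, fs, 30, 50, gamma_sd)
      pre[ch, ] <- bg + th + gm
      post[ch, ] <- bg + sqrt(theta_multiplier) * th + sqrt(gamma_multiplier) * gm
    }
    list(pre = eeg_recording(pre, fs, labels, "pre"),
         post = eeg_recording(post, fs, labels, "post"))
  })
}

#' Write or read a recording as CSV plus JSON sidecar
#'
#' The CSV holds one column per channel (sample index implicit); the
#' sidecar records the sampling rate, channel labels and condition.
#'
#' @param recording An [eeg_recording()].
#' @param path CSV path; the sidecar is written at `paste0(path, ".json")`.
#' @return `read_eeg_recording()` returns an `eeg_recording`;
#'   `write_eeg_recording()` returns `path` invisibly.
#' @export
write_eeg_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  df <- as.data.frame(t(recording$samples))
  names(df) <- recording$channel_labels
  utils::write.csv(format_numeric_frame(df), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = recording$fs, channel_labels = recording$channel_labels,
         condition = recording$condition),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_eeg_recording
#' @export
read_eeg_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), meta$fs, meta$channel_labels, meta$condition)
}
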