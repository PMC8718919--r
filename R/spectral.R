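#' Construct a multichannel EEG recording
#'
#' Container for a resting-state recording: a channels-by-samples numeric
#' matrix in microvolts, sampling rate, ordered 10-20 channel labels,
#' recording condition (eyes closed or eyes open) and subject id.
#'
#' @param data numeric matrix, channels in rows, samples in columns (µV).
#' @param fs sampling rate in Hz.
#' @param channel_labels channel names; validated against [montage_1020()].
#' @param condition \code{"EC"} or \code{"EO"}.
#' @param subject_id identifier string.
#' @return Object of class \code{eeg_recording}.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          condition = c("EC", "EO"),
                          subject_id = "subject") {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  if (fs <= 0) stop("fs must be positive")
  if (length(channel_labels) != nrow(data))
    stop("channel_labels length must match the number of rows of data")
  if (anyNA(data)) stop("recording contains missing samples")
  channel_labels <- normalize_channel_label(channel_labels)
  rownames(data) <- channel_labels
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 condition = condition, subject_id = subject_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s [%s]: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  invisible(x)
}

#' Read an EEG matrix from CSV
#'
#' Reads a plain numeric CSV whose header row holds channel labels and
#' whose rows are consecutive samples.
#'
#' @param path CSV file path.
#' @param fs sampling rate in Hz (CSV carries no rate).
#' @param condition,subject_id stored on the recording;
#'   \code{subject_id} defaults to the file name.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, fs, condition = "EC",
                         subject_id = sub("\\.csv$", "", basename(path))) {
  df <- utils::read.csv(path, check.names = FALSE)
  eeg_recording(t(as.matrix(df)), fs = fs, channel_labels = names(df),
                condition = condition, subject_id = subject_id)
}

#' Write an EEG recording to CSV
#'
#' @param rec an [eeg_recording()].
#' @param path output CSV path (header = channel labels, rows = samples).
#' @export
write_eeg_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Smooth raised-cosine step from 0 at x <= 0 to 1 at x >= 1.
raised_cosine <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  0.5 - 0.5 * cos(pi * x)
}

#' Band-pass, notch and common-average-reference an EEG recording
#'
#' Zero-phase frequency-domain filtering: the two-sided spectrum of each
#' channel is multiplied by a real transfer function that passes
#' \code{bandpass} with raised-cosine transitions and removes a narrow
#' notch around the mains frequency; the filtered channels are then
#' re-referenced to the common average (CAR), after which the mean across
#' channels is zero at every sample. Defaults follow standard clinical
#' resting-state practice: 1--45.5 Hz band-pass and a mains notch (60 Hz
#' here; set \code{notch = 50} for 50 Hz mains).
#'
#' @param rec an [eeg_recording()].
#' @param bandpass numeric length 2, pass-band edges in Hz.
#' @param notch mains frequency in Hz, or \code{NULL} to skip.
#' @param notch_width full stop-band width of the notch in Hz.
#' @param transition transition width of the band-pass edges in Hz.
#' @param car apply common-average re-referencing (default TRUE).
#' @return The filtered [eeg_recording()].
#' @export
preprocess <- function(rec, bandpass = c(1, 45.5), notch = 60,
                       notch_width = 2, transition = 0.5, car = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (bandpass[2] >= nyq)
    stop("upper band edge ", bandpass[2], " Hz requires fs > ",
         2 * bandpass[2], " Hz")
  n <- ncol(rec$data)
  f <- seq(0, rec$fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, rec$fs - f)
  H <- raised_cosine((f - (bandpass[1] - transition)) / transition) *
    (1 - raised_cosine((f - bandpass[2]) / transition))
  if (!is.null(notch) && notch < nyq) {
    half <- notch_width / 2
    H <- H * (1 - (raised_cosine((f - (notch - half - transition)) / transition) *
                     (1 - raised_cosine((f - (notch + half)) / transition))))
  }
  X <- stats::mvfft(t(rec$data))
  filtered <- t(Re(stats::mvfft(X * H, inverse = TRUE)) / n)
  if (car) filtered <- sweep(filtered, 2, colMeans(filtered))
  rec$data <- filtered
  rownames(rec$data) <- rec$channel_labels
  rec
}

#' Split a recording into epochs and reject high-amplitude ones
#'
#' Cuts the recording into non-overlapping epochs and drops any epoch in
#' which any channel exceeds the amplitude threshold. This is a declared
#' simple stand-in for subspace-based artifact rejection: it removes gross
#' movement/electrode artifacts but not stereotyped ocular or myogenic
#' components.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_len epoch length in seconds (default 4).
#' @param amp_thresh rejection threshold in µV (default 100).
#' @return List of class \code{eeg_epochs}: \code{epochs} (list of
#'   channels-by-samples matrices), \code{fs}, \code{channel_labels},
#'   \code{retained} (indices kept), \code{n_total}, \code{subject_id}.
#' @export
epoch_and_reject <- function(rec, epoch_len = 4, amp_thresh = 100) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(epoch_len * rec$fs)
  if (ncol(rec$data) < len)
    stop("recording shorter than one epoch (", epoch_len, " s)")
  n_total <- floor(ncol(rec$data) / len)
  epochs <- lapply(seq_len(n_total), function(i) {
    rec$data[, ((i - 1) * len + 1):(i * len), drop = FALSE]
  })
  keep <- vapply(epochs, function(e) max(abs(e)) <= amp_thresh, logical(1))
  if (!any(keep))
    stop("no epochs retained for subject ", rec$subject_id,
         " (all exceeded ", amp_thresh, " µV)")
  structure(list(epochs = epochs[keep], fs = rec$fs,
                 channel_labels = rec$channel_labels,
                 retained = which(keep), n_total = n_total,
                 subject_id = rec$subject_id),
            class = "eeg_epochs")
}

#' Welch power spectral density of epoched EEG
#'
#' Averaged modified periodogram: each epoch is divided into Hann-tapered
#' segments of \code{window_len} seconds with the given fractional overlap,
#' segments are mean-detrended, and their one-sided periodograms are
#' averaged across segments and epochs. The frequency resolution is
#' \code{1/window_len} Hz and the estimate is non-negative everywhere;
#' integrating it over frequency recovers the signal variance (Parseval).
#'
#' @param epochs an \code{eeg_epochs} object from [epoch_and_reject()], or
#'   a single [eeg_recording()] (treated as one epoch).
#' @param window_len segment length in seconds (default 2).
#' @param overlap fractional overlap between segments in \code{[0, 1)}
#'   (default 0.5).
#' @return List of class \code{eeg_psd}: \code{freq} (Hz), \code{psd}
#'   (channels x frequencies, µV²/Hz), \code{fs}, \code{channel_labels},
#'   \code{n_segments}.
#' @export
welch_psd <- function(epochs, window_len = 2, overlap = 0.5) {
  if (inherits(epochs, "eeg_recording")) {
    epochs <- structure(list(epochs = list(epochs$data), fs = epochs$fs,
                             channel_labels = epochs$channel_labels,
                             retained = 1L, n_total = 1L,
                             subject_id = epochs$subject_id),
                        class = "eeg_epochs")
  }
  stopifnot(inherits(epochs, "eeg_epochs"))
  fs <- epochs$fs
  L <- round(window_len * fs)
  if (any(vapply(epochs$epochs, ncol, integer(1)) < L))
    stop("window_len exceeds the epoch length")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, round(L * (1 - overlap)))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / (L + 1))  # Hann
  U <- sum(w^2)
  nfreq <- L %/% 2 + 1
  acc <- matrix(0, nrow = length(epochs$channel_labels), ncol = nfreq)
  nseg <- 0L
  for (e in epochs$epochs) {
    starts <- seq(1L, ncol(e) - L + 1L, by = step)
    for (s in starts) {
      seg <- e[, s:(s + L - 1L), drop = FALSE]
      seg <- seg - rowMeans(seg)
      X <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
      pxx <- (Mod(X[seq_len(nfreq), , drop = FALSE])^2) / (fs * U)
      pxx[2:(nfreq - 1L), ] <- 2 * pxx[2:(nfreq - 1L), ]
      acc <- acc + t(pxx)
      nseg <- nseg + 1L
    }
  }
  structure(list(freq = seq(0, fs / 2, length.out = nfreq),
                 psd = acc / nseg, fs = fs,
                 channel_labels = epochs$channel_labels,
                 n_segments = nseg, subject_id = epochs$subject_id),
            class = "eeg_psd")
}

#' Integrate a PSD over a frequency band
#'
#' Trapezoidal integral of the power spectral density over \code{[low,
#' high]}; adjacent bands share their edge frequency so that contiguous
#' bands add up to the integral over their union without double counting.
#'
#' @param psd an \code{eeg_psd} from [welch_psd()] (or any list with
#'   \code{freq} and a channels-by-frequencies \code{psd} matrix).
#' @param band a band name from [band_definitions()], a numeric
#'   \code{c(low, high)} in Hz, or a one-row band-definition data frame.
#' @return Named numeric vector of band power (µV²), one entry per channel.
#' @export
band_power <- function(psd, band) {
  if (is.character(band)) {
    check_band(band)
    bd <- band_definitions()
    band <- c(bd$low[bd$band == band], bd$high[bd$band == band])
  } else if (is.data.frame(band)) {
    band <- c(band$low, band$high)
  }
  lo <- band[1]; hi <- band[2]
  if (lo < min(psd$freq) || hi > max(psd$freq))
    stop("band [", lo, ", ", hi, "] Hz outside the PSD frequency grid [",
         min(psd$freq), ", ", max(psd$freq), "] Hz")
  sel <- psd$freq >= lo & psd$freq <= hi
  f <- psd$freq[sel]
  p <- psd$psd[, sel, drop = FALSE]
  if (length(f) < 2) stop("band narrower than the frequency resolution")
  dw <- diff(f)
  out <- as.numeric(p[, -length(f), drop = FALSE] %*% dw +
                      p[, -1, drop = FALSE] %*% dw) / 2
  names(out) <- rownames(psd$psd) %||% psd$channel_labels
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the band-power feature table from a set of recordings
#'
#' Runs epoching/rejection, Welch spectral estimation and band-power
#' integration for every recording, then natural-log-transforms the
#' absolute power (the transform that removes the strong right skew of
#' power across ages). Subjects whose recordings retain no clean epoch are
#' skipped with a warning rather than aborting the cohort.
#'
#' @param recordings list of (already preprocessed) [eeg_recording()]
#'   objects with unique subject ids.
#' @param bands band-definition table (default [band_definitions()]).
#' @param epoch_len,amp_thresh epoching parameters, see
#'   [epoch_and_reject()].
#' @param window_len,overlap Welch parameters, see [welch_psd()].
#' @return Data frame with one row per (subject, channel, band):
#'   \code{id}, \code{channel}, \code{band}, \code{power_uv2},
#'   \code{log_power}, \code{n_epochs_used}.
#' @export
build_band_power_table <- function(recordings, bands = band_definitions(),
                                   epoch_len = 4, amp_thresh = 100,
                                   window_len = 2, overlap = 0.5) {
  ids <- vapply(recordings, function(r) r$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- list()
  for (rec in recordings) {
    ep <- tryCatch(epoch_and_reject(rec, epoch_len, amp_thresh),
                   error = function(e) {
                     warning("skipping subject ", rec$subject_id, ": ",
                             conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(ep)) next
    psd <- welch_psd(ep, window_len, overlap)
    for (bi in seq_len(nrow(bands))) {
      p <- band_power(psd, bands[bi, ])
      rows[[length(rows) + 1L]] <- data.frame(
        id = rec$subject_id, channel = rec$channel_labels,
        band = bands$band[bi], power_uv2 = unname(p),
        log_power = ifelse(p > 0, log(p), NA_real_),
        n_epochs_used = length(ep$retained),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
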