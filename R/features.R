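#' High-frequency envelope of bipolar SEEG
#'
#' Per contact, the signal is (1) high-pass filtered at 50 Hz (zero-phase
#' 2nd-order Butterworth), (2) squared, (3) smoothed with a centered moving
#' average of 50 ms, (4) log-transformed, (5) low-pass filtered at 5 Hz
#' (zero-phase 2nd-order Butterworth), and (6) normalized to `[0, 1]`.  The
#' log uses `log(p + eps)` with `eps` a small fraction of the recording-wide
#' maximum smoothed power, so silent channels sit on a common floor and the
#' cross-channel amplitude ordering (the spatial information the inversion
#' relies on) survives the log; normalization is accordingly global
#' (min-max over the whole montage) by default, with a per-contact option.
#'
#' @param rec A bipolar `seeg_recording`.
#' @param fs Sampling rate (Hz); defaults to `1000 / rec$dt`.
#' @param hp_freq,lp_freq High-/low-pass cutoffs (Hz).
#' @param ma_window Moving-average window (ms).
#' @param eps_rel `eps` as a fraction of the recording-wide maximum power.
#' @param per_contact If TRUE, normalize each contact separately instead of
#'   globally.
#' @param edge_ms Zero-phase filters ring at the recording boundaries; the
#'   smoothed power over the first and last `edge_ms` is clamped to the value
#'   at the edge of the valid zone before the log.
#' @return Contacts x samples envelope matrix in `[0, 1]`; all-constant
#'   channels are flagged via the `degenerate` attribute and mapped to zeros
#'   under per-contact normalization.
#' @export
seeg_envelope <- function(rec, fs = NULL, hp_freq = 50, lp_freq = 5,
                          ma_window = 50, eps_rel = 1e-3,
                          per_contact = FALSE, edge_ms = 100) {
  if (rec$montage != "bipolar") stop("envelope expects a bipolar recording")
  x <- rec$signal
  if (is.null(fs)) fs <- 1000 / rec$dt
  if (ncol(x) < 0.1 * fs) stop("need at least 100 ms of signal")
  degenerate <- apply(x, 1, function(r) diff(range(r)) == 0)
  bh <- signal::butter(2, hp_freq / (fs / 2), type = "high")
  bl <- signal::butter(2, lp_freq / (fs / 2), type = "low")
  nw <- max(1L, round(ma_window / 1000 * fs))
  p <- x
  ne <- min(round(edge_ms / 1000 * fs), floor(ncol(x) / 4))
  pad_hp <- round(0.1 * fs)            # ~5 cycles of the 50 Hz cutoff
  pad_lp <- round(fs)                  # ~5 cycles of the 5 Hz cutoff
  for (i in seq_len(nrow(x))) {
    hp <- filtfilt_padded(bh, x[i, ], pad_hp)
    pi <- moving_average(hp^2, nw)
    if (ne > 0) {
      pi[seq_len(ne)] <- pi[ne + 1]
      pi[ncol(x) - seq_len(ne) + 1] <- pi[ncol(x) - ne]
    }
    p[i, ] <- pi
  }
  eps <- eps_rel * max(p)
  if (eps == 0) eps <- .Machine$double.xmin
  env <- log(p + eps)
  for (i in seq_len(nrow(env))) {
    env[i, ] <- filtfilt_padded(bl, env[i, ], pad_lp)
  }
  env[degenerate, ] <- 0
  if (per_contact) {
    for (i in seq_len(nrow(env))) {
      if (degenerate[i]) next
      rg <- range(env[i, ])
      if (diff(rg) == 0) {
        degenerate[i] <- TRUE
        env[i, ] <- 0
      } else {
        env[i, ] <- (env[i, ] - rg[1]) / diff(rg)
      }
    }
  } else if (!all(degenerate)) {
    rg <- range(env[!degenerate, ])
    if (diff(rg) == 0) {
      degenerate[] <- TRUE
      env[] <- 0
    } else {
      env[!degenerate, ] <- (env[!degenerate, , drop = FALSE] - rg[1]) /
        diff(rg)
    }
  }
  attr(env, "degenerate") <- degenerate
  env
}

# zero-phase filtering with mirror padding: filtfilt starts from zero initial
# conditions, so without padding a signal with nonzero boundary values rings
# violently at both ends
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(filt, xp)
  y[pad + seq_len(n)]
}

# centered moving average via cumulative sums; the window shrinks at the
# edges so no samples are lost
moving_average <- function(x, n) {
  if (n <= 1) return(x)
  N <- length(x)
  half <- n %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(N) - half, 1)
  hi <- pmin(seq_len(N) + (n - half - 1), N)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Detect the ictal window from envelope traces
#'
#' The detection trace is the across-contact maximum of the envelopes; the
#' window runs from the first up-crossing `t_up` to the last down-crossing
#' `t_down` of the threshold, extended by half the ictal duration
#' `d = t_down - t_up` on each side and clipped to the recording.
#'
#' @param env Contacts x samples envelope matrix.
#' @param time Sample times (ms).
#' @param threshold Detection threshold on the normalized envelope.
#' @return List `t_up`, `t_down`, `d_ictal`, `window` (= `c(start, end)` ms,
#'   clipped).
#' @export
detect_ictal_window <- function(env, time, threshold = 0.1) {
  m <- apply(env, 2, max)
  above <- m >= threshold
  if (!any(above)) stop("no seizure detected: envelope never crosses threshold")
  t_up <- time[which(above)[1]]
  t_down <- time[tail(which(above), 1)]
  if (t_down <= t_up) stop("degenerate ictal window")
  d <- t_down - t_up
  window <- c(max(time[1], t_up - d / 2), min(time[length(time)], t_down + d / 2))
  list(t_up = t_up, t_down = t_down, d_ictal = d, window = window)
}

#' Crop to the ictal window and resample to a fixed length
#'
#' Linear-interpolation resampling of the cropped envelopes onto `n` uniform
#' samples; affine segments are reproduced exactly and upsampling of short
#' windows is allowed.
#'
#' @param env Contacts x samples envelope matrix.
#' @param time Sample times (ms).
#' @param window Length-2 window (ms) from [detect_ictal_window()].
#' @param n Output sample count (default 512).
#' @return A `data_features` object: `x` (contacts x n in `[0, 1]`),
#'   `window`, `time` (the n resampled times, ms).
#' @export
crop_resample <- function(env, time, window, n = 512) {
  if (window[1] < time[1] - 1e-9 || window[2] > time[length(time)] + 1e-9) {
    stop("window outside recording")
  }
  tt <- seq(window[1], window[2], length.out = n)
  out <- matrix(0, nrow(env), n)
  for (i in seq_len(nrow(env))) {
    out[i, ] <- approx(time, env[i, ], xout = tt, rule = 2)$y
  }
  structure(list(x = out, window = window, time = tt),
            class = "data_features")
}

#' Full data-feature pipeline for one recording
#'
#' Envelope extraction, ictal-window detection, and fixed-length resampling
#' in one call.
#'
#' @param rec A bipolar `seeg_recording`.
#' @param n Output sample count.
#' @param threshold Ictal detection threshold.
#' @param ... Passed to [seeg_envelope()].
#' @return A `data_features` object.
#' @export
extract_features <- function(rec, n = 512, threshold = 0.1, ...) {
  env <- seeg_envelope(rec, ...)
  time <- rec$dt * seq_len(ncol(env))
  win <- detect_ictal_window(env, time, threshold)
  crop_resample(env, time, win$window, n = n)
}

#' Write / read data features as CSV with a JSON sidecar
#' @param features A `data_features`.
#' @param path CSV path (sidecar at `<path>.json`).
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` returns a `data_features`.
#' @export
write_features_csv <- function(features, path) {
  write.csv(features$x, path, row.names = FALSE)
  jsonlite::write_json(list(window = features$window),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  x <- as.matrix(read.csv(path))
  dimnames(x) <- NULL
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(x = x, window = side$window,
                 time = seq(side$window[1], side$window[2],
                            length.out = ncol(x))),
            class = "data_features")
}
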