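#' Baseline calibration of evoked trials
#'
#' EEG recorded while a subject merely rests still contains ongoing activity
#' unrelated to the stimulus. Calibration removes it: the pre-stimulus
#' baseline epoch is averaged (per channel, per sample within the epoch;
#' for the usual single epoch the average is the epoch itself), tiled to
#' span the stimulus window — e.g. a 3 s baseline replicated 20 times over
#' 60 s — and subtracted sample-wise from the stimulus-period signal. Any
#' component that is periodic with the baseline length (such as a constant
#' recording artifact) cancels exactly.
#'
#' @param ts a `crgcn_trialset` whose trials start with
#'   `baseline_seconds` of baseline followed by the stimulus window
#' @param stimulus_seconds stimulus length, s; must be an integer multiple of
#'   `baseline_seconds` (otherwise the replication count is undefined);
#'   defaults to all post-baseline samples
#' @return a `crgcn_trialset` containing only the calibrated stimulus data
#'   (`baseline_seconds` set to 0)
#' @export
calibrate_baseline <- function(ts, stimulus_seconds = NULL) {
  stopifnot(inherits(ts, "crgcn_trialset"))
  fs <- ts$sampling_rate
  nb <- as.integer(round(ts$baseline_seconds * fs))
  if (nb < 1L)
    stop("calibrate_baseline: trial set has no baseline window")
  n_smp <- dim(ts$data)[3L]
  if (is.null(stimulus_seconds)) stimulus_seconds <- (n_smp - nb) / fs
  ns <- as.integer(round(stimulus_seconds * fs))
  if (nb + ns > n_smp)
    stop("calibrate_baseline: trial length ", n_smp,
         " < baseline + stimulus samples (", nb + ns, ")")
  reps <- ns / nb
  if (abs(reps - round(reps)) > 1e-9)
    stop("calibrate_baseline: stimulus length (", stimulus_seconds,
         " s) is not an integer multiple of the baseline length (",
         ts$baseline_seconds, " s); replication count undefined")
  reps <- as.integer(round(reps))

  d <- ts$data
  n_tr <- dim(d)[1L]; n_ch <- dim(d)[2L]
  out <- array(0, dim = c(n_tr, n_ch, ns))
  tile_idx <- rep(seq_len(nb), times = reps)
  for (tr in seq_len(n_tr)) {
    base <- d[tr, , seq_len(nb), drop = FALSE][1L, , ]  # n_ch x nb
    stim <- d[tr, , nb + seq_len(ns), drop = FALSE][1L, , ]
    out[tr, , ] <- stim - base[, tile_idx, drop = FALSE]
  }
  trialset(out, ts$ratings, fs, baseline_seconds = 0,
           subject_id = ts$subject_id)
}

#' Sliding-window segmentation
#'
#' Partitions each trial's stimulus data into overlapping windows of length
#' `window_seconds` starting every `stride_seconds`:
#' `floor((stimulus_seconds - T) / S) + 1` segments per trial (T = 6 s,
#' S = 3 s give 19 segments of a 60 s stimulus). Windows are sample-aligned
#' half-open intervals; no partial trailing window is emitted.
#'
#' @param ts a calibrated `crgcn_trialset` (`baseline_seconds = 0`)
#' @param window_seconds window length T, s
#' @param stride_seconds stride S, s
#' @return a `crgcn_segmentset`: list with `segments` (array
#'   `trials x n_segments x channels x window_samples`), `window_seconds`,
#'   `stride_seconds`, `sampling_rate`, `ratings`, `trial` bookkeeping
#' @export
segment_trials <- function(ts, window_seconds = 6, stride_seconds = 3) {
  stopifnot(inherits(ts, "crgcn_trialset"))
  if (ts$baseline_seconds != 0)
    stop("segment_trials: calibrate_baseline() first (trial set still ",
         "contains a baseline window)")
  fs <- ts$sampling_rate
  n_smp <- dim(ts$data)[3L]
  stim_sec <- n_smp / fs
  if (window_seconds > stim_sec)
    stop("segment_trials: window (", window_seconds,
         " s) exceeds stimulus duration (", stim_sec, " s)")
  if (stride_seconds <= 0) stop("segment_trials: stride must be > 0")
  wn <- window_seconds * fs
  sn <- stride_seconds * fs
  if (abs(wn - round(wn)) > 1e-9 || abs(sn - round(sn)) > 1e-9)
    stop("segment_trials: window/stride must give integer sample counts at ",
         fs, " Hz")
  wn <- as.integer(round(wn)); sn <- as.integer(round(sn))
  n_seg <- floor((n_smp - wn) / sn) + 1L

  n_tr <- dim(ts$data)[1L]; n_ch <- dim(ts$data)[2L]
  seg <- array(0, dim = c(n_tr, n_seg, n_ch, wn))
  for (s in seq_len(n_seg)) {
    idx <- (s - 1L) * sn + seq_len(wn)
    seg[, s, , ] <- ts$data[, , idx]
  }
  structure(list(segments = seg, window_seconds = window_seconds,
                 stride_seconds = stride_seconds, sampling_rate = fs,
                 ratings = ts$ratings, subject_id = ts$subject_id),
            class = "crgcn_segmentset")
}

#' @export
print.crgcn_segmentset <- function(x, ...) {
  d <- dim(x$segments)
  cat("<crgcn_segmentset> ", d[1L], " trials x ", d[2L], " segments x ",
      d[3L], " channels x ", d[4L], " samples (T = ", x$window_seconds,
      " s, S = ", x$stride_seconds, " s)\n", sep = "")
  invisible(x)
}

#' Binarize affect ratings
#'
#' Maps continuous 1-9 ratings on the chosen axis to binary classes:
#' above `threshold` is positive/high (1), below is negative/low (0).
#' Ratings exactly at the threshold follow `tie_rule` (only strict
#' inequalities are inherent to the scale; the default assigns ties to the
#' low class).
#'
#' @param ratings `trials x 4` matrix (valence, arousal, dominance, liking)
#'   or a numeric vector of ratings on one axis
#' @param axis `"valence"` or `"arousal"` (ignored for vector input)
#' @param threshold split point on the 1-9 scale (default 5)
#' @param tie_rule class for ratings exactly at the threshold: `"low"`
#'   (default) or `"high"`
#' @return integer vector of 0/1 labels, one per trial
#' @export
binarize_labels <- function(ratings, axis = c("valence", "arousal"),
                            threshold = 5, tie_rule = c("low", "high")) {
  axis <- match.arg(axis)
  tie_rule <- match.arg(tie_rule)
  r <- if (is.matrix(ratings))
    ratings[, if (axis == "valence") 1L else 2L] else as.numeric(ratings)
  if (any(r < 1 | r > 9))
    stop("binarize_labels: ratings must lie in [1, 9]")
  lab <- as.integer(r > threshold)
  if (tie_rule == "high") lab[r == threshold] <- 1L
  lab
}
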