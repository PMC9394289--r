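#' Configuration for the synthetic DEAP-layout EEG generator
#'
#' Describes a synthetic recording session shaped like one DEAP subject file:
#' `n_trials_per_subject` trials of `baseline_seconds + stimulus_seconds`
#' multichannel EEG at `sampling_rate`, with per-trial affect ratings. The
#' generator plants the statistical structure the classifier consumes:
#'
#' * 1/f-shaped broadband noise whose inter-channel correlation decays
#'   exponentially with electrode distance at scale `spatial_corr_scale`;
#' * band-limited theta/alpha/beta/gamma oscillations whose amplitudes are
#'   scaled per trial class through `band_effect`;
#' * a group of distant channels (`corr_group`) driven mostly by one common
#'   source, planting near-perfect inter-channel correlation for the
#'   functional-connectivity matrix to detect;
#' * per-channel multiplicative gain heterogeneity (electrode
#'   impedance/contact variability) of log-scale sd `channel_gain_sd`,
#'   a feature-scale confound that z-score normalization removes;
#' * a trial-invariant additive artifact (period = `baseline_seconds`) of
#'   amplitude `baseline_artifact_amp`, present in both baseline and stimulus
#'   windows, which baseline calibration must cancel exactly.
#'
#' @param n_subjects number of subjects a dataset built from this config has
#' @param n_trials_per_subject trials per subject (DEAP: 40)
#' @param n_channels EEG channels (>= 2; DEAP: 32)
#' @param sampling_rate Hz (DEAP preprocessed: 128)
#' @param baseline_seconds pre-stimulus baseline length, s
#' @param stimulus_seconds stimulus length, s
#' @param band_effect named list mapping band name to a length-2 numeric
#'   `c(class0, class1)` amplitude multiplier; default doubles gamma
#'   amplitude for class 1
#' @param band_base_amp named numeric, baseline oscillation amplitude per
#'   band, microvolts
#' @param noise_amp broadband 1/f noise standard deviation, microvolts
#' @param spatial_corr_scale decay length (unit head radii) of inter-channel
#'   noise correlation
#' @param corr_group integer channel indices sharing a common source
#'   (defaults to the distant frontal/parietal/occipital set Fp1, Fp2, P7,
#'   P8, O1, O2 in the 32-channel DEAP ordering)
#' @param corr_group_purity fraction of common-source variance in corr_group
#'   channels (their pairwise signal correlation)
#' @param channel_gain_sd log-normal sd of per-channel gains (0 disables)
#' @param baseline_artifact_amp artifact amplitude, microvolts (0 disables)
#' @param seed integer RNG seed
#' @return a `crgcn_synth_config` list
#' @export
synth_config <- function(n_subjects = 4,
                         n_trials_per_subject = 40,
                         n_channels = 32,
                         sampling_rate = 128,
                         baseline_seconds = 3,
                         stimulus_seconds = 60,
                         band_effect = list(theta = c(1, 1), alpha = c(1, 1),
                                            beta = c(1, 1), gamma = c(1, 2)),
                         band_base_amp = c(theta = 6, alpha = 8,
                                           beta = 4, gamma = 3),
                         noise_amp = 10,
                         spatial_corr_scale = 0.4,
                         corr_group = c(1L, 17L, 12L, 30L, 14L, 32L),
                         corr_group_purity = 0.995,
                         channel_gain_sd = 0.3,
                         baseline_artifact_amp = 15,
                         seed = 1L) {
  total <- (baseline_seconds + stimulus_seconds) * sampling_rate
  if (abs(total - round(total)) > 1e-9)
    stop("synth_config: (baseline + stimulus) x sampling_rate must be an ",
         "integer number of samples, got ", total)
  if (n_channels < 2) stop("synth_config: n_channels must be >= 2")
  stopifnot(sampling_rate > 0, baseline_seconds > 0, stimulus_seconds > 0,
            noise_amp > 0, spatial_corr_scale > 0,
            all(unlist(band_effect) > 0), all(band_base_amp > 0),
            corr_group_purity > 0, corr_group_purity <= 1,
            channel_gain_sd >= 0, baseline_artifact_amp >= 0)
  corr_group <- corr_group[corr_group <= n_channels]
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_subject = as.integer(n_trials_per_subject),
                 n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate,
                 baseline_seconds = baseline_seconds,
                 stimulus_seconds = stimulus_seconds,
                 band_effect = band_effect,
                 band_base_amp = band_base_amp,
                 noise_amp = noise_amp,
                 spatial_corr_scale = spatial_corr_scale,
                 corr_group = as.integer(corr_group),
                 corr_group_purity = corr_group_purity,
                 channel_gain_sd = channel_gain_sd,
                 baseline_artifact_amp = baseline_artifact_amp,
                 seed = as.integer(seed)),
            class = "crgcn_synth_config")
}

#' Construct a trial set
#'
#' A trial set is the per-subject container of the DEAP layout: a
#' `trials x channels x samples` data array (microvolts) and a `trials x 4`
#' ratings matrix (valence, arousal, dominance, liking on 1-9).
#'
#' @param data numeric array `trials x channels x samples`
#' @param ratings numeric matrix `trials x 4`, values in 1..9
#' @param sampling_rate Hz
#' @param baseline_seconds seconds of pre-stimulus baseline at the start of
#'   each trial (0 if already calibrated)
#' @param subject_id label
#' @return a `crgcn_trialset`
#' @export
trialset <- function(data, ratings, sampling_rate, baseline_seconds,
                     subject_id = "s01") {
  if (length(dim(data)) != 3L)
    stop("trialset: data must be a trials x channels x samples array")
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != dim(data)[1L] || ncol(ratings) != 4L)
    stop("trialset: ratings must be ", dim(data)[1L],
         " x 4 (trials x valence/arousal/dominance/liking), got ",
         nrow(ratings), " x ", ncol(ratings))
  if (any(ratings < 1 | ratings > 9))
    stop("trialset: ratings must lie in [1, 9]")
  structure(list(data = data, ratings = ratings,
                 sampling_rate = sampling_rate,
                 baseline_seconds = baseline_seconds,
                 subject_id = subject_id),
            class = "crgcn_trialset")
}

#' @export
print.crgcn_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat("<crgcn_trialset> subject ", x$subject_id, ": ", d[1L], " trials x ",
      d[2L], " channels x ", d[3L], " samples @ ", x$sampling_rate, " Hz (",
      x$baseline_seconds, " s baseline)\n", sep = "")
  invisible(x)
}

# band edges used for synthesis and (by default) feature extraction
synth_bands <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             lo = c(4, 8, 13, 30), hi = c(8, 13, 30, 45))
}

#' Generate a synthetic DEAP-layout trial set
#'
#' Each trial is the sum of spatially correlated 1/f broadband noise,
#' class-modulated band-limited oscillations, a common-source component on
#' the `corr_group` channels and a trial-invariant periodic artifact; see
#' [synth_config()] for the planted structure. Ratings encode the class on
#' the valence and arousal axes as 7 (class 1) / 3 (class 0), away from the
#' binarization threshold of 5. Fully reproducible from `cfg$seed`.
#'
#' @param cfg a `crgcn_synth_config`
#' @param class_labels binary vector, one label per trial
#' @param subject_id label stored in the result
#' @return a `crgcn_trialset` with `trials x channels x samples` data
#' @export
generate_trialset <- function(cfg, class_labels,
                              subject_id = "s01") {
  stopifnot(inherits(cfg, "crgcn_synth_config"))
  if (length(class_labels) != cfg$n_trials_per_subject)
    stop("generate_trialset: expected ", cfg$n_trials_per_subject,
         " class labels (one per trial), got ", length(class_labels))
  if (!all(class_labels %in% c(0, 1)))
    stop("generate_trialset: class_labels must be binary (0/1)")

  fs <- cfg$sampling_rate
  n_ch <- cfg$n_channels
  n_smp <- as.integer(round((cfg$baseline_seconds + cfg$stimulus_seconds) * fs))
  n_tr <- cfg$n_trials_per_subject
  bands <- synth_bands()

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)

  # spatial mixing of broadband noise: exponential-decay covariance over
  # electrode distance (bundled montage when the channel count matches)
  sigma <- spatial_covariance(cfg)
  cr <- chol(sigma)

  # fixed per-subject channel gains (impedance/contact heterogeneity)
  gains <- exp(stats::rnorm(n_ch, 0, cfg$channel_gain_sd))

  freqs <- fft_freqs(n_smp, fs)
  noise_shape <- one_over_f_shape(freqs)
  band_masks <- lapply(seq_len(nrow(bands)), function(b)
    freqs >= bands$lo[b] & freqs < bands$hi[b] |
      freqs <= -bands$lo[b] & freqs > -bands$hi[b])

  # trial-invariant artifact: periodic with period = baseline_seconds so the
  # tiled-baseline subtraction cancels it exactly; deterministic per channel
  tt <- (seq_len(n_smp) - 1) / fs
  phase <- 2 * pi * seq_len(n_ch) / n_ch
  artifact <- cfg$baseline_artifact_amp *
    (cos(outer(rep(2 * pi / cfg$baseline_seconds, n_ch) , tt) +
           phase) * 0.8 + 0.2)  # oscillation plus DC offset, same every trial

  p <- cfg$corr_group_purity
  grp <- cfg$corr_group
  dat <- array(0, dim = c(n_tr, n_ch, n_smp))
  for (tr in seq_len(n_tr)) {
    cls <- class_labels[tr]
    # correlated 1/f noise: white -> spatial chol mix -> spectral shaping
    w <- matrix(stats::rnorm(n_smp * n_ch), n_smp, n_ch) %*% cr
    x <- shape_columns(w, noise_shape)
    x <- scale_columns_sd(x) * cfg$noise_amp
    # band oscillations, class-scaled amplitudes
    for (b in seq_len(nrow(bands))) {
      amp <- cfg$band_base_amp[[bands$name[b]]] *
        cfg$band_effect[[bands$name[b]]][cls + 1L]
      wb <- matrix(stats::rnorm(n_smp * n_ch), n_smp, n_ch)
      xb <- mask_columns(wb, band_masks[[b]])
      x <- x + scale_columns_sd(xb) * amp
    }
    # common source across the planted correlation group
    if (length(grp) >= 2L) {
      src <- x[, grp[1L]]
      x[, grp] <- sqrt(p) * src + sqrt(1 - p) * x[, grp]
    }
    x <- x * rep(gains, each = n_smp)
    dat[tr, , ] <- t(x) + artifact
  }

  ratings <- matrix(5, n_tr, 4L)
  ratings[, 1L] <- ifelse(class_labels == 1, 7, 3)  # valence
  ratings[, 2L] <- ifelse(class_labels == 1, 7, 3)  # arousal
  trialset(dat, ratings, fs, cfg$baseline_seconds, subject_id)
}

#' Generate a multi-subject synthetic dataset
#'
#' Draws a balanced random class assignment per subject and generates each
#' subject's trial set with a subject-specific seed derived from `cfg$seed`.
#'
#' @param cfg a `crgcn_synth_config`
#' @return list of `crgcn_trialset`, one per subject, with an attribute
#'   `labels` (list of per-subject class labels)
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "crgcn_synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_trials_per_subject
  labels <- lapply(seq_len(cfg$n_subjects), function(s) {
    l <- rep(c(0L, 1L), length.out = n)
    sample(l)
  })
  subs <- lapply(seq_len(cfg$n_subjects), function(s) {
    cfg_s <- cfg
    cfg_s$seed <- (cfg$seed + 7919L * s) %% .Machine$integer.max
    generate_trialset(cfg_s, labels[[s]], subject_id = sprintf("s%02d", s))
  })
  attr(subs, "labels") <- labels
  subs
}

# ---- helpers ----------------------------------------------------------------

spatial_covariance <- function(cfg) {
  n_ch <- cfg$n_channels
  mont <- tryCatch(default_montage(), error = function(e) NULL)
  if (!is.null(mont) && length(mont$channels) >= n_ch) {
    pos <- mont$positions[seq_len(n_ch), , drop = FALSE]
    d <- as.matrix(stats::dist(pos))
  } else {
    # fall back to a ring layout for nonstandard channel counts
    ang <- 2 * pi * seq_len(n_ch) / n_ch
    d <- as.matrix(stats::dist(cbind(cos(ang), sin(ang), 0)))
  }
  exp(-d / cfg$spatial_corr_scale)
}

fft_freqs <- function(n, fs) {
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  if (n %% 2 == 0) k <- c(0:(n / 2 - 1), -(n / 2):-1)
  k * fs / n
}

one_over_f_shape <- function(freqs) {
  f0 <- 1  # flatten below 1 Hz to keep finite power at DC-adjacent bins
  s <- 1 / sqrt(pmax(abs(freqs), f0))
  s[freqs == 0] <- 0
  s
}

# multiply each column's spectrum by `shape` and return the real signal
shape_columns <- function(x, shape) {
  sp <- stats::mvfft(x) * shape
  Re(stats::mvfft(sp, inverse = TRUE)) / nrow(x)
}

mask_columns <- function(x, mask) {
  sp <- stats::mvfft(x)
  sp[!mask, ] <- 0
  Re(stats::mvfft(sp, inverse = TRUE)) / nrow(x)
}

scale_columns_sd <- function(x) {
  s <- apply(x, 2L, stats::sd)
  s[s == 0] <- 1
  x / rep(s, each = nrow(x))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# ---- per-subject container i/o ---------------------------------------------

#' Write / read a trial set as a per-subject container file
#'
#' The container mirrors the DEAP per-subject layout: a named `data` array
#' (`trials x channels x samples`) and a named `labels` matrix
#' (`trials x 4`), plus sampling metadata, serialized with R's native `RDS`
#' format. Round-trips are bitwise exact.
#'
#' @param ts a `crgcn_trialset`
#' @param path file path
#' @return `read_trialset` returns a `crgcn_trialset`; if the stored `data`
#'   array has more channels than `n_channels_eeg`, only the first
#'   `n_channels_eeg` are exposed as EEG (DEAP files carry 40 channels of
#'   which the first 32 are EEG)
#' @export
write_trialset <- function(ts, path) {
  stopifnot(inherits(ts, "crgcn_trialset"))
  obj <- list(data = ts$data, labels = ts$ratings,
              sampling_rate = ts$sampling_rate,
              baseline_seconds = ts$baseline_seconds,
              subject_id = ts$subject_id)
  saveRDS(obj, path)
  invisible(path)
}

#' @param n_channels_eeg number of leading channels exposed as EEG
#' @rdname write_trialset
#' @export
read_trialset <- function(path, n_channels_eeg = 32L) {
  obj <- readRDS(path)
  if (!is.list(obj) || !all(c("data", "labels") %in% names(obj)))
    stop("read_trialset: malformed container (need named 'data' and ",
         "'labels' arrays): ", path)
  d <- dim(obj$data)
  if (length(d) != 3L)
    stop("read_trialset: 'data' must be trials x channels x samples, got ",
         paste(d, collapse = " x "))
  lab <- as.matrix(obj$labels)
  if (nrow(lab) != d[1L] || ncol(lab) != 4L)
    stop("read_trialset: 'labels' shaped ", nrow(lab), " x ", ncol(lab),
         ", expected ", d[1L], " x 4")
  if (d[2L] > n_channels_eeg)
    obj$data <- obj$data[, seq_len(n_channels_eeg), , drop = FALSE]
  trialset(obj$data, lab,
           sampling_rate = obj$sampling_rate %||% 128,
           baseline_seconds = obj$baseline_seconds %||% 3,
           subject_id = obj$subject_id %||% "s01")
}
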