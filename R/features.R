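#' Power spectral density of a multichannel segment
#'
#' Finite-sample estimate of the power spectral density (power per Hz,
#' one-sided, 0 to Nyquist). The default estimator is Welch's method: the
#' segment is split into `subwindow_seconds`-long Hann-tapered sub-windows
#' with `overlap` fractional overlap, each sub-window's squared-magnitude
#' Fourier spectrum is scaled by its duration, and the results are averaged.
#' `method = "periodogram"` instead computes a single untapered
#' squared-magnitude spectrum of the whole segment — the direct finite-T
#' periodogram, useful as an oracle since for a sinusoid of amplitude `a`
#' its integrated power is exactly `a^2/2` and for stochastic signals the
#' Parseval identity ties integrated PSD to time-domain variance.
#'
#' @param segment numeric matrix `channels x samples` (or a vector, taken as
#'   one channel)
#' @param fs sampling rate, Hz
#' @param method `"welch"` (default) or `"periodogram"`
#' @param subwindow_seconds Welch sub-window length, s (default 1)
#' @param overlap Welch fractional overlap in `[0, 1)` (default 0.5)
#' @param demean subtract each (sub-)window's mean before transforming
#' @return list of class `crgcn_psd` with `freq` (Hz) and `power`
#'   (`channels x n_freq` matrix, power density units)
#' @export
psd <- function(segment, fs, method = c("welch", "periodogram"),
                subwindow_seconds = 1, overlap = 0.5, demean = TRUE) {
  method <- match.arg(method)
  if (is.vector(segment)) segment <- matrix(segment, nrow = 1L)
  if (anyNA(segment) || any(!is.finite(segment)))
    stop("psd: segment contains NaN/Inf values")
  if (all(segment == 0))
    stop("psd: segment is identically zero")
  n <- ncol(segment)
  if (n < 2L) stop("psd: need >= 2 samples")
  stopifnot(fs > 0)

  if (method == "periodogram") {
    x <- t(segment)
    if (demean) x <- sweep(x, 2L, colMeans(x))
    sp <- stats::mvfft(x)
    pw <- (Mod(sp)^2) / (fs * n)           # two-sided density
    out <- one_sided(pw, n)
    return(structure(list(freq = out$freq * fs / n, power = t(out$power)),
                     class = "crgcn_psd"))
  }

  nw <- as.integer(round(subwindow_seconds * fs))
  if (nw > n) nw <- n
  step <- max(1L, as.integer(round(nw * (1 - overlap))))
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- as.numeric(signal::hanning(nw))
  u <- mean(w^2)                           # window power normalization
  n_ch <- nrow(segment)
  # stack all (sub-window x channel) slices into one FFT call
  big <- matrix(0, nw, length(starts) * n_ch)
  jj <- 0L
  for (s0 in starts) {
    sl <- t(segment[, s0 + seq_len(nw) - 1L, drop = FALSE])
    if (demean) sl <- sweep(sl, 2L, colMeans(sl))
    big[, jj + seq_len(n_ch)] <- sl * w
    jj <- jj + n_ch
  }
  sp <- stats::mvfft(big)
  pw <- (Mod(sp)^2) / (fs * nw * u)
  # average over sub-windows per channel
  avg <- matrix(rowMeans(array(pw, dim = c(nw * n_ch, length(starts)))),
                nw, n_ch)
  out <- one_sided(avg, nw)
  structure(list(freq = out$freq * fs / nw, power = t(out$power)),
            class = "crgcn_psd")
}

# fold a two-sided density (rows = FFT bins) onto 0..Nyquist
one_sided <- function(pw, n) {
  half <- floor(n / 2) + 1L
  p <- pw[seq_len(half), , drop = FALSE]
  dbl <- 2:(if (n %% 2 == 0) half - 1L else half)
  p[dbl, ] <- 2 * p[dbl, , drop = FALSE]
  list(freq = 0:(half - 1L), power = p)
}

#' @export
print.crgcn_psd <- function(x, ...) {
  cat("<crgcn_psd> ", nrow(x$power), " channels x ", length(x$freq),
      " frequencies (0-", max(x$freq), " Hz)\n", sep = "")
  invisible(x)
}

#' Default EEG band edges
#'
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz; the emotion-relevant
#' higher bands (the delta band is excluded).
#'
#' @return data.frame with columns `name`, `lo`, `hi`
#' @export
default_bands <- function() synth_bands()

#' Average PSD over frequency bands
#'
#' Mean power density across the bins whose center frequency lies in
#' `[lo, hi)`, per band per channel.
#'
#' @param p a `crgcn_psd` (from [psd()])
#' @param bands data.frame with columns `name`, `lo`, `hi`
#' @return numeric matrix `channels x bands` (columns named by band)
#' @export
band_average <- function(p, bands = default_bands()) {
  stopifnot(inherits(p, "crgcn_psd"))
  nyq <- max(p$freq)
  out <- matrix(0, nrow(p$power), nrow(bands),
                dimnames = list(NULL, bands$name))
  for (b in seq_len(nrow(bands))) {
    if (bands$lo[b] <= 0 || bands$hi[b] <= bands$lo[b] || bands$hi[b] > nyq + 1e-9)
      stop("band_average: band '", bands$name[b], "' [", bands$lo[b], ", ",
           bands$hi[b], ") outside the frequency axis (0, ", nyq, "]")
    sel <- p$freq >= bands$lo[b] & p$freq < bands$hi[b]
    if (!any(sel))
      stop("band_average: band '", bands$name[b], "' contains no ",
           "frequency bins")
    out[, b] <- rowMeans(p$power[, sel, drop = FALSE])
  }
  out
}

#' Extract the band-PSD feature cube of a segment set
#'
#' Applies [psd()] and [band_average()] to every segment of every trial and
#' stacks the results into the node-feature cube consumed by the classifier.
#'
#' @param segset a `crgcn_segmentset` (from [segment_trials()])
#' @param bands band definition data.frame
#' @param method PSD estimator, see [psd()]
#' @return list of class `crgcn_features`: `values` (array
#'   `total_segments x channels x bands`), `trial` (originating trial index
#'   per segment), `subject_id`, `ratings`, `band_names`
#' @export
extract_features <- function(segset, bands = default_bands(),
                             method = "welch") {
  stopifnot(inherits(segset, "crgcn_segmentset"))
  d <- dim(segset$segments)   # trials x segs x channels x samples
  n_total <- d[1L] * d[2L]
  vals <- array(0, dim = c(n_total, d[3L], nrow(bands)),
                dimnames = list(NULL, NULL, bands$name))
  trial <- integer(n_total)
  i <- 0L
  for (tr in seq_len(d[1L])) {
    for (s in seq_len(d[2L])) {
      i <- i + 1L
      p <- psd(segset$segments[tr, s, , ], segset$sampling_rate,
               method = method)
      vals[i, , ] <- band_average(p, bands)
      trial[i] <- tr
    }
  }
  structure(list(values = vals, trial = trial,
                 subject_id = segset$subject_id,
                 ratings = segset$ratings, band_names = bands$name),
            class = "crgcn_features")
}

#' @export
print.crgcn_features <- function(x, ...) {
  d <- dim(x$values)
  cat("<crgcn_features> ", d[1L], " segments x ", d[2L], " channels x ",
      d[3L], " bands (", paste(x$band_names, collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Fit / apply per-(channel, band) z-score normalization
#'
#' `fit_normalizer` computes the mean and the population (1/N) standard
#' deviation of each (channel, band) feature over a training population;
#' `apply_normalizer` standardizes features with those stored statistics
#' (`z = (x - mu) / sigma`), never refitting on test data.
#'
#' @param values feature array `segments x channels x bands` (or a
#'   `crgcn_features`)
#' @return `fit_normalizer`: list of class `crgcn_normalizer` with matrices
#'   `mu` and `sigma` (`channels x bands`); `apply_normalizer`: array of the
#'   same shape as its input
#' @export
fit_normalizer <- function(values) {
  v <- feature_values(values)
  n <- dim(v)[1L]
  if (n < 2L) stop("fit_normalizer: need >= 2 training segments")
  mu <- apply(v, c(2L, 3L), mean)
  sg <- sqrt(apply(v, c(2L, 3L), function(x) mean((x - mean(x))^2)))
  if (any(sg == 0)) {
    bad <- which(sg == 0, arr.ind = TRUE)
    stop("fit_normalizer: zero standard deviation (degenerate feature) at ",
         "channel/band ", paste(bad[1L, ], collapse = "/"))
  }
  structure(list(mu = mu, sigma = sg), class = "crgcn_normalizer")
}

#' @param stats a `crgcn_normalizer` from `fit_normalizer`
#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(values, stats) {
  stopifnot(inherits(stats, "crgcn_normalizer"))
  v <- feature_values(values)
  d <- dim(v)
  if (!all(d[2:3] == dim(stats$mu)))
    stop("apply_normalizer: feature shape ", d[2L], " x ", d[3L],
         " does not match fitted statistics ",
         paste(dim(stats$mu), collapse = " x "))
  mu <- aperm(array(stats$mu, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  sg <- aperm(array(stats$sigma, dim = c(d[2L], d[3L], d[1L])), c(3L, 1L, 2L))
  (v - mu) / sg
}

feature_values <- function(values) {
  if (inherits(values, "crgcn_features")) values <- values$values
  if (length(dim(values)) != 3L)
    stop("expected a segments x channels x bands feature array")
  values
}
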