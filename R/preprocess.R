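# Spectrogram geometry: a 400-sample segment analysed with a 256-point
# Hamming-windowed DFT and 184-point overlap (hop 72) yields exactly three
# windows -- samples 1-256, 73-328, 145-400 -- and a one-sided spectrum of
# 256/2 + 1 = 129 rows, of which the lowest 95 are kept.
SEG_LEN <- 400L
FFT_LEN <- 256L
FFT_HOP <- 72L          # = 256 - 184 overlapping samples
N_TIME_BINS <- 3L
N_FREQ_KEPT <- 95L

#' Cut a recording into overlapping analysis segments
#'
#' Segments of `window` samples are taken every `hop` samples starting at
#' the first sample; trailing samples that do not fill a window are
#' discarded, so the count is `floor((N - window)/hop) + 1`.
#'
#' @param recording An [emg_recording].
#' @param window Segment length in samples (default 400).
#' @param hop Step between segment starts (default 200, i.e. 200 samples
#'   shared between consecutive segments).
#' @return A list of segments; each has `samples` (length `window`),
#'   `start_index` (0-based offset) and `stage`.
#' @export
segment_signal <- function(recording, window = 400L, hop = 200L) {
  stopifnot(inherits(recording, "emg_recording"))
  n <- length(recording$samples)
  if (n < window) {
    stopf("recording of %d samples is shorter than one %d-sample window",
          n, window)
  }
  starts <- seq(0L, n - window, by = hop)
  lapply(starts, function(s) {
    list(stage = recording$stage, start_index = s,
         samples = recording$samples[(s + 1L):(s + window)])
  })
}

# Symmetric Hamming window (periodic endpoints matched at 0.08), the
# convention of MATLAB's hamming(n).
hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Short-time Fourier magnitude spectrogram of one segment
#'
#' Each of the three 256-sample windows (offsets 0, 72, 144 within the
#' 400-sample segment) is Hamming-tapered and transformed with a 256-point
#' DFT; the magnitude of the lowest 95 one-sided bins (DC included) forms
#' one time column. Frequency spacing is `fs/256` Hz per row.
#'
#' @param segment A segment from [segment_signal], or a bare numeric vector
#'   of length 400.
#' @param fs Sampling rate in Hz (default 1000).
#' @return A `spectrogram`: a 95 x 3 non-negative matrix with attribute
#'   `bin_hz = fs/256`.
#' @export
compute_spectrogram <- function(segment, fs = 1000) {
  x <- if (is.list(segment)) segment$samples else segment
  if (length(x) != SEG_LEN) {
    stopf("segment has %d samples, expected exactly %d", length(x), SEG_LEN)
  }
  w <- hamming_window(FFT_LEN)
  out <- matrix(0, N_FREQ_KEPT, N_TIME_BINS)
  for (b in seq_len(N_TIME_BINS)) {
    off <- (b - 1L) * FFT_HOP
    win <- x[(off + 1L):(off + FFT_LEN)] * w
    out[, b] <- Mod(stats::fft(win))[seq_len(N_FREQ_KEPT)]
  }
  structure(out, bin_hz = fs / FFT_LEN, class = c("spectrogram", "matrix"))
}

#' Fit percentile min-max normalization statistics
#'
#' The 1st and 99th percentiles of all spectral magnitudes, pooled across
#' the supplied spectrograms, define the minimum and maximum of the
#' normalization map. Percentiles use linear interpolation between order
#' statistics ([stats::quantile] type 7). Statistics carry a scope
#' identifier (the leg they were fitted on) so that application to the
#' wrong leg can be caught downstream.
#'
#' @param spectrograms Non-empty list of 95 x 3 spectrogram matrices.
#' @param scope_id Identifier for the leg/fold the stats belong to.
#' @return A `norm_stats` object with elements `lo`, `hi`, `scope_id`.
#' @export
fit_norm_stats <- function(spectrograms, scope_id = "leg") {
  if (length(spectrograms) == 0) stopf("no spectrograms supplied")
  pooled <- unlist(spectrograms, use.names = FALSE)
  q <- stats::quantile(pooled, c(0.01, 0.99), names = FALSE, type = 7)
  structure(list(lo = q[1], hi = q[2], scope_id = as.character(scope_id)),
            class = "norm_stats")
}

#' Apply percentile min-max normalization
#'
#' Maps each entry through `(x - lo) / (hi - lo)` and clips to `[0, 1]`.
#' Degenerate statistics (`lo == hi`, a constant spectrum) map everything
#' to zero.
#'
#' @param spec A 95 x 3 spectrogram.
#' @param stats A `norm_stats` object from [fit_norm_stats].
#' @return The normalized spectrogram, entries in `[0, 1]`.
#' @export
normalize_spectrogram <- function(spec, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$lo > stats$hi) stopf("invalid normalization stats: lo > hi")
  if (stats$hi == stats$lo) {
    spec[] <- 0
    return(spec)
  }
  spec[] <- pmin(1, pmax(0, (spec - stats$lo) / (stats$hi - stats$lo)))
  spec
}

#' Flatten a spectrogram to the 285-element feature vector
#'
#' Frequency-major order: the 95 rows of time bin 1, then bin 2, then
#' bin 3 (R's native column-major flattening of the 95 x 3 matrix).
#' [unvectorize_spectrogram] is the exact inverse.
#'
#' @param spec A 95 x 3 spectrogram matrix.
#' @return Numeric vector of length 285.
#' @export
vectorize_spectrogram <- function(spec) {
  if (!is.matrix(spec) || !all(dim(spec) == c(N_FREQ_KEPT, N_TIME_BINS))) {
    stopf("expected a %d x %d spectrogram", N_FREQ_KEPT, N_TIME_BINS)
  }
  as.numeric(spec)
}

#' @rdname vectorize_spectrogram
#' @param v Numeric vector of length 285.
#' @export
unvectorize_spectrogram <- function(v) {
  if (length(v) != N_FREQ_KEPT * N_TIME_BINS) {
    stopf("expected a length-%d vector", N_FREQ_KEPT * N_TIME_BINS)
  }
  matrix(v, N_FREQ_KEPT, N_TIME_BINS)
}

# Segment every requested stage of a leg and compute raw (un-normalized)
# spectrograms once; normalization and PCA are refit per CV rotation.
# Returns list(spectrograms = list, stage = chr vector, n = count).
leg_spectrograms <- function(leg, stages) {
  stopifnot(inherits(leg, "leg_dataset"))
  check_stage(stages)
  missing <- setdiff(stages, names(leg$recordings))
  if (length(missing)) {
    stopf("leg %s-%s is missing stage(s): %s", leg$pig_id, leg$leg,
          paste(missing, collapse = ", "))
  }
  specs <- list(); stage_of <- character(0)
  for (s in stages) {
    segs <- segment_signal(leg$recordings[[s]])
    specs <- c(specs, lapply(segs, compute_spectrogram, fs = leg$fs))
    stage_of <- c(stage_of, rep(s, length(segs)))
  }
  list(spectrograms = specs, stage = stage_of, n = length(specs))
}
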