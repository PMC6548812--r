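#' @keywords internal
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Frame start indices for a sliding analysis; at least one frame.
frame_starts <- function(n, frame_n, hop_n) {
  if (n <= frame_n) return(1L)
  seq(1L, n - frame_n + 1L, by = hop_n)
}

#' Utterance duration in milliseconds
#'
#' @param w a [waveform()].
#' @return Duration `n_samples / rate * 1000`, rounded to the nearest ms.
#' @export
duration_ms <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (length(w$samples) == 0L) stop("empty waveform")
  round(length(w$samples) / w$rate * 1000)
}

#' Track fundamental frequency
#'
#' Frame-wise f0 estimation by the normalized autocorrelation method with
#' parabolic peak interpolation and a voicing decision (autocorrelation peak
#' above `voicing_threshold` and frame RMS above a silence floor). The
#' default search range 150-1000 Hz brackets the pitch range of young-infant
#' phonation with margin on both sides.
#'
#' @param w a [waveform()].
#' @param f0_min,f0_max f0 search range in Hz.
#' @param frame_s,hop_s analysis frame and hop in seconds. The frame must
#'   hold at least two periods of `f0_min`.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @param silence_rel frames whose RMS falls below `silence_rel` times the
#'   waveform's peak RMS are marked unvoiced.
#' @return A `data.frame` of class `pitch_track` with columns `time` (frame
#'   centre, s) and `f0` (Hz, `NA` when unvoiced).
#' @export
pitch_track <- function(w, f0_min = 150, f0_max = 1000,
                        frame_s = 0.04, hop_s = 0.01,
                        voicing_threshold = 0.35, silence_rel = 0.05) {
  stopifnot(inherits(w, "waveform"))
  if (f0_min >= f0_max) stop("f0_min must be below f0_max")
  if (w$rate < 2 * f0_max) stop("sampling rate below Nyquist for f0_max")
  if (frame_s < 2 / f0_min)
    stop("frame_s must hold at least two periods of f0_min")
  x <- w$samples
  N <- round(frame_s * w$rate); H <- max(1L, round(hop_s * w$rate))
  lmin <- max(2L, floor(w$rate / f0_max)); lmax <- ceiling(w$rate / f0_min)
  starts <- frame_starts(length(x), N, H)
  peak_rms <- max_rms(w)
  nfft <- 2^ceiling(log2(2 * N))
  res <- vapply(starts, function(s) {
    fr <- x[s:min(s + N - 1L, length(x))]
    fr <- fr - mean(fr)
    rms <- sqrt(mean(fr^2))
    if (rms < silence_rel * peak_rms || rms == 0) return(NA_real_)
    # biased autocorrelation via FFT (favors the shorter of T vs 2T)
    X <- stats::fft(c(fr, rep(0, nfft - length(fr))))
    r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(lmax + 2L)]
    r <- r / r[1L]
    lag <- (lmin:lmax) + 1L
    i <- lag[which.max(r[lag])]
    if (r[i] < voicing_threshold) return(NA_real_)
    # parabolic interpolation around the peak
    num <- r[i - 1L] - r[i + 1L]
    den <- r[i - 1L] - 2 * r[i] + r[i + 1L]
    l <- (i - 1L) + if (den != 0) 0.5 * num / den else 0
    w$rate / l
  }, numeric(1))
  out <- data.frame(time = w$t0 + (starts - 1L + N / 2) / w$rate, f0 = res)
  class(out) <- c("pitch_track", "data.frame")
  attr(out, "frame_s") <- frame_s; attr(out, "hop_s") <- hop_s
  out
}

#' Summarize a pitch track
#'
#' @param track a [pitch_track()].
#' @return Named numeric vector `c(avg_pitch_hz, max_pitch_hz)`: mean and
#'   maximum f0 over voiced frames only.
#' @export
pitch_summary <- function(track) {
  v <- track$f0[!is.na(track$f0)]
  if (!length(v)) stop("no voiced frames in pitch track")
  c(avg_pitch_hz = mean(v), max_pitch_hz = max(v))
}

#' Peak sliding-window RMS amplitude
#'
#' Maximum of the root-mean-square amplitude over a sliding window; the
#' study's "Max amplitude (RMS)" parameter. If the window is at least as
#' long as the waveform a single full-span RMS is returned.
#'
#' @param w a [waveform()].
#' @param window_s,hop_s RMS window and hop in seconds.
#' @return Peak RMS in linear amplitude units.
#' @export
max_rms <- function(w, window_s = 0.030, hop_s = 0.010) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  N <- round(window_s * w$rate)
  if (N >= length(x)) return(sqrt(mean(x^2)))
  H <- max(1L, round(hop_s * w$rate))
  cs <- cumsum(c(0, x^2))
  starts <- frame_starts(length(x), N, H)
  sqrt(max((cs[starts + N] - cs[starts]) / N))
}

#' Long-term average spectrum (Welch)
#'
#' Welch-averaged one-sided power spectrum: Hann windows of `window_s`
#' seconds with 50% overlap, `nfft` the next power of two at or above the
#' window length. Per-bin powers are scaled so that their sum approximates
#' the signal's mean-square power (Parseval). Segments shorter than one
#' window are zero-padded into a single frame and flagged.
#'
#' @param w a [waveform()].
#' @param window_s analysis window in seconds.
#' @param nfft FFT length; default next power of two >= window length.
#' @return An object of class `ltas` with fields `freqs` (Hz, 0 to
#'   Nyquist), `power` (linear, per bin), `df` (bin width), `n_frames`, and
#'   `short_segment` flag.
#' @export
ltas <- function(w, window_s = 0.025, nfft = NULL) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  N <- round(window_s * w$rate)
  short <- length(x) < N
  if (short) {
    x <- c(x, rep(0, N - length(x)))
  }
  if (is.null(nfft)) nfft <- 2^ceiling(log2(N))
  win <- hann_window(N)
  H <- max(1L, N %/% 2L)
  starts <- frame_starts(length(x), N, H)
  acc <- numeric(nfft)
  for (s in starts) {
    fr <- x[s:(s + N - 1L)] * win
    acc <- acc + Mod(stats::fft(c(fr, rep(0, nfft - N))))^2
  }
  p2 <- acc / length(starts) / (nfft * sum(win^2) / N) / N  # two-sided
  half <- nfft %/% 2L
  power <- p2[1:(half + 1L)]
  power[2:half] <- 2 * power[2:half]
  structure(list(freqs = (0:half) * w$rate / nfft, power = power,
                 df = w$rate / nfft, nfft = nfft, n_frames = length(starts),
                 window_s = window_s, short_segment = short),
            class = "ltas")
}

#' @export
print.ltas <- function(x, ...) {
  cat(sprintf("<ltas: %d bins, df = %.1f Hz, %d frame(s)%s>\n",
              length(x$freqs), x$df, x$n_frames,
              if (x$short_segment) ", short segment (zero-padded)" else ""))
  invisible(x)
}

#' Low/high spectral band-energy ratio
#'
#' Ratio of spectral energy below `split` Hz to energy above it, in dB:
#' `10 log10(P_low / P_high)`. High distress phonation carries relatively
#' more energy above 2 kHz, pushing the ratio down. `P_high` is floored at
#' `1e-10` of total power and the result capped to +/-60 dB, so a pure low-
#' band tone returns the cap rather than infinity.
#'
#' @param spectrum an [ltas()].
#' @param split band split frequency in Hz (default 2000).
#' @param cap_db absolute cap on the returned ratio.
#' @return Band energy ratio in dB.
#' @export
spectral_ratio_db <- function(spectrum, split = 2000, cap_db = 60) {
  stopifnot(inherits(spectrum, "ltas"))
  if (max(spectrum$freqs) <= split)
    stop("spectrum does not extend beyond the split frequency")
  total <- sum(spectrum$power)
  lo <- sum(spectrum$power[spectrum$freqs < split])
  hi <- max(sum(spectrum$power[spectrum$freqs >= split]), 1e-10 * total)
  lo <- max(lo, 1e-10 * total)
  min(cap_db, max(-cap_db, 10 * log10(lo / hi)))
}

#' Spectral concentration: power-weighted mean and dispersion
#'
#' First and second power-weighted moments of the long-term average
#' spectrum, in kHz: the study's "Spectral mean" and "Spectral dispersion
#' (SD)" parameters.
#'
#' @param spectrum an [ltas()].
#' @return Named vector `c(mean_khz, sd_khz)`.
#' @export
spectral_concentration <- function(spectrum) {
  stopifnot(inherits(spectrum, "ltas"))
  p <- spectrum$power; f <- spectrum$freqs
  if (sum(p) <= 0) stop("spectrum has zero total power")
  mu <- sum(f * p) / sum(p)
  sd <- sqrt(sum(p * (f - mu)^2) / sum(p))
  c(mean_khz = mu / 1000, sd_khz = sd / 1000)
}

#' Cepstral peak prominence
#'
#' CPP indexes periodicity: the height (dB) of the cepstral peak in the
#' quefrency band `[1/f0_max, 1/f0_min]` above a linear regression baseline
#' fitted to the cepstrum across the analyzed quefrency band. Frames of
#' `frame_s` seconds (Hann windowed, 50% overlap) are analyzed and their
#' cepstra averaged before peak picking.
#'
#' @param w a [waveform()] segment, at least two periods of `f0_min` long.
#' @param f0_min,f0_max quefrency band limits expressed as f0 range (Hz).
#' @param frame_s analysis frame in seconds (default 0.04).
#' @return CPP in dB.
#' @export
cpp_db <- function(w, f0_min = 150, f0_max = 1000, frame_s = 0.04) {
  stopifnot(inherits(w, "waveform"))
  x <- w$samples
  if (length(x) < 2 * w$rate / f0_min)
    stop("segment too short for CPP at f0_min = ", f0_min, " Hz")
  N <- min(length(x), round(frame_s * w$rate))
  nfft <- 2^ceiling(log2(2 * N))
  win <- hann_window(N)
  starts <- frame_starts(length(x), N, max(1L, N %/% 2L))
  acc <- numeric(nfft)
  for (s in starts) {
    fr <- x[s:(s + N - 1L)]
    fr <- (fr - mean(fr)) * win
    L <- 10 * log10(Mod(stats::fft(c(fr, rep(0, nfft - N))))^2 + 1e-30)
    acc <- acc + (2 / nfft) * Mod(stats::fft(L))
  }
  # cepstral magnitude (averaged over frames) on a dB scale; the peak is
  # referred to a linear regression baseline over the analyzed band
  cep <- 20 * log10(acc / length(starts) + 1e-12)
  q <- (0:(nfft - 1L)) / w$rate
  qlo <- 1 / f0_max; qhi <- 1 / f0_min
  band <- which(q >= 0.0005 & q <= qhi)           # baseline fit band
  fit <- stats::lm.fit(cbind(1, q[band]), cep[band])
  peakband <- which(q >= qlo & q <= qhi)
  i <- peakband[which.max(cep[peakband])]
  unname(cep[i] - (fit$coefficients[1] + fit$coefficients[2] * q[i]))
}

#' Per-utterance acoustic profile with regime-wise aggregation
#'
#' Computes the nine predictor parameters. Duration, average/max pitch and
#' peak RMS are whole-utterance quantities. The spectral trio and
#' periodicity are measured within each vibratory-regime segment and
#' aggregated by the extremum that marks distress: spectral ratio and CPP by
#' the minimum over segments, spectral mean and dispersion by the maximum.
#' `n_regimes` is the segment count.
#'
#' @param x an [utterance_record()], or a [waveform()] (then `tier` must be
#'   given).
#' @param tier a [regime_tier()] tiling the phonated span.
#' @param f0_min,f0_max pitch search range passed to [pitch_track()] and
#'   [cpp_db()].
#' @param ... further arguments passed to [pitch_track()].
#' @return An object of class `acoustic_profile`: a list with the nine
#'   utterance-level parameters and a `per_regime` data.frame of the
#'   regime-wise measurements.
#' @export
extract_profile <- function(x, tier = NULL, f0_min = 150, f0_max = 1000, ...) {
  if (inherits(x, "utterance_record")) {
    tier <- x$tier; w <- x$waveform; id <- x$id
  } else {
    w <- x; id <- if (!is.null(tier)) tier$utterance_id else "utt"
  }
  stopifnot(inherits(w, "waveform"), inherits(tier, "regime_tier"))
  segs <- tier$segments
  per <- lapply(seq_len(nrow(segs)), function(i) {
    sw <- tryCatch(slice_waveform(w, segs[i, ]),
                   error = function(e) stop("segment ", i, ": ",
                                            conditionMessage(e), call. = FALSE))
    sp <- ltas(sw)
    conc <- spectral_concentration(sp)
    data.frame(segment = i, label = segs$label[i],
               start = segs$start[i], end = segs$end[i],
               spectral_ratio_db = spectral_ratio_db(sp),
               spectral_mean_khz = unname(conc["mean_khz"]),
               spectral_sd_khz = unname(conc["sd_khz"]),
               cpp_db = tryCatch(cpp_db(sw, f0_min, f0_max),
                                 error = function(e) stop("segment ", i, ": ",
                                   conditionMessage(e), call. = FALSE)),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ps <- pitch_summary(pitch_track(w, f0_min = f0_min, f0_max = f0_max, ...))
  structure(list(
    id = id,
    duration_ms = duration_ms(w),
    avg_pitch_hz = unname(ps["avg_pitch_hz"]),
    max_pitch_hz = unname(ps["max_pitch_hz"]),
    max_rms = max_rms(w),
    spectral_ratio_db = min(per$spectral_ratio_db),
    spectral_mean_khz = max(per$spectral_mean_khz),
    spectral_sd_khz = max(per$spectral_sd_khz),
    periodicity_cpp_db = min(per$cpp_db),
    n_regimes = count_regimes(tier),
    per_regime = per), class = "acoustic_profile")
}

#' @export
print.acoustic_profile <- function(x, ...) {
  cat(sprintf("<acoustic_profile '%s'>\n", x$id))
  print(as.data.frame(profile_row(x)))
  invisible(x)
}

#' Flatten an acoustic profile to a one-row data.frame
#'
#' @param p an `acoustic_profile`.
#' @return One-row `data.frame` with the nine parameters (column names match
#'   the package's feature-table convention).
#' @export
profile_row <- function(p) {
  stopifnot(inherits(p, "acoustic_profile"))
  data.frame(stimulus = p$id, duration_ms = p$duration_ms,
             avg_pitch_hz = p$avg_pitch_hz, max_pitch_hz = p$max_pitch_hz,
             max_rms = p$max_rms, spectral_ratio = p$spectral_ratio_db,
             spectral_mean_khz = p$spectral_mean_khz,
             spectral_sd_khz = p$spectral_sd_khz,
             periodicity_cpp_db = p$periodicity_cpp_db,
             n_regimes = p$n_regimes, stringsAsFactors = FALSE)
}

#' Two-stage correlation screening of candidate parameters
#'
#' Stage 1 ranks candidate columns by absolute Pearson correlation with the
#' ratings (constant columns are dropped with a warning). Stage 2 walks
#' pairs of surviving candidates whose inter-correlation exceeds
#' `redundancy_r` in absolute value and drops from each pair the member less
#' correlated with the ratings, until no redundant pair remains.
#'
#' @param candidates `data.frame` of numeric candidate columns.
#' @param ratings numeric response aligned with the rows of `candidates`.
#' @param redundancy_r absolute inter-candidate correlation above which a
#'   pair is considered redundant (default 0.8).
#' @return A list with `selected` (surviving column names, ranked by
#'   `|r|` with ratings), `rating_r` (named correlations), and `audit`
#'   (data.frame of drops: column, reason, partner).
#' @export
screen_parameters <- function(candidates, ratings, redundancy_r = 0.8) {
  stopifnot(is.data.frame(candidates), nrow(candidates) == length(ratings))
  num <- vapply(candidates, is.numeric, logical(1))
  candidates <- candidates[num]
  if (ncol(candidates) < 2) stop("need at least two candidate columns")
  audit <- data.frame(column = character(), reason = character(),
                      partner = character(), stringsAsFactors = FALSE)
  sds <- vapply(candidates, stats::sd, numeric(1))
  if (any(sds == 0)) {
    for (nm in names(candidates)[sds == 0])
      audit <- rbind(audit, data.frame(column = nm, reason = "constant",
                                       partner = NA_character_))
    warning("dropping constant column(s): ",
            paste(names(candidates)[sds == 0], collapse = ", "))
    candidates <- candidates[sds > 0]
  }
  rr <- vapply(candidates, function(col) stats::cor(col, ratings), numeric(1))
  surv <- names(sort(abs(rr), decreasing = TRUE))
  repeat {
    if (length(surv) < 2) break
    cm <- abs(stats::cor(candidates[surv]))
    diag(cm) <- 0
    if (max(cm) <= redundancy_r) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- surv[ij[1]]; b <- surv[ij[2]]
    drop <- if (abs(rr[a]) < abs(rr[b])) a else b
    keep <- setdiff(c(a, b), drop)
    audit <- rbind(audit, data.frame(column = drop, reason = "redundant",
                                     partner = keep))
    surv <- setdiff(surv, drop)
  }
  list(selected = surv, rating_r = rr[surv], audit = audit)
}
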