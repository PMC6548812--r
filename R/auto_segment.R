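#' Configuration for automatic regime detection
#'
#' Defaults implement the package's frame-wise classifier: 25 ms frames at a
#' 10 ms hop; segments shorter than `min_segment_s` (50 ms, the annotation
#' rule under which very short subharmonic events are not labeled) are
#' merged into a neighbor; frames with f0 below `pulse_f0_max_hz` are
#' pulse; frames whose cepstral peak prominence falls below
#' `cpp_aperiodic_db` are aperiodic; frames whose subharmonic-to-harmonic
#' energy ratio (energy at half-integer multiples of the carrier f0 relative
#' to energy at integer multiples) exceeds `shr_subharmonic` are
#' subharmonic.
#'
#' @param frame_s,hop_s analysis frame and hop (s).
#' @param min_segment_s minimum emitted segment duration (s).
#' @param pulse_f0_max_hz f0 ceiling for the pulse regime.
#' @param cpp_aperiodic_db CPP floor below which a frame is aperiodic.
#' @param shr_subharmonic subharmonic-to-harmonic energy ratio threshold.
#' @param f0_min,f0_max f0 search range for the classifier (extends below
#'   the modal range so pulse-register periods are measurable).
#' @param voicing_threshold normalized autocorrelation floor for phonation.
#' @return A list of class `regime_detection_config`.
#' @export
regime_detection_config <- function(frame_s = 0.025, hop_s = 0.010,
                                    min_segment_s = 0.05,
                                    pulse_f0_max_hz = 180,
                                    cpp_aperiodic_db = 20,
                                    shr_subharmonic = 0.25,
                                    f0_min = 80, f0_max = 1000,
                                    voicing_threshold = 0.30) {
  stopifnot(min_segment_s > 0, frame_s > 0, hop_s > 0,
            is.finite(cpp_aperiodic_db), is.finite(shr_subharmonic))
  structure(list(frame_s = frame_s, hop_s = hop_s,
                 min_segment_s = min_segment_s,
                 pulse_f0_max_hz = pulse_f0_max_hz,
                 cpp_aperiodic_db = cpp_aperiodic_db,
                 shr_subharmonic = shr_subharmonic,
                 f0_min = f0_min, f0_max = f0_max,
                 voicing_threshold = voicing_threshold),
            class = "regime_detection_config")
}

# Subharmonic-to-harmonic energy ratio of one frame spectrum for a given
# carrier f0: energy in bands (half-width carrier/5) around half-integer
# multiples of the carrier relative to energy around integer multiples.
# The spectrum is whitened by its smooth envelope first, so the ratio
# reflects the vocal-fold source rather than the vocal-tract filter.
frame_shr <- function(power, freqs, carrier) {
  df <- freqs[2] - freqs[1]
  span <- max(3L, 2L * (round(carrier / df) %/% 2L) + 1L)  # ~one carrier period
  env <- stats::filter(power, rep(1 / span, span), sides = 2)
  env[is.na(env)] <- mean(power)
  power <- power / pmax(as.numeric(env), 1e-30)
  bw <- carrier / 5
  top <- min(5000, max(freqs))
  comb_energy <- function(centers) {
    centers <- centers[centers <= top]
    if (!length(centers)) return(0)
    sum(vapply(centers, function(fc)
      sum(power[abs(freqs - fc) <= bw]), numeric(1)))
  }
  h <- comb_energy((1:12) * carrier)
  s <- comb_energy(((1:12) - 0.5) * carrier)
  if (h > 0) s / h else 0
}

#' Automatically propose a vibratory-regime tier
#'
#' Frame-wise classification of a phonated utterance into the four regimes
#' (modal / aperiodic / subharmonic / pulse) followed by label smoothing and
#' merging of segments shorter than `min_segment_s`. The study's tiers were
#' produced by trained annotators from spectrographic and auditory
#' inspection; this detector automates comparable criteria so the pipeline
#' can be exercised end-to-end, and is validated only against the package's
#' utterance synthesizer. Ties follow the priority aperiodic > subharmonic >
#' pulse > modal (the rarer regimes are the marked categories). Trill and
#' flutter modulations are never auto-detected.
#'
#' @param w a [waveform()].
#' @param config a [regime_detection_config()].
#' @param utterance_id id for the returned tier.
#' @return A validated, tiling [regime_tier()].
#' @export
auto_segment_regimes <- function(w, config = regime_detection_config(),
                                 utterance_id = "utt") {
  stopifnot(inherits(w, "waveform"), inherits(config, "regime_detection_config"))
  x <- w$samples
  N <- round(config$frame_s * w$rate)
  H <- max(1L, round(config$hop_s * w$rate))
  starts <- frame_starts(length(x), N, H)
  lmin <- max(2L, floor(w$rate / config$f0_max))
  lmax <- ceiling(w$rate / config$f0_min)
  nfft_acf <- 2^ceiling(log2(N + lmax + 2L))
  nfft_spec <- 2^ceiling(log2(4L * N))
  freqs <- (0:(nfft_spec %/% 2L)) * w$rate / nfft_spec
  win <- hann_window(N)
  any_voiced <- FALSE
  labels <- character(length(starts))
  peak <- max_rms(w, window_s = config$frame_s, hop_s = config$hop_s)
  # pass 1: frame-wise measurements (tracked f0, periodicity, CPP)
  meas <- matrix(NA_real_, length(starts), 3,
                 dimnames = list(NULL, c("f0", "acf", "cpp")))
  frames <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    fr <- x[starts[k]:min(starts[k] + N - 1L, length(x))]
    if (length(fr) < N) fr <- c(fr, rep(0, N - length(fr)))
    fr <- fr - mean(fr)
    frames[[k]] <- fr
    if (sqrt(mean(fr^2)) < 0.05 * peak) next  # ramp or pause: fill later
    X <- stats::fft(c(fr, rep(0, nfft_acf - N)))
    r <- Re(stats::fft(Mod(X)^2, inverse = TRUE))[1:(lmax + 1L)]
    r <- r / r[1L]  # biased: favors the fundamental period over its octave
    lag <- (lmin:lmax)
    i <- lag[which.max(r[lag + 1L])]
    meas[k, ] <- c(w$rate / i, r[i + 1L],
                   cpp_db(waveform(fr + 1e-12, w$rate),
                          f0_min = config$f0_min, f0_max = config$f0_max,
                          frame_s = config$frame_s))
  }
  voiced <- !is.na(meas[, "acf"]) & meas[, "acf"] >= config$voicing_threshold
  if (!any(voiced)) stop("no phonation detected")
  # carrier reference: median tracked f0 of confidently periodic frames in
  # the modal band (subharmonic frames track the doubled period, f0/2)
  conf <- voiced & meas[, "acf"] >= 0.55 & meas[, "f0"] >= 250
  f0_ref <- if (any(conf)) stats::median(meas[conf, "f0"])
            else stats::median(meas[voiced, "f0"])
  # pass 2: classification, priority aperiodic > subharmonic > pulse > modal
  for (k in seq_along(starts)) {
    if (is.na(meas[k, "acf"])) next  # silent frame
    f0 <- meas[k, "f0"]; acf_peak <- meas[k, "acf"]; cpp <- meas[k, "cpp"]
    # aperiodic: no periodicity, or weak periodicity with a flat cepstrum
    # (pulse register is periodic but CPP-poor, hence the ACF guard)
    if (!voiced[k] || (cpp < config$cpp_aperiodic_db && acf_peak < 0.55)) {
      labels[k] <- "aperiodic"
      next
    }
    ratio <- f0 / f0_ref
    if (ratio > 0.42 && ratio < 0.58) {
      # tracked period is double the carrier's: period doubling, confirmed
      # by actual energy at half-integer multiples of the carrier
      fr <- frames[[k]]
      S <- Mod(stats::fft(c(fr * win, rep(0, nfft_spec - N))))^2
      shr <- frame_shr(S[1:(nfft_spec %/% 2L + 1L)], freqs, 2 * f0)
      labels[k] <- if (shr > config$shr_subharmonic) "subharmonic" else "modal"
    } else if (f0 < config$pulse_f0_max_hz) {
      labels[k] <- "pulse"
    } else {
      labels[k] <- "modal"
    }
  }
  labels[labels == ""] <- NA_character_
  labels <- fill_silent_labels(labels)
  labels <- smooth_labels(labels, width = 5L)
  segs <- labels_to_segments(labels, starts, N, H, w, config$min_segment_s)
  regime_tier(segs, utterance_id = utterance_id)
}

# Low-energy frames inherit the label of the nearest classified frame.
fill_silent_labels <- function(labels) {
  if (!anyNA(labels)) return(labels)
  known <- which(!is.na(labels))
  if (!length(known)) stop("no phonation detected")
  for (k in which(is.na(labels)))
    labels[k] <- labels[known[which.min(abs(known - k))]]
  labels
}

# Majority (mode) filter over a centered window of odd width; priority order
# breaks ties toward the marked categories.
smooth_labels <- function(labels, width = 5L) {
  prio <- c(aperiodic = 1, subharmonic = 2, pulse = 3, modal = 4)
  half <- width %/% 2L
  n <- length(labels)
  out <- labels
  for (k in seq_len(n)) {
    win <- labels[max(1L, k - half):min(n, k + half)]
    tab <- table(win)
    best <- names(tab)[tab == max(tab)]
    out[k] <- best[order(prio[best])][1]
  }
  out
}

# Convert a frame label sequence to merged, tiling segments.
labels_to_segments <- function(labels, starts, N, H, w, min_segment_s) {
  rl <- rle(labels)
  runs <- data.frame(label = rl$values,
                     from = cumsum(c(1L, utils::head(rl$lengths, -1L))),
                     len = rl$lengths)
  # merge runs shorter than the minimum into the longer neighbor
  min_frames <- max(1, min_segment_s / (H / w$rate))
  while (nrow(runs) > 1L && min(runs$len) < min_frames) {
    j <- which.min(runs$len)
    nb <- if (j == 1L) 2L
          else if (j == nrow(runs)) j - 1L
          else if (runs$len[j - 1L] >= runs$len[j + 1L]) j - 1L else j + 1L
    lo <- min(j, nb); hi <- max(j, nb)
    runs$len[lo] <- runs$len[lo] + runs$len[hi]
    runs$label[lo] <- runs$label[if (nb < j) lo else hi]
    runs <- runs[-hi, , drop = FALSE]
    # re-merge adjacent runs that now share a label
    if (nrow(runs) > 1L) {
      same <- which(runs$label[-1L] == runs$label[-nrow(runs)])
      while (length(same)) {
        s1 <- same[1L]
        runs$len[s1] <- runs$len[s1] + runs$len[s1 + 1L]
        runs <- runs[-(s1 + 1L), , drop = FALSE]
        same <- which(runs$label[-1L] == runs$label[-nrow(runs)])
      }
    }
    runs$from <- cumsum(c(1L, utils::head(runs$len, -1L)))
  }
  dur <- duration_s(w)
  centre <- function(k) (starts[k] - 1L + N / 2) / w$rate
  bounds <- numeric(nrow(runs) + 1L)
  bounds[1L] <- 0
  bounds[nrow(runs) + 1L] <- dur
  if (nrow(runs) > 1L)
    for (j in 2:nrow(runs)) {
      k_prev <- runs$from[j] - 1L
      bounds[j] <- (centre(k_prev) + centre(runs$from[j])) / 2
    }
  do.call(rbind, lapply(seq_len(nrow(runs)), function(j)
    regime_segment(bounds[j], bounds[j + 1L], runs$label[j])))
}
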