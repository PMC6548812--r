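# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specification for a synthetic utterance
#'
#' States the world the synthesizer emulates: a phonation-only infant
#' utterance of 400-2000 ms with f0 in the 300-510 Hz band of the study's
#' stimuli, a scheduled sequence of vibratory regimes, and a source-filter
#' production model (glottal pulse train, formant resonators, spectral
#' tilt, jitter/shimmer, noise floor).
#'
#' @param duration_s utterance duration in seconds (0.4-2.0).
#' @param f0_base_hz base fundamental frequency (150-1000 Hz).
#' @param contour `"flat"`, `"rise_fall"`, `"rise_flat"`, or `"custom"`
#'   (then supply `breakpoints`).
#' @param f0_peak_hz contour peak for the rise shapes.
#' @param breakpoints for `"custom"`: 2-column matrix of (time fraction in
#'   `[0, 1]`, f0 Hz) breakpoints.
#' @param tilt_db_per_octave source spectral tilt above 300 Hz (negative =
#'   low-pass; wails carry relatively more high-frequency energy, i.e. a
#'   shallower tilt).
#' @param formants `data.frame` with `freq` and `bw` (Hz) of vocal-tract
#'   resonances; defaults approximate a newborn vocal tract.
#' @param regime_schedule `data.frame` (start, end, label) tiling
#'   `[0, duration_s)`; labels as in [regime_segment()].
#' @param jitter_pct,shimmer_pct cycle-to-cycle period and amplitude
#'   perturbation (percent) in periodic regimes.
#' @param noise_floor_db aspiration-noise floor relative to signal RMS.
#' @param subharmonic_depth alternate-period amplitude modulation depth in
#'   subharmonic segments (creates the f0/2 component).
#' @param pulse_f0_hz f0 used within pulse-regime segments (< 180 Hz).
#' @param aperiodic_jitter_pct,aperiodic_noise_db source perturbation and
#'   added noise within aperiodic segments.
#' @param seed integer seed; a spec plus its seed fully reproduces the audio.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 1.0, f0_base_hz = 400,
                       contour = c("flat", "rise_fall", "rise_flat", "custom"),
                       f0_peak_hz = f0_base_hz * 1.15, breakpoints = NULL,
                       tilt_db_per_octave = -6,
                       formants = data.frame(freq = c(1000, 3200, 5200),
                                             bw = c(150, 300, 400)),
                       regime_schedule = data.frame(start = 0, end = duration_s,
                                                    label = "modal"),
                       jitter_pct = 0.5, shimmer_pct = 3,
                       noise_floor_db = -35, subharmonic_depth = 0.6,
                       pulse_f0_hz = 120,
                       aperiodic_jitter_pct = 12, aperiodic_noise_db = -5,
                       seed = NULL) {
  contour <- match.arg(contour)
  if (duration_s <= 0) stop("duration_s must be positive")
  f0s <- c(f0_base_hz, if (contour %in% c("rise_fall", "rise_flat")) f0_peak_hz,
           if (!is.null(breakpoints)) breakpoints[, 2])
  if (any(f0s < 150 | f0s > 1000))
    stop("f0 contour values must lie in [150, 1000] Hz")
  sch <- regime_schedule[order(regime_schedule$start), , drop = FALSE]
  if (abs(sch$start[1]) > 1e-9 ||
      abs(sch$end[nrow(sch)] - duration_s) > 1e-9 ||
      (nrow(sch) > 1 && any(abs(sch$start[-1] - sch$end[-nrow(sch)]) > 1e-9)))
    stop("regime_schedule must tile [0, duration_s)")
  sch$label <- vapply(sch$label, normalize_regime_label, character(1))
  structure(list(duration_s = duration_s, f0_base_hz = f0_base_hz,
                 contour = contour, f0_peak_hz = f0_peak_hz,
                 breakpoints = breakpoints,
                 tilt_db_per_octave = tilt_db_per_octave, formants = formants,
                 regime_schedule = sch, jitter_pct = jitter_pct,
                 shimmer_pct = shimmer_pct, noise_floor_db = noise_floor_db,
                 subharmonic_depth = subharmonic_depth,
                 pulse_f0_hz = pulse_f0_hz,
                 aperiodic_jitter_pct = aperiodic_jitter_pct,
                 aperiodic_noise_db = aperiodic_noise_db, seed = seed),
            class = "synth_spec")
}

contour_f0 <- function(spec, t) {
  frac <- t / spec$duration_s
  switch(spec$contour,
    flat = rep(spec$f0_base_hz, length(t)),
    rise_fall = spec$f0_base_hz + (spec$f0_peak_hz - spec$f0_base_hz) *
      (1 - abs(2 * frac - 1)),
    rise_flat = pmin(spec$f0_peak_hz,
                     spec$f0_base_hz + (spec$f0_peak_hz - spec$f0_base_hz) *
                       pmin(1, frac / 0.3)),
    custom = stats::approx(spec$breakpoints[, 1], spec$breakpoints[, 2],
                           xout = frac, rule = 2)$y)
}

schedule_label_at <- function(sch, t) {
  i <- findInterval(t, sch$start)
  sch$label[max(1L, min(i, nrow(sch)))]
}

# two-pole resonator (formant) filter
resonate <- function(x, freq, bw, rate) {
  r <- exp(-pi * bw / rate)
  th <- 2 * pi * freq / rate
  a <- c(2 * r * cos(th), -r^2)
  g <- (1 - r) * sqrt(1 - 2 * r * cos(2 * th) + r^2)  # rough unity-ish gain
  stats::filter(x * g, a, method = "recursive")
}

# zero-phase spectral tilt: gain_db(f) = tilt * log2(max(f, ref)/ref)
apply_tilt <- function(x, tilt_db_per_octave, rate, ref = 300) {
  n <- length(x)
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  f <- (0:(nfft - 1)) * rate / nfft
  f <- pmin(f, nfft * rate / nfft - f)  # mirror for negative frequencies
  g <- 10^((tilt_db_per_octave * log2(pmax(f, ref) / ref)) / 20)
  Re(stats::fft(X * g, inverse = TRUE))[1:n] / nfft
}

#' Synthesize an utterance with scheduled vibratory regimes
#'
#' Source-filter synthesis: a glottal impulse train follows the f0 contour
#' (with jitter and shimmer), is filtered by formant resonators and a
#' spectral-tilt filter, and carries the scheduled regime events --
#' subharmonic segments apply alternate-period amplitude modulation
#' (creating components at f0/2), aperiodic segments use heavy jitter plus
#' strong noise, pulse segments drop f0 to the pulse register. The exact
#' schedule is returned as a ground-truth tier.
#'
#' @param spec a [synth_spec()].
#' @param rate sampling rate in Hz (study audio is 16 kHz).
#' @param utterance_id id for the ground-truth tier.
#' @return A list with `waveform` (a [waveform()], peak-normalized to 0.9)
#'   and `tier` (the ground-truth [regime_tier()]).
#' @export
synth_utterance <- function(spec, rate = 16000, utterance_id = "synth") {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * rate)
    src <- numeric(n)
    noise_mask <- numeric(n)
    t <- 0
    k <- 0L
    while (t < spec$duration_s) {
      lab <- schedule_label_at(spec$regime_schedule, t)
      f0 <- if (lab == "pulse") spec$pulse_f0_hz else contour_f0(spec, t)
      jit <- if (lab == "aperiodic") spec$aperiodic_jitter_pct else spec$jitter_pct
      period <- (1 / f0) * (1 + stats::rnorm(1, 0, jit / 100))
      amp <- 1 + stats::rnorm(1, 0, spec$shimmer_pct / 100)
      if (lab == "subharmonic")
        amp <- amp * (1 + spec$subharmonic_depth * (2 * (k %% 2L) - 1))
      i <- round(t * rate) + 1L
      if (i >= 1L && i <= n) src[i] <- src[i] + amp
      t <- t + max(period, 1e-4)
      k <- k + 1L
    }
    # aperiodic segments: strong additive noise
    for (j in seq_len(nrow(spec$regime_schedule))) {
      if (spec$regime_schedule$label[j] == "aperiodic") {
        i0 <- max(1L, round(spec$regime_schedule$start[j] * rate) + 1L)
        i1 <- min(n, round(spec$regime_schedule$end[j] * rate))
        noise_mask[i0:i1] <- 1
      }
    }
    y <- src
    for (j in seq_len(nrow(spec$formants)))
      y <- as.numeric(resonate(y, spec$formants$freq[j], spec$formants$bw[j], rate))
    y <- apply_tilt(y, spec$tilt_db_per_octave, rate)
    sig_rms <- sqrt(mean(y^2))
    y <- y + stats::rnorm(n, 0, sig_rms * 10^(spec$noise_floor_db / 20))
    if (any(noise_mask > 0))
      y <- y + noise_mask * stats::rnorm(n, 0, sig_rms *
                                           10^(spec$aperiodic_noise_db / 20))
    # onset/offset ramps to avoid clicks
    ramp_n <- min(round(0.02 * rate), n %/% 4L)
    env <- rep(1, n)
    env[1:ramp_n] <- (1 - cos(pi * (1:ramp_n) / ramp_n)) / 2
    env[(n - ramp_n + 1L):n] <- rev(env[1:ramp_n])
    y <- y * env
    y <- 0.9 * y / max(abs(y))
    # pin the ground-truth tier to the realized (sample-quantized) duration
    sch <- spec$regime_schedule
    sch$end[nrow(sch)] <- n / rate
    segs <- do.call(rbind, lapply(seq_len(nrow(sch)), function(j)
      regime_segment(sch$start[j], sch$end[j], sch$label[j])))
    list(waveform = waveform(y, rate), tier = regime_tier(segs, utterance_id))
  })
}

# class templates calibrated to the published stimulus ranges: durations
# 452-2000 ms, pitch 298-510 Hz, 1-5 regimes; wails long / shallow tilt /
# multi-regime, vocants short / steep tilt / modal-only.
class_template <- function(class, f0_offset = 0) {
  switch(class,
    wail = list(dur = stats::runif(1, 1.0, 2.0),
                f0 = stats::runif(1, 390, 490) + f0_offset,
                tilt = stats::runif(1, -4, -2),
                n_events = sample(1:2, 1, prob = c(0.5, 0.5)),
                contour = sample(c("rise_fall", "flat", "rise_flat"), 1)),
    whine = list(dur = stats::runif(1, 0.6, 1.4),
                 f0 = stats::runif(1, 350, 450) + f0_offset,
                 tilt = stats::runif(1, -8, -5),
                 n_events = sample(0:1, 1, prob = c(0.4, 0.6)),
                 contour = sample(c("flat", "rise_flat"), 1)),
    vocant = list(dur = stats::runif(1, 0.45, 0.95),
                  f0 = stats::runif(1, 310, 400) + f0_offset,
                  tilt = stats::runif(1, -12, -9),
                  n_events = 0L,
                  contour = "flat"))
}

# schedule with n_events dysphonation events inside a modal carrier;
# constructive placement: event lengths 0.12-0.35 s, modal stretches of at
# least 0.1 s at the edges and 0.12 s between events, remaining slack split
# randomly. Infeasible (too short) utterances fall back to fewer events.
random_schedule <- function(dur, n_events) {
  edge <- max(0.1 * dur, 0.08)
  while (n_events > 0L) {
    avail <- dur - 2 * edge - 0.12 * (n_events - 1L)
    max_len <- min(0.35, avail / n_events)
    if (max_len >= 0.12) break
    n_events <- n_events - 1L
  }
  if (n_events == 0L)
    return(data.frame(start = 0, end = dur, label = "modal"))
  len <- stats::runif(n_events, 0.12, max_len)
  free <- dur - 2 * edge - 0.12 * (n_events - 1L) - sum(len)
  u <- stats::runif(n_events + 1L)
  g <- free * u / sum(u)
  lab <- sample(c("subharmonic", "aperiodic"), n_events, replace = TRUE)
  segs <- NULL
  cursor <- 0
  for (j in seq_len(n_events)) {
    pos <- cursor + (if (j == 1L) edge else 0.12) + g[j]
    segs <- rbind(segs,
                  data.frame(start = cursor, end = pos, label = "modal"),
                  data.frame(start = pos, end = pos + len[j], label = lab[j]))
    cursor <- pos + len[j]
  }
  rbind(segs, data.frame(start = cursor, end = dur, label = "modal"))
}

#' Build a synthetic stimulus set mirroring the study design
#'
#' One utterance per infant x vocal class x age cell (default 7 x 3 x 2 =
#' 42 records), drawn from class templates and rejection-resampled so every
#' duration lies within the 400-2000 ms selection bounds.
#'
#' @param n_infants number of infants (default 7).
#' @param classes vocal classes (default wail, whine, vocant).
#' @param ages ages in months (default 0 and 1).
#' @param seed integer seed.
#' @param synthesize if `TRUE` (default) each record carries synthesized
#'   audio and its ground-truth tier; if `FALSE`, only specs are returned
#'   (fast, for design-level tests).
#' @return A list of [utterance_record()] (or of `synth_spec` when
#'   `synthesize = FALSE`).
#' @export
build_stimulus_set <- function(n_infants = 7,
                               classes = c("wail", "whine", "vocant"),
                               ages = c(0, 1), seed = NULL,
                               synthesize = TRUE) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n_infants)) {
      f0_off <- stats::runif(1, -25, 25)
      for (a in ages) for (cl in classes) {
        repeat {
          tm <- class_template(cl, f0_off)
          if (tm$dur >= 0.4 && tm$dur <= 2.0) break  # rejection filter
        }
        id <- sprintf("i%02d_a%d_%s", i, a, cl)
        spec <- synth_spec(duration_s = tm$dur, f0_base_hz = tm$f0,
                           contour = tm$contour,
                           tilt_db_per_octave = tm$tilt,
                           regime_schedule = random_schedule(tm$dur, tm$n_events),
                           seed = sample.int(.Machine$integer.max, 1))
        if (synthesize) {
          sy <- synth_utterance(spec, utterance_id = id)
          out[[id]] <- utterance_record(id, sy$waveform, sy$tier,
                                        infant_id = i, age_months = a,
                                        designated_class = cl)
        } else {
          spec$id <- id; spec$infant_id <- i; spec$age_months <- a
          spec$designated_class <- cl
          out[[id]] <- spec
        }
      }
    }
    out
  })
}

#' Specification for a simulated listener panel
#'
#' The generative stand-in for the study's rating model: each listener's
#' rating of a stimulus is a noisy, possibly drifting linear function of the
#' standardized acoustic features, plus a listener-level scale bias, clipped
#' to the 0-100 scale. Defaults state the study's world: 39 listeners (19
#' experienced), 10 trial blocks, grand mean near 45.8, listener bias SD
#' near the published 7.2.
#'
#' @param n_listeners,n_trials panel dimensions.
#' @param intercept grand intercept on the rating scale.
#' @param weight_mean mean feature weight(s), rating points per feature SD;
#'   recycled over features.
#' @param weight_sd between-listener SD of the weights.
#' @param bias_sd SD of the listener-level additive bias.
#' @param noise_sd SD of the per-rating noise.
#' @param drift_slope per-trial drift of the weights (rating points per SD
#'   per trial block) applied to drifting listeners, with random sign.
#' @param drift_fraction fraction of listeners that drift.
#' @param drift_parameters indices or names of features that drift (default
#'   all).
#' @param experience_effect added to the weights of features named in
#'   `experience_parameters` for the inexperienced group (the study found
#'   inexperienced listeners leaned more on the spectral parameters).
#' @param experience_parameters feature names receiving the effect.
#' @param n_experienced number of experienced listeners (default 19 of 39).
#' @param clip clip ratings to `[0, 100]` (default TRUE).
#' @param seed integer seed.
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(n_listeners = 39, n_trials = 10, intercept = 45.8,
                       weight_mean = 6, weight_sd = 1.5, bias_sd = 7.2,
                       noise_sd = 10, drift_slope = 0, drift_fraction = 0,
                       drift_parameters = NULL,
                       experience_effect = 0, experience_parameters = NULL,
                       n_experienced = round(n_listeners * 19 / 39),
                       clip = TRUE, seed = NULL) {
  stopifnot(n_listeners >= 2, n_trials >= 1, weight_sd >= 0, bias_sd >= 0,
            noise_sd >= 0, drift_fraction >= 0, drift_fraction <= 1)
  structure(as.list(environment()), class = "panel_spec")
}

#' Simulate a rating panel from acoustic features
#'
#' Draws per-listener weight vectors, biases, drifts and rating noise per
#' [panel_spec()], applies them to the standardized feature matrix, and
#' returns the panel together with the ground truth needed for recovery
#' tests. Warns if clipping affects 5% or more of the ratings (the linear
#' analyses assume clipping is rare).
#'
#' @param spec a [panel_spec()].
#' @param features `data.frame` with a `stimulus` column and numeric feature
#'   columns (a `mean_rating` column, if present, is ignored).
#' @return A list with `panel` (a [rating_panel()]) and `truth` (list:
#'   `weights` listener x feature matrix, `drift` matrix, `bias`,
#'   `intercept`, `clipped_fraction`).
#' @export
simulate_panel <- function(spec, features) {
  stopifnot(inherits(spec, "panel_spec"), is.data.frame(features))
  fcols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                   c("stimulus", "mean_rating"))
  if (!length(fcols)) stop("features has no usable numeric columns")
  Z <- as.matrix(standardize(features[fcols]))
  ns <- nrow(Z); np <- ncol(Z)
  nl <- spec$n_listeners; nt <- spec$n_trials
  with_seed(spec$seed, {
    wm <- rep_len(spec$weight_mean, np)
    W <- matrix(stats::rnorm(nl * np, rep(wm, each = nl), spec$weight_sd),
                nl, np, dimnames = list(NULL, fcols))
    exp_flag <- rep(FALSE, nl)
    if (nl >= 1) exp_flag[seq_len(min(spec$n_experienced, nl))] <- TRUE
    if (spec$experience_effect != 0) {
      ep <- spec$experience_parameters
      if (is.null(ep)) ep <- fcols
      W[!exp_flag, ep] <- W[!exp_flag, ep] + spec$experience_effect
    }
    D <- matrix(0, nl, np, dimnames = list(NULL, fcols))
    if (spec$drift_fraction > 0 && spec$drift_slope != 0) {
      drifters <- sample.int(nl, round(spec$drift_fraction * nl))
      dp <- spec$drift_parameters
      if (is.null(dp)) dp <- fcols
      D[drifters, dp] <- spec$drift_slope *
        sample(c(-1, 1), length(drifters), replace = TRUE)
    }
    bias <- stats::rnorm(nl, 0, spec$bias_sd)
    arr <- array(NA_real_, dim = c(nl, ns, nt),
                 dimnames = list(listener = sprintf("L%02d", seq_len(nl)),
                                 stimulus = as.character(features$stimulus),
                                 trial = as.character(seq_len(nt))))
    for (t in seq_len(nt)) {
      Wt <- W + D * (t - 1)
      mu <- spec$intercept + Wt %*% t(Z) + bias   # nl x ns
      arr[, , t] <- mu + stats::rnorm(nl * ns, 0, spec$noise_sd)
    }
    clipped <- mean(arr < 0 | arr > 100)
    if (spec$clip) {
      arr[arr < 0] <- 0
      arr[arr > 100] <- 100
    }
    if (clipped >= 0.05)
      warning(sprintf("clipping affects %.1f%% of ratings (>= 5%%)",
                      100 * clipped))
    meta <- data.frame(listener = dimnames(arr)[[1]], experienced = exp_flag,
                       stringsAsFactors = FALSE)
    list(panel = rating_panel(arr, listeners = meta),
         truth = list(weights = W, drift = D, bias = bias,
                      intercept = spec$intercept, features = fcols,
                      experienced = exp_flag, clipped_fraction = clipped))
  })
}
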