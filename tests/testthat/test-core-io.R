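test_that("waveform invariants and duration identities hold", {
  w <- waveform(numeric(16000), 16000)
  expect_equal(duration_s(w), 1.0)
  expect_equal(duration_ms(w), 1000)
  expect_error(waveform(numeric(0), 16000), "at least one sample")
  expect_error(waveform(0, -1), "positive")
  # Table-style formatting: 12144 samples at 16 kHz print as 759 ms
  expect_equal(duration_ms(waveform(numeric(12144), 16000)), 759)
})

test_that("WAV writer/reader round-trips within 16-bit quantization", {
  w <- tone(400, dur = 0.25)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path)
  back <- read_wav(path)
  expect_equal(back$rate, 16000)
  expect_equal(length(back$samples), length(w$samples))
  expect_lt(max(abs(back$samples - w$samples)), 1 / 32767)
})

test_that("multichannel and malformed WAVs are rejected", {
  # hand-build a 2-channel WAV header
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL); writeBin(36L, con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL); writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little"); writeBin(2L, con, 2, endian = "little")
  writeBin(16000L, con, 4, endian = "little")
  writeBin(64000L, con, 4, endian = "little")
  writeBin(4L, con, 2, endian = "little"); writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL); writeBin(0L, con, 4, endian = "little")
  close(con)
  expect_error(read_wav(path), "multichannel")
  path2 <- withr::local_tempfile(fileext = ".wav")
  writeLines("not audio", path2)
  expect_error(read_wav(path2))
})

test_that("regime tiers validate labels, overlaps and gaps", {
  segs <- rbind(regime_segment(0, 0.5, "modal"),
                regime_segment(0.5, 0.9, "subharmonic"))
  tier <- regime_tier(segs, "u1")
  expect_equal(count_regimes(tier), 2)
  expect_equal(tier$segments$label, c("modal", "subharmonic"))
  # numeric aliases and modulation codes
  seg <- regime_segment(0, 1, "3", modulations = c("5", "flutter"))
  expect_equal(seg$label, "subharmonic")
  expect_equal(seg$modulations, "trill,flutter")
  expect_error(regime_segment(0, 1, "loft"), "unknown regime label")
  expect_error(regime_tier(rbind(regime_segment(0, 0.6, "modal"),
                                 regime_segment(0.5, 0.9, "pulse"))),
               "overlap")
  expect_error(regime_tier(rbind(regime_segment(0, 0.4, "modal"),
                                 regime_segment(0.5, 0.9, "pulse"))),
               "gaps")
  # validation is idempotent: a validated tier re-validates cleanly
  expect_silent(regime_tier(tier$segments, tier$utterance_id))
})

test_that("tier TSV and TextGrid writers round-trip losslessly", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0.0\t0.5\tmodal\n0.5\t0.9\tsubharmonic", tsv)
  tier <- read_regime_tier(tsv)
  expect_equal(nrow(tier$segments), 2)
  expect_equal(tier$segments$end, c(0.5, 0.9))
  for (fmt in c("tsv", "textgrid")) {
    segs <- rbind(regime_segment(0, 0.35, "modal", "trill"),
                  regime_segment(0.35, 0.8, "aperiodic"),
                  regime_segment(0.8, 1.2, "pulse"))
    t0 <- regime_tier(segs, "rt")
    p <- withr::local_tempfile(fileext = if (fmt == "tsv") ".tsv" else ".TextGrid")
    write_regime_tier(t0, p, format = fmt)
    back <- read_regime_tier(p, utterance_id = "rt")
    expect_equal(back$segments$start, t0$segments$start, tolerance = 1e-8)
    expect_equal(back$segments$end, t0$segments$end, tolerance = 1e-8)
    expect_equal(back$segments$label, t0$segments$label)
    expect_equal(back$segments$modulations, t0$segments$modulations)
  }
  ov <- withr::local_tempfile(fileext = ".tsv")
  writeLines("0.0\t0.6\tmodal\n0.5\t0.9\tpulse", ov)
  expect_error(read_regime_tier(ov), "overlap")
})

test_that("rating tables validate, densify and round-trip", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("listener,stimulus,trial,rating",
               "L1,s1,1,10", "L1,s2,1,20", "L1,s3,1,30",
               "L2,s1,1,40", "L2,s2,1,50", "L2,s3,1,60"), csv)
  p <- read_rating_table(csv)
  expect_equal(dim(p$ratings), c(2, 3, 1))
  expect_equal(sum(p$ratings), 210)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("listener,stimulus,trial,rating", "L1,s1,1,101"), bad)
  expect_error(read_rating_table(bad), "\\[0, 100\\]")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("listener,stimulus,trial,rating", "L1,s1,1,5", "L1,s1,1,6"), dup)
  expect_error(read_rating_table(dup), "duplicate")
  # simulate -> write -> read -> bit-identical values
  sim <- simulate_panel(panel_spec(n_listeners = 5, n_trials = 3, seed = 42),
                        load_table3()[1:8, ])
  rt <- withr::local_tempfile(fileext = ".csv")
  write_rating_table(sim$panel, rt)
  back <- read_rating_table(rt)
  expect_identical(dim(back$ratings), dim(sim$panel$ratings))
  expect_equal(back$ratings[dimnames(sim$panel$ratings)[[1]],
                            dimnames(sim$panel$ratings)[[2]],
                            dimnames(sim$panel$ratings)[[3]]],
               sim$panel$ratings)
  expect_equal(back$listeners$experienced, sim$panel$listeners$experienced)
})

test_that("the packaged 42-stimulus table matches the published summaries", {
  t3 <- load_table3()
  expect_equal(nrow(t3), 42)
  expect_equal(unlist(t3[1, -1]),
               c(mean_rating = 3.93, duration_ms = 759, avg_pitch_hz = 318,
                 spectral_ratio = 19.8, n_regimes = 1))
  expect_equal(unlist(t3[42, -1]),
               c(mean_rating = 91.29, duration_ms = 1891, avg_pitch_hz = 423.6,
                 spectral_ratio = -8.9, n_regimes = 5))
  expect_equal(mean(t3$mean_rating), 45.82, tolerance = 0.01 / 45.82)
  # the duration repair reconciles the published duration mean (SD)
  t3c <- load_table3(corrected = TRUE)
  expect_equal(t3c$duration_ms[12], 738)
  expect_equal(round(mean(t3c$duration_ms), 1), 1030.6)
  expect_equal(round(sd(t3c$duration_ms), 0), round(450.9, 0))
  expect_equal(sum(t3$duration_ms != t3c$duration_ms), 1)
})

test_that("feature table IO enforces unique stimulus keys", {
  ft <- data.frame(stimulus = c("a", "b"), duration_ms = c(500, 700))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(ft, p)
  expect_equal(read_feature_table(p)$duration_ms, c(500, 700))
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stimulus,x", "a,1", "a,2"), dup)
  expect_error(read_feature_table(dup), "duplicate")
})
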