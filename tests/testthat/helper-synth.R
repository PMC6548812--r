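# Small signal builders used across the suite. Everything is generated in
# code; no audio fixtures are stored.

tone <- function(freq, dur = 1, rate = 16000, amp = 0.5) {
  waveform(amp * sin(2 * pi * freq * (0:(round(dur * rate) - 1)) / rate), rate)
}

noise_wave <- function(dur = 1, rate = 16000, sd = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  waveform(stats::rnorm(round(dur * rate), 0, sd), rate)
}

# impulse train at a fixed f0, optionally with cycle-to-cycle jitter (%)
pulse_train <- function(f0, dur = 1, rate = 16000, jitter_pct = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(dur * rate)
  x <- numeric(n)
  t <- 0
  while (t < dur) {
    i <- round(t * rate) + 1
    if (i <= n) x[i] <- 1
    t <- t + (1 / f0) * (1 + stats::rnorm(1, 0, jitter_pct / 100))
  }
  waveform(x, rate)
}

# dense complete panel with chosen values
panel_from_array <- function(values, nl, ns, nt) {
  rating_panel(array(values, dim = c(nl, ns, nt)))
}

# a three-segment schedule with a middle event
event_schedule <- function(dur, ev_start, ev_end, label) {
  data.frame(start = c(0, ev_start, ev_end), end = c(ev_start, ev_end, dur),
             label = c("modal", label, "modal"))
}
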