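#' Bundle an utterance's audio, tier and design metadata
#'
#' @param id utterance identifier.
#' @param waveform a [waveform()].
#' @param tier a [regime_tier()].
#' @param infant_id infant identifier.
#' @param age_months age in months, 0 or 1 in the study design.
#' @param designated_class one of `"wail"`, `"whine"`, `"vocant"`.
#' @param check_duration reject durations outside `[400, 2000]` ms, the
#'   stimulus-selection rule (set `FALSE` to carry flagged out-of-bound
#'   material).
#' @return An object of class `utterance_record`.
#' @export
utterance_record <- function(id, waveform, tier, infant_id = NA,
                             age_months = NA,
                             designated_class = c("wail", "whine", "vocant"),
                             check_duration = TRUE) {
  stopifnot(inherits(waveform, "waveform"), inherits(tier, "regime_tier"))
  designated_class <- match.arg(designated_class)
  if (!is.na(age_months) && !age_months %in% c(0, 1))
    stop("age_months must be 0 or 1")
  d <- duration_ms(waveform)
  if (check_duration && (d < 400 || d > 2000))
    stop("utterance duration ", d, " ms outside the 400-2000 ms selection bounds")
  structure(list(id = as.character(id), waveform = waveform, tier = tier,
                 infant_id = infant_id, age_months = age_months,
                 designated_class = designated_class),
            class = "utterance_record")
}

#' @export
print.utterance_record <- function(x, ...) {
  cat(sprintf("<utterance '%s': %s, infant %s, age %s mo, %d ms, %d regime(s)>\n",
              x$id, x$designated_class, x$infant_id, x$age_months,
              duration_ms(x$waveform), count_regimes(x$tier)))
  invisible(x)
}
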