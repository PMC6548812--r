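#' Load the packaged 42-stimulus distress table
#'
#' The package ships the published per-stimulus summary of the 42 infant
#' utterances (7 infants x 3 vocal types x 2 ages): mean distress rating of
#' the 39-listener panel (0-100), utterance duration (ms), average pitch
#' (Hz), spectral ratio (dB, minimum across regime segments) and number of
#' vibratory regimes.
#'
#' The printed duration of stimulus 12 (73 ms) contradicts the study's own
#' inclusion rule (utterances shorter than 400 ms were excluded) and is
#' inconsistent with the published duration summary mean (SD) of
#' 1030.6 (450.9): replacing 73 by 738 ms reproduces that mean and SD
#' exactly, so 738 ms is taken to be the value actually used in the
#' published regression. `corrected = TRUE` applies this single-cell repair;
#' the default returns the table exactly as printed.
#'
#' @param corrected replace stimulus 12's duration (73 ms as printed) by
#'   738 ms. Default `FALSE`.
#' @return A `data.frame` with 42 rows and columns `stimulus`,
#'   `mean_rating`, `duration_ms`, `avg_pitch_hz`, `spectral_ratio`,
#'   `n_regimes`.
#' @examples
#' t3 <- load_table3()
#' mean(t3$mean_rating)  # 45.82
#' @export
load_table3 <- function(corrected = FALSE) {
  path <- system.file("extdata", "distress_stimuli.csv", package = "cryregimes",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 42L)
  if (corrected) tab$duration_ms[tab$stimulus == 12] <- 738
  tab
}
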