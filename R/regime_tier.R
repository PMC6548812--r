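#' Vibratory-regime segments and tiers
#'
#' Infant utterances commonly chain several vibratory regimes -- sustained
#' modes of vocal-fold vibration. Four regimes are distinguished here:
#' `modal` (regular vibration, harmonics at integer multiples of f0),
#' `aperiodic` (chaotic or biphonated, harmonically unclear), `subharmonic`
#' (intervening harmonics at integer fractions of f0, period doubling or
#' tripling) and `pulse` (very low f0, individually resolvable glottal
#' pulses). Two modulation types, `trill` and `flutter`, may additionally be
#' flagged on a segment; they are carried through from manual annotation but
#' never auto-detected.
#'
#' Intervals are half-open `[start, end)` in seconds.
#'
#' @param start,end segment boundaries in seconds, `end > start`.
#' @param label one of `"modal"`, `"aperiodic"`, `"subharmonic"`, `"pulse"`
#'   (numeric codes `"1"`-`"4"` are accepted as aliases).
#' @param modulations character vector, subset of `c("trill", "flutter")`
#'   (codes `"5"`/`"6"` accepted).
#' @return `regime_segment()`: a one-row `data.frame` with columns `start`,
#'   `end`, `label`, `modulations` (comma-joined, `""` if none).
#' @export
regime_segment <- function(start, end, label, modulations = character()) {
  label <- normalize_regime_label(label)
  modulations <- vapply(modulations, normalize_modulation, character(1))
  if (!is.finite(start) || !is.finite(end) || end <= start)
    stop("segment must have finite end > start (got [", start, ", ", end, "))")
  data.frame(start = as.numeric(start), end = as.numeric(end),
             label = label,
             modulations = paste(unique(modulations), collapse = ","),
             stringsAsFactors = FALSE)
}

REGIME_LABELS <- c("modal", "aperiodic", "subharmonic", "pulse")

normalize_regime_label <- function(label) {
  aliases <- c("1" = "modal", "2" = "aperiodic", "3" = "subharmonic",
               "4" = "pulse",
               stats::setNames(REGIME_LABELS, REGIME_LABELS))
  key <- tolower(trimws(as.character(label)))
  if (!key %in% names(aliases))
    stop("unknown regime label: '", label, "' (expected one of ",
         paste(REGIME_LABELS, collapse = ", "), " or codes 1-4)")
  unname(aliases[key])
}

normalize_modulation <- function(m) {
  aliases <- c("5" = "trill", "6" = "flutter", trill = "trill", flutter = "flutter")
  key <- tolower(trimws(as.character(m)))
  if (!key %in% names(aliases))
    stop("unknown modulation flag: '", m, "' (expected trill/flutter or 5/6)")
  unname(aliases[key])
}

#' @rdname regime_segment
#' @param segments a `data.frame` of segments as returned by
#'   [regime_segment()] (rows will be sorted by `start`).
#' @param utterance_id identifier carried with the tier.
#' @param allow_gaps if `FALSE` (default) segments must tile the phonated
#'   span with no gaps.
#' @return `regime_tier()`: an object of class `regime_tier` with fields
#'   `segments` and `utterance_id`.
#' @export
regime_tier <- function(segments, utterance_id = "utt", allow_gaps = FALSE) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "label") %in% names(segments)))
  if (nrow(segments) == 0L) stop("tier must contain at least one segment")
  if (is.null(segments$modulations)) segments$modulations <- ""
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  segments$label <- vapply(segments$label, normalize_regime_label, character(1))
  if (any(segments$end <= segments$start))
    stop("segments must have end > start")
  if (nrow(segments) > 1L) {
    gap <- segments$start[-1L] - segments$end[-nrow(segments)]
    ov <- which(gap < -1e-9)
    if (length(ov))
      stop("overlapping segments at rows ", paste(ov, ov + 1L, collapse = "; ",
           sep = "-"))
    if (!allow_gaps && any(gap > 1e-6))
      stop("tier has gaps between segments (rows ",
           paste(which(gap > 1e-6), collapse = ", "),
           "); pass allow_gaps = TRUE to permit")
  }
  structure(list(segments = segments, utterance_id = as.character(utterance_id)),
            class = "regime_tier")
}

#' @export
print.regime_tier <- function(x, ...) {
  cat(sprintf("<regime_tier '%s': %d segment(s), %.3f-%.3f s>\n",
              x$utterance_id, nrow(x$segments),
              min(x$segments$start), max(x$segments$end)))
  print(x$segments)
  invisible(x)
}

#' Number of regime segments in a tier
#'
#' The number of vibratory-regime tokens within an utterance, one of the
#' strongest predictors of perceived distress.
#'
#' @param tier a [regime_tier()].
#' @return Integer count, >= 1.
#' @export
count_regimes <- function(tier) {
  stopifnot(inherits(tier, "regime_tier"))
  n <- nrow(tier$segments)
  if (n < 1L) stop("empty tier")
  n
}

#' Read a regime tier from TSV or Praat TextGrid
#'
#' TSV format: three or four tab-separated columns `start`, `end`, `label`
#' (optionally `modulations`), no header. TextGrid format: a full or short
#' Praat TextGrid; the interval tier named `"regimes"` (or the first
#' interval tier) is used, empty-label intervals are skipped. Labels may be
#' regime names or codes 1-4, with `+trill` / `+flutter` suffixes.
#'
#' @param path input path.
#' @param format `"textgrid"` or `"tsv"`; guessed from the file extension by
#'   default.
#' @param utterance_id identifier for the tier (default: file base name).
#' @return A validated [regime_tier()].
#' @export
read_regime_tier <- function(path, format = c("auto", "textgrid", "tsv"),
                             utterance_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.textgrid$", tolower(path))) "textgrid" else "tsv"
  }
  if (is.null(utterance_id))
    utterance_id <- sub("\\.[^.]*$", "", basename(path))
  rows <- if (format == "tsv") parse_tier_tsv(path) else parse_tier_textgrid(path)
  segs <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    lab <- parse_regime_label(rows$label[i])
    regime_segment(rows$start[i], rows$end[i], lab$label, lab$modulations)
  }))
  regime_tier(segs, utterance_id = utterance_id)
}

parse_regime_label <- function(s) {
  parts <- strsplit(trimws(s), "+", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  list(label = parts[1], modulations = if (length(parts) > 1) parts[-1] else character())
}

parse_tier_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           colClasses = "character")
  if (ncol(tab) < 3) stop("tier TSV needs at least 3 columns (start, end, label)")
  label <- tab[[3]]
  if (ncol(tab) >= 4) {
    extra <- tab[[4]]
    has <- !is.na(extra) & nzchar(trimws(extra))
    label[has] <- paste(label[has], gsub(",", "+", trimws(extra[has])), sep = "+")
  }
  data.frame(start = as.numeric(tab[[1]]), end = as.numeric(tab[[2]]),
             label = label, stringsAsFactors = FALSE)
}

parse_tier_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  num <- function(s) as.numeric(sub(".*=\\s*", "", s))
  str <- function(s) gsub("\"", "", sub(".*=\\s*", "", s))
  # long-format TextGrid: find the "regimes" interval tier (or first one)
  tier_starts <- grep("item \\[", lines)
  if (!length(tier_starts)) stop("no tiers found in TextGrid: ", path)
  tier_starts <- tier_starts[-1]  # first match is "item []:"
  pick <- NULL
  for (ts in tier_starts) {
    nm <- str(lines[grep("name =", lines[ts:length(lines)])[1] + ts - 1])
    cl <- str(lines[grep("class =", lines[ts:length(lines)])[1] + ts - 1])
    if (identical(cl, "IntervalTier") && (is.null(pick) || identical(nm, "regimes")))
      if (is.null(pick) || identical(nm, "regimes")) pick <- ts
    if (!is.null(pick) && identical(nm, "regimes")) break
  }
  if (is.null(pick)) stop("no interval tier found in TextGrid: ", path)
  end_of_tier <- c(tier_starts[tier_starts > pick], length(lines) + 1L)[1] - 1L
  block <- lines[pick:end_of_tier]
  xmins <- num(grep("xmin =", block, value = TRUE))[-1]  # first xmin is tier's own
  xmaxs <- num(grep("xmax =", block, value = TRUE))[-1]
  texts <- str(grep("text =", block, value = TRUE))
  keep <- nzchar(trimws(texts))
  if (!any(keep)) stop("TextGrid tier has no labeled intervals: ", path)
  data.frame(start = xmins[keep], end = xmaxs[keep], label = texts[keep],
             stringsAsFactors = FALSE)
}

#' Write a regime tier
#'
#' @param tier a [regime_tier()].
#' @param path output path.
#' @param format `"tsv"` (default) or `"textgrid"`.
#' @return `path`, invisibly.
#' @export
write_regime_tier <- function(tier, path, format = c("tsv", "textgrid")) {
  stopifnot(inherits(tier, "regime_tier"))
  format <- match.arg(format)
  s <- tier$segments
  lab <- ifelse(nzchar(s$modulations),
                paste(s$label, gsub(",", "+", s$modulations), sep = "+"), s$label)
  if (format == "tsv") {
    utils::write.table(
      data.frame(start = s$start, end = s$end, label = lab),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    xmin <- min(s$start); xmax <- max(s$end)
    out <- c('File type = "ooTextFile"', 'Object class = "TextGrid"', "",
             sprintf("xmin = %.10g", xmin), sprintf("xmax = %.10g", xmax),
             "tiers? <exists>", "size = 1", "item []:", "    item [1]:",
             '        class = "IntervalTier"', '        name = "regimes"',
             sprintf("        xmin = %.10g", xmin),
             sprintf("        xmax = %.10g", xmax),
             sprintf("        intervals: size = %d", nrow(s)))
    for (i in seq_len(nrow(s))) {
      out <- c(out, sprintf("        intervals [%d]:", i),
               sprintf("            xmin = %.10g", s$start[i]),
               sprintf("            xmax = %.10g", s$end[i]),
               sprintf('            text = "%s"', lab[i]))
    }
    writeLines(out, path)
  }
  invisible(path)
}

#' Extract the audio of one regime segment
#'
#' Returns the samples covering exactly `[start, end)` at the original rate.
#'
#' @param w a [waveform()].
#' @param segment a one-row segment `data.frame` (from a tier's `segments`)
#'   or anything with `start` and `end` fields in seconds.
#' @return A [waveform()] whose `t0` is the segment start.
#' @export
slice_waveform <- function(w, segment) {
  stopifnot(inherits(w, "waveform"))
  s <- as.numeric(segment$start); e <- as.numeric(segment$end)
  # allow spillover of half a sample: tier ends are stated in continuous
  # time while the waveform is quantized to whole samples
  if (s < w$t0 - 1e-9 || e > w$t0 + duration_s(w) + 0.5 / w$rate)
    stop(sprintf("segment [%g, %g) lies outside waveform span [%g, %g)",
                 s, e, w$t0, w$t0 + duration_s(w)))
  i0 <- round((s - w$t0) * w$rate)
  i1 <- round((e - w$t0) * w$rate)
  i1 <- min(i1, length(w$samples))
  waveform(w$samples[(i0 + 1L):i1], rate = w$rate, t0 = s)
}
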