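#' Construct a listener rating panel
#'
#' A rating panel stores distress ratings on the 0-100 scale for every
#' listener x stimulus x trial cell of a blocked-presentation design (the
#' study design is 39 listeners x 42 stimuli x 10 trial blocks). Missing
#' cells are `NA`. Listener metadata carries at minimum the `experienced`
#' flag (prior training in infant vocalization coding).
#'
#' @param ratings a 3-d numeric array `[listener, stimulus, trial]` with
#'   dimnames, values in `[0, 100]` or `NA`.
#' @param listeners optional `data.frame` of listener metadata with a
#'   `listener` column and (optionally) `experienced`, `parent`, `sex`.
#' @return An object of class `rating_panel`.
#' @export
rating_panel <- function(ratings, listeners = NULL) {
  stopifnot(is.array(ratings), length(dim(ratings)) == 3L)
  bad <- !is.na(ratings) & (ratings < 0 | ratings > 100)
  if (any(bad))
    stop(sum(bad), " rating(s) outside [0, 100]; first offender ",
         format(ratings[which(bad)[1]]))
  if (is.null(dimnames(ratings)))
    dimnames(ratings) <- list(
      listener = paste0("L", seq_len(dim(ratings)[1])),
      stimulus = paste0("S", seq_len(dim(ratings)[2])),
      trial = as.character(seq_len(dim(ratings)[3])))
  names(dimnames(ratings)) <- c("listener", "stimulus", "trial")
  if (is.null(listeners))
    listeners <- data.frame(listener = dimnames(ratings)[[1]],
                            experienced = NA, stringsAsFactors = FALSE)
  stopifnot(all(dimnames(ratings)[[1]] %in% listeners$listener))
  listeners <- listeners[match(dimnames(ratings)[[1]], listeners$listener), ,
                         drop = FALSE]
  rownames(listeners) <- NULL
  structure(list(ratings = ratings, listeners = listeners),
            class = "rating_panel")
}

#' @export
print.rating_panel <- function(x, ...) {
  d <- dim(x$ratings)
  cat(sprintf("<rating_panel: %d listeners x %d stimuli x %d trials, %d missing>\n",
              d[1], d[2], d[3], sum(is.na(x$ratings))))
  invisible(x)
}

#' Read a long-format rating table
#'
#' Expects a UTF-8 comma-separated file with header columns `listener`,
#' `stimulus`, `trial`, `rating` and optionally `experienced`. Each
#' (listener, stimulus, trial) key must occur at most once; ratings must lie
#' in `[0, 100]`. Unobserved cells become `NA`.
#'
#' @param path CSV path.
#' @return A [rating_panel()].
#' @export
read_rating_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("listener", "stimulus", "trial", "rating")
  if (!all(need %in% names(tab)))
    stop("rating CSV must have columns ", paste(need, collapse = ", "))
  if (any(tab$rating < 0 | tab$rating > 100, na.rm = TRUE))
    stop("ratings outside [0, 100] in ", path)
  key <- paste(tab$listener, tab$stimulus, tab$trial, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (listener, stimulus, trial) rows: e.g. ",
         gsub("\r", "/", key[duplicated(key)][1]))
  ls <- sort(unique(as.character(tab$listener)))
  ss <- unique(as.character(tab$stimulus))  # keep file order for stimuli
  ts <- sort(unique(tab$trial))
  arr <- array(NA_real_, dim = c(length(ls), length(ss), length(ts)),
               dimnames = list(listener = ls, stimulus = ss,
                               trial = as.character(ts)))
  arr[cbind(match(as.character(tab$listener), ls),
            match(as.character(tab$stimulus), ss),
            match(tab$trial, ts))] <- tab$rating
  meta <- if ("experienced" %in% names(tab)) {
    m <- unique(tab[, c("listener", "experienced")])
    m$listener <- as.character(m$listener)
    if (anyDuplicated(m$listener))
      stop("inconsistent 'experienced' flag within a listener")
    m
  } else NULL
  rating_panel(arr, listeners = meta)
}

#' Write a rating panel as a long-format CSV
#'
#' Inverse of [read_rating_table()]: round-trips losslessly (missing cells
#' are omitted from the file).
#'
#' @param panel a [rating_panel()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rating_table <- function(panel, path) {
  stopifnot(inherits(panel, "rating_panel"))
  dn <- dimnames(panel$ratings)
  long <- expand.grid(listener = dn[[1]], stimulus = dn[[2]], trial = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$rating <- as.vector(panel$ratings)
  long <- long[!is.na(long$rating), , drop = FALSE]
  if ("experienced" %in% names(panel$listeners) &&
      !all(is.na(panel$listeners$experienced)))
    long$experienced <- panel$listeners$experienced[
      match(long$listener, panel$listeners$listener)]
  long$trial <- as.integer(long$trial)
  long <- long[order(long$listener, long$stimulus, long$trial), , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a feature table
#'
#' A feature table is a `data.frame` keyed by `stimulus` holding per-
#' utterance acoustic parameters (fixed units: ms, Hz, dB, kHz, count) and
#' optionally a `mean_rating` column.
#'
#' @param path CSV path.
#' @return `read_feature_table()`: a `data.frame` with unique `stimulus` ids.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"stimulus" %in% names(tab)) stop("feature CSV must have a 'stimulus' column")
  if (anyDuplicated(tab$stimulus))
    stop("duplicate stimulus ids: ", tab$stimulus[duplicated(tab$stimulus)][1])
  tab
}

#' @rdname read_feature_table
#' @param features a feature `data.frame` with a `stimulus` column.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(is.data.frame(features), "stimulus" %in% names(features))
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
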