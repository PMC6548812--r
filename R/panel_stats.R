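#' Mean individual ratings: listener x stimulus means over trials
#'
#' The "mean individual ratings" of the study design: for each listener and
#' stimulus, the mean rating across the trial blocks, missing-aware.
#'
#' @param panel a [rating_panel()].
#' @return A listener x stimulus numeric matrix.
#' @export
per_listener_means <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  m <- apply(panel$ratings, c(1, 2), mean, na.rm = TRUE)
  if (any(is.nan(m))) {
    warning(sum(is.nan(m)), " listener x stimulus cell(s) have no trials; ",
            "left missing")
    m[is.nan(m)] <- NA_real_
  }
  m
}

# Pearson r, NA when either side is degenerate (zero variance).
safe_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Pairwise inter-rater correlations
#'
#' Pearson correlation over stimuli for every unordered pair of listeners'
#' mean individual ratings (C(n, 2) pairs). Pairs involving a zero-variance
#' listener are undefined and excluded from the summary with a warning.
#'
#' @param means listener x stimulus matrix from [per_listener_means()].
#' @return List with `pairs` (data.frame listener_a, listener_b, r), `mean`
#'   and `range` over defined pairs.
#' @export
interrater_pairwise <- function(means) {
  n <- nrow(means)
  if (n < 2 || ncol(means) < 3) stop("need >= 2 listeners and >= 3 stimuli")
  idx <- utils::combn(n, 2)
  r <- apply(idx, 2, function(p) safe_cor(means[p[1], ], means[p[2], ]))
  pairs <- data.frame(listener_a = rownames(means)[idx[1, ]],
                      listener_b = rownames(means)[idx[2, ]], r = r)
  if (anyNA(r)) warning(sum(is.na(r)), " pair(s) with undefined correlation excluded")
  list(pairs = pairs, mean = mean(r, na.rm = TRUE),
       range = range(r, na.rm = TRUE))
}

#' Leave-one-out inter-rater correlations
#'
#' For each listener, the Pearson correlation between that listener's mean
#' individual ratings and the mean of all other listeners' ratings.
#'
#' @param means listener x stimulus matrix from [per_listener_means()].
#' @return List with `r` (named per-listener vector), `mean` and `range`.
#' @export
leave_one_out <- function(means) {
  n <- nrow(means)
  if (n < 3) stop("need >= 3 listeners")
  r <- vapply(seq_len(n), function(i)
    safe_cor(means[i, ], colMeans(means[-i, , drop = FALSE], na.rm = TRUE)),
    numeric(1))
  names(r) <- rownames(means)
  if (anyNA(r)) warning(sum(is.na(r)), " undefined correlation(s) excluded")
  list(r = r, mean = mean(r, na.rm = TRUE), range = range(r, na.rm = TRUE))
}

#' Intra-rater consistency across trial blocks
#'
#' For each listener, the Pearson correlation (over stimuli) between every
#' unordered pair of trial-block rating vectors -- C(n_trials, 2) pairs, 45
#' in the 10-block design -- and its per-listener mean.
#'
#' @param panel a [rating_panel()].
#' @return List with `per_listener` (named mean r per listener), `pair_r`
#'   (matrix listener x pair), `mean` and `range` of the per-listener means.
#' @export
intrarater_consistency <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  nt <- dim(panel$ratings)[3]
  if (nt < 2) stop("need >= 2 trial blocks")
  idx <- utils::combn(nt, 2)
  nl <- dim(panel$ratings)[1]
  pr <- t(vapply(seq_len(nl), function(l)
    apply(idx, 2, function(p)
      safe_cor(panel$ratings[l, , p[1]], panel$ratings[l, , p[2]])),
    numeric(ncol(idx))))
  rownames(pr) <- dimnames(panel$ratings)[[1]]
  per <- rowMeans(pr, na.rm = TRUE)
  if (anyNA(pr)) warning("undefined trial-pair correlation(s) excluded from means")
  list(per_listener = per, pair_r = pr, mean = mean(per), range = range(per))
}

#' Inter- vs intra-rater coefficient-of-variation analysis
#'
#' `inter_cv` is the SD/mean of the listeners' grand mean ratings (scale-
#' usage bias across listeners). `intra_cv` is, per listener, the SD/mean of
#' that listener's trial-block mean ratings (rating noise within a
#' listener), averaged over listeners. Their difference (`excess`, also as a
#' percentage of the intra-rater CV) measures bias across listeners beyond
#' rating noise.
#'
#' @param panel a [rating_panel()].
#' @return List with `inter_cv`, `intra_cv` (mean), `intra_cv_per_listener`,
#'   `excess` and `excess_pct`.
#' @export
cv_analysis <- function(panel) {
  stopifnot(inherits(panel, "rating_panel"))
  grand <- apply(panel$ratings, 1, mean, na.rm = TRUE)
  if (mean(grand) == 0) stop("zero grand mean rating")
  inter <- stats::sd(grand) / mean(grand)
  block_means <- apply(panel$ratings, c(1, 3), mean, na.rm = TRUE)
  intra_per <- apply(block_means, 1, function(b) stats::sd(b) / mean(b))
  intra <- mean(intra_per)
  list(inter_cv = inter, intra_cv = intra, intra_cv_per_listener = intra_per,
       excess = inter - intra, excess_pct = 100 * (inter - intra) / intra)
}

#' Scale-usage histogram of mean ratings
#'
#' Counts the per-listener per-stimulus mean ratings within 20 intervals of
#' width 5 across the 0-100 scale. Bins are `(0,5], (5,10], ..., (95,100]`
#' with exact 0 assigned to the first bin; a full 39 x 42 panel yields 1638
#' means in total.
#'
#' @param means listener x stimulus matrix from [per_listener_means()].
#' @param bin_width bin width (default 5; must divide 100).
#' @return A `data.frame` with `bin_low`, `bin_high`, `count`; counts sum to
#'   the number of non-missing means.
#' @export
rating_histogram <- function(means, bin_width = 5) {
  v <- as.vector(means)
  v <- v[!is.na(v)]
  if (any(v < 0 | v > 100)) stop("mean ratings outside [0, 100]")
  if (100 %% bin_width != 0) stop("bin_width must divide 100")
  edges <- seq(0, 100, by = bin_width)
  cuts <- cut(v, breaks = edges, include.lowest = TRUE, right = TRUE)
  counts <- as.integer(table(cuts))
  data.frame(bin_low = utils::head(edges, -1), bin_high = edges[-1],
             count = counts)
}

#' Full agreement report for a rating panel
#'
#' Bundles [interrater_pairwise()], [leave_one_out()],
#' [intrarater_consistency()] and [cv_analysis()] into one report.
#'
#' @param panel a [rating_panel()].
#' @return A list of class `agreement_report`.
#' @export
agreement_report <- function(panel) {
  means <- per_listener_means(panel)
  loo <- if (nrow(means) >= 3) leave_one_out(means) else NULL
  structure(list(interrater = interrater_pairwise(means),
                 leave_one_out = loo,
                 intrarater = intrarater_consistency(panel),
                 cv = cv_analysis(panel)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "Agreement report\n  inter-rater pairwise r: mean %.3f (range %.3f-%.3f, %d pairs)\n",
    x$interrater$mean, x$interrater$range[1], x$interrater$range[2],
    nrow(x$interrater$pairs)))
  if (!is.null(x$leave_one_out))
    cat(sprintf("  leave-one-out r:        mean %.3f (range %.3f-%.3f)\n",
                x$leave_one_out$mean, x$leave_one_out$range[1],
                x$leave_one_out$range[2]))
  cat(sprintf(paste0(
    "  intra-rater trial r:    mean %.3f (range %.3f-%.3f)\n",
    "  inter CV %.3f vs mean intra CV %.3f (excess %.3f, %.0f%%)\n"),
    x$intrarater$mean, x$intrarater$range[1], x$intrarater$range[2],
    x$cv$inter_cv, x$cv$intra_cv, x$cv$excess, x$cv$excess_pct))
  invisible(x)
}
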