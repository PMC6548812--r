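#' Trial-wise listener-parameter correlation cube
#'
#' For each listener, acoustic parameter and trial block, the Pearson
#' correlation (across stimuli) between that trial block's ratings and the
#' parameter values -- the raw material of the within- and across-listener
#' analyses of acoustic-cue use.
#'
#' @param panel a [rating_panel()] whose stimulus dimension aligns with
#'   `features` rows.
#' @param features `data.frame` with a `stimulus` column and numeric
#'   parameter columns.
#' @param parameters parameter column names (default: all numeric columns
#'   except `stimulus`).
#' @return A 3-d array `r[listener, parameter, trial]` of class
#'   `trial_correlation_cube`; degenerate (zero-variance) cells are `NA`
#'   with a warning.
#' @export
trial_parameter_correlations <- function(panel, features, parameters = NULL) {
  stopifnot(inherits(panel, "rating_panel"), is.data.frame(features))
  sn <- dimnames(panel$ratings)[[2]]
  if (!"stimulus" %in% names(features)) stop("features needs a 'stimulus' column")
  idx <- match(sn, as.character(features$stimulus))
  if (anyNA(idx))
    stop("stimuli missing from features: ", paste(sn[is.na(idx)], collapse = ", "))
  features <- features[idx, , drop = FALSE]
  if (is.null(parameters))
    parameters <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                          c("stimulus", "mean_rating"))
  d <- dim(panel$ratings)
  cube <- array(NA_real_, dim = c(d[1], length(parameters), d[3]),
                dimnames = list(listener = dimnames(panel$ratings)[[1]],
                                parameter = parameters,
                                trial = dimnames(panel$ratings)[[3]]))
  for (p in seq_along(parameters)) {
    fv <- features[[parameters[p]]]
    for (t in seq_len(d[3]))
      cube[, p, t] <- apply(panel$ratings[, , t, drop = FALSE][, , 1], 1,
                            function(row) safe_cor(row, fv))
  }
  if (anyNA(cube)) warning(sum(is.na(cube)), " degenerate cell(s) in cube")
  class(cube) <- c("trial_correlation_cube", class(cube))
  cube
}

#' Cox-Stuart test for monotone trend
#'
#' Nonparametric sign test: the series is split into halves (the middle
#' element dropped when the length is odd), element i of the first half is
#' paired with element i of the second, tied pairs are dropped, and the
#' count S of positive differences is referred to Binomial(n_pairs, 1/2)
#' for a two-sided p-value.
#'
#' Note the test's discreteness: with the study's 10 trial blocks there are
#' only 5 pairs, so the smallest attainable two-sided p is 0.0625 and no
#' series can reject at 0.05 two-sided; `alternative = "increasing"` /
#' `"decreasing"` give the one-sided variants.
#'
#' @param series numeric vector, length >= 4.
#' @param alternative `"two.sided"` (default), `"increasing"` or
#'   `"decreasing"`.
#' @return A list of class `trend_result`: `S`, `n_pairs`, `p`,
#'   `direction` (`"increasing"`, `"decreasing"` or `"none"`), `degenerate`
#'   (all pairs tied).
#' @export
cox_stuart <- function(series,
                       alternative = c("two.sided", "increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  series <- as.numeric(series)
  n <- length(series)
  if (n < 4) stop("series must have length >= 4")
  m <- n %/% 2L
  first <- series[seq_len(m)]
  second <- series[(n - m + 1L):n]
  d <- second - first
  d <- d[d != 0]
  np <- length(d)
  if (np == 0L)
    return(structure(list(S = 0L, n_pairs = 0L, p = 1, direction = "none",
                          degenerate = TRUE), class = "trend_result"))
  S <- sum(d > 0)
  p <- switch(alternative,
    two.sided = min(1, 2 * stats::pbinom(max(S, np - S) - 1L, np, 0.5,
                                         lower.tail = FALSE)),
    increasing = stats::pbinom(S - 1L, np, 0.5, lower.tail = FALSE),
    decreasing = stats::pbinom(S, np, 0.5))
  structure(list(S = as.integer(S), n_pairs = np, p = p,
                 direction = if (S > np / 2) "increasing"
                             else if (S < np / 2) "decreasing" else "none",
                 degenerate = FALSE),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Cox-Stuart trend: S = %d of %d pairs, two-sided p = %.4g (%s)%s\n",
              x$S, x$n_pairs, x$p, x$direction,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Trend battery and prevalence test across listeners
#'
#' Applies [cox_stuart()] to each listener's trial-wise correlation series
#' for each parameter, counts listeners with a significant trend
#' (p <= `alpha`), and tests each count against the chance proportion `p0`
#' with a 1-df chi-square goodness-of-fit; the effect size is
#' `w = sqrt(chi2 / n)`. Degenerate series count as non-significant.
#'
#' @param cube a [trial_parameter_correlations()] cube.
#' @param alpha significance level for the per-listener trend tests.
#' @param p0 chance proportion for the prevalence test (default `alpha`).
#' @param alternative passed to [cox_stuart()]; note that with 10 trial
#'   blocks the two-sided test cannot reject at alpha = 0.05.
#' @return A `data.frame` with one row per parameter: `n_significant`,
#'   `n_listeners`, `chi_square`, `p`, `effect_w`, plus attribute `trends`
#'   (per listener x parameter p-value matrix).
#' @export
trend_battery <- function(cube, alpha = 0.05, p0 = alpha,
                          alternative = "two.sided") {
  stopifnot(length(dim(cube)) == 3L)
  if (dim(cube)[3] < 4) stop("need >= 4 trials per listener")
  nl <- dim(cube)[1]; params <- dimnames(cube)[[2]]
  pmat <- matrix(NA_real_, nl, length(params),
                 dimnames = list(dimnames(cube)[[1]], params))
  for (p in seq_along(params))
    for (l in seq_len(nl)) {
      s <- cube[l, p, ]
      pmat[l, p] <- if (anyNA(s)) NA_real_ else cox_stuart(s, alternative)$p
    }
  res <- do.call(rbind, lapply(params, function(pp) {
    k <- sum(pmat[, pp] <= alpha, na.rm = TRUE)
    exp_k <- nl * p0
    chi2 <- (k - exp_k)^2 / exp_k + ((nl - k) - nl * (1 - p0))^2 / (nl * (1 - p0))
    data.frame(parameter = pp, n_significant = k, n_listeners = nl,
               chi_square = chi2,
               p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
               effect_w = sqrt(chi2 / nl), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "trends") <- pmat
  res
}

#' Permutation test of across-listener heterogeneity in cue use
#'
#' Tests, for one acoustic parameter, whether listeners differ in how
#' strongly their ratings correlate with the parameter. Each permutation
#' draws two subgroups of listeners with replacement (size `group_size`,
#' default `floor(n/2)`; identical draws are redrawn) and compares the
#' subgroup means of the Fisher-z transformed per-listener correlations
#' with a two-sample z-test whose standard error is the known sampling
#' error of a correlation computed over `n_stimuli` items
#' (`1/sqrt(n_stimuli - 3)` per listener). Under homogeneity --
#' between-listener differences no larger than correlation sampling noise
#' -- the test rejects at rate `alpha`; genuine subpopulations inflate the
#' between-listener spread beyond that error and drive the rejection rate
#' up for any random split. Reported is the proportion of permutations
#' failing to reject, near `1 - alpha` under homogeneity and well below it
#' under heterogeneity.
#'
#' @param per_listener_r numeric vector: each listener's correlation with
#'   the parameter (e.g. mean over trials of a cube slice).
#' @param n_stimuli number of stimuli each correlation was computed over
#'   (42 in the study design); sets the within-listener sampling error.
#' @param n_perm number of permutations (default 10000; a warning is given
#'   below 100).
#' @param group_size subgroup size for each draw.
#' @param alpha test level within each permutation.
#' @param seed optional integer seed for reproducibility.
#' @return A list of class `permutation_report`: `proportion_fail_to_reject`,
#'   `n_permutations`, `group_size`, `alpha`, `n_stimuli`, `seed`.
#' @export
interrater_permutation <- function(per_listener_r, n_stimuli = 42,
                                   n_perm = 10000, group_size = NULL,
                                   alpha = 0.05, seed = NULL) {
  r <- per_listener_r[!is.na(per_listener_r)]
  n <- length(r)
  if (n < 4) stop("need >= 4 listeners with defined correlations")
  if (n_stimuli < 4) stop("n_stimuli must be at least 4")
  if (n_perm < 100) warning("n_perm < 100: proportion estimate will be noisy")
  if (is.null(group_size)) group_size <- n %/% 2L
  if (!is.null(seed)) set.seed(seed)
  z <- atanh(pmin(0.999999, pmax(-0.999999, r)))
  se1 <- 1 / sqrt(n_stimuli - 3)
  crit <- stats::qnorm(1 - alpha / 2)
  fails <- 0L
  for (i in seq_len(n_perm)) {
    repeat {
      g1 <- sample.int(n, group_size, replace = TRUE)
      g2 <- sample.int(n, group_size, replace = TRUE)
      if (!identical(sort(g1), sort(g2))) break
    }
    stat <- (mean(z[g1]) - mean(z[g2])) / (se1 * sqrt(2 / group_size))
    if (abs(stat) <= crit) fails <- fails + 1L
  }
  structure(list(proportion_fail_to_reject = fails / n_perm,
                 n_permutations = n_perm, group_size = group_size,
                 alpha = alpha, n_stimuli = n_stimuli, seed = seed),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf(
    "Permutation heterogeneity test: %.3f of %d permutations fail to reject (alpha = %g)\n",
    x$proportion_fail_to_reject, x$n_permutations, x$alpha))
  invisible(x)
}

#' Experience contrast on acoustic-cue use and rating level
#'
#' Compares experienced vs inexperienced listeners: per acoustic parameter,
#' a Wilcoxon rank-sum test on the per-listener mean correlations with the
#' parameter, Bonferroni-adjusted over the family of parameters; plus a
#' separate Wilcoxon contrast on the listeners' grand mean rating levels.
#'
#' @param cube a [trial_parameter_correlations()] cube.
#' @param experienced logical vector per listener (aligned with the cube's
#'   listener dimension).
#' @param panel optional [rating_panel()] for the rating-level contrast.
#' @param alpha family-wise level for the Bonferroni decisions.
#' @return A list with `by_parameter` (data.frame: parameter, p_raw,
#'   p_bonferroni, reject, mean r per group) and `rating_level` (list with
#'   the group means and Wilcoxon p), of class `experience_contrast`.
#' @export
experience_contrast <- function(cube, experienced, panel = NULL, alpha = 0.05) {
  stopifnot(length(dim(cube)) == 3L,
            length(experienced) == dim(cube)[1])
  experienced <- as.logical(experienced)
  if (!any(experienced) || all(experienced))
    stop("both experienced and inexperienced groups must be non-empty")
  if (min(sum(experienced), sum(!experienced)) < 3)
    warning("a group has fewer than 3 listeners; tests will be underpowered")
  params <- dimnames(cube)[[2]]
  mean_r <- apply(cube, c(1, 2), mean, na.rm = TRUE)
  m <- length(params)
  by_param <- do.call(rbind, lapply(seq_along(params), function(p) {
    x <- mean_r[experienced, p]; y <- mean_r[!experienced, p]
    praw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
    data.frame(parameter = params[p],
               mean_r_experienced = mean(x), mean_r_inexperienced = mean(y),
               p_raw = praw, p_bonferroni = min(1, praw * m),
               reject = min(1, praw * m) <= alpha, stringsAsFactors = FALSE)
  }))
  rating_level <- NULL
  if (!is.null(panel)) {
    grand <- apply(panel$ratings, 1, mean, na.rm = TRUE)
    pr <- suppressWarnings(stats::wilcox.test(grand[experienced],
                                              grand[!experienced],
                                              exact = FALSE)$p.value)
    rating_level <- list(mean_experienced = mean(grand[experienced]),
                         mean_inexperienced = mean(grand[!experienced]),
                         p = pr, reject = pr <= alpha)
  }
  structure(list(by_parameter = by_param, rating_level = rating_level,
                 alpha = alpha, family_size = m),
            class = "experience_contrast")
}

#' @export
print.experience_contrast <- function(x, ...) {
  cat(sprintf("Experience contrast (Bonferroni over %d parameters, alpha = %g)\n",
              x$family_size, x$alpha))
  print(x$by_parameter, row.names = FALSE)
  if (!is.null(x$rating_level))
    cat(sprintf("Rating level: experienced %.1f vs inexperienced %.1f (p = %.3g)\n",
                x$rating_level$mean_experienced,
                x$rating_level$mean_inexperienced, x$rating_level$p))
  invisible(x)
}
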