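#' Z-score the columns of a feature table
#'
#' Columns are centered and scaled to unit sample SD (n-1 denominator).
#' Constant columns are an error since their z-score is undefined.
#'
#' @param table `data.frame` of numeric columns.
#' @return The z-scored `data.frame`, with attributes `center` and `scale`
#'   holding the per-column means and SDs.
#' @export
standardize <- function(table) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1))
  if (!all(num)) stop("all columns must be numeric")
  ctr <- vapply(table, mean, numeric(1))
  scl <- vapply(table, stats::sd, numeric(1))
  if (any(scl == 0))
    stop("constant column(s): ", paste(names(table)[scl == 0], collapse = ", "))
  out <- as.data.frame(mapply(function(col, m, s) (col - m) / s,
                              table, ctr, scl, SIMPLIFY = FALSE))
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  out
}

# Gaussian AIC up to an additive constant: n log(RSS/n) + 2k, where k counts
# all estimated mean coefficients (intercept included). Matches the scale
# used by stats::extractAIC.
rss_aic <- function(rss, n, k) n * log(rss / n) + 2 * k

#' Ordinary least squares fit of distress ratings on acoustic predictors
#'
#' Fits `response ~ predictors` with an intercept by least squares.
#' Standardized coefficients are computed from the same fit on z-scored
#' predictors with the raw response, so they are in rating points per
#' predictor SD and the standardized intercept equals the mean response.
#' Variance inflation factors are reported (not enforced) as a collinearity
#' diagnostic.
#'
#' @param features `data.frame` holding the predictor columns.
#' @param response numeric response aligned with `features` rows.
#' @param predictors character vector of predictor column names (default:
#'   all numeric columns of `features`).
#' @return An object of class `distress_fit` with fields `coefficients`
#'   (incl. intercept), `std_coefficients`, `p_values`, `r_squared`,
#'   `adj_r_squared`, `aic`, `n`, `predictors`, `vif`, and the underlying
#'   `lm` objects.
#' @export
fit_ols <- function(features, response, predictors = NULL) {
  stopifnot(is.data.frame(features), nrow(features) == length(response))
  if (is.null(predictors))
    predictors <- names(features)[vapply(features, is.numeric, logical(1))]
  missing <- setdiff(predictors, names(features))
  if (length(missing)) stop("predictors not in features: ",
                            paste(missing, collapse = ", "))
  X <- features[predictors]
  n <- nrow(X); p <- length(predictors)
  if (n <= p + 1) stop("need n > p + 1 observations")
  dat <- cbind(.response = response, X)
  qx <- qr(cbind(`(Intercept)` = 1, as.matrix(X)))
  if (qx$rank < p + 1) {
    aliased <- c("(Intercept)", predictors)[qx$pivot[-seq_len(qx$rank)]]
    stop("singular design; linearly dependent column(s): ",
         paste(aliased, collapse = ", "))
  }
  fml <- stats::as.formula(paste(".response ~",
                                 paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- stats::lm(fml, data = dat)
  zdat <- cbind(.response = response, standardize(X))
  zfit <- stats::lm(fml, data = zdat)
  sm <- summary(fit)
  rss <- sum(stats::residuals(fit)^2)
  cf <- stats::coef(fit)
  names(cf) <- c("(Intercept)", predictors)
  zcf <- stats::coef(zfit)
  names(zcf) <- c("(Intercept)", predictors)
  vif <- if (p >= 2) vapply(predictors, function(v) {
    r2 <- summary(stats::lm(stats::as.formula(
      paste(sprintf("`%s`", v), "~",
            paste(sprintf("`%s`", setdiff(predictors, v)), collapse = " + "))),
      data = X))$r.squared
    1 / (1 - min(r2, 1 - 1e-12))
  }, numeric(1)) else stats::setNames(rep(1, p), predictors)
  structure(list(coefficients = cf, std_coefficients = zcf,
                 p_values = stats::setNames(sm$coefficients[, 4],
                                            c("(Intercept)", predictors)),
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 aic = rss_aic(rss, n, p + 1), rss = rss, n = n,
                 predictors = predictors, vif = vif,
                 lm = fit, lm_std = zfit),
            class = "distress_fit")
}

#' @export
print.distress_fit <- function(x, ...) {
  cat(sprintf("Distress OLS fit: n = %d, R^2 = %.4f, adj R^2 = %.4f, AIC = %.2f\n",
              x$n, x$r_squared, x$adj_r_squared, x$aic))
  print(data.frame(coefficient = x$coefficients,
                   standardized = x$std_coefficients,
                   p_value = signif(x$p_values, 3)))
  invisible(x)
}

#' Predict ratings from a fitted distress model
#'
#' @param object a `distress_fit`.
#' @param newdata `data.frame` carrying all model predictors.
#' @param clip clip predictions to the 0-100 rating scale.
#' @param ... unused.
#' @return Numeric vector of predicted ratings.
#' @export
predict.distress_fit <- function(object, newdata, clip = FALSE, ...) {
  missing <- setdiff(object$predictors, names(newdata))
  if (length(missing)) stop("newdata lacks predictor(s): ",
                            paste(missing, collapse = ", "))
  b <- object$coefficients
  yhat <- b[1] + as.matrix(newdata[object$predictors]) %*% b[-1]
  yhat <- drop(yhat)
  if (clip) yhat <- pmin(100, pmax(0, yhat))
  unname(yhat)
}

#' Backward model selection by AIC
#'
#' Starting from the full predictor set, iteratively drops the single
#' predictor whose removal yields the lowest AIC, as long as that AIC
#' improves on the current model's; stops otherwise. AIC is the Gaussian
#' `n log(RSS/n) + 2k` (k = coefficients incl. intercept). Ties between
#' candidate drops are broken by dropping the predictor with the larger
#' p-value in the current model.
#'
#' @param features,response,predictors as in [fit_ols()].
#' @return A list with `fit` (the final `distress_fit`) and `path` (a
#'   `data.frame` of accepted steps: step, dropped, aic_before, aic_after).
#' @export
backward_select_aic <- function(features, response, predictors = NULL) {
  if (is.null(predictors))
    predictors <- names(features)[vapply(features, is.numeric, logical(1))]
  current <- fit_ols(features, response, predictors)
  path <- data.frame(step = integer(), dropped = character(),
                     aic_before = numeric(), aic_after = numeric())
  step_i <- 0L
  repeat {
    if (length(current$predictors) == 0L) break
    cand <- current$predictors
    aics <- vapply(cand, function(drop) {
      keep <- setdiff(cand, drop)
      if (length(keep) == 0L) {
        rss0 <- sum((response - mean(response))^2)
        rss_aic(rss0, length(response), 1L)
      } else fit_ols(features, response, keep)$aic
    }, numeric(1))
    best <- min(aics)
    if (best >= current$aic) break
    ties <- cand[aics <= best + 1e-9]
    drop <- if (length(ties) > 1L)
      ties[which.max(current$p_values[ties])] else ties
    step_i <- step_i + 1L
    path <- rbind(path, data.frame(step = step_i, dropped = drop,
                                   aic_before = current$aic, aic_after = best))
    keep <- setdiff(current$predictors, drop)
    if (length(keep) == 0L) {
      rss0 <- sum((response - mean(response))^2)
      current <- structure(list(coefficients = c(`(Intercept)` = mean(response)),
                                std_coefficients = c(`(Intercept)` = mean(response)),
                                p_values = c(`(Intercept)` = NA_real_),
                                r_squared = 0, adj_r_squared = 0,
                                aic = rss_aic(rss0, length(response), 1L),
                                rss = rss0, n = length(response),
                                predictors = character(), vif = numeric(),
                                lm = NULL, lm_std = NULL),
                           class = "distress_fit")
    } else {
      current <- fit_ols(features, response, keep)
    }
  }
  list(fit = current, path = path)
}
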