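#' Extract acoustic profiles for matched audio/tier files
#'
#' For each WAV file, the regime tier with the same base name (`.tsv` or
#' `.TextGrid`) is read and [extract_profile()] applied; one feature row per
#' utterance is returned. Unmatched audio files are an error listing every
#' offender.
#'
#' @param audio_paths character vector of WAV paths, or a directory.
#' @param tier_dir directory holding tiers (default: alongside the audio).
#' @param out_csv optional path to write the resulting feature table.
#' @param ... passed to [extract_profile()].
#' @return A feature `data.frame`, one row per utterance.
#' @export
extract_features <- function(audio_paths, tier_dir = NULL, out_csv = NULL, ...) {
  if (length(audio_paths) == 1L && dir.exists(audio_paths))
    audio_paths <- list.files(audio_paths, "\\.wav$", ignore.case = TRUE,
                              full.names = TRUE)
  if (!length(audio_paths)) stop("no audio files given")
  tier_for <- function(p) {
    base <- sub("\\.wav$", "", basename(p), ignore.case = TRUE)
    dirs <- if (is.null(tier_dir)) dirname(p) else tier_dir
    cand <- c(file.path(dirs, paste0(base, ".tsv")),
              file.path(dirs, paste0(base, ".TextGrid")))
    cand[file.exists(cand)][1]
  }
  tiers <- vapply(audio_paths, tier_for, character(1))
  if (anyNA(tiers))
    stop("no tier found for: ",
         paste(basename(audio_paths[is.na(tiers)]), collapse = ", "))
  rows <- lapply(seq_along(audio_paths), function(i) {
    w <- read_wav(audio_paths[i])
    tier <- read_regime_tier(tiers[i])
    profile_row(extract_profile(w, tier, ...))
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) write_feature_table(out, out_csv)
  out
}

#' Reproduce the published four-predictor distress regression
#'
#' Fits mean distress ratings on duration, average pitch, spectral ratio and
#' number of regimes from the packaged 42-stimulus table and compares the
#' result with the published best-model statistics (R-squared 0.84;
#' coefficients 0.02, 0.09, -0.92, 7.0). Because the published predictor
#' columns are themselves rounded, agreement is checked to within one unit
#' in the last printed decimal place of each quantity.
#'
#' @param corrected use the duration-repaired table (see [load_table3()]);
#'   default `TRUE`, which is the variant consistent with the published
#'   duration summary and the only one inside the published tolerance.
#' @return A list of class `table2_report` with the fit, a comparison
#'   `data.frame` and an overall `pass` flag.
#' @export
reproduce_table2 <- function(corrected = TRUE) {
  t3 <- load_table3(corrected = corrected)
  preds <- c("duration_ms", "avg_pitch_hz", "spectral_ratio", "n_regimes")
  fit <- fit_ols(t3, t3$mean_rating, preds)
  reference <- data.frame(
    quantity = c("r_squared", "duration_ms", "avg_pitch_hz",
                 "spectral_ratio", "n_regimes"),
    published = c(0.84, 0.02, 0.09, -0.92, 7.0),
    digits = c(2L, 2L, 2L, 2L, 1L))
  cmp <- data.frame(reference,
                    computed = unname(c(fit$r_squared, fit$coefficients[preds])),
                    stringsAsFactors = FALSE)
  # the published inputs are themselves rounded, so agreement is judged at
  # printed precision: round, then allow one unit in the last printed place
  cmp$rounded <- round(cmp$computed, cmp$digits)
  cmp$within <- abs(cmp$rounded - cmp$published) <= 10^(-cmp$digits) + 1e-9
  structure(list(fit = fit, comparison = cmp, pass = all(cmp$within),
                 corrected = corrected),
            class = "table2_report")
}

#' @export
print.table2_report <- function(x, ...) {
  cat(sprintf("Best-model reproduction (%s stimulus table): %s\n",
              if (x$corrected) "duration-repaired" else "as-printed",
              if (x$pass) "all quantities within tolerance" else "MISMATCH"))
  print(transform(x$comparison, computed = signif(computed, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Run the full perceptual-rating analysis bundle
#'
#' Produces the five report families of the study's statistical analysis:
#' (1) agreement and CV statistics with the scale-usage histogram, (2) the
#' full and backward-selected regressions of mean ratings on the acoustic
#' parameters, (3) the per-listener Cox-Stuart trend battery, (4) the
#' across-listener permutation heterogeneity tests, and (5) the experience
#' contrast.
#'
#' @param panel a [rating_panel()].
#' @param features feature `data.frame` aligned with the panel's stimuli.
#' @param parameters acoustic parameter columns to analyze (default: all
#'   numeric except `stimulus` / `mean_rating`).
#' @param n_perm permutations per parameter for the heterogeneity test.
#' @param alpha significance level used throughout.
#' @param seed seed for the permutation draws.
#' @param out_dir optional directory; when given, every report plus the run
#'   configuration is written there as JSON/CSV.
#' @return A list of class `analysis_bundle` with elements `agreement`,
#'   `histogram`, `regression` (full fit + selection), `trends`,
#'   `heterogeneity`, `experience`.
#' @export
analyze_panel <- function(panel, features, parameters = NULL, n_perm = 2000,
                          alpha = 0.05, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(panel, "rating_panel"))
  sn <- dimnames(panel$ratings)[[2]]
  if (!all(sn %in% as.character(features$stimulus)))
    stop("panel stimuli missing from features: ",
         paste(setdiff(sn, features$stimulus), collapse = ", "))
  if (is.null(parameters))
    parameters <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                          c("stimulus", "mean_rating"))
  means <- per_listener_means(panel)
  agreement <- agreement_report(panel)
  hist <- rating_histogram(means)
  mean_ratings <- colMeans(means, na.rm = TRUE)
  feats <- features[match(sn, as.character(features$stimulus)), , drop = FALSE]
  full <- fit_ols(feats, mean_ratings, parameters)
  selection <- backward_select_aic(feats, mean_ratings, parameters)
  cube <- trial_parameter_correlations(panel, features, parameters)
  trends <- trend_battery(cube, alpha = alpha)
  heterogeneity <- if (dim(panel$ratings)[1] < 4) {
    message("fewer than 4 listeners: permutation heterogeneity test skipped")
    NULL
  } else {
    mean_r <- apply(cube, c(1, 2), mean, na.rm = TRUE)
    stats::setNames(lapply(seq_along(parameters), function(p)
      interrater_permutation(mean_r[, p], n_stimuli = length(sn),
                             n_perm = n_perm, alpha = alpha,
                             seed = seed + p)), parameters)
  }
  experience <- if (all(is.na(panel$listeners$experienced)) ||
                    length(unique(stats::na.omit(panel$listeners$experienced))) < 2) {
    NULL
  } else {
    experience_contrast(cube, panel$listeners$experienced, panel, alpha = alpha)
  }
  bundle <- structure(list(agreement = agreement, histogram = hist,
                           regression = list(full = full, selection = selection),
                           trends = trends, heterogeneity = heterogeneity,
                           experience = experience,
                           config = list(parameters = parameters,
                                         n_perm = n_perm, alpha = alpha,
                                         seed = seed)),
                      class = "analysis_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# serialize an analysis bundle (JSON + CSV) alongside its configuration
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  j <- function(x, f) jsonlite::write_json(x, file.path(out_dir, f),
                                           auto_unbox = TRUE, digits = NA,
                                           force = TRUE, pretty = TRUE)
  ag <- bundle$agreement
  j(list(interrater_mean = ag$interrater$mean, interrater_range = ag$interrater$range,
         loo_mean = ag$leave_one_out$mean, loo_range = ag$leave_one_out$range,
         intrarater_mean = ag$intrarater$mean, intrarater_range = ag$intrarater$range,
         inter_cv = ag$cv$inter_cv, intra_cv = ag$cv$intra_cv,
         excess = ag$cv$excess, excess_pct = ag$cv$excess_pct),
    "agreement.json")
  utils::write.csv(bundle$histogram, file.path(out_dir, "histogram.csv"),
                   row.names = FALSE)
  full <- bundle$regression$full
  sel <- bundle$regression$selection
  j(list(full = list(coefficients = as.list(full$coefficients),
                     std_coefficients = as.list(full$std_coefficients),
                     r_squared = full$r_squared,
                     adj_r_squared = full$adj_r_squared, aic = full$aic),
         best = list(coefficients = as.list(sel$fit$coefficients),
                     r_squared = sel$fit$r_squared, aic = sel$fit$aic,
                     path = sel$path)),
    "regression.json")
  j(bundle$trends, "trend_battery.json")
  if (!is.null(bundle$heterogeneity))
    j(lapply(bundle$heterogeneity, unclass), "heterogeneity.json")
  if (!is.null(bundle$experience))
    j(list(by_parameter = bundle$experience$by_parameter,
           rating_level = bundle$experience$rating_level), "experience.json")
  j(bundle$config, "config.json")
  invisible(out_dir)
}

#' @export
print.analysis_bundle <- function(x, ...) {
  cat("Analysis bundle\n================\n")
  print(x$agreement)
  cat("\nBest model (backward AIC):\n")
  print(x$regression$selection$fit)
  cat("\nTrend battery:\n")
  print(x$trends, row.names = FALSE)
  if (!is.null(x$experience)) { cat("\n"); print(x$experience) }
  invisible(x)
}
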