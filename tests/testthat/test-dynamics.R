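test_that("the correlation cube matches brute-force loops", {
  t3 <- load_table3()[1:12, ]
  sim <- simulate_panel(panel_spec(n_listeners = 4, n_trials = 5, seed = 30), t3)
  params <- c("duration_ms", "avg_pitch_hz", "spectral_ratio", "n_regimes")
  cube <- trial_parameter_correlations(sim$panel, t3, params)
  expect_equal(dim(cube), c(4, 4, 5))
  for (l in 1:4) for (p in seq_along(params)) for (t in 1:5)
    expect_equal(cube[l, p, t],
                 cor(sim$panel$ratings[l, , t], t3[[params[p]]]))
  # a listener rating exactly along one parameter correlates at 1 everywhere
  arr <- array(NA_real_, c(2, 12, 3),
               dimnames = list(listener = c("a", "b"),
                               stimulus = as.character(t3$stimulus),
                               trial = 1:3))
  zdur <- scale(t3$duration_ms)[, 1]
  for (t in 1:3) {
    arr[1, , t] <- 50 + 10 * zdur
    arr[2, , t] <- runif(12, 0, 100)
  }
  cube1 <- trial_parameter_correlations(rating_panel(arr), t3, params)
  expect_true(all(abs(cube1[1, "duration_ms", ] - 1) < 1e-12))
  expect_error(trial_parameter_correlations(sim$panel, t3[1:5, ], params),
               "missing from features")
})

test_that("Cox-Stuart p-values match closed forms and exact enumeration", {
  out <- cox_stuart(1:10)
  expect_equal(out$n_pairs, 5)
  expect_equal(out$S, 5)
  expect_equal(out$p, 0.0625)
  expect_equal(out$direction, "increasing")
  con <- cox_stuart(rep(3, 8))
  expect_true(con$degenerate)
  expect_equal(con$p, 1)
  expect_equal(cox_stuart(1:10, alternative = "increasing")$p, 0.03125)
  expect_error(cox_stuart(1:3), "length >= 4")
  # exact oracle: enumerate all sign patterns for n_pairs <= 10
  enum_p <- function(S, np) {
    stat <- max(S, np - S)
    mean(vapply(0:(2^np - 1), function(b) {
      k <- sum(bitwAnd(b, 2^(0:(np - 1))) > 0)
      max(k, np - k) >= stat
    }, logical(1)))
  }
  set.seed(31)
  for (n in c(8, 9, 13, 20)) {
    s <- rnorm(n)
    out <- cox_stuart(s)
    expect_equal(out$p, enum_p(out$S, out$n_pairs))
  }
})

test_that("Cox-Stuart is conservative under the i.i.d. null", {
  set.seed(32)
  rej <- mean(replicate(10000, cox_stuart(rnorm(14))$p <= 0.05))
  expect_lte(rej, 0.05)
  # the attainable rejection rate is P(S = 0 or 7) = 2/128
  expect_equal(rej, 2 / 128, tolerance = 0.35)
})

test_that("trend battery flags drifted parameters and satisfies w^2 n = chi2", {
  build_cube <- function(drift_listeners, nt = 14, nl = 39, npar = 4,
                         drift = 0.05, seed = 33) {
    set.seed(seed)
    cube <- array(rnorm(nl * npar * nt, 0.4, 0.05), c(nl, npar, nt),
                  dimnames = list(paste0("L", 1:nl),
                                  paste0("par", 1:npar),
                                  1:nt))
    for (l in drift_listeners)
      cube[l, 1, ] <- cube[l, 1, ] + drift * (1:nt)
    class(cube) <- c("trial_correlation_cube", class(cube))
    cube
  }
  # 30% of listeners drift on parameter 1 at 0.05 r-units per trial
  res <- trend_battery(build_cube(1:12))
  expect_equal(which.max(res$n_significant), 1L)
  expect_gte(res$n_significant[1], 6)        # power >= 0.5 over 12 drifters
  expect_equal(res$effect_w^2 * res$n_listeners, res$chi_square,
               tolerance = 1e-12)
  # zero drift: counts near alpha * n within a binomial envelope
  res0 <- trend_battery(build_cube(integer(0), seed = 34))
  expect_true(all(res0$n_significant <= qbinom(0.999, 39, 0.05)))
})

test_that("permutation heterogeneity test calibrates and detects subgroups", {
  set.seed(35)
  # homogeneity: one shared true correlation, spread = sampling error of a
  # correlation over 42 stimuli (1/sqrt(39) on the Fisher-z scale)
  r_hom <- tanh(atanh(0.6) + rnorm(20, 0, 1 / sqrt(39)))
  rep_hom <- interrater_permutation(r_hom, n_stimuli = 42, n_perm = 1500,
                                    seed = 99)
  expect_gt(rep_hom$proportion_fail_to_reject, 0.85)
  # two planted subpopulations with opposite parameter weights
  r_het <- c(tanh(atanh(0.6) + rnorm(10, 0, 1 / sqrt(39))),
             tanh(atanh(-0.6) + rnorm(10, 0, 1 / sqrt(39))))
  rep_het <- interrater_permutation(r_het, n_stimuli = 42, n_perm = 1500,
                                    seed = 99)
  expect_lt(rep_het$proportion_fail_to_reject,
            rep_hom$proportion_fail_to_reject - 0.3)
  # fixed seed: bit-identical rerun
  rep2 <- interrater_permutation(r_hom, n_stimuli = 42, n_perm = 1500,
                                 seed = 99)
  expect_identical(rep_hom$proportion_fail_to_reject,
                   rep2$proportion_fail_to_reject)
  expect_error(interrater_permutation(c(0.5, 0.6)), ">= 4 listeners")
  expect_warning(interrater_permutation(r_hom, n_perm = 50), "noisy")
})

test_that("experience contrast flags only planted group differences", {
  nl <- 30; nt <- 6
  params <- c("duration_ms", "spectral_ratio", "spectral_mean_khz")
  exp_flag <- rep(c(TRUE, FALSE), each = 15)
  set.seed(36)
  cube <- array(rnorm(nl * 3 * nt, 0.5, 0.05), c(nl, 3, nt),
                dimnames = list(paste0("L", 1:nl), params, 1:nt))
  # identical groups: no rejections
  out <- experience_contrast(cube, exp_flag)
  expect_true(all(!out$by_parameter$reject))
  expect_true(all(out$by_parameter$p_bonferroni >
                  out$by_parameter$p_raw - 1e-12))
  # planted offset on the spectral parameters only
  cube2 <- cube
  cube2[!exp_flag, 2:3, ] <- cube2[!exp_flag, 2:3, ] + 0.25
  out2 <- experience_contrast(cube2, exp_flag)
  expect_false(out2$by_parameter$reject[1])
  expect_true(all(out2$by_parameter$reject[2:3]))
  expect_error(experience_contrast(cube, rep(TRUE, nl)), "non-empty")
})
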