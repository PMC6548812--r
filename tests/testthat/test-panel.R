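test_that("per-listener means reduce trials correctly", {
  p <- panel_from_array(50, 3, 4, 5)
  expect_true(all(per_listener_means(p) == 50))
  arr <- array(NA_real_, dim = c(1, 1, 3))
  arr[1, 1, ] <- c(10, 20, 30)
  expect_equal(as.vector(per_listener_means(rating_panel(arr))), 20)
  # matches brute force on a simulated panel
  sim <- simulate_panel(panel_spec(n_listeners = 4, n_trials = 6, seed = 9),
                        load_table3()[1:10, ])
  m <- per_listener_means(sim$panel)
  for (l in 1:4) for (s in 1:10)
    expect_equal(m[l, s], mean(sim$panel$ratings[l, s, ]))
})

test_that("pairwise inter-rater correlations hit exact anchors", {
  base <- matrix(c(10, 30, 50, 70), 1)
  means <- rbind(base, base, base)
  rownames(means) <- paste0("L", 1:3)
  out <- interrater_pairwise(means)
  expect_true(all(out$pairs$r == 1))
  expect_equal(nrow(out$pairs), choose(3, 2))
  # exact negation about the scale midpoint gives r = -1
  means2 <- rbind(base, 100 - base)
  rownames(means2) <- c("a", "b")
  expect_equal(interrater_pairwise(means2)$pairs$r, -1)
  # pair count for a 39-listener panel is C(39,2) = 741
  set.seed(10)
  big <- matrix(rnorm(39 * 5, 50, 10), 39, dimnames = list(paste0("L", 1:39), NULL))
  expect_equal(nrow(interrater_pairwise(big)$pairs), 741)
  expect_error(interrater_pairwise(means[1, , drop = FALSE]), ">= 2 listeners")
})

test_that("leave-one-out agreement matches a by-hand oracle and beats pairwise", {
  m <- rbind(c(10, 40, 60, 90), c(15, 35, 65, 85), c(5, 45, 55, 95))
  rownames(m) <- paste0("L", 1:3)
  out <- leave_one_out(m)
  for (i in 1:3)
    expect_equal(unname(out$r[i]), cor(m[i, ], colMeans(m[-i, ])))
  # with homogeneous listeners and moderate noise, averaging the others
  # denoises the reference: mean LOO r exceeds mean pairwise r
  sim <- simulate_panel(panel_spec(n_listeners = 12, n_trials = 4,
                                   noise_sd = 12, bias_sd = 2, weight_sd = 0.3,
                                   seed = 11),
                        load_table3())
  means <- per_listener_means(sim$panel)
  expect_gt(leave_one_out(means)$mean, interrater_pairwise(means)$mean)
})

test_that("intra-rater consistency counts trial pairs and attenuates with noise", {
  sim <- simulate_panel(panel_spec(n_listeners = 3, n_trials = 10,
                                   noise_sd = 0, bias_sd = 0, weight_sd = 0,
                                   seed = 12),
                        load_table3())
  out <- intrarater_consistency(sim$panel)
  expect_equal(ncol(out$pair_r), 45)  # C(10,2)
  expect_true(all(abs(out$pair_r - 1) < 1e-12))
  # known signal/noise ratio rho: mean trial-pair r ~ rho/(rho+1); averaged
  # over 20 independent listeners the Monte-Carlo SE is ~0.013, so a 0.04
  # band is a ~3-sigma check (signal SD moderate: clipping negligible)
  set.seed(13)
  nl <- 20; ns <- 42; nt <- 10; sig_sd <- 15; noise_sd <- 10
  rho <- sig_sd^2 / noise_sd^2
  arr <- array(NA_real_, c(nl, ns, nt))
  for (l in seq_len(nl)) {
    mu <- rnorm(ns, 50, sig_sd)
    for (t in seq_len(nt))
      arr[l, , t] <- pmin(100, pmax(0, mu + rnorm(ns, 0, noise_sd)))
  }
  out <- intrarater_consistency(rating_panel(arr))
  expect_lt(abs(out$mean - rho / (rho + 1)), 0.04)
})

test_that("CV analysis separates listener bias from rating noise", {
  p <- panel_from_array(40, 4, 5, 3)
  cv <- cv_analysis(p)
  expect_equal(cv$inter_cv, 0)
  expect_equal(cv$intra_cv, 0)
  # listener grand means {40,50,60}: inter CV = sd/mean = 10/50
  arr <- array(rep(c(40, 50, 60), times = 6), dim = c(3, 3, 2))
  cv <- cv_analysis(rating_panel(arr))
  expect_equal(cv$inter_cv, sd(c(40, 50, 60)) / 50)
  # injected listener bias inflates inter CV, not intra CV
  t3 <- load_table3()
  lo <- simulate_panel(panel_spec(bias_sd = 1, noise_sd = 6, seed = 14), t3)
  hi <- simulate_panel(panel_spec(bias_sd = 12, noise_sd = 6, seed = 14), t3)
  cv_lo <- cv_analysis(lo$panel); cv_hi <- cv_analysis(hi$panel)
  expect_gt(cv_hi$inter_cv, cv_lo$inter_cv * 2)
  expect_lt(abs(cv_hi$intra_cv - cv_lo$intra_cv), 0.02)
})

test_that("rating histogram conserves mass over the 20 bins", {
  m <- matrix(2, 3, 4)
  h <- rating_histogram(m)
  expect_equal(nrow(h), 20)
  expect_equal(h$count[1], 12)
  expect_equal(sum(h$count), 12)
  set.seed(15)
  u <- matrix(runif(5000, 0, 100), 50)
  h <- rating_histogram(u)
  expect_equal(sum(h$count), 5000)
  expect_true(all(abs(h$count - 250) < 5 * sqrt(250)))
  expect_error(rating_histogram(matrix(c(50, 101), 1)), "outside")
})

test_that("agreement statistics are invariant under common affine rescaling", {
  sim <- simulate_panel(panel_spec(n_listeners = 6, n_trials = 5,
                                   noise_sd = 8, seed = 16),
                        load_table3())
  means <- per_listener_means(sim$panel)
  means2 <- means * 0.5 + 20
  expect_equal(interrater_pairwise(means2)$pairs$r,
               interrater_pairwise(means)$pairs$r, tolerance = 1e-12)
  expect_equal(leave_one_out(means2)$r, leave_one_out(means)$r,
               tolerance = 1e-12)
})

test_that("all agreement statistics approach 1 as panel noise vanishes", {
  sim <- simulate_panel(panel_spec(n_listeners = 8, n_trials = 6,
                                   weight_sd = 0, noise_sd = 0.01, bias_sd = 0,
                                   seed = 17),
                        load_table3())
  rep <- agreement_report(sim$panel)
  expect_gt(rep$interrater$mean, 0.999)
  expect_gt(rep$leave_one_out$mean, 0.999)
  expect_gt(rep$intrarater$mean, 0.999)
})
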