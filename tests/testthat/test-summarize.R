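test_that("the 1D mixture EM recovers known components", {
  set.seed(91)
  # single tight cluster, K = 1
  x1 <- rnorm(200, 3, 0.5)
  f1 <- fit_gaussian_mixture_1d(x1, K = 1)
  expect_equal(f1$means, mean(x1), tolerance = 1e-6)
  expect_equal(f1$weights, 1)
  # two components: weights recovered within 0.02
  x2 <- c(rnorm(3000, 0, 1), rnorm(7000, 20, 1))
  f2 <- fit_gaussian_mixture_1d(x2, K = 2, seed = 2)
  expect_lt(abs(f2$weights[1] - 0.3), 0.02)
  expect_lt(abs(f2$means[1] - 0) , 3 * 1 / sqrt(3000))
  expect_lt(abs(f2$means[2] - 20), 3 * 1 / sqrt(7000))
  # likelihood trace is monotone
  expect_true(all(diff(f2$loglik_trace) > -1e-6))
  # degenerate inputs
  expect_error(fit_gaussian_mixture_1d(x2, K = 0), "K")
  expect_error(fit_gaussian_mixture_1d(rnorm(15), K = 2), "samples")
  expect_error(fit_gaussian_mixture_1d(rep(1, 100), K = 2), "identical")
})

test_that("the five-peak mixture is recovered at the reported sample size", {
  lay <- five_peak_layout()
  set.seed(92)
  comp <- sample.int(5, 4660, replace = TRUE, prob = lay$weight)
  x <- rnorm(4660, lay$position[comp], lay$sd[comp])
  fit <- fit_gaussian_mixture_1d(x, K = 5, seed = 3)
  # each recovered mean within 3 SE of its generator
  se <- lay$sd / sqrt(pmax(4660 * lay$weight, 1))
  expect_true(all(abs(fit$means - lay$position) < 3 * se + 0.1))
  expect_lt(abs(fit$weights[3] - 0.493), 0.03)
})

test_that("mclust agrees with the in-package EM on a well-separated mixture", {
  skip_if_not_installed("mclust")
  set.seed(93)
  x <- c(rnorm(2000, -10, 1.5), rnorm(3000, 8, 1.2))
  ours <- fit_gaussian_mixture_1d(x, K = 2, seed = 4)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(ours$means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_lt(abs(ours$loglik - mc$loglik), 1)
})

test_that("exponential dwell fitting handles truncation, MLE agreement and edge cases", {
  # single dwell, truncation 0: degenerate MLE
  f0 <- fit_exponential_dwell(137)
  expect_equal(f0$tau, 137)
  expect_true(f0$degenerate)
  expect_error(fit_exponential_dwell(c(10, 50), truncation = 40), ">=")
  # left-truncated draws at the central-peak time constant, printed n
  set.seed(94)
  d <- 40 + rexp(708, 1 / 160)
  fit <- fit_exponential_dwell(d, truncation = 40)
  se_oracle <- 160 / sqrt(708)
  expect_lt(abs(fit$tau - 160), 3 * se_oracle)
  expect_equal(fit$mle, mean(d) - 40, tolerance = 1e-12)
  # CDF fit and MLE agree within 2% on large continuous samples
  set.seed(95)
  d2 <- rexp(1e4, 1 / 500)
  fit2 <- fit_exponential_dwell(d2)
  expect_lt(abs(fit2$tau - fit2$mle) / fit2$mle, 0.02)
  # order invariance and duplication: same tau, smaller SE
  fit_shuf <- fit_exponential_dwell(sample(d), truncation = 40)
  expect_equal(fit_shuf$tau, fit$tau, tolerance = 1e-9)
  fit_dup <- fit_exponential_dwell(c(d, d), truncation = 40)
  expect_equal(fit_dup$tau, fit$tau, tolerance = 1e-6)
  expect_lt(fit_dup$se, fit$se)
})

test_that("dwell ratio and powerstroke decomposition do the printed arithmetic", {
  # equal dwells: ratio 1  (rate line with zero slope, dwell = 1/intercept)
  expect_equal(dwell_ratio(1e5, list(slope = 0, intercept = 10), 0), 1)
  # slope 0, intercept 10 s^-1, weak dwell 10 ms -> 10x
  expect_equal(dwell_ratio(1e4, list(slope = 0, intercept = 10), 500), 10)
  # printed line at 2 uM with the most forward peak dwell: ~250-fold
  r <- dwell_ratio(513, list(slope = 0.0038, intercept = 0.17), 2000)
  expect_equal(round(r / 10) * 10, 250)
  expect_error(dwell_ratio(100, list(slope = 0, intercept = -1), 10), "rate")

  ps <- powerstroke_decompose(3.9, 1.1, 7.9, 2.6)
  expect_equal(ps$second_mean, 4.0, tolerance = 1e-12)
  expect_equal(ps$second_sd, sqrt(2.6^2 - 1.1^2), tolerance = 1e-12)
  expect_equal(powerstroke_decompose(5, 1, 5, 2)$second_mean, 0)
  p2 <- powerstroke_decompose(2, 1, 5, 2)
  expect_equal(p2$second_mean, 3)
  expect_equal(p2$second_sd, sqrt(3), tolerance = 1e-12)
  expect_true(powerstroke_decompose(2, 2, 5, 1.5)$sd_flag)
  expect_error(powerstroke_decompose(5, 1, 4, 2), "total_mean")
})

test_that("peak summaries count events like the brute-force tally", {
  # two hand-built chains with known state layouts
  mk_fit <- function(runs_spec, seed) {
    # runs_spec: list of (state, n_runs, run_len); states at fixed means
    path <- rep(1L, 10000)
    pos <- 1
    for (rs in runs_spec) {
      for (r in seq_len(rs$n_runs)) {
        path[pos:(pos + rs$run_len - 1)] <- rs$state
        pos <- pos + rs$run_len + 20
      }
    }
    mu <- c(0, -13, 10)
    myoratchet:::build_ihmm_fit(numeric(0), path, mu, 40, 1, 1,
                                ihmm_config(), seed, TRUE)
  }
  f1 <- mk_fit(list(list(state = 2L, n_runs = 30, run_len = 5),
                    list(state = 3L, n_runs = 10, run_len = 6)), 1L)
  f2 <- mk_fit(list(list(state = 2L, n_runs = 20, run_len = 4),
                    list(state = 3L, n_runs = 20, run_len = 7)), 2L)
  mix <- structure(list(means = c(-13, 10), sds = c(1.5, 1.5),
                        weights = c(0.6, 0.4), K = 2, n = 80,
                        loglik = 0, loglik_trace = 0, bic = 0),
                   class = "gmm1d")
  pk <- summarize_peaks(list(f1, f2), mix, access_floor = 0.0)
  # brute force: chain access ratios by event counting
  acc1 <- c(30, 10) / 40; acc2 <- c(20, 20) / 40
  expect_equal(pk$access_ratio, (acc1 + acc2) / 2, tolerance = 1e-12)
  expect_equal(pk$access_sd, apply(rbind(acc1, acc2), 2, sd),
               tolerance = 1e-12)
  # retained access ratios sum to 1
  expect_equal(sum(pk$access_ratio), 1, tolerance = 0.01)
  # pooled dwells per peak
  expect_equal(pk$n_events, c(50L, 30L))
  expect_equal(pk$dwell_us[1],
               fit_exponential_dwell(c(rep(200, 30), rep(160, 20)))$mle,
               tolerance = 1e-6)
  # single site, all events one peak: access ratio 1
  pk1 <- summarize_peaks(list(f1), structure(list(
    means = -13, sds = c(1.5), weights = 1, K = 1, n = 10, loglik = 0,
    loglik_trace = 0, bic = 0), class = "gmm1d"), access_floor = 0)
  expect_equal(pk1$access_ratio, 30 / 40)
  # a peak below the access floor is excluded from dwell reporting
  pk_floor <- summarize_peaks(list(f1, f2), mix, access_floor = 0.45)
  expect_true(pk_floor$excluded[2])
  expect_true(is.na(pk_floor$dwell_us[2]))
  expect_false(pk_floor$excluded[1])
})

test_that("end-to-end five-site recovery reproduces access ratios and dwells", {
  lay <- five_peak_layout()
  sites <- lapply(seq_len(5), function(i)
    weak_site(lay$position[i], lay$weight[i], lay$dwell_us[i]))
  sch <- kinetic_scheme(sites = sites, duration_us = 1e4 * 40)
  tr <- simulate_trajectory(sch, seed = 96)
  cfg <- ihmm_config(mcmc_iterations = 1000, window_frames = 1e4)
  runs <- run_repeated(tr, cfg, n = 10, seed = 960)
  pos <- pooled_positions(runs)
  expect_gt(length(pos), 10)
  # oracles: the generating access weights, and each site's realized mean
  # event dwell in this window (what the 400 ms record actually contains)
  ev <- attr(tr, "events")
  true_dwell <- tapply(ev$dwell_us, factor(ev$state, levels = 1:5), mean)
  # mixture over detected peaks: use the generating layout as reference so
  # peak identity is unambiguous
  mix <- structure(list(means = lay$position, sds = pmax(lay$sd, 1.5),
                        weights = lay$weight, K = 5, n = length(pos),
                        loglik = 0, loglik_trace = 0, bic = 0),
                   class = "gmm1d")
  pk <- summarize_peaks(runs, mix, access_floor = 0.05)
  for (i in which(!pk$excluded)) {
    expect_lt(abs(pk$access_ratio[i] - lay$weight[i]), 0.05)
    expect_lt(abs(pk$dwell_us[i] - true_dwell[i]) / true_dwell[i], 0.25)
  }
  # the dominant central peak must be among the recovered ones
  expect_false(pk$excluded[3])
  # the lowest-access site is excluded, as its visits are too rare to dwell-fit
  expect_true(pk$excluded[1])
})
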