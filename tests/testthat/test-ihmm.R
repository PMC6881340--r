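test_that("forward-filter backward-sampling matches brute-force enumeration", {
  inst <- pinned_instance()
  post <- enumerate_path_posterior(inst$emit, inst$Pi)
  set.seed(123)
  draws <- myoratchet:::cpp_ffbs(inst$emit, inst$Pi, inst$Pi[1, ], 1e5)
  keys <- apply(draws, 1, paste, collapse = "")
  freq <- table(keys) / length(keys)
  phat <- setNames(numeric(length(post)), names(post))
  phat[names(freq)] <- as.numeric(freq)
  tv <- 0.5 * sum(abs(phat - post))
  expect_lt(tv, 0.02)
  # per-frame marginals agree too
  marg_exact <- sapply(1:8, function(t) {
    s <- substr(names(post), t, t)
    vapply(c("1", "2", "3"), function(k) sum(post[s == k]), numeric(1))
  })
  marg_hat <- sapply(1:8, function(t)
    vapply(1:3, function(k) mean(draws[, t] == k), numeric(1)))
  expect_lt(max(abs(marg_exact - marg_hat)), 0.01)
})

test_that("the beam-sliced kernel leaves the exact path posterior invariant", {
  inst <- pinned_instance()
  post <- enumerate_path_posterior(inst$emit, inst$Pi)
  set.seed(321)
  path <- myoratchet:::cpp_ffbs(inst$emit, inst$Pi, inst$Pi[1, ], 1)[1, ]
  n_sweep <- 2e4
  counts <- setNames(numeric(length(post)), names(post))
  for (i in seq_len(n_sweep)) {
    prev <- c(1L, path[-length(path)])
    u <- runif(length(path)) * inst$Pi[cbind(prev, path)]
    path <- myoratchet:::cpp_ffbs_beam(inst$emit, inst$Pi, u, 1L)
    counts[paste(path, collapse = "")] <-
      counts[paste(path, collapse = "")] + 1
  }
  tv <- 0.5 * sum(abs(counts / n_sweep - post))
  expect_lt(tv, 0.05)
})

test_that("inference is seed-deterministic and n = 1 matches a single chain", {
  sch <- kinetic_scheme(sites = list(weak_site(20, 1, 300)),
                        duration_us = 1500 * 40)
  tr <- simulate_trajectory(sch, seed = 51)
  cfg <- ihmm_config(mcmc_iterations = 150, window_frames = 1500,
                     n_inferences = 1)
  a <- run_ihmm(tr, cfg, seed = 5)
  b <- run_ihmm(tr, cfg, seed = 5)
  expect_identical(a$path, b$path)
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  runs1 <- run_repeated(tr, cfg, n = 1, seed = 5, filter = FALSE)
  expect_equal(runs1[[1]]$states, a$states, tolerance = 1e-12)
  # pooled multisets identical across repeated calls
  runs_a <- run_repeated(tr, cfg, n = 3, seed = 7)
  runs_b <- run_repeated(tr, cfg, n = 3, seed = 7)
  expect_equal(sort(pooled_positions(runs_a)), sort(pooled_positions(runs_b)),
               tolerance = 1e-12)
})

test_that("binding-to-binding transitions never occur in sampled paths", {
  sch <- kinetic_scheme(sites = list(weak_site(-15, 0.5, 200),
                                     weak_site(20, 0.5, 300)),
                        duration_us = 2000 * 40)
  tr <- simulate_trajectory(sch, seed = 61)
  cfg <- ihmm_config(mcmc_iterations = 200, window_frames = 2000)
  for (s in 1:3) {
    fit <- run_ihmm(tr, cfg, seed = 60 + s)
    K <- length(fit$mu)
    if (K < 3) next
    N <- myoratchet:::cpp_transition_counts(fit$path, K, 1L)
    bb <- N[-1, -1, drop = FALSE]
    diag(bb) <- 0L
    expect_identical(sum(bb), 0L)
  }
})

test_that("pure detached windows rarely yield binding states after filtering", {
  sch <- kinetic_scheme(duration_us = 2000 * 40)
  tr <- simulate_trajectory(sch, seed = 71)
  cfg <- ihmm_config(mcmc_iterations = 300, window_frames = 2000)
  runs <- run_repeated(tr, cfg, n = 10, seed = 70)
  n_fp <- sum(vapply(runs, function(f) nrow(f$states) > 0, logical(1)))
  expect_lte(n_fp, 1)  # <= 10% of chains
})

test_that("the occupancy and dwell filters match their predicates (brute force)", {
  # hand-built path on a 10,000-frame window: state 2 at 0.5% occupancy,
  # state 3 at 3% with 200 us dwells, state 4 flickering at 1 frame
  path <- rep(1L, 10000)
  path[seq(1, 50) + rep(seq(0, 9000, by = 1000), each = 5)] <- 2L
  for (s in seq(101, 3000, by = 100)) path[s:(s + 4)] <- 3L
  for (s in seq(5001, 5600, by = 4)) path[s] <- 4L
  mu <- c(0, 10, 20, -15)
  fit <- myoratchet:::build_ihmm_fit(numeric(0), path, mu, 40, 1, 1,
                                     ihmm_config(), 1L, FALSE)
  filt <- filter_states(fit)
  # brute-force predicates
  st <- fit$states
  keep <- st$occupancy >= 0.01 & (st$mean_dwell_us - 40) >= 40
  expect_equal(nrow(filt$states), sum(keep))
  expect_equal(sort(filt$states$mean_nm), sort(st$mean_nm[keep]))
  # reassigned frames end up detached
  expect_equal(sum(filt$path == 1), sum(!path %in% st$state[keep]))
  # empty state list passes through unchanged
  null_fit <- myoratchet:::build_ihmm_fit(numeric(0), rep(1L, 10000), 0,
                                          40, 1, 1, ihmm_config(), 1L, FALSE)
  expect_equal(nrow(filter_states(null_fit)$states), 0)
})

test_that("window-length and degenerate inputs are rejected", {
  cfg <- ihmm_config(mcmc_iterations = 10, window_frames = 1000)
  sch <- kinetic_scheme(duration_us = 500 * 40)
  tr <- simulate_trajectory(sch, seed = 1)
  expect_error(run_ihmm(tr, cfg), "window_frames")
  flat <- trajectory((0:999) * 40, rep(1, 1000))
  expect_error(run_ihmm(flat, cfg), "identical")
  expect_error(ihmm_config(min_occupancy = 0), "min_occupancy")
})

test_that("repeated chains recover transient-state positions and dwells", {
  sch <- kinetic_scheme(sites = list(weak_site(-15, 0.5, 150),
                                     weak_site(22, 0.5, 250)),
                        duration_us = 4000 * 40)
  tr <- simulate_trajectory(sch, seed = 81)
  cfg <- ihmm_config(mcmc_iterations = 400, window_frames = 4000)
  runs <- run_repeated(tr, cfg, n = 6, seed = 80)
  ps <- pooled_states(runs)
  expect_gt(nrow(ps), 0)
  # every retained state sits within 3 nm of a true site
  d <- pmin(abs(ps$relative_position_nm + 15), abs(ps$relative_position_nm - 22))
  expect_lt(max(d), 3)
  # both sites detected somewhere in the pool
  expect_true(any(abs(ps$relative_position_nm + 15) < 3))
  expect_true(any(abs(ps$relative_position_nm - 22) < 3))
  # pooled dwells within 25% of what this window actually contains
  # (realized mean event dwell at the site, the realization oracle)
  ev <- attr(tr, "events")
  realized22 <- mean(ev$dwell_us[ev$state == 2])
  near22 <- abs(ps$relative_position_nm - 22) < 3
  dw22 <- unlist(lapply(which(near22), function(r)
    runs[[ps$chain[r]]]$dwell_events[[ps$state[r] - 1L]]))
  expect_lt(abs(mean(dw22) - realized22) / realized22, 0.25)
})
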