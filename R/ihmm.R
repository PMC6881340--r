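#' Configuration for the constrained infinite-HMM inference
#'
#' Emission SDs are fixed, not estimated: the detached state keeps the
#' tethered-diffusion SD (12.5 nm) and every binding state shares the
#' strong-binding SD (4.7 nm); only the state means, the transition
#' structure and the HDP concentrations are inferred.
#'
#' @param sd_detached Fixed detached emission SD, nm (default 12.5).
#' @param sd_bound Fixed shared binding emission SD, nm (default 4.7).
#' @param mcmc_iterations MCMC sweeps per chain (default 1000); the final
#'   sweep is the chain's reported sample.
#' @param n_inferences Number of independent chains pooled downstream
#'   (default 1000).
#' @param window_frames Required trajectory length (default 10,000 frames =
#'   400 ms at 40 us); longer records are windowed by the caller.
#' @param min_occupancy Occupancy floor for retained states (default 0.01).
#' @param min_dwell_us Dwell floor for retained states, us (default 40, one
#'   frame); must be >= the frame interval.
#' @param dwell_filter How the dwell predicate is evaluated:
#'   `"truncated_mean"` (default) compares `mean(events) - frame_interval`
#'   (the left-truncated-exponential estimate, so sub-resolution flicker
#'   states can actually fail the floor) or `"mean"` (raw mean of events).
#' @param alpha_prior,gamma_prior Gamma(shape, rate) hyperpriors on the HDP
#'   concentrations (default Gamma(1, 1) each).
#' @param mean_prior_sd SD of the Gaussian prior on state means, nm
#'   (default 50, weakly informative over the ~80 nm tether span); the prior
#'   center is the window mean.
#' @param max_states Hard cap on represented states (default 50).
#' @param seed Base seed (default 1).
#' @return An object of class `ihmm_config`.
#' @export
ihmm_config <- function(sd_detached = 12.5, sd_bound = 4.7,
                        mcmc_iterations = 1000, n_inferences = 1000,
                        window_frames = 10000, min_occupancy = 0.01,
                        min_dwell_us = 40,
                        dwell_filter = c("truncated_mean", "mean"),
                        alpha_prior = c(1, 1), gamma_prior = c(1, 1),
                        mean_prior_sd = 50, max_states = 50, seed = 1L) {
  stopifnot(sd_detached > 0, sd_bound > 0, mcmc_iterations >= 1,
            min_occupancy > 0, min_occupancy < 1, min_dwell_us > 0,
            mean_prior_sd > 0)
  structure(list(sd_detached = sd_detached, sd_bound = sd_bound,
                 mcmc_iterations = as.integer(mcmc_iterations),
                 n_inferences = as.integer(n_inferences),
                 window_frames = as.integer(window_frames),
                 min_occupancy = min_occupancy,
                 min_dwell_us = min_dwell_us,
                 dwell_filter = match.arg(dwell_filter),
                 alpha_prior = alpha_prior, gamma_prior = gamma_prior,
                 mean_prior_sd = mean_prior_sd,
                 max_states = as.integer(max_states),
                 seed = as.integer(seed)),
            class = "ihmm_config")
}

# Chinese-restaurant table count: number of tables for n customers at
# concentration ab (Antoniak draw).
crt_sample <- function(n, ab) {
  if (n == 0L) return(0L)
  sum(runif(n) < ab / (ab + seq_len(n) - 1))
}

# safe Beta draw for possibly tiny shape parameters
rbeta_safe <- function(a, b) {
  x <- rbeta(1, max(a, 1e-8), max(b, 1e-8))
  min(max(x, 1e-12), 1 - 1e-12)
}

#' Constrained HDP-HMM inference of transient binding states
#'
#' One beam-sampled MCMC chain of a hierarchical-Dirichlet-process hidden
#' Markov model with a reserved detached state and an unbounded pool of
#' binding states. Structure: state 1 is detached (emission SD
#' `sd_detached`, free mean); binding states share emission SD `sd_bound`
#' with free means; every binding-to-binding transition probability is
#' fixed at zero (rows renormalized over self-transition and
#' return-to-detached), so binding excursions are always separated by the
#' detached state. Each sweep slice-truncates the state space with beam
#' variables, draws the path by forward-filter backward-sampling, then
#' resamples state means (conjugate Gaussian), transition rows (Dirichlet),
#' the shared stick weights, and the HDP concentrations alpha and gamma
#' under Gamma hyperpriors. The final sweep is the chain's reported sample;
#' posterior spread comes from repeating chains ([run_repeated()]).
#'
#' @param traj A `trajectory` whose length equals `cfg$window_frames` (1D).
#' @param cfg An [ihmm_config()].
#' @param seed Chain seed; overrides `cfg$seed` when given.
#' @return An object of class `ihmm_fit`: `detached_mean`, a `states` data
#'   frame (mean, relative position, occupancy, visit count, mean dwell),
#'   per-state dwell-event lists, the sampled path, concentrations, and the
#'   seed used. Unfiltered; apply [filter_states()] before summarizing.
#' @references Van Gael, Saatci, Teh & Ghahramani (2008) Beam sampling for
#'   the infinite hidden Markov model. ICML.
#' @export
run_ihmm <- function(traj, cfg = ihmm_config(), seed = NULL) {
  y <- if (inherits(traj, "trajectory")) traj$x_nm else as.numeric(traj)
  dt <- if (inherits(traj, "trajectory")) attr(traj, "frame_interval_us")
        else 40
  if (cfg$min_dwell_us < dt)
    stop("min_dwell_us must be >= the frame interval")
  T_ <- length(y)
  if (T_ != cfg$window_frames)
    stop("trajectory length (", T_, ") must equal cfg$window_frames (",
         cfg$window_frames, "); window longer inputs upstream")
  if (stats::sd(y) == 0) stop("all points identical")
  if (is.null(seed)) seed <- cfg$seed
  set.seed(as.integer(seed))

  m0 <- mean(y); s0 <- cfg$mean_prior_sd
  sdd <- cfg$sd_detached; sdb <- cfg$sd_bound
  a_al <- cfg$alpha_prior[1]; b_al <- cfg$alpha_prior[2]
  a_ga <- cfg$gamma_prior[1]; b_ga <- cfg$gamma_prior[2]

  # initial representation: detached + 5 binding states at spread quantiles
  K <- 6L
  mu <- c(m0, as.numeric(stats::quantile(y, c(0.05, 0.275, 0.5, 0.725, 0.95))))
  beta_w <- rep(1 / (K + 1), K + 1)   # last entry: unrepresented rest
  alpha <- 1; gamma_c <- 1
  path <- rep(1L, T_)

  sample_rows <- function(N, beta_w, K) {
    # K x (K+1) transition matrix; last column = aggregate mass to new states
    Pi <- matrix(0, K, K + 1)
    for (j in seq_len(K)) {
      shape <- c(N[j, ], 0) + alpha * beta_w
      g <- rgamma(K + 1, shape = pmax(shape, 1e-8))
      if (j > 1) {                     # binding row: only self and detached
        keep <- c(1L, j)
        g[-keep] <- 0
        g[K + 1] <- 0
      }
      tot <- sum(g)
      if (tot <= 0) { g[j] <- 1; tot <- 1 }
      Pi[j, ] <- g / tot
    }
    Pi
  }

  for (iter in seq_len(cfg$mcmc_iterations)) {
    N <- cpp_transition_counts(path, K, 1L)
    Pi <- sample_rows(N, beta_w, K)

    # beam slice variables (first sweep: u = 0 gives an emission-driven,
    # constraint-respecting initial path)
    if (iter == 1L) {
      u <- rep(0, T_)
    } else {
      prev <- c(1L, path[-T_])
      u <- runif(T_) * Pi[cbind(prev, path)]
      u_min <- min(u)
      # expand representation while unrepresented mass remains reachable
      while (max(Pi[, K + 1]) > u_min && K < cfg$max_states) {
        b <- rbeta_safe(1, gamma_c)
        beta_new <- b * beta_w[K + 1]
        beta_rest <- (1 - b) * beta_w[K + 1]
        beta_w <- c(beta_w[seq_len(K)], beta_new, beta_rest)
        mu <- c(mu, rnorm(1, m0, s0))
        # split each row's aggregate mass between the new state and the rest
        newcol <- numeric(K)
        for (j in seq_len(K)) {
          if (Pi[j, K + 1] <= 0) { newcol[j] <- 0; next }
          frac <- rbeta_safe(alpha * beta_new, alpha * beta_rest)
          newcol[j] <- Pi[j, K + 1] * frac
          Pi[j, K + 1] <- Pi[j, K + 1] * (1 - frac)
        }
        Pi <- cbind(Pi[, seq_len(K), drop = FALSE], newcol, Pi[, K + 1])
        # the new binding state's own row: detached vs self only
        g1 <- rgamma(1, pmax(alpha * beta_w[1], 1e-8))
        g2 <- rgamma(1, pmax(alpha * beta_new, 1e-8))
        if (g1 + g2 <= 0) { g1 <- 1e-6; g2 <- 1 }
        newrow <- numeric(K + 2)
        newrow[1] <- g1 / (g1 + g2)
        newrow[K + 1] <- g2 / (g1 + g2)
        Pi <- rbind(Pi, newrow)
        K <- K + 1L
      }
    }

    # emissions and constrained FFBS path draw
    emit <- matrix(0, T_, K)
    emit[, 1] <- dnorm(y, mu[1], sdd)
    for (k in seq_len(K - 1) + 1) emit[, k] <- dnorm(y, mu[k], sdb)
    path <- cpp_ffbs_beam(emit, Pi[, seq_len(K), drop = FALSE], u, 1L)

    # compact: drop unoccupied binding states, fold their sticks back
    occ_states <- sort(unique(path))
    keep <- union(1L, occ_states)
    if (length(keep) < K) {
      drop <- setdiff(seq_len(K), keep)
      beta_rest_new <- beta_w[K + 1] + sum(beta_w[drop])
      remap <- integer(K); remap[keep] <- seq_along(keep)
      path <- remap[path]
      mu <- mu[keep]
      beta_w <- c(beta_w[keep], beta_rest_new)
      K <- length(keep)
    }

    # conjugate Gaussian update of state means (fixed emission SDs)
    nk <- tabulate(path, K)
    sums <- vapply(seq_len(K), function(k) sum(y[path == k]), numeric(1))
    sd_k <- c(sdd, rep(sdb, K - 1))
    post_var <- 1 / (1 / s0^2 + nk / sd_k^2)
    post_mean <- post_var * (m0 / s0^2 + sums / sd_k^2)
    mu <- rnorm(K, post_mean, sqrt(post_var))

    # HDP bookkeeping: table counts, shared sticks, concentrations
    N <- cpp_transition_counts(path, K, 1L)
    M <- matrix(0L, K, K)
    for (j in seq_len(K)) for (k in seq_len(K)) {
      if (N[j, k] > 0L) M[j, k] <- crt_sample(N[j, k], alpha * beta_w[k])
    }
    mdot <- colSums(M)
    beta_w <- {
      g <- rgamma(K + 1, shape = pmax(c(mdot, gamma_c), 1e-8))
      g / sum(g)
    }
    # alpha | tables (auxiliary-variable scheme)
    nj <- rowSums(N)
    act <- which(nj > 0)
    if (length(act)) {
      w <- vapply(act, function(j) rbeta_safe(alpha + 1, nj[j]), numeric(1))
      s <- rbinom(length(act), 1, nj[act] / (nj[act] + alpha))
      alpha <- rgamma(1, shape = a_al + sum(M) - sum(s),
                      rate = b_al - sum(log(w)))
      alpha <- min(max(alpha, 1e-3), 1e3)
    }
    # gamma | number of represented states and total tables
    m_tot <- max(sum(M), 1L)
    eta <- rbeta_safe(gamma_c + 1, m_tot)
    odds <- (a_ga + K - 1) / (m_tot * (b_ga - log(eta)))
    mix <- runif(1) < odds / (1 + odds)
    gamma_c <- rgamma(1, shape = a_ga + K - ifelse(mix, 0, 1),
                      rate = b_ga - log(eta))
    gamma_c <- min(max(gamma_c, 1e-3), 1e3)
  }

  build_ihmm_fit(y, path, mu, dt, alpha, gamma_c, cfg, seed,
                 filtered = FALSE)
}

# assemble an ihmm_fit from a path + means
build_ihmm_fit <- function(y, path, mu, dt, alpha, gamma_c, cfg, seed,
                           filtered) {
  K <- length(mu)
  r <- rle(path)
  dwell_events <- lapply(seq_len(K), function(k)
    r$lengths[r$values == k] * dt)
  occ <- tabulate(path, K) / length(path)
  if (K > 1) {
    ks <- 2:K
    states <- data.frame(
      state = ks,
      mean_nm = mu[ks],
      rel_position_nm = mu[ks] - mu[1],
      occupancy = occ[ks],
      n_events = vapply(ks, function(k) sum(r$values == k), integer(1)),
      mean_dwell_us = vapply(ks, function(k) {
        d <- dwell_events[[k]]
        if (length(d)) mean(d) else NA_real_
      }, numeric(1)))
  } else {
    states <- data.frame(state = integer(0), mean_nm = numeric(0),
                         rel_position_nm = numeric(0), occupancy = numeric(0),
                         n_events = integer(0), mean_dwell_us = numeric(0))
  }
  structure(list(detached_mean = mu[1], states = states,
                 dwell_events = dwell_events[-1],
                 path = path, mu = mu,
                 alpha = alpha, gamma = gamma_c,
                 frame_interval_us = dt, cfg = cfg,
                 seed = as.integer(seed), filtered = filtered),
            class = "ihmm_fit")
}

#' @export
print.ihmm_fit <- function(x, ...) {
  cat(sprintf("Constrained iHMM sample (seed %d%s): detached at %.2f nm, %d binding state(s)\n",
              x$seed, if (x$filtered) ", filtered" else "", x$detached_mean,
              nrow(x$states)))
  if (nrow(x$states)) {
    df <- x$states
    df$mean_nm <- round(df$mean_nm, 2)
    df$rel_position_nm <- round(df$rel_position_nm, 2)
    df$occupancy <- round(df$occupancy, 4)
    df$mean_dwell_us <- round(df$mean_dwell_us, 1)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Apply the occupancy and dwell filters to an inference sample
#'
#' Removes binding states whose occupancy is below `min_occupancy` or whose
#' dwell statistic is below `min_dwell_us`; their frames are reassigned to
#' the detached state in the path. With the default
#' `dwell_filter = "truncated_mean"` the dwell statistic is
#' `mean(events) - frame_interval` (frame-quantized events can never average
#' below one frame, so the raw mean would make the floor vacuous; the
#' truncation-corrected mean lets sub-resolution flicker states fail it).
#'
#' @param fit An `ihmm_fit` from [run_ihmm()].
#' @param cfg Optional [ihmm_config()] supplying the thresholds; defaults to
#'   the config stored in `fit`.
#' @return The filtered `ihmm_fit` (`filtered = TRUE`).
#' @export
filter_states <- function(fit, cfg = NULL) {
  stopifnot(inherits(fit, "ihmm_fit"))
  if (is.null(cfg)) cfg <- fit$cfg
  if (!nrow(fit$states)) { fit$filtered <- TRUE; return(fit) }
  dt <- fit$frame_interval_us
  stat <- if (cfg$dwell_filter == "truncated_mean")
    fit$states$mean_dwell_us - dt else fit$states$mean_dwell_us
  drop <- fit$states$occupancy < cfg$min_occupancy |
    !is.finite(stat) | stat < cfg$min_dwell_us
  drop_states <- fit$states$state[drop]
  path <- fit$path
  path[path %in% drop_states] <- 1L
  keep <- sort(unique(path))
  remap <- integer(length(fit$mu)); remap[keep] <- seq_along(keep)
  path <- remap[path]
  mu <- fit$mu[keep]
  out <- build_ihmm_fit(numeric(0), path, mu, dt, fit$alpha, fit$gamma,
                        cfg, fit$seed, filtered = TRUE)
  # occupancy/dwell computed from the relabeled path; detached mean kept
  out$detached_mean <- fit$detached_mean
  out$states$rel_position_nm <- out$states$mean_nm - fit$detached_mean
  out
}

#' Run repeated independent inference chains
#'
#' `n` chains on the same window with seeds `seed, seed + 1, ...`
#' (seed-indexed, so results are schedule-independent and reproducible).
#' Chains are filtered by default before pooling.
#'
#' @param traj A `trajectory` of `cfg$window_frames` frames.
#' @param cfg An [ihmm_config()].
#' @param n Number of chains (default `cfg$n_inferences`).
#' @param seed Base seed (default `cfg$seed`).
#' @param filter Apply [filter_states()] to each chain (default TRUE).
#' @param progress Print a dot per chain (default FALSE).
#' @return List of `ihmm_fit` objects, class `ihmm_runs`.
#' @export
run_repeated <- function(traj, cfg = ihmm_config(), n = cfg$n_inferences,
                         seed = cfg$seed, filter = TRUE, progress = FALSE) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- tryCatch(run_ihmm(traj, cfg, seed = seed + i - 1L),
                    error = function(e)
                      stop("chain ", i, ": ", conditionMessage(e)))
    out[[i]] <- if (filter) filter_states(fit, cfg) else fit
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  class(out) <- "ihmm_runs"
  out
}

#' @export
print.ihmm_runs <- function(x, ...) {
  ns <- vapply(x, function(f) nrow(f$states), integer(1))
  cat("iHMM runs:", length(x), "chains;",
      sum(ns), "retained binding states (median", stats::median(ns),
      "per chain)\n")
  invisible(x)
}

#' Pool retained binding states across chains
#'
#' @param results A list of `ihmm_fit` objects (e.g. from [run_repeated()]).
#' @return Data frame with one row per retained binding state per chain:
#'   `chain, state, relative_position_nm, occupancy, n_events,
#'   mean_dwell_us`.
#' @export
pooled_states <- function(results) {
  rows <- lapply(seq_along(results), function(i) {
    st <- results[[i]]$states
    if (!nrow(st)) return(NULL)
    data.frame(chain = i, state = st$state,
               relative_position_nm = st$rel_position_nm,
               occupancy = st$occupancy, n_events = st$n_events,
               mean_dwell_us = st$mean_dwell_us)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(chain = integer(0), state = integer(0),
                      relative_position_nm = numeric(0),
                      occupancy = numeric(0), n_events = integer(0),
                      mean_dwell_us = numeric(0))
  out
}

#' @rdname pooled_states
#' @return `pooled_positions`: the vector of relative binding positions (nm).
#' @export
pooled_positions <- function(results) {
  pooled_states(results)$relative_position_nm
}
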