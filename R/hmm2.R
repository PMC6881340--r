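#' Two-state Gaussian HMM for the detached-to-strong-binding step
#'
#' Expectation-maximization over the two state means and the 2x2 transition
#' matrix of a Gaussian hidden Markov model whose emission SDs are held
#' fixed: a broad detached state (12.5 nm default) and a narrow bound state
#' (4.7 nm default). The step size is the bound mean minus the detached
#' mean. States are identified structurally by their fixed SDs, so the fit
#' is label-unambiguous even when the bound state dominates occupancy (as at
#' micromolar ATP). EM is run from two deterministic initializations -- the
#' histogram mode assigned to the broad state, and the swap -- and the
#' higher-likelihood fit is returned, making the estimator deterministic.
#'
#' @param traj A `trajectory` (or numeric vector of positions, nm).
#' @param sd_detached Fixed emission SD of the detached state, nm
#'   (default 12.5).
#' @param sd_bound Fixed emission SD of the bound state, nm (default 4.7);
#'   must be smaller than `sd_detached`.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @return An object of class `hmm2_fit`: means, `step` (bound - detached),
#'   transition matrix, Viterbi `path` (1 = detached, 2 = bound), occupancy,
#'   log-likelihood trace, and flags (`converged`, `reliable`).
#' @examples
#' sch <- kinetic_scheme(sites = list(weak_site(44, 1, 1.3e5)),
#'                       encounter_rate_s = 50, duration_us = 4e5)
#' fit <- fit_two_state_hmm(simulate_trajectory(sch, seed = 2))
#' coef(fit)["step"]
#' @export
fit_two_state_hmm <- function(traj, sd_detached = 12.5, sd_bound = 4.7,
                              max_iter = 500, tol = 1e-6) {
  y <- if (inherits(traj, "trajectory")) traj$x_nm else as.numeric(traj)
  if (length(y) < 100) stop("trajectory must have at least 100 frames")
  if (!(sd_detached > sd_bound && sd_bound > 0))
    stop("need sd_detached > sd_bound > 0")

  dens <- stats::density(y, n = 512)
  mode_y <- dens$x[which.max(dens$y)]
  sk <- mean((y - mean(y))^3) / stats::sd(y)^3
  tail_side <- if (sk >= 0) 1 else -1
  q <- stats::quantile(y, if (tail_side > 0) 0.95 else 0.05)
  tail_mean <- mean(y[if (tail_side > 0) y >= q else y <= q])

  run_em <- function(mu0) {
    mu <- mu0
    A <- matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE)
    pi0 <- c(0.5, 0.5)
    sds <- c(sd_detached, sd_bound)
    ll_trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      emit <- cbind(dnorm(y, mu[1], sds[1]), dnorm(y, mu[2], sds[2]))
      fb <- cpp_forward_backward(emit, A, pi0)
      ll_trace <- c(ll_trace, fb$loglik)
      g <- fb$gamma
      mu_new <- colSums(g * y) / colSums(g)
      xi <- fb$xi
      A_new <- xi / rowSums(xi)
      pi0 <- g[1, ]
      if (it > 1 && abs(ll_trace[it] - ll_trace[it - 1]) < tol) {
        mu <- mu_new; A <- A_new; converged <- TRUE; break
      }
      mu <- mu_new; A <- A_new
    }
    list(mu = mu, A = A, pi0 = pi0, ll = ll_trace, converged = converged)
  }

  cand <- list(run_em(c(mode_y, tail_mean)), run_em(c(tail_mean, mode_y)))
  best <- cand[[which.max(vapply(cand, function(z) tail(z$ll, 1),
                                 numeric(1)))]]

  sds <- c(sd_detached, sd_bound)
  emit_log <- cbind(dnorm(y, best$mu[1], sds[1], log = TRUE),
                    dnorm(y, best$mu[2], sds[2], log = TRUE))
  path <- cpp_viterbi(emit_log, log(best$A), log(pmax(best$pi0, 1e-300)))
  occ <- tabulate(path, 2) / length(path)
  reliable <- all(occ > 0.01)
  step <- best$mu[2] - best$mu[1]
  structure(list(detached_mean = best$mu[1], bound_mean = best$mu[2],
                 step = step, transition = best$A,
                 sd_detached = sd_detached, sd_bound = sd_bound,
                 path = path, occupancy = occ,
                 loglik = tail(best$ll, 1), loglik_trace = best$ll,
                 converged = best$converged, reliable = reliable,
                 n = length(y),
                 frame_interval_us = if (inherits(traj, "trajectory"))
                   attr(traj, "frame_interval_us") else NA_real_),
            class = "hmm2_fit")
}

#' @export
print.hmm2_fit <- function(x, ...) {
  cat(sprintf(
    "Two-state HMM fit (n = %d): detached %.2f nm, bound %.2f nm, step %.2f nm\n",
    x$n, x$detached_mean, x$bound_mean, x$step))
  cat(sprintf("  occupancy detached %.1f%%, bound %.1f%%; logLik %.1f%s%s\n",
              100 * x$occupancy[1], 100 * x$occupancy[2], x$loglik,
              if (!x$converged) " [not converged]" else "",
              if (!x$reliable) " [step unreliable]" else ""))
  invisible(x)
}

#' @export
coef.hmm2_fit <- function(object, ...) {
  c(detached_mean = object$detached_mean, bound_mean = object$bound_mean,
    step = object$step)
}

#' @export
logLik.hmm2_fit <- function(object, ...) {
  structure(object$loglik, df = 2 + 2, nobs = object$n, class = "logLik")
}

#' @export
summary.hmm2_fit <- function(object, ...) {
  dt <- object$frame_interval_us
  r <- rle(object$path)
  dw <- if (is.finite(dt)) r$lengths[r$values == 2] * dt else NULL
  out <- list(fit = object,
              n_bound_events = sum(r$values == 2),
              mean_bound_dwell_us = if (length(dw)) mean(dw) else NA_real_)
  class(out) <- "summary.hmm2_fit"
  out
}

#' @export
print.summary.hmm2_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d bound events, mean dwell %.0f us\n",
              x$n_bound_events, x$mean_bound_dwell_us))
  invisible(x)
}

#' @export
residuals.hmm2_fit <- function(object, traj = NULL, ...) {
  if (is.null(traj)) stop("supply the fitted trajectory to compute residuals")
  y <- if (inherits(traj, "trajectory")) traj$x_nm else as.numeric(traj)
  mu <- c(object$detached_mean, object$bound_mean)[object$path]
  y - mu
}

#' @export
simulate.hmm2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  mu <- c(object$detached_mean, object$bound_mean)
  sds <- c(object$sd_detached, object$sd_bound)
  for (i in seq_len(nsim)) {
    s <- integer(object$n)
    s[1] <- sample(1:2, 1)
    for (t in 2:object$n)
      s[t] <- sample(1:2, 1, prob = object$transition[s[t - 1], ])
    out[[i]] <- rnorm(object$n, mu[s], sds[s])
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.hmm2_fit <- function(x, traj = NULL, ...) {
  if (!is.null(traj)) {
    y <- if (inherits(traj, "trajectory")) traj$x_nm else as.numeric(traj)
    t <- seq_along(y)
    plot(t, y, type = "l", col = grey(0.6), xlab = "frame",
         ylab = "position (nm)", ...)
    lines(t, c(x$detached_mean, x$bound_mean)[x$path], col = "red", lwd = 1.5)
  } else {
    plot(x$loglik_trace, type = "b", xlab = "EM iteration",
         ylab = "log-likelihood", ...)
  }
  invisible(x)
}

#' Compare two groups of step estimates
#'
#' Group means, SEMs, the mean difference with propagated SEM
#' (`sqrt(s1^2/n1 + s2^2/n2)`), a two-tailed unpaired Student's t-test and
#' Hedges' g with the small-sample correction `1 - 3/(4*df - 1)`.
#'
#' @param group1,group2 Numeric vectors of step estimates (nm), n >= 2 each.
#' @return A list of class `step_comparison`.
#' @export
compare_step_groups <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  v1 <- stats::var(group1); v2 <- stats::var(group2)
  if (v1 == 0 && v2 == 0) stop("zero variance in both groups")
  n1 <- length(group1); n2 <- length(group2)
  m1 <- mean(group1); m2 <- mean(group2)
  sem1 <- sqrt(v1 / n1); sem2 <- sqrt(v2 / n2)
  diff_sem <- sqrt(v1 / n1 + v2 / n2)
  tt <- stats::t.test(group1, group2, var.equal = TRUE)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df)
  g <- (m1 - m2) / sp * (1 - 3 / (4 * df - 1))
  structure(list(mean1 = m1, sem1 = sem1, n1 = n1,
                 mean2 = m2, sem2 = sem2, n2 = n2,
                 difference = m1 - m2, difference_sem = diff_sem,
                 t = unname(tt$statistic), p = tt$p.value, df = df,
                 hedges_g = g),
            class = "step_comparison")
}

#' @export
print.step_comparison <- function(x, ...) {
  cat(sprintf("Group 1: %.1f +- %.1f nm (SEM, n = %d)\n", x$mean1, x$sem1,
              x$n1))
  cat(sprintf("Group 2: %.1f +- %.1f nm (SEM, n = %d)\n", x$mean2, x$sem2,
              x$n2))
  cat(sprintf("Difference: %.1f +- %.2f nm; t(%d) = %.2f, p = %.3g, Hedges' g = %.2f\n",
              x$difference, x$difference_sem, x$df, x$t, x$p, x$hedges_g))
  invisible(x)
}
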