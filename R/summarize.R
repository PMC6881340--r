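#' Fit a K-component 1D Gaussian mixture by EM
#'
#' Maximum-likelihood mixture fit for the pooled binding-position samples.
#' Initialization is deterministic given `seed`: k-means++ style center
#' seeding followed by EM, with `restarts` independent seedings; the best
#' final likelihood is returned. Component means are reported in ascending
#' order.
#'
#' @param samples Numeric vector (>= 10 * K values).
#' @param K Number of components (default 5, the binding-peak count over the
#'   tether span).
#' @param seed Integer seed for the restarts.
#' @param restarts Number of seeded restarts (default 5).
#' @param max_iter,tol EM stopping rule (default 500 iterations, 1e-8
#'   relative log-likelihood).
#' @return An object of class `gmm1d`: `means`, `sds`, `weights` (ascending
#'   mean order), `loglik`, `loglik_trace` (of the best restart), `bic`.
#' @export
fit_gaussian_mixture_1d <- function(samples, K = 5, seed = 1L,
                                    restarts = 5, max_iter = 500,
                                    tol = 1e-8) {
  x <- as.numeric(samples)
  if (K < 1) stop("K must be >= 1")
  if (length(x) < 10 * K) stop("need at least 10*K samples")
  if (K > 1 && stats::sd(x) == 0)
    stop("all samples identical; cannot fit K > 1 components")
  set.seed(as.integer(seed))
  n <- length(x)

  kmeanspp_centers <- function() {
    c1 <- x[sample.int(n, 1)]
    centers <- c1
    while (length(centers) < K) {
      d2 <- vapply(x, function(v) min((v - centers)^2), numeric(1))
      if (sum(d2) == 0) centers <- c(centers, x[sample.int(n, 1)])
      else centers <- c(centers, x[sample.int(n, 1, prob = d2)])
    }
    centers
  }

  run_em <- function(centers) {
    mu <- sort(centers)
    sig <- rep(max(stats::sd(x) / K, 1e-3), K)
    w <- rep(1 / K, K)
    trace <- numeric(0)
    sd_floor <- max(1e-3 * stats::sd(x), 1e-6)
    for (it in seq_len(max_iter)) {
      dens <- vapply(seq_len(K), function(k) w[k] * dnorm(x, mu[k], sig[k]),
                     numeric(n))
      if (K == 1) dens <- matrix(dens, ncol = 1)
      rowsum_d <- rowSums(dens)
      rowsum_d[rowsum_d == 0] <- .Machine$double.xmin
      ll <- sum(log(rowsum_d))
      trace <- c(trace, ll)
      r <- dens / rowsum_d
      nk <- colSums(r)
      if (any(nk < 1e-8)) {  # dead component: restart it at a random point
        dead <- which(nk < 1e-8)
        mu[dead] <- x[sample.int(n, length(dead))]
        sig[dead] <- sd_floor * 10
        next
      }
      w <- nk / n
      mu <- colSums(r * x) / nk
      sig <- sqrt(vapply(seq_len(K), function(k)
        sum(r[, k] * (x - mu[k])^2) / nk[k], numeric(1)))
      sig <- pmax(sig, sd_floor)
      if (it > 1 && abs(trace[it] - trace[it - 1]) <
            tol * (abs(trace[it - 1]) + 1)) break
    }
    list(mu = mu, sig = sig, w = w, trace = trace)
  }

  best <- NULL
  for (r in seq_len(max(restarts, 1))) {
    fit <- run_em(if (r == 1 && K > 1)
      as.numeric(stats::quantile(x, (seq_len(K) - 0.5) / K))
      else kmeanspp_centers())
    if (is.null(best) || tail(fit$trace, 1) > tail(best$trace, 1))
      best <- fit
  }
  ord <- order(best$mu)
  structure(list(means = best$mu[ord], sds = best$sig[ord],
                 weights = best$w[ord], K = K, n = n,
                 loglik = tail(best$trace, 1),
                 loglik_trace = best$trace,
                 bic = -2 * tail(best$trace, 1) + (3 * K - 1) * log(n)),
            class = "gmm1d")
}

#' @export
print.gmm1d <- function(x, ...) {
  cat("Gaussian mixture (K =", x$K, ", n =", x$n, "), logLik",
      round(x$loglik, 1), "\n")
  print(data.frame(mean = round(x$means, 2), sd = round(x$sds, 2),
                   weight = round(x$weights, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
coef.gmm1d <- function(object, ...) {
  cbind(mean = object$means, sd = object$sds, weight = object$weights)
}

#' @export
plot.gmm1d <- function(x, samples = NULL, bin_nm = 1, ...) {
  if (!is.null(samples)) {
    h <- hist(samples, breaks = seq(min(samples) - bin_nm,
                                    max(samples) + bin_nm, by = bin_nm),
              freq = FALSE, xlab = "relative position (nm)",
              main = "binding-position mixture", col = grey(0.9), ...)
    xs <- seq(min(h$breaks), max(h$breaks), length.out = 400)
  } else {
    xs <- seq(min(x$means) - 4 * max(x$sds), max(x$means) + 4 * max(x$sds),
              length.out = 400)
    plot(NA, xlim = range(xs), ylim = c(0, 1), xlab = "position (nm)",
         ylab = "density", ...)
  }
  dens <- rowSums(vapply(seq_len(x$K), function(k)
    x$weights[k] * dnorm(xs, x$means[k], x$sds[k]), numeric(length(xs))))
  lines(xs, dens, col = "magenta", lwd = 2)
  invisible(x)
}

#' Fit an exponential dwell-time distribution by its CDF
#'
#' Least-squares fit of the empirical cumulative distribution (midpoint
#' plotting positions `(i - 0.5)/n`) to the left-truncated exponential
#' `1 - exp(-(t - truncation)/tau)`. Use `truncation` for genuinely
#' left-truncated samples (the observability floor); frame-quantized
#' run-length dwells should be fitted with `truncation = 0`, because
#' rounding to whole frames preserves the mean rather than truncating the
#' distribution. The maximum-likelihood value `mean(dwells) - truncation`
#' is reported as a cross-check.
#'
#' @param dwells Dwell times (us), all >= `truncation`.
#' @param truncation Left-truncation point, us (default 0).
#' @return An object of class `dwell_fit`: `tau`, `se` (from the CDF fit),
#'   `mle`, `truncation`, `n`. With fewer than 10 dwells the MLE is
#'   returned with a degenerate-fit flag.
#' @export
fit_exponential_dwell <- function(dwells, truncation = 0) {
  d <- as.numeric(dwells)
  if (!length(d)) stop("no dwells")
  if (any(d < truncation - 1e-9))
    stop("all dwells must be >= truncation")
  n <- length(d)
  mle <- mean(d) - truncation
  if (n < 10 || stats::sd(d) < 1e-9 * max(mean(d), 1)) {
    return(structure(list(tau = mle, se = NA_real_, mle = mle,
                          truncation = truncation, n = n,
                          degenerate = TRUE), class = "dwell_fit"))
  }
  ts <- sort(d)
  Fe <- (seq_len(n) - 0.5) / n
  fit <- tryCatch(
    stats::nls(Fe ~ 1 - exp(-(ts - truncation) / tau),
               start = list(tau = max(mle, 1e-6)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    obj <- function(tau) sum((Fe - (1 - exp(-(ts - truncation) / tau)))^2)
    opt <- stats::optimize(obj, c(1e-6, 100 * max(mle, 1)))
    tau <- opt$minimum; se <- NA_real_
  } else {
    tau <- coef(fit)[["tau"]]
    se <- summary(fit)$coefficients["tau", "Std. Error"]
  }
  structure(list(tau = tau, se = se, mle = mle, truncation = truncation,
                 n = n, degenerate = FALSE), class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("Exponential dwell fit: tau = %.1f +- %.1f us (n = %d%s; MLE %.1f us, truncation %g us)\n",
              x$tau, x$se, x$n, if (x$degenerate) ", degenerate" else "",
              x$mle, x$truncation))
  invisible(x)
}

#' @export
coef.dwell_fit <- function(object, ...) c(tau = object$tau)

#' Summarize pooled inferences into binding-position peaks
#'
#' Each retained inferred state is assigned to the mixture peak whose
#' mean +- 1 SD window contains its position (nearest peak in SD units when
#' windows overlap; states in no window stay unassigned). Per chain, a
#' peak's access ratio is the fraction of that chain's binding events
#' (visits) carried by its assigned states; the reported access ratio is
#' the mean +- SD across chains. Dwell events are pooled across chains per
#' peak and fitted with [fit_exponential_dwell()]. Peaks whose mean access
#' ratio falls below `access_floor` are flagged excluded from dwell
#' reporting (too few visits to estimate a dwell).
#'
#' @param results List of filtered `ihmm_fit` objects.
#' @param mixture A `gmm1d` fitted on `pooled_positions(results)`.
#' @param access_floor Exclusion floor on the mean access ratio
#'   (default 0.05).
#' @param access_mode `"events"` (default; per-chain fraction of binding
#'   visits) or `"points"` (fraction of bound frames).
#' @param dwell_truncation Truncation passed to the per-peak dwell fit
#'   (default 0; see [fit_exponential_dwell()]).
#' @return A data frame of class `peak_summary`: one row per peak with
#'   position, position SD, access ratio (mean and SD across chains), dwell
#'   (the exponential MLE, the consistent estimate for frame-quantized
#'   run-length events, with its SE; the CDF-fit value in `dwell_cdf_us` as
#'   cross-check), event count, and exclusion flag.
#' @export
summarize_peaks <- function(results, mixture, access_floor = 0.05,
                            access_mode = c("events", "points"),
                            dwell_truncation = 0) {
  access_mode <- match.arg(access_mode)
  stopifnot(inherits(mixture, "gmm1d"))
  Kp <- mixture$K
  n_chains <- length(results)
  access <- matrix(NA_real_, n_chains, Kp)
  dwell_pool <- vector("list", Kp)
  n_states <- integer(Kp)

  for (i in seq_len(n_chains)) {
    st <- results[[i]]$states
    if (!nrow(st)) next
    # z-distance to each peak; assigned iff within 1 SD of the nearest peak
    z <- abs(outer(st$rel_position_nm, mixture$means, "-")) /
      rep(mixture$sds, each = nrow(st))
    peak <- apply(z, 1, which.min)
    peak[z[cbind(seq_len(nrow(st)), peak)] > 1] <- NA
    tot <- if (access_mode == "events") sum(st$n_events)
           else sum(st$occupancy)
    if (tot <= 0) next
    for (p in seq_len(Kp)) {
      sel <- which(!is.na(peak) & peak == p)
      access[i, p] <- if (access_mode == "events")
        sum(st$n_events[sel]) / tot else sum(st$occupancy[sel]) / tot
      if (length(sel)) {
        n_states[p] <- n_states[p] + length(sel)
        ev <- unlist(results[[i]]$dwell_events[st$state[sel] - 1L])
        dwell_pool[[p]] <- c(dwell_pool[[p]], ev)
      }
    }
  }

  acc_mean <- colMeans(access, na.rm = TRUE)
  acc_sd <- apply(access, 2, stats::sd, na.rm = TRUE)
  out <- data.frame(peak = seq_len(Kp),
                    position_nm = mixture$means,
                    position_sd_nm = mixture$sds,
                    access_ratio = acc_mean,
                    access_sd = acc_sd,
                    dwell_us = NA_real_, dwell_se_us = NA_real_,
                    dwell_cdf_us = NA_real_,
                    n_events = vapply(dwell_pool, length, integer(1)),
                    n_states = n_states,
                    excluded = FALSE, reason = "")
  for (p in seq_len(Kp)) {
    if (!is.finite(acc_mean[p]) || out$n_events[p] == 0) {
      out$excluded[p] <- TRUE; out$reason[p] <- "no assigned states"
    } else if (acc_mean[p] < access_floor) {
      out$excluded[p] <- TRUE
      out$reason[p] <- "accessibility below floor"
    }
    if (out$n_events[p] > 0 && !out$excluded[p]) {
      df <- fit_exponential_dwell(dwell_pool[[p]],
                                  truncation = dwell_truncation)
      out$dwell_us[p] <- df$mle
      out$dwell_se_us[p] <- df$mle / sqrt(df$n)
      out$dwell_cdf_us[p] <- df$tau
    }
  }
  structure(out, dwell_pool = dwell_pool, access_matrix = access,
            class = c("peak_summary", "data.frame"))
}

#' @export
print.peak_summary <- function(x, ...) {
  df <- as.data.frame(x)
  for (cl in c("position_nm", "position_sd_nm", "dwell_us", "dwell_se_us",
               "dwell_cdf_us"))
    df[[cl]] <- round(df[[cl]], 1)
  for (cl in c("access_ratio", "access_sd")) df[[cl]] <- round(df[[cl]], 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Weak-to-strong dwell prolongation
#'
#' Fold change between the mean strong-binding dwell predicted by the ATP
#' rate line at a given concentration, `1 / (slope * atp + intercept)`, and
#' a weak-binding dwell time.
#'
#' @param weak_dwell_us Weak-binding dwell, us (> 0).
#' @param rate_fit A `rate_fit` object (see [fit_rate_line()]) or a list
#'   with elements `slope` (s^-1 nM^-1) and `intercept` (s^-1).
#' @param atp_nM ATP concentration, nM.
#' @return Fold prolongation (dimensionless).
#' @examples
#' dwell_ratio(513, list(slope = 0.0038, intercept = 0.17), 2000)
#' @export
dwell_ratio <- function(weak_dwell_us, rate_fit, atp_nM) {
  stopifnot(weak_dwell_us > 0)
  rate <- rate_fit$slope * atp_nM + rate_fit$intercept
  if (!is.finite(rate) || rate <= 0)
    stop("predicted strong-binding rate must be > 0")
  strong_dwell_us <- 1e6 / rate
  strong_dwell_us / weak_dwell_us
}

#' Decompose the total powerstroke into its two substeps
#'
#' The second substep is the total head displacement minus the first; its SD
#' is reported under the independence convention
#' `sqrt(total_sd^2 - first_sd^2)`, flagged `NA` when the total SD does not
#' exceed the first-step SD.
#'
#' @param first_mean,first_sd First-substep displacement, nm (mean, SD).
#' @param total_mean,total_sd Whole-step displacement, nm (mean, SD).
#' @return List with `second_mean`, `second_sd` and `sd_flag`.
#' @examples
#' powerstroke_decompose(3.9, 1.1, 7.9, 2.6)
#' @export
powerstroke_decompose <- function(first_mean, first_sd, total_mean,
                                  total_sd) {
  if (total_mean < first_mean)
    stop("total_mean must be >= first_mean")
  second_mean <- total_mean - first_mean
  if (total_sd > first_sd) {
    second_sd <- sqrt(total_sd^2 - first_sd^2)
    flag <- FALSE
  } else {
    second_sd <- NA_real_
    flag <- TRUE
  }
  list(second_mean = second_mean, second_sd = second_sd, sd_flag = flag)
}
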