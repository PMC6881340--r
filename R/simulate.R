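#' Construct a trajectory object
#'
#' A uniformly sampled 1D (optionally 2D) position record. Mostly produced by
#' [simulate_trajectory()] or [project_major_axis()]; exposed for building
#' trajectories from external tables.
#'
#' @param t_us Frame times, microseconds, uniformly spaced.
#' @param x_nm Positions along the analysis axis, nm.
#' @param y_nm Optional lateral positions, nm.
#' @param label Optional integer per-frame ground-truth state labels
#'   (0 = detached, k = site k).
#' @param frame_interval_us Frame interval; inferred from `t_us` if missing.
#' @return A data frame of class `trajectory` with attribute
#'   `frame_interval_us`.
#' @export
trajectory <- function(t_us, x_nm, y_nm = NULL, label = NULL,
                       frame_interval_us = NULL) {
  stopifnot(length(t_us) == length(x_nm), all(is.finite(x_nm)))
  if (length(t_us) > 1) {
    dt <- diff(t_us)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("t_us must be strictly increasing with constant spacing")
    if (is.null(frame_interval_us)) frame_interval_us <- dt[1]
  }
  if (is.null(frame_interval_us))
    stop("frame_interval_us required for single-frame records")
  df <- data.frame(t_us = t_us, x_nm = x_nm)
  if (!is.null(y_nm)) {
    stopifnot(length(y_nm) == length(x_nm), all(is.finite(y_nm)))
    df$y_nm <- y_nm
  }
  if (!is.null(label)) {
    stopifnot(length(label) == length(x_nm))
    df$label <- as.integer(label)
  }
  structure(df, frame_interval_us = frame_interval_us,
            class = c("trajectory", "data.frame"))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", nrow(x), "frames at",
      attr(x, "frame_interval_us"), "us (",
      signif(nrow(x) * attr(x, "frame_interval_us") / 1e3, 4), "ms )\n")
  cat("  x range [", signif(min(x$x_nm), 4), ",", signif(max(x$x_nm), 4),
      "] nm", if ("y_nm" %in% names(x)) "; 2D", "\n")
  ev <- attr(x, "events")
  if (!is.null(ev)) cat("  ground truth:", nrow(ev), "binding events\n")
  invisible(x)
}

#' @export
plot.trajectory <- function(x, ...) {
  plot(x$t_us / 1e3, x$x_nm, type = "l", xlab = "time (ms)",
       ylab = "position (nm)", col = grey(0.3), ...)
  if ("label" %in% names(x)) {
    b <- x$label > 0
    points(x$t_us[b] / 1e3, x$x_nm[b], col = "magenta", pch = 16, cex = 0.3)
  }
  invisible(x)
}

# state-sequence core: returns per-frame labels (0 = detached, k = site k)
# and a ground-truth event table with continuous and frame-quantized dwells.
sim_state_sequence <- function(scheme, n_frames) {
  dt <- scheme$frame_interval_us
  w <- vapply(scheme$sites, `[[`, numeric(1), "access_weight")
  n_sites <- length(scheme$sites)
  p_enc <- if (n_sites == 0) 0
           else min(1, scheme$encounter_rate_s * dt * 1e-6)
  labels <- integer(n_frames)
  ev_state <- integer(0); ev_start <- integer(0)
  ev_dwell_cont <- numeric(0); ev_frames <- integer(0)
  pos <- 1L
  while (pos <= n_frames) {
    # detached sojourn: per-frame Bernoulli entry => geometric frame count
    stay <- if (p_enc <= 0) n_frames else rgeom(1, p_enc) + 1L
    end <- min(pos + stay - 1L, n_frames)
    # labels already 0
    pos <- end + 1L
    if (pos > n_frames || p_enc <= 0) break
    k <- if (n_sites == 1L) 1L else sample.int(n_sites, 1L, prob = w)
    strong <- !is.null(scheme$strong_site_index) &&
      k == scheme$strong_site_index
    mean_us <- if (strong)
      1e6 / (scheme$rate_slope * scheme$atp_nM + scheme$rate_intercept)
    else scheme$sites[[k]]$mean_dwell_us
    d_us <- rexp(1, 1 / mean_us)
    # continuous dwell, rounded to whole frames, minimum one frame
    nf <- max(1L, as.integer(round(d_us / dt)))
    end <- min(pos + nf - 1L, n_frames)
    labels[pos:end] <- k
    ev_state <- c(ev_state, k); ev_start <- c(ev_start, pos)
    ev_dwell_cont <- c(ev_dwell_cont, d_us)
    ev_frames <- c(ev_frames, end - pos + 1L)
    pos <- end + 1L
  }
  list(labels = labels,
       events = data.frame(state = ev_state, start_frame = ev_start,
                           n_frames = ev_frames,
                           dwell_us = ev_frames * dt,
                           dwell_true_us = ev_dwell_cont))
}

#' Simulate a tethered-head trajectory
#'
#' Alternating-renewal generative process: from the detached state the head
#' enters a binding site k each frame with probability
#' `encounter_rate_s * dt * access_weight[k]`; weak dwells are exponential
#' with the site mean, strong dwells exponential with mean
#' `1 / (rate_slope * atp_nM + rate_intercept)`. Dwells are drawn in
#' continuous time and rounded to whole frames (minimum one frame, the
#' observability floor). Emissions are independent Gaussians per frame:
#' detached `N(detached_mean, detached_sd^2)`, bound
#' `N(site position, bound_sd^2)` (no motion blur within a frame).
#'
#' @param scheme A [kinetic_scheme()].
#' @param seed Integer seed; identical scheme + seed gives identical output.
#' @return A [trajectory()] with per-frame ground-truth `label` and an
#'   `events` attribute: one row per binding event with its continuous
#'   (`dwell_true_us`) and frame-quantized (`dwell_us`) dwell.
#' @examples
#' sch <- kinetic_scheme(sites = list(weak_site(22.8, 1, 500)),
#'                       duration_us = 2e5)
#' traj <- simulate_trajectory(sch, seed = 1)
#' @export
simulate_trajectory <- function(scheme, seed = 1L) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  n_frames <- floor(scheme$duration_us / scheme$frame_interval_us)
  if (n_frames < 1) stop("duration_us shorter than one frame")
  set.seed(as.integer(seed))
  ss <- sim_state_sequence(scheme, n_frames)
  site_pos <- vapply(scheme$sites, `[[`, numeric(1), "position_nm")
  mean_by_label <- c(scheme$detached_mean_nm,
                     scheme$detached_mean_nm + site_pos)
  sd_by_label <- c(scheme$detached_sd_nm,
                   rep(scheme$bound_sd_nm, length(site_pos)))
  mu <- mean_by_label[ss$labels + 1L]
  # optional lever-arm substeps: bound mean advances within strong events
  if (!is.null(scheme$substeps) && !is.null(scheme$strong_site_index) &&
      nrow(ss$events)) {
    dt <- scheme$frame_interval_us
    strong_ev <- which(ss$events$state == scheme$strong_site_index)
    for (i in strong_ev) {
      off <- 0
      lat_us <- 0
      for (p in seq_len(nrow(scheme$substeps))) {
        lat_us <- lat_us + rexp(1, 1 / scheme$substeps$mean_latency_us[p])
        from <- ss$events$start_frame[i] + as.integer(ceiling(lat_us / dt))
        to <- ss$events$start_frame[i] + ss$events$n_frames[i] - 1L
        if (from > to) break
        off <- scheme$substeps$displacement_nm[p]
        mu[from:to] <- mu[from:to] + off
      }
    }
  }
  x <- rnorm(n_frames, mean = mu, sd = sd_by_label[ss$labels + 1L])
  y <- if (!is.null(scheme$lateral_sd_nm))
    rnorm(n_frames, 0, scheme$lateral_sd_nm) else NULL
  tr <- trajectory(t_us = (seq_len(n_frames) - 1) * scheme$frame_interval_us,
                   x_nm = x, y_nm = y, label = ss$labels,
                   frame_interval_us = scheme$frame_interval_us)
  attr(tr, "events") <- ss$events
  attr(tr, "scheme") <- scheme
  attr(tr, "seed") <- as.integer(seed)
  tr
}

#' Simulate an image stack of a diffusing diffraction-limited spot
#'
#' Each frame is an independent Poisson realization of an isotropic Gaussian
#' point-spread function centered at the frame's true position, on a uniform
#' background. Pixel values integrate the PSF over the pixel area
#' (difference-of-normal-CDF model), so the noiseless frame centroid equals
#' the true center analytically. Pixel centers sit at integer pixel
#' coordinates with the first pixel's center at (0, 0); nm = px * pixel size.
#'
#' @param center_track Either a `trajectory` (its `x_nm`/`y_nm` used as lab
#'   coordinates) or a 2-column matrix/data.frame of centers in nm.
#' @param pixel_size_nm Pixel pitch, nm (default 123).
#' @param psf_sigma_nm PSF Gaussian SD, nm.
#' @param photon_rate Expected photons per frame in the spot (> 0 unless 0
#'   for background-only frames).
#' @param background Expected background counts per pixel.
#' @param dim Frame size `c(rows, cols)` in pixels.
#' @param seed Integer seed.
#' @param poisson If `FALSE`, return the noiseless expected counts.
#' @return An object of class `image_stack`: list with `frames` (list of
#'   matrices), `pixel_size_nm`, `frame_interval_us`, and the true centers
#'   (`centers_px`, nm-scale `centers_nm`) for oracle use.
#' @export
simulate_spot_stack <- function(center_track, pixel_size_nm = 123,
                                psf_sigma_nm = 150, photon_rate = 5000,
                                background = 20, dim = c(24L, 24L),
                                seed = 1L, poisson = TRUE) {
  stopifnot(pixel_size_nm > 0, psf_sigma_nm > 0, photon_rate >= 0,
            background >= 0)
  if (inherits(center_track, "trajectory")) {
    cx <- center_track$x_nm
    cy <- if ("y_nm" %in% names(center_track)) center_track$y_nm
          else rep(0, nrow(center_track))
    frame_interval_us <- attr(center_track, "frame_interval_us")
  } else {
    m <- as.matrix(center_track)
    stopifnot(ncol(m) == 2)
    cx <- m[, 1]; cy <- m[, 2]
    frame_interval_us <- NA_real_
  }
  # lab origin at the frame center so tracks centered on 0 stay in view
  ox <- (dim[2] - 1) / 2; oy <- (dim[1] - 1) / 2
  cpx <- cx / pixel_size_nm + ox
  cpy <- cy / pixel_size_nm + oy
  s_px <- psf_sigma_nm / pixel_size_nm
  if (any(cpx < 1 | cpx > dim[2] - 2 | cpy < 1 | cpy > dim[1] - 2))
    stop("track leaves the field of view; enlarge dim")
  set.seed(as.integer(seed))
  xe <- seq_len(dim[2]) - 1  # pixel centers 0..cols-1; edges at +-0.5
  ye <- seq_len(dim[1]) - 1
  frames <- vector("list", length(cpx))
  for (f in seq_along(cpx)) {
    px <- pnorm(xe + 0.5, cpx[f], s_px) - pnorm(xe - 0.5, cpx[f], s_px)
    py <- pnorm(ye + 0.5, cpy[f], s_px) - pnorm(ye - 0.5, cpy[f], s_px)
    lambda <- background + photon_rate * outer(py, px)
    frames[[f]] <- if (poisson)
      matrix(rpois(length(lambda), lambda), nrow = dim[1])
    else lambda
  }
  structure(list(frames = frames, pixel_size_nm = pixel_size_nm,
                 frame_interval_us = frame_interval_us,
                 centers_px = cbind(x = cpx, y = cpy),
                 centers_nm = cbind(x = cpx * pixel_size_nm,
                                    y = cpy * pixel_size_nm)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("Image stack:", length(x$frames), "frames,", d[1], "x", d[2],
      "px at", x$pixel_size_nm, "nm/px\n")
  invisible(x)
}

#' Simulate a fluorescent-ATP intensity trace
#'
#' Baseline-plus-spike renewal process: dark gaps between spikes are
#' exponential with mean `1/event_rate` and spike on-times exponential with
#' mean `on_mean`, emulating single Cy3-ATP turnovers at a myosin head imaged
#' at 1000 fps. Gaussian read noise is added per frame.
#'
#' @param event_rate Spike (ATP binding) rate, s^-1.
#' @param on_mean Mean spike duration, s.
#' @param frame_rate Sampling rate, frames per second (default 1000).
#' @param duration Record length, s.
#' @param spike_amplitude Spike height, counts.
#' @param noise_sd Gaussian noise SD, counts.
#' @param baseline Baseline level, counts.
#' @param seed Integer seed.
#' @return An object of class `fluor_trace`: data frame `t_s`, `intensity`
#'   with attributes `frame_rate`, `events` (true start/end times) and
#'   `overlap_warning` (TRUE when `on_mean >= mean gap`, i.e. spikes merge).
#' @export
simulate_atp_trace <- function(event_rate, on_mean, frame_rate = 1000,
                               duration = 10, spike_amplitude = 100,
                               noise_sd = 5, baseline = 0, seed = 1L) {
  stopifnot(event_rate >= 0, on_mean > 0, frame_rate > 0, duration > 0)
  set.seed(as.integer(seed))
  starts <- numeric(0); ends <- numeric(0)
  t <- 0
  if (event_rate > 0) {
    repeat {
      gap <- rexp(1, event_rate)
      t <- t + gap
      if (t >= duration) break
      on <- rexp(1, 1 / on_mean)
      starts <- c(starts, t); ends <- c(ends, min(t + on, duration))
      t <- t + on
    }
  }
  n <- floor(duration * frame_rate)
  tt <- (seq_len(n) - 0.5) / frame_rate
  intensity <- rep(baseline, n)
  for (i in seq_along(starts)) {
    idx <- tt >= starts[i] & tt < ends[i]
    intensity[idx] <- intensity[idx] + spike_amplitude
  }
  if (noise_sd > 0) intensity <- intensity + rnorm(n, 0, noise_sd)
  overlap <- event_rate > 0 && on_mean >= 1 / event_rate
  if (overlap)
    warning("mean on-time >= mean gap: spikes overlap, waiting times unreliable")
  structure(data.frame(t_s = tt, intensity = intensity),
            frame_rate = frame_rate,
            events = data.frame(t_start = starts, t_end = ends),
            overlap_warning = overlap,
            class = c("fluor_trace", "data.frame"))
}
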