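#' Sub-pixel spot localization by radial symmetry
#'
#' Per-frame center estimate as the point minimizing the summed squared
#' (intensity-weighted) distances to the lines through pixel-block midpoints
#' along the local intensity-gradient direction -- the standard
#' radial-symmetry-center method for isotropic spots. Gradients are taken on
#' the half-pixel midpoint grid from diagonal differences of 2x2 blocks and
#' smoothed 3x3. Non-iterative, so fast enough for 25,000 fps stacks.
#'
#' Frames whose peak contrast `(max - median)` falls below
#' `contrast_min * mad(frame)` are flagged and localized as `NA`.
#'
#' @param stack An `image_stack`.
#' @param contrast_min Contrast threshold in robust-noise units (default 3).
#' @return A `track2d`: data frame `t_us, x_nm, y_nm, ok` with pixel-scale
#'   positions in attribute `xy_px`. Coordinates follow the package pixel
#'   convention (first pixel center at 0,0; nm = px * pixel size).
#' @export
localize_radial_symmetry <- function(stack, contrast_min = 3) {
  stopifnot(inherits(stack, "image_stack"))
  n <- length(stack$frames)
  out <- matrix(NA_real_, n, 2)
  ok <- logical(n)
  for (f in seq_len(n)) {
    I <- stack$frames[[f]]
    ctr <- radial_center(I, contrast_min)
    out[f, ] <- ctr
    ok[f] <- all(is.finite(ctr))
  }
  track2d(out * stack$pixel_size_nm, stack, ok, xy_px = out)
}

# radial-symmetry center of one frame; returns c(x, y) in pixel coords or NA
radial_center <- function(I, contrast_min = 3) {
  noise <- stats::mad(I)
  if (max(I) - stats::median(I) <= contrast_min * max(noise, .Machine$double.eps))
    return(c(NA_real_, NA_real_))
  nr <- nrow(I); nc <- ncol(I)
  # midpoint grid between pixel centers: (nr-1) x (nc-1), at +0.5 offsets
  A <- I[-nr, -nc]; B <- I[-nr, -1]; C <- I[-1, -nc]; D <- I[-1, -1]
  # 45-degree derivatives (u along +x+y, v along +x-y)
  du <- B - C   # I(x+1,y) - I(x,y+1)
  dv <- D - A   # I(x+1,y+1) - I(x,y)
  # 3x3 boxcar smoothing
  sm <- function(M) {
    P <- matrix(0, nrow(M) + 2, ncol(M) + 2)
    P[2:(nrow(M) + 1), 2:(ncol(M) + 1)] <- M
    cnt <- matrix(0, nrow(M) + 2, ncol(M) + 2)
    cnt[2:(nrow(M) + 1), 2:(ncol(M) + 1)] <- 1
    S <- P * 0; Cn <- cnt * 0
    for (di in -1:1) for (dj in -1:1) {
      S <- S + shift_mat(P, di, dj)
      Cn <- Cn + shift_mat(cnt, di, dj)
    }
    (S / pmax(Cn, 1))[2:(nrow(M) + 1), 2:(ncol(M) + 1)]
  }
  du <- sm(du); dv <- sm(dv)
  # rotate 45 deg back to x/y gradient components
  gx <- (du + dv) / sqrt(2)
  gy <- (dv - du) / sqrt(2)
  g2 <- gx^2 + gy^2
  keep <- g2 > 0
  if (!any(keep)) return(c(NA_real_, NA_real_))
  # midpoint coordinates (pixel centers at integers starting from 0)
  xm <- matrix(rep(seq_len(nc - 1) - 0.5, each = nr - 1), nr - 1)
  ym <- matrix(rep(seq_len(nr - 1) - 0.5, nc - 1), nr - 1)
  # line through (xm, ym) with direction (gx, gy): minimize weighted
  # squared perpendicular distance from (xc, yc) to all lines
  m2 <- g2[keep]
  # distance weighting: gradient magnitude over distance to rough centroid
  xc0 <- sum(xm[keep] * m2) / sum(m2); yc0 <- sum(ym[keep] * m2) / sum(m2)
  dcen <- sqrt((xm[keep] - xc0)^2 + (ym[keep] - yc0)^2)
  wgt <- m2 / pmax(dcen, 0.5)
  ux <- gx[keep] / sqrt(m2); uy <- gy[keep] / sqrt(m2)
  # perpendicular distance to line: |( p - m ) x u |; normal n = (-uy, ux)
  nx <- -uy; ny <- ux
  # minimize sum w ((xc - xm) nx + (yc - ym) ny)^2
  Sxx <- sum(wgt * nx * nx); Sxy <- sum(wgt * nx * ny)
  Syy <- sum(wgt * ny * ny)
  bx <- sum(wgt * nx * (nx * xm[keep] + ny * ym[keep]))
  by <- sum(wgt * ny * (nx * xm[keep] + ny * ym[keep]))
  det <- Sxx * Syy - Sxy^2
  if (!is.finite(det) || abs(det) < 1e-12) return(c(NA_real_, NA_real_))
  xc <- (Syy * bx - Sxy * by) / det
  yc <- (Sxx * by - Sxy * bx) / det
  c(xc, yc)
}

shift_mat <- function(M, di, dj) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  ri <- seq_len(nr) - di; ci <- seq_len(nc) - dj
  okr <- ri >= 1 & ri <= nr; okc <- ci >= 1 & ci <= nc
  out[okr, okc] <- M[ri[okr], ci[okc]]
  out
}

track2d <- function(xy_nm, stack, ok, xy_px = NULL, quality = NULL) {
  n <- nrow(xy_nm)
  dt <- stack$frame_interval_us
  t_us <- if (is.finite(dt)) (seq_len(n) - 1) * dt else seq_len(n) - 1
  df <- data.frame(t_us = t_us, x_nm = xy_nm[, 1], y_nm = xy_nm[, 2],
                   ok = ok)
  structure(df, pixel_size_nm = stack$pixel_size_nm, xy_px = xy_px,
            quality = quality,
            frame_interval_us = dt,
            class = c("track2d", "data.frame"))
}

#' @export
print.track2d <- function(x, ...) {
  cat("2D track:", nrow(x), "frames,", sum(!x$ok), "flagged\n")
  invisible(x)
}

#' Refine spot centers by least-squares Gaussian fitting
#'
#' Per-frame nonlinear least-squares fit (Levenberg-Marquardt) of an
#' isotropic 2D Gaussian plus constant background, started from `init`
#' centers (typically the radial-symmetry track). Frames that fail to
#' converge keep the initial value and are flagged.
#'
#' @param stack An `image_stack`.
#' @param init A `track2d` providing starting centers (or `NULL` to start
#'   from [localize_radial_symmetry()]).
#' @param max_iter Maximum LM iterations per frame (default 100).
#' @return A `track2d` with per-frame fitted `sigma_px`, `amplitude`,
#'   `background` in the `quality` attribute.
#' @export
localize_gaussian_refine <- function(stack, init = NULL, max_iter = 100) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(init)) init <- localize_radial_symmetry(stack)
  init_px <- attr(init, "xy_px")
  if (is.null(init_px)) init_px <- cbind(init$x_nm, init$y_nm) / stack$pixel_size_nm
  n <- length(stack$frames)
  out <- matrix(NA_real_, n, 2)
  ok <- logical(n)
  qual <- data.frame(sigma_px = rep(NA_real_, n), amplitude = NA_real_,
                     background = NA_real_)
  nr <- nrow(stack$frames[[1]]); nc <- ncol(stack$frames[[1]])
  xs <- rep(seq_len(nc) - 1, each = nr)
  ys <- rep(seq_len(nr) - 1, nc)
  for (f in seq_len(n)) {
    I <- as.vector(stack$frames[[f]])
    p0 <- c(x = init_px[f, 1], y = init_px[f, 2], logs = log(1.2),
            A = max(I) - stats::median(I), b = stats::median(I))
    if (!all(is.finite(p0)) || p0["A"] <= 0) { out[f, ] <- init_px[f, ]; next }
    resid_fn <- function(p) {
      s <- exp(p[3])
      I - (p[5] + p[4] * exp(-((xs - p[1])^2 + (ys - p[2])^2) / (2 * s^2)))
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9) ||
        !all(is.finite(fit$par))) {
      out[f, ] <- init_px[f, ]
      ok[f] <- FALSE
    } else {
      out[f, ] <- fit$par[1:2]
      ok[f] <- TRUE
      qual$sigma_px[f] <- exp(fit$par[3])
      qual$amplitude[f] <- fit$par[4]
      qual$background[f] <- fit$par[5]
    }
  }
  track2d(out * stack$pixel_size_nm, stack, ok, xy_px = out, quality = qual)
}

#' Screen tracks by span and ellipticity
#'
#' Keeps tracks whose peak-to-peak span along the major axis lies within
#' `span_window * expected_span_nm` and whose major/minor SD ratio is at
#' least `ellipticity_min`; the complex geometry predicts an elongated
#' (~80 nm) excursion along actin, so isotropic or immobile particles are
#' rejected (non-specific surface binders, loose tethers).
#'
#' @param tracks A list of `track2d` objects (a single track is accepted).
#' @param expected_span_nm Expected major-axis peak-to-peak span, nm.
#' @param span_window Multiplicative acceptance window (default
#'   `c(0.5, 1.5)`).
#' @param ellipticity_min Minimum major/minor SD ratio (default 1.5).
#' @return List with `kept` (list of tracks) and `log` (data frame of
#'   per-track decisions and reasons).
#' @export
screen_tracks <- function(tracks, expected_span_nm,
                          span_window = c(0.5, 1.5), ellipticity_min = 1.5) {
  if (inherits(tracks, "track2d")) tracks <- list(tracks)
  res <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    xy <- cbind(tr$x_nm, tr$y_nm)
    xy <- xy[stats::complete.cases(xy), , drop = FALSE]
    if (nrow(xy) < 3)
      return(data.frame(track = i, kept = FALSE, span_nm = NA,
                        ellipticity = NA, reason = "too few frames"))
    ev <- eigen(stats::cov(xy), symmetric = TRUE)
    proj <- (xy - rep(colMeans(xy), each = nrow(xy))) %*% ev$vectors
    span <- diff(range(proj[, 1]))
    ell <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
    reason <- ""
    if (span < span_window[1] * expected_span_nm ||
        span > span_window[2] * expected_span_nm)
      reason <- "span outside window"
    else if (ell < ellipticity_min)
      reason <- "insufficient ellipticity"
    data.frame(track = i, kept = reason == "", span_nm = span,
               ellipticity = ell, reason = reason)
  })
  log <- do.call(rbind, res)
  list(kept = tracks[log$kept], log = log)
}

#' Project a 2D track onto its major axis
#'
#' The principal axis is the leading eigenvector of the 2D position
#' covariance; 1D positions are signed projections onto it, origin at the
#' track centroid. The axis sign is data-driven: the heavier-tailed side
#' (positive sample skewness) is oriented positive, so that strong-binding
#' excursions map to positive displacements; the convention is recorded in
#' the output's `axis` attribute.
#'
#' @param track A `track2d` (flagged frames are dropped).
#' @return A 1D `trajectory`; attribute `axis` holds the unit vector, angle
#'   and sign convention.
#' @export
project_major_axis <- function(track) {
  stopifnot(inherits(track, "track2d"))
  keep <- track$ok & is.finite(track$x_nm) & is.finite(track$y_nm)
  xy <- cbind(track$x_nm, track$y_nm)[keep, , drop = FALSE]
  if (nrow(xy) < 3) stop("need at least 3 localized frames")
  cv <- stats::cov(xy)
  if (max(abs(cv)) < .Machine$double.eps)
    stop("degenerate covariance: all points identical")
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors[, 1]
  centred <- xy - rep(colMeans(xy), each = nrow(xy))
  proj <- as.vector(centred %*% v)
  # orient the binding side positive: bound frames have low local variance
  # (narrow emission), so the signed mean of quiet frames marks the binding
  # direction; fall back to skewness when no quiet excursions exist
  n <- length(proj)
  win <- 5
  if (n >= 2 * win) {
    mat <- stats::embed(proj, win)
    local_sd <- apply(mat, 1, stats::sd)
    quiet <- which(local_sd <= stats::quantile(local_sd, 0.2))
    noisy <- which(local_sd >= stats::quantile(local_sd, 0.5))
    flip <- mean(mat[quiet, ]) < mean(mat[noisy, ])
  } else {
    flip <- FALSE
  }
  sk <- mean(proj^3) / max(stats::sd(proj), .Machine$double.eps)^3
  if (n < 2 * win && is.finite(sk) && sk < 0) flip <- TRUE
  if (flip) { v <- -v; proj <- -proj }
  dt <- attr(track, "frame_interval_us")
  if (!is.finite(dt)) dt <- 1
  tr <- trajectory(t_us = (seq_along(proj) - 1) * dt, x_nm = proj,
                   frame_interval_us = dt)
  attr(tr, "axis") <- list(vector = v,
                           angle_deg = atan2(v[2], v[1]) * 180 / pi,
                           sign_convention = "heavier-tailed side positive",
                           skewness = sk)
  tr
}
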