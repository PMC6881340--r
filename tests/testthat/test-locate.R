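test_that("radial symmetry is exact on a noiseless centered spot", {
  st <- static_spot_stack(center_nm = c(0, 0), n_frames = 1, poisson = FALSE,
                          background = 0)
  tk <- localize_radial_symmetry(st)
  expect_true(tk$ok[1])
  expect_lt(abs(attr(tk, "xy_px")[1, 1] - st$centers_px[1, "x"]), 1e-6)
  expect_lt(abs(attr(tk, "xy_px")[1, 2] - st$centers_px[1, "y"]), 1e-6)
})

test_that("radial symmetry has sub-5% pixel bias on noisy subpixel spots", {
  # spot at (10.30, 7.70) px in a 21x16 frame, Poisson noise
  px <- 123
  cx <- (10.30 - (21 - 1) / 2) * px
  cy <- (7.70 - (16 - 1) / 2) * px
  st <- simulate_spot_stack(matrix(rep(c(cx, cy), each = 400), ncol = 2),
                            pixel_size_nm = px, psf_sigma_nm = 160,
                            photon_rate = 2e4, background = 20,
                            dim = c(16L, 21L), seed = 9)
  expect_equal(unname(st$centers_px[1, ]), c(10.30, 7.70), tolerance = 1e-9)
  tk <- localize_radial_symmetry(st)
  xy <- attr(tk, "xy_px")
  expect_lt(abs(mean(xy[, 1]) - 10.30), 0.05)
  expect_lt(abs(mean(xy[, 2]) - 7.70), 0.05)
  # cross-check against the per-frame least-squares Gaussian fit
  gk <- localize_gaussian_refine(st, tk)
  gxy <- attr(gk, "xy_px")
  expect_lt(mean(abs(gxy[, 1] - xy[, 1])), 0.1)
  expect_lt(mean(abs(gxy[, 2] - xy[, 2])), 0.1)
})

test_that("high-SNR localization reaches sub-nanometre precision", {
  st <- static_spot_stack(center_nm = c(20, -10), n_frames = 150,
                          photon_rate = 1e6, background = 10, seed = 4)
  tk <- localize_radial_symmetry(st)
  expect_lt(sd(tk$x_nm), 0.7)
  expect_lt(sd(tk$y_nm), 0.7)
})

test_that("Gaussian refinement recovers truth and flags failures", {
  st <- static_spot_stack(center_nm = c(30, 40), n_frames = 1,
                          poisson = FALSE, background = 5,
                          photon_rate = 1e4)
  # init deliberately offset by one pixel
  init <- localize_radial_symmetry(st)
  ip <- attr(init, "xy_px")
  ip[1, ] <- ip[1, ] + 1
  attr(init, "xy_px") <- ip
  gk <- localize_gaussian_refine(st, init)
  expect_true(gk$ok[1])
  expect_lt(abs(attr(gk, "xy_px")[1, 1] - st$centers_px[1, "x"]), 1e-4)
  expect_lt(abs(attr(gk, "xy_px")[1, 2] - st$centers_px[1, "y"]), 1e-4)
  q <- attr(gk, "quality")
  # fitted width includes the pixel-integration variance of 1/12 px^2
  expect_equal(q$sigma_px[1], sqrt((160 / 123)^2 + 1 / 12), tolerance = 0.01)
  expect_equal(q$background[1], 5, tolerance = 0.02)
  # flat frame: flagged, init kept
  flat <- st
  flat$frames[[1]][] <- 5
  fk <- localize_gaussian_refine(flat, init)
  expect_false(fk$ok[1])
  expect_equal(attr(fk, "xy_px")[1, ], ip[1, ], tolerance = 1e-9)
  # empty/contrast-less frame flagged by the radial localizer
  rk <- localize_radial_symmetry(flat)
  expect_false(rk$ok[1])
  expect_true(is.na(rk$x_nm[1]))
})

test_that("screening applies the span and ellipticity rules (brute force)", {
  set.seed(21)
  mk <- function(xsd, ysd, n = 400) {
    df <- data.frame(t_us = (seq_len(n) - 1) * 40,
                     x_nm = rnorm(n, 0, xsd), y_nm = rnorm(n, 0, ysd),
                     ok = TRUE)
    structure(df, frame_interval_us = 40,
              class = c("track2d", "data.frame"))
  }
  # isotropic cloud rejected at ellipticity_min 2
  iso <- mk(10, 10)
  out <- screen_tracks(list(iso), expected_span_nm = 60,
                       ellipticity_min = 2)
  expect_length(out$kept, 0)
  expect_match(out$log$reason[1], "ellipticity|span")
  # ~80 nm elongated track kept with defaults
  el <- mk(14, 4)   # span ~ 6 sigma ~ 84 nm
  out2 <- screen_tracks(list(el), expected_span_nm = 80)
  expect_length(out2$kept, 1)
  # mixed batch matches brute-force application of the two rules
  batch <- lapply(1:10, function(i) mk(runif(1, 2, 20), runif(1, 2, 8)))
  res <- screen_tracks(batch, expected_span_nm = 80)
  brute <- vapply(batch, function(tr) {
    xy <- cbind(tr$x_nm, tr$y_nm)
    ev <- eigen(cov(xy), symmetric = TRUE)
    pr <- (xy - rep(colMeans(xy), each = nrow(xy))) %*% ev$vectors
    span <- diff(range(pr[, 1]))
    ell <- sqrt(ev$values[1] / ev$values[2])
    span >= 40 && span <= 120 && ell >= 1.5
  }, logical(1))
  expect_equal(res$log$kept, brute)
  # idempotence: screening the kept set changes nothing
  res2 <- screen_tracks(res$kept, expected_span_nm = 80)
  expect_length(res2$kept, length(res$kept))
  expect_true(all(res2$log$kept))
})

test_that("major-axis projection is an isometry on lines and recovers the axis", {
  # collinear points along 45 degrees
  s <- seq(0, 100, length.out = 50)
  tr <- structure(data.frame(t_us = (seq_along(s) - 1) * 40,
                             x_nm = s / sqrt(2), y_nm = s / sqrt(2),
                             ok = TRUE),
                  frame_interval_us = 40, class = c("track2d", "data.frame"))
  pj <- project_major_axis(tr)
  expect_equal(diff(range(pj$x_nm)), 100, tolerance = 1e-10)
  expect_equal(as.vector(dist(pj$x_nm[1:5])), as.vector(dist(s[1:5])),
               tolerance = 1e-10)
  # anisotropic cloud at a known 30-degree axis: angle within 2 degrees
  set.seed(31)
  n <- 1e4
  a <- 30 * pi / 180
  major <- rnorm(n, 0, 12.5); minor <- rnorm(n, 0, 4)
  x <- major * cos(a) - minor * sin(a)
  y <- major * sin(a) + minor * cos(a)
  tr2 <- structure(data.frame(t_us = (seq_len(n) - 1) * 40, x_nm = x,
                              y_nm = y, ok = TRUE),
                   frame_interval_us = 40, class = c("track2d", "data.frame"))
  pj2 <- project_major_axis(tr2)
  ang <- attr(pj2, "axis")$angle_deg %% 180
  expect_lt(min(abs(ang - 30), abs(ang - 210 %% 180 - 30)), 2)
  # variance ordering and preservation
  cv <- cov(cbind(x, y))
  ev <- eigen(cv, symmetric = TRUE)$values
  expect_gte(var(pj2$x_nm), ev[2])
  centred <- cbind(x - mean(x), y - mean(y))
  minor_proj <- centred %*% c(-attr(pj2, "axis")$vector[2],
                              attr(pj2, "axis")$vector[1])
  expect_equal(var(pj2$x_nm) + as.numeric(var(minor_proj)), sum(diag(cv)),
               tolerance = 1e-10)
  # degenerate covariance errors
  trd <- structure(data.frame(t_us = c(0, 40, 80), x_nm = c(1, 1, 1),
                              y_nm = c(2, 2, 2), ok = TRUE),
                   frame_interval_us = 40, class = c("track2d", "data.frame"))
  expect_error(project_major_axis(trd), "degenerate")
})

test_that("the projected axis orients binding excursions positive", {
  sch <- kinetic_scheme(sites = list(weak_site(22.8, 1, 500)),
                        lateral_sd_nm = 4, duration_us = 8e4)
  tr <- simulate_trajectory(sch, seed = 6)
  tk <- structure(data.frame(t_us = tr$t_us, x_nm = tr$x_nm, y_nm = tr$y_nm,
                             ok = TRUE),
                  frame_interval_us = 40, class = c("track2d", "data.frame"))
  pj <- project_major_axis(tk)
  # bound frames sit on the positive side under the sign convention
  expect_gt(mean(pj$x_nm[tr$label == 1]), mean(pj$x_nm[tr$label == 0]))
})
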