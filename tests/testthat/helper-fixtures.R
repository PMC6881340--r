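# shared fixture builders; everything is generated in code at test time

# four weak sites at experimentally realistic spacings, equal access,
# 100 us dwell: the layout of the detection-accuracy simulation
four_site_scheme <- function(duration_us = 4e5, dwell_us = 100) {
  kinetic_scheme(
    sites = list(weak_site(-12.9, 0.25, dwell_us),
                 weak_site(-1.1, 0.25, dwell_us),
                 weak_site(9.9, 0.25, dwell_us),
                 weak_site(22.8, 0.25, dwell_us)),
    duration_us = duration_us)
}

# the five-peak layout printed for the lever-arm-less head: positions,
# position SDs, access weights and dwells of the binding-position peaks
five_peak_layout <- function() {
  data.frame(position = c(-26.0, -12.9, -1.1, 9.9, 22.8),
             sd = c(0.8, 0.8, 0.7, 0.7, 1.2),
             weight = c(0.014, 0.184, 0.493, 0.245, 0.064),
             dwell_us = c(322, 237, 160, 238, 513))
}

# strong-binding-only scheme for step-size fitting (one site, ATP-limited)
strong_step_scheme <- function(step_nm = 44.0, atp_nM = 2000,
                               duration_us = 4e5) {
  kinetic_scheme(sites = list(weak_site(step_nm, 1, 1000)),
                 strong_site_index = 1, atp_nM = atp_nM,
                 encounter_rate_s = 50, duration_us = duration_us)
}

# small synthetic spot stack with a static center
static_spot_stack <- function(center_nm = c(0, 0), n_frames = 50,
                              photon_rate = 2e4, background = 20,
                              pixel_size_nm = 123, psf_sigma_nm = 160,
                              seed = 1, poisson = TRUE, dim = c(21L, 21L)) {
  centers <- matrix(rep(center_nm, each = n_frames), ncol = 2)
  simulate_spot_stack(centers, pixel_size_nm = pixel_size_nm,
                      psf_sigma_nm = psf_sigma_nm,
                      photon_rate = photon_rate, background = background,
                      dim = dim, seed = seed, poisson = poisson)
}

# brute-force path posterior by enumeration for a pinned, constrained HMM:
# returns named probabilities over all K^T paths (names = collapsed states)
enumerate_path_posterior <- function(emit, Pi, s0 = 1L) {
  T_ <- nrow(emit); K <- ncol(emit)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  grid <- grid[, rev(seq_len(T_)), drop = FALSE]  # frame order
  probs <- apply(grid, 1, function(s) {
    p <- Pi[s0, s[1]] * emit[1, s[1]]
    for (t in 2:T_) p <- p * Pi[s[t - 1], s[t]] * emit[t, s[t]]
    p
  })
  names(probs) <- apply(grid, 1, paste, collapse = "")
  probs / sum(probs)
}

# constrained 3-state transition matrix (1 = detached) used by the pinned
# FFBS instances: binding rows have support {detached, self} only
pinned_instance <- function() {
  Pi <- rbind(c(0.90, 0.05, 0.05),
              c(0.40, 0.60, 0.00),
              c(0.30, 0.00, 0.70))
  mu <- c(0, 30, -30)
  sds <- c(12.5, 4.7, 4.7)
  y <- c(0, 30, 30, 0, -30, -30, 0, 0)
  emit <- vapply(1:3, function(k) dnorm(y, mu[k], sds[k]), numeric(length(y)))
  list(Pi = Pi, emit = emit, y = y)
}
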