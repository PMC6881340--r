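#' Weak-binding site specification
#'
#' One transient actin-binding site seen by a tethered myosin head: its
#' position along the actin axis (relative to the mean detached position),
#' the probability that a binding excursion lands there (access weight), and
#' the mean of its exponential dwell-time distribution.
#'
#' @param position_nm Site position in nm, relative to the detached mean.
#' @param access_weight Probability that an encounter binds this site.
#'   Weights over all sites of a scheme must sum to 1.
#' @param mean_dwell_us Mean weak-binding dwell, microseconds (> 0).
#' @return An object of class `weak_site`.
#' @export
weak_site <- function(position_nm, access_weight, mean_dwell_us) {
  stopifnot(is.finite(position_nm), length(position_nm) == 1L)
  if (!is.finite(access_weight) || access_weight < 0 || access_weight > 1)
    stop("access_weight must lie in [0, 1]")
  if (!is.finite(mean_dwell_us) || mean_dwell_us <= 0)
    stop("mean_dwell_us must be > 0")
  structure(list(position_nm = position_nm,
                 access_weight = access_weight,
                 mean_dwell_us = mean_dwell_us),
            class = "weak_site")
}

#' Kinetic scheme for a tethered myosin head
#'
#' Generative model behind the synthetic trajectories: a Gaussian-emission
#' detached state (tethered diffusion, SD 12.5 nm by default), a set of
#' weak-binding sites with exponential dwells (Gaussian emission, SD 4.7 nm),
#' and optionally one strong-binding site whose dwell is set by the ATP
#' concentration through the linear rate law
#' `rate = rate_slope * atp_nM + rate_intercept` (the ATP waiting time at the
#' site equals the strong-binding dwell at limiting ATP).
#'
#' @param detached_mean_nm Mean detached position, nm.
#' @param detached_sd_nm Emission SD of the detached state, nm (default 12.5).
#' @param bound_sd_nm Shared emission SD of all binding states, nm
#'   (default 4.7).
#' @param sites List of [weak_site()] objects (may be empty). Access weights
#'   must sum to 1 when non-empty.
#' @param strong_site_index Index into `sites` of the site that binds
#'   strongly (its dwell then follows the ATP rate law instead of
#'   `mean_dwell_us`), or `NULL` for weak-only schemes.
#' @param atp_nM ATP concentration in nM (used only with a strong site).
#' @param rate_slope Slope of the ATP-binding rate line, s^-1 nM^-1
#'   (default 0.0038).
#' @param rate_intercept Intercept of the rate line, s^-1 (default 0.17).
#' @param encounter_rate_s Rate (s^-1) at which the diffusing detached head
#'   encounters actin and enters a binding state; the per-frame entry
#'   probability is `encounter_rate_s * frame_interval`. The microscopy
#'   constrains emission SDs and dwells but not this entry kinetics, so it is
#'   a free parameter (default 1000 s^-1, giving a mean detached sojourn of
#'   1 ms and realistic weak-binding occupancy).
#' @param substeps Optional lever-arm substep phases: a data.frame with
#'   columns `displacement_nm` and `mean_latency_us`; after strong binding
#'   the bound mean advances by each displacement after an exponential
#'   latency. Default `NULL` (off; the tracking data resolve a single
#'   apparent step).
#' @param lateral_sd_nm If non-`NULL`, a second lateral coordinate with this
#'   Gaussian SD is generated (to exercise major-axis projection).
#' @param frame_interval_us Sampling interval, microseconds (default 40).
#' @param duration_us Record duration, microseconds (default 4e5, i.e.
#'   10,000 frames at 40 us).
#' @return An object of class `kinetic_scheme`.
#' @seealso [simulate_trajectory()]
#' @export
kinetic_scheme <- function(detached_mean_nm = 0,
                           detached_sd_nm = 12.5,
                           bound_sd_nm = 4.7,
                           sites = list(),
                           strong_site_index = NULL,
                           atp_nM = 2000,
                           rate_slope = 0.0038,
                           rate_intercept = 0.17,
                           encounter_rate_s = 1000,
                           substeps = NULL,
                           lateral_sd_nm = NULL,
                           frame_interval_us = 40,
                           duration_us = 4e5) {
  if (!is.finite(detached_sd_nm) || detached_sd_nm <= 0)
    stop("detached_sd_nm must be > 0")
  if (!is.finite(bound_sd_nm) || bound_sd_nm <= 0)
    stop("bound_sd_nm must be > 0")
  if (!is.finite(frame_interval_us) || frame_interval_us <= 0)
    stop("frame_interval_us must be > 0")
  if (!is.finite(duration_us) || duration_us <= 0)
    stop("duration_us must be > 0")
  if (encounter_rate_s < 0) stop("encounter_rate_s must be >= 0")
  if (length(sites)) {
    if (!all(vapply(sites, inherits, logical(1), "weak_site")))
      stop("sites must be a list of weak_site objects")
    w <- vapply(sites, `[[`, numeric(1), "access_weight")
    if (abs(sum(w) - 1) > 1e-8)
      stop("site access weights must sum to 1 (got ", signif(sum(w), 6), ")")
  }
  if (!is.null(strong_site_index)) {
    if (!length(sites) || strong_site_index < 1 ||
        strong_site_index > length(sites))
      stop("strong_site_index must index an entry of sites")
    if (rate_slope * atp_nM + rate_intercept <= 0)
      stop("strong-binding rate rate_slope*atp_nM + rate_intercept must be > 0")
  }
  if (!is.null(substeps)) {
    stopifnot(is.data.frame(substeps),
              all(c("displacement_nm", "mean_latency_us") %in%
                    names(substeps)),
              all(substeps$mean_latency_us > 0))
  }
  structure(list(detached_mean_nm = detached_mean_nm,
                 detached_sd_nm = detached_sd_nm,
                 bound_sd_nm = bound_sd_nm,
                 sites = sites,
                 strong_site_index = strong_site_index,
                 atp_nM = atp_nM,
                 rate_slope = rate_slope,
                 rate_intercept = rate_intercept,
                 encounter_rate_s = encounter_rate_s,
                 substeps = substeps,
                 lateral_sd_nm = lateral_sd_nm,
                 frame_interval_us = frame_interval_us,
                 duration_us = duration_us),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  n_frames <- floor(x$duration_us / x$frame_interval_us)
  cat("Kinetic scheme:", length(x$sites), "binding site(s),",
      n_frames, "frames at", x$frame_interval_us, "us\n")
  cat("  detached: mean", x$detached_mean_nm, "nm, SD", x$detached_sd_nm,
      "nm; bound SD", x$bound_sd_nm, "nm\n")
  if (length(x$sites)) {
    for (i in seq_along(x$sites)) {
      s <- x$sites[[i]]
      strong <- !is.null(x$strong_site_index) && i == x$strong_site_index
      cat(sprintf("  site %d: %+.1f nm, weight %.3f, %s\n", i, s$position_nm,
                  s$access_weight,
                  if (strong)
                    sprintf("strong (ATP %g nM -> dwell %.1f ms)", x$atp_nM,
                            1e3 / (x$rate_slope * x$atp_nM + x$rate_intercept))
                  else sprintf("dwell %g us", s$mean_dwell_us)))
    }
  }
  invisible(x)
}

#' Read a kinetic scheme from a JSON or YAML config file
#'
#' The config mirrors the [kinetic_scheme()] argument names; `sites` is a
#' list of objects with `position_nm`, `access_weight`, `mean_dwell_us`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `kinetic_scheme`.
#' @export
read_scheme <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$sites)) {
    sites <- cfg$sites
    if (is.data.frame(sites)) sites <- split(sites, seq_len(nrow(sites)))
    cfg$sites <- lapply(sites, function(s)
      weak_site(s$position_nm, s$access_weight, s$mean_dwell_us))
  }
  do.call(kinetic_scheme, cfg)
}
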