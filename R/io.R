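#' Write / read trajectory tables
#'
#' Plain-text interchange for trajectories: columns `t_us, x_nm[, y_nm][,
#' label]` with a header line, comma- or tab-separated by file extension.
#'
#' @param traj A `trajectory`.
#' @param path Output path (`.csv` or `.tsv`).
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(traj), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("t_us", "x_nm") %in% names(df)))
    stop("trajectory file must have columns t_us, x_nm")
  trajectory(df$t_us, df$x_nm,
             y_nm = if ("y_nm" %in% names(df)) df$y_nm,
             label = if ("label" %in% names(df)) df$label)
}

#' Write / read image stacks as multi-page TIFF with a JSON sidecar
#'
#' Frames are written as 16-bit unsigned TIFF pages; a sidecar JSON
#' (`<path>.json`) records `pixel_size_nm`, `frame_interval_us` and, when
#' available, the true spot centers for oracle use.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `write_stack` returns `path` invisibly; `read_stack` returns an
#'   `image_stack`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- max(1, vapply(stack$frames, max, numeric(1)))
  scale <- if (mx > 65535) 65535 / mx else 1
  pages <- lapply(stack$frames, function(f) round(f * scale) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(pixel_size_nm = stack$pixel_size_nm,
               frame_interval_us = stack$frame_interval_us,
               intensity_scale = scale)
  if (!is.null(stack$centers_px))
    side$centers_px <- unname(as.data.frame(stack$centers_px))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else list(pixel_size_nm = NA_real_, frame_interval_us = NA_real_,
                    intensity_scale = 1)
  frames <- lapply(pages, function(p) p / side$intensity_scale)
  centers <- if (!is.null(side$centers_px)) {
    m <- as.matrix(side$centers_px); colnames(m) <- c("x", "y"); m
  }
  structure(list(frames = frames, pixel_size_nm = side$pixel_size_nm,
                 frame_interval_us = side$frame_interval_us,
                 centers_px = centers),
            class = "image_stack")
}

#' Write / read fluorescence traces
#'
#' CSV with columns `t_s, intensity`.
#'
#' @param trace A `fluor_trace`.
#' @param path Output path.
#' @return `write_trace` returns `path` invisibly; `read_trace` a
#'   `fluor_trace`.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[c("t_s", "intensity")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("t_s", "intensity") %in% names(df)))
  fr <- if (nrow(df) > 1) 1 / mean(diff(df$t_s)) else NA_real_
  structure(df[c("t_s", "intensity")], frame_rate = fr,
            class = c("fluor_trace", "data.frame"))
}

#' Write pooled inference results as TSV
#'
#' One row per retained binding state per chain:
#' `chain, state, relative_position_nm, occupancy, n_events, mean_dwell_us`.
#'
#' @param results List of `ihmm_fit` objects (see [run_repeated()]).
#' @param path Output path; `NULL` returns the data frame only.
#' @return The pooled data frame, invisibly when written.
#' @export
write_pooled <- function(results, path = NULL) {
  df <- pooled_states(results)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(df))
  }
  df
}
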