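#' Read and write per-cell mRNA count tables
#'
#' CSV layout: `cell_id, dose_uM, clone, mrna_count`.
#'
#' @param table counts data frame (e.g. from [simulate_dose_series()]).
#' @param path file path.
#' @return `read_counts_csv` returns the counts data frame.
#' @export
write_counts_csv <- function(table, path) {
  stopifnot(all(c("cell_id", "dose_uM", "clone", "mrna_count") %in%
                  names(table)))
  write.csv(table[c("cell_id", "dose_uM", "clone", "mrna_count")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_csv
#' @export
read_counts_csv <- function(path) {
  out <- read.csv(path)
  stopifnot(all(c("cell_id", "dose_uM", "clone", "mrna_count") %in%
                  names(out)))
  out
}

#' Read and write transcription-site trace tables
#'
#' Long CSV layout: `trace_id, time_min, intensity` and optionally
#' `true_state`.
#'
#' @param traces list of `intensity_trace` objects.
#' @param path file path.
#' @param frame_interval frame spacing used to rebuild `trace_config`s on
#'   read (inferred from the time stamps by default).
#' @return `read_traces_csv` returns a named list of `intensity_trace`s.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "intensity_trace")) traces <- list(trace_1 = traces)
  if (is.null(names(traces)))
    names(traces) <- paste0("trace_", seq_along(traces))
  rows <- lapply(names(traces), function(id) {
    tr <- traces[[id]]
    df <- data.frame(trace_id = id, time_min = tr$time_min,
                     intensity = tr$intensity)
    if (!is.null(tr$true_state)) df$true_state <- tr$true_state
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path, frame_interval = NULL) {
  df <- read.csv(path)
  stopifnot(all(c("trace_id", "time_min", "intensity") %in% names(df)))
  out <- lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time_min), ]
    dt <- if (is.null(frame_interval)) min(diff(d$time_min))
          else frame_interval
    cfg <- trace_config(frame_interval = dt, duration = max(d$time_min),
                        nascent_dwell = 5, noise_sd = 0, mode = "steady")
    structure(list(time_min = d$time_min, intensity = d$intensity,
                   true_state = if ("true_state" %in% names(d))
                     as.integer(d$true_state) else NULL,
                   dwells = NULL, cfg = cfg),
              class = "intensity_trace")
  })
  out[unique(df$trace_id)]
}

#' Write a dwell table extracted from decoded traces
#'
#' CSV layout: `trace_id, state, duration_min, censored`.
#'
#' @param dwell_sets named list of `dwell_set`s (one per trace).
#' @param path file path.
#' @export
write_dwells_csv <- function(dwell_sets, path) {
  if (is.null(names(dwell_sets)))
    names(dwell_sets) <- paste0("trace_", seq_along(dwell_sets))
  rows <- lapply(names(dwell_sets), function(id)
    cbind(trace_id = id, as.data.frame(dwell_sets[[id]])))
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read and write synthetic spot fields as TIFF + JSON truth sidecar
#'
#' The image is stored as a single-plane 32-bit float grayscale TIFF scaled
#' to `[0, 1]` (the scale factor lives in the sidecar); ground-truth spots
#' and painted regions go to `<path>.json`.
#'
#' @param field a `spot_field` from [render_image()].
#' @param path TIFF path; sidecar written next to it.
#' @return `read_spot_field_tiff` returns a `spot_field`.
#' @export
write_spot_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "spot_field"))
  mn <- min(field$image)
  mx <- max(max(field$image) - mn, 1e-12)
  tiff::writeTIFF((field$image - mn) / mx, path, bits.per.sample = 32L)
  sidecar <- list(scale = mx, offset = mn, psf_sigma = field$psf_sigma,
                  background = field$background, spots = field$spots,
                  nuclei = field$nuclei, cells = field$cells)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spot_field_tiff
#' @export
read_spot_field_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(image = img * side$scale + side$offset,
                 spots = as.data.frame(side$spots),
                 nuclei = if (is.null(side$nuclei)) NULL
                          else as.data.frame(side$nuclei),
                 cells = if (is.null(side$cells)) NULL
                         else as.data.frame(side$cells),
                 psf_sigma = side$psf_sigma, background = side$background),
            class = "spot_field")
}
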