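#' Dose-to-activation map for a frequency-modulated dose series
#'
#' Under frequency modulation the only dose-dependent rate is the activation
#' rate: `a(dose) = k * dose`. Together with the shared inactivation rate
#' this fixes the half-maximal dose at `EC50 = b / k`.
#'
#' @param doses ligand concentrations (uM), strictly positive and increasing.
#' @param activation_scale constant `k` (1/(min uM)), `> 0`.
#' @return An object of class `dose_map`.
#' @export
#' @examples
#' dose_map(c(1.56, 3.125, 6.25, 12.5, 25, 50), activation_scale = 1.5 / 9.6)
dose_map <- function(doses, activation_scale) {
  stopifnot(is.numeric(doses), length(doses) >= 1L,
            length(activation_scale) == 1L)
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly positive and increasing")
  if (activation_scale <= 0) stop("activation_scale must be > 0")
  structure(list(doses = doses, activation_scale = activation_scale),
            class = "dose_map")
}

#' Configuration of a transcription-site trace simulation
#'
#' @param frame_interval minutes between frames (`> 0`).
#' @param duration total imaging time in minutes (`>= frame_interval`).
#' @param nascent_dwell minutes a nascent transcript persists at the site
#'   after initiation (elongation + release); each initiation contributes one
#'   intensity unit for this long.
#' @param noise_sd standard deviation of additive Gaussian measurement noise
#'   on the frame intensity (`>= 0`).
#' @param mode `"steady"` (stationary promoter), `"induction"` (starts
#'   inactive at t = 0), `"pulse"` (starts active once, never re-activates),
#'   or `"always_on"` (never inactivates).
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(frame_interval = 15, duration = 900,
                         nascent_dwell = 5, noise_sd = 0,
                         mode = c("steady", "induction", "pulse", "always_on")) {
  mode <- match.arg(mode)
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (duration < frame_interval) stop("duration must be >= frame_interval")
  if (nascent_dwell <= 0) stop("nascent_dwell must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(frame_interval = frame_interval, duration = duration,
                 nascent_dwell = nascent_dwell, noise_sd = noise_sd,
                 mode = mode), class = "trace_config")
}

#' Simulate per-cell mRNA counts from the telegraph model
#'
#' Exact Gillespie simulation of promoter switching, initiation and decay.
#' In `"steady"` mode each cell starts inactive with zero transcripts and is
#' evolved for `burn_factor / min(positive rates)` time units before its
#' count is read out, which relaxes the chain to stationarity; the empirical
#' distribution is an independent check of [telegraph_pmf()]. A numeric
#' `horizon` gives the transient count at that time after induction
#' (inactive, 0 mRNA at t = 0).
#'
#' @param params a [telegraph_params()]; a [normalized_params()] is taken at
#'   unit decay rate (time then in units of the mRNA lifetime).
#' @param n_cells number of cells (`> 0`).
#' @param horizon `"steady"` or a time in the units of `params`.
#' @param seed integer seed; every cell is drawn from this one stream.
#' @param burn_factor burn-in multiplier for steady mode (default 20 mean
#'   lifetimes of the slowest process).
#' @return Integer vector of `n_cells` non-negative counts.
#' @export
#' @examples
#' x <- simulate_counts(normalized_params(1.5, 1.5, 340), 200, seed = 1)
#' mean(x)  # ~ 170 = 340 * 0.5
simulate_counts <- function(params, n_cells, horizon = "steady", seed = 1L,
                            burn_factor = 20) {
  if (inherits(params, "normalized_params"))
    params <- telegraph_params(params$alpha, params$beta, params$gamma, 1)
  stopifnot(inherits(params, "telegraph_params"))
  n_cells <- as.integer(n_cells)
  if (is.na(n_cells) || n_cells <= 0) stop("n_cells must be a positive integer")
  steady <- identical(horizon, "steady")
  if (steady && params$d <= 0) stop("steady-state sampling requires d > 0")
  set.seed(as.integer(seed))
  if (steady) {
    if (params$a == 0 || params$c == 0)        # never activates / never fires
      return(integer(n_cells))
    rates <- c(params$a, params$b, params$d)
    t_end <- burn_factor / min(rates[rates > 0])
  } else {
    t_end <- as.numeric(horizon)
    if (!is.finite(t_end) || t_end < 0) stop("horizon must be >= 0 or 'steady'")
  }
  sim_counts_cpp(params$a, params$b, params$c, params$d, n_cells, t_end)
}

#' Simulate a transcription-site intensity trace
#'
#' Exact Gillespie trajectory of the promoter state and its initiation
#' events; the site intensity at each frame is the number of initiation
#' events inside the trailing `nascent_dwell` window (each nascent transcript
#' contributes one unit while it persists) plus Gaussian noise. The hidden
#' promoter state at frame times and the exact dwell intervals are returned
#' for oracle testing.
#'
#' @param params a [telegraph_params()] or [normalized_params()]; only `a`,
#'   `b`, `c` are used (mature mRNA is not imaged).
#' @param cfg a [trace_config()].
#' @param seed integer seed.
#' @return An object of class `intensity_trace`: list with `time_min`,
#'   `intensity`, `true_state` (0/1 at frame times), `dwells` (data frame of
#'   exact state intervals with censoring flags), `cfg`.
#' @export
simulate_trace <- function(params, cfg, seed = 1L) {
  if (inherits(params, "normalized_params"))
    params <- telegraph_params(params$alpha, params$beta, params$gamma, 1)
  stopifnot(inherits(params, "telegraph_params"), inherits(cfg, "trace_config"))
  set.seed(as.integer(seed))
  tr <- simulate_trace_stream(params, cfg)
  tr
}

# internal: one trace consuming the current RNG stream (no set.seed)
simulate_trace_stream <- function(params, cfg) {
  a <- params$a; b <- params$b; c <- params$c
  start <- switch(cfg$mode,
                  steady = if (a + b > 0) rbinom(1L, 1L, a / (a + b)) else 0L,
                  induction = 0L,
                  pulse = 1L,
                  always_on = 1L)
  if (cfg$mode == "pulse") a <- 0
  if (cfg$mode == "always_on") b <- 0
  ev <- sim_trace_cpp(a, b, c, as.integer(start), cfg$duration)
  frames <- seq(cfg$frame_interval, cfg$duration, by = cfg$frame_interval)
  inits <- ev$inits
  intensity <- findInterval(frames, inits) -
    findInterval(frames - cfg$nascent_dwell, inits)
  if (cfg$noise_sd > 0)
    intensity <- intensity + rnorm(length(frames), 0, cfg$noise_sd)
  nflip <- findInterval(frames, ev$flips)
  state <- (start + nflip) %% 2L
  bounds <- c(0, ev$flips, cfg$duration)
  durs <- diff(bounds)
  k <- length(durs)
  dstate <- (start + seq_len(k) - 1L) %% 2L
  keep <- durs > 0
  dwells <- data.frame(state = ifelse(dstate[keep] == 1L, "on", "off"),
                       duration_min = durs[keep],
                       censored = seq_len(sum(keep)) %in% c(1L, sum(keep)))
  structure(list(time_min = frames, intensity = as.numeric(intensity),
                 true_state = as.integer(state), dwells = dwells, cfg = cfg),
            class = "intensity_trace")
}

#' Simulate a batch of traces from one seed
#'
#' @inheritParams simulate_trace
#' @param n_traces number of traces.
#' @return List of `intensity_trace` objects, names `trace_1` ...
#' @export
simulate_traces <- function(params, cfg, n_traces, seed = 1L) {
  if (inherits(params, "normalized_params"))
    params <- telegraph_params(params$alpha, params$beta, params$gamma, 1)
  stopifnot(n_traces >= 1)
  set.seed(as.integer(seed))
  out <- vector("list", n_traces)
  for (i in seq_len(n_traces)) out[[i]] <- simulate_trace_stream(params, cfg)
  names(out) <- paste0("trace_", seq_len(n_traces))
  out
}

#' Simulate a steady-state dose series of mRNA counts
#'
#' One population of cells per dose with activation rate `a = k * dose` and
#' the inactivation, initiation and decay rates shared across doses — the
#' frequency-modulation scenario. Generative truth is attached for
#' parameter-recovery testing.
#'
#' @param params_template a [telegraph_params()] or [normalized_params()]
#'   supplying the shared `b`, `c`, `d` (its `a` is ignored).
#' @param dosemap a [dose_map()].
#' @param n_cells_per_dose cells per dose.
#' @param seed integer seed.
#' @param clone label recorded in the `clone` column.
#' @return Data frame with columns `cell_id`, `dose_uM`, `clone`,
#'   `mrna_count`; attribute `"truth"` holds the per-dose generative
#'   parameters.
#' @export
simulate_dose_series <- function(params_template, dosemap, n_cells_per_dose,
                                 seed = 1L, clone = "sim") {
  if (inherits(params_template, "normalized_params"))
    params_template <- telegraph_params(params_template$alpha,
                                        params_template$beta,
                                        params_template$gamma, 1)
  stopifnot(inherits(params_template, "telegraph_params"),
            inherits(dosemap, "dose_map"))
  seed <- as.integer(seed)
  groups <- vector("list", length(dosemap$doses))
  truth <- vector("list", length(dosemap$doses))
  for (i in seq_along(dosemap$doses)) {
    dose <- dosemap$doses[i]
    p <- telegraph_params(dosemap$activation_scale * dose,
                          params_template$b, params_template$c,
                          params_template$d)
    cnt <- simulate_counts(p, n_cells_per_dose, horizon = "steady",
                           seed = seed + i - 1L)
    groups[[i]] <- data.frame(
      cell_id = sprintf("d%02d_c%04d", i, seq_along(cnt)),
      dose_uM = dose, clone = clone, mrna_count = cnt)
    truth[[i]] <- p
  }
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  attr(out, "dosemap") <- dosemap
  out
}

#' Render a synthetic single-molecule fluorescence image
#'
#' Draws diffraction-limited spots as 2-D Gaussians of fixed PSF width over a
#' flat background, optionally paints elliptical nucleus/cell regions so that
#' segmentation is testable, and applies a camera noise model (Poisson shot
#' noise on the expected photon image plus Gaussian read noise). Ground truth
#' is retained in the returned object.
#'
#' Coordinate convention (used throughout the package): positions are
#' 0-based `(x, y)` with `x` the column and `y` the row, and spot centers
#' measured at pixel centers, so the pixel `image[r, c]` (1-based R indexing)
#' is centered at `x = c - 1`, `y = r - 1`.
#'
#' @param truth_spots data frame with columns `x`, `y`, `amplitude` (peak
#'   height above local background); may have zero rows.
#' @param shape image size `c(rows, cols)`, each `>= 16`.
#' @param psf_sigma Gaussian PSF standard deviation in pixels (`> 0`).
#' @param background constant background level.
#' @param poisson_noise apply Poisson shot noise to the expected image.
#' @param read_noise_sd Gaussian read-noise standard deviation.
#' @param nuclei,cells optional data frames of ellipses (`cx`, `cy`, `rx`,
#'   `ry`, `level`) added to the background before spots; `cells` are
#'   typically larger and dimmer than `nuclei`.
#' @param seed integer seed (used only when noise is on).
#' @return An object of class `spot_field`: list with `image` (matrix),
#'   `spots`, `nuclei`, `cells`, `psf_sigma`, `background`.
#' @export
render_image <- function(truth_spots, shape = c(128L, 128L), psf_sigma = 1.3,
                         background = 10, poisson_noise = TRUE,
                         read_noise_sd = 1, nuclei = NULL, cells = NULL,
                         seed = 1L) {
  stopifnot(length(shape) == 2L, all(shape >= 16L), psf_sigma > 0)
  if (is.null(truth_spots))
    truth_spots <- data.frame(x = numeric(), y = numeric(),
                              amplitude = numeric())
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (nrow(truth_spots) > 0 &&
      (any(truth_spots$x < 0) || any(truth_spots$x > nc - 1) ||
       any(truth_spots$y < 0) || any(truth_spots$y > nr - 1)))
    stop("spot outside image bounds")
  img <- matrix(background, nr, nc)
  paint_ellipses <- function(img, ell) {
    if (is.null(ell) || nrow(ell) == 0) return(img)
    xs <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
    ys <- matrix(0:(nr - 1), nr, nc)
    for (i in seq_len(nrow(ell))) {
      inside <- ((xs - ell$cx[i]) / ell$rx[i])^2 +
                ((ys - ell$cy[i]) / ell$ry[i])^2 <= 1
      img[inside] <- img[inside] + ell$level[i]
    }
    img
  }
  img <- paint_ellipses(img, cells)
  img <- paint_ellipses(img, nuclei)
  if (!is.null(cells) || !is.null(nuclei)) {
    # diffuse staining: soften region boundaries so they do not masquerade
    # as diffraction-limited structure
    img <- sep_convolve(img, gauss_kernel(2 * psf_sigma))
  }
  w <- ceiling(5 * psf_sigma)
  for (i in seq_len(nrow(truth_spots))) {
    x0 <- truth_spots$x[i]; y0 <- truth_spots$y[i]
    rows <- max(0, floor(y0) - w):min(nr - 1, ceiling(y0) + w)
    cols <- max(0, floor(x0) - w):min(nc - 1, ceiling(x0) + w)
    g <- truth_spots$amplitude[i] *
      exp(-outer((rows - y0)^2, (cols - x0)^2, "+") / (2 * psf_sigma^2))
    img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] + g
  }
  if (poisson_noise || read_noise_sd > 0) {
    set.seed(as.integer(seed))
    if (poisson_noise) img[] <- rpois(length(img), pmax(img, 0))
    if (read_noise_sd > 0)
      img[] <- img + rnorm(length(img), 0, read_noise_sd)
  }
  structure(list(image = img, spots = truth_spots, nuclei = nuclei,
                 cells = cells, psf_sigma = psf_sigma,
                 background = background),
            class = "spot_field")
}
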