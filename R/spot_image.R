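#' Segment nuclei and cells in a fluorescence image
#'
#' Nuclei: intensity threshold (Otsu by default, manual override supported)
#' on the image, hole filling, connected-component labeling, an area filter,
#' and removal of nuclei touching the image border. Cells: a lower
#' intensity threshold defines the cell mask, which is partitioned among
#' the nucleus seeds by watershed-style seeded region growing
#' (`EBImage::propagate`), so every cell label contains its nucleus.
#'
#' @param field a `spot_field` (from [render_image()]) or image matrix.
#' @param nucleus_threshold `"otsu"` or a numeric threshold on raw intensity.
#' @param cell_threshold threshold for the cell mask; default halfway
#'   between background and the nucleus threshold.
#' @param min_area,max_area nucleus area filter in pixels.
#' @param border_policy `"remove"` (drop border-touching nuclei, the
#'   default) or `"keep"`.
#' @return An object of class `segmentation_masks`: list with integer label
#'   matrices `nuclei` and `cells` (0 = background, labels contiguous), and
#'   `empty` flag set when no nucleus survives filtering.
#' @export
segment <- function(field, nucleus_threshold = "otsu", cell_threshold = NULL,
                    min_area = 50, max_area = Inf,
                    border_policy = c("remove", "keep")) {
  border_policy <- match.arg(border_policy)
  img <- if (inherits(field, "spot_field")) field$image else field
  stopifnot(is.matrix(img), all(dim(img) >= 16L), all(is.finite(img)))
  # winsorize before Otsu so isolated bright puncta (transcription sites,
  # single molecules) cannot drag the nucleus threshold above the nuclei
  wimg <- pmin(img, quantile(img, 0.995))
  rng <- range(wimg)
  scaled <- if (diff(rng) > 0) (wimg - rng[1]) / diff(rng) else wimg * 0
  thr <- if (identical(nucleus_threshold, "otsu")) {
    rng[1] + EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * diff(rng)
  } else as.numeric(nucleus_threshold)

  mask <- EBImage::fillHull(EBImage::Image(img > thr))
  lab <- EBImage::bwlabel(mask)
  labm <- EBImage::imageData(lab)
  if (max(labm) > 0) {
    areas <- tabulate(labm[labm > 0], nbins = max(labm))
    drop <- which(areas < min_area | areas > max_area)
    if (border_policy == "remove") {
      border_labels <- unique(c(labm[1, ], labm[nrow(labm), ],
                                labm[, 1], labm[, ncol(labm)]))
      drop <- union(drop, setdiff(border_labels, 0))
    }
    if (length(drop)) labm[labm %in% drop] <- 0L
    # relabel contiguously
    keep <- sort(setdiff(unique(as.integer(labm)), 0L))
    relab <- integer(max(labm, 1L))
    relab[keep] <- seq_along(keep)
    labm[labm > 0] <- relab[labm[labm > 0]]
  }
  nuclei <- matrix(as.integer(labm), nrow(img), ncol(img))
  empty <- max(nuclei) == 0L
  if (empty)
    warning("no nuclei found after filtering; returning empty masks")

  if (is.null(cell_threshold)) {
    # cytoplasm is dimmer than nuclei: split the sub-nuclear-threshold
    # pixels (background vs cell body) with a second Otsu pass
    sub <- img[img < thr]
    rs <- if (length(sub)) range(sub) else c(thr, thr)
    cell_threshold <- if (diff(rs) > 0)
      rs[1] + EBImage::otsu(EBImage::Image(matrix((sub - rs[1]) / diff(rs))),
                            range = c(0, 1)) * diff(rs)
    else thr
  }
  cellmask <- img > cell_threshold
  cells <- if (empty) nuclei * 0L else {
    seeds <- EBImage::Image(nuclei)
    grown <- EBImage::propagate(EBImage::Image(scaled), seeds,
                                mask = cellmask | (nuclei > 0))
    cm <- matrix(as.integer(EBImage::imageData(grown)), nrow(img), ncol(img))
    cm[nuclei > 0] <- nuclei[nuclei > 0]
    cm
  }
  structure(list(nuclei = nuclei, cells = cells, threshold = thr,
                 empty = empty), class = "segmentation_masks")
}

#' Localize diffraction-limited spots with an iterative Gaussian mask
#'
#' Candidate detection by a difference-of-Gaussians band-pass filter and
#' strict 8-neighbor local maxima above a robust threshold; each candidate
#' is then refined to sub-pixel precision by the iterative Gaussian-mask
#' centroid (fixed PSF width): pixel intensities above a local background
#' are weighted by a Gaussian centered on the current estimate and the
#' center updated until the shift is `< 1e-3` px. The integrated intensity
#' is the least-squares Gaussian amplitude times `2 pi sigma^2`. Duplicates
#' within 1 px are merged (brightest kept).
#'
#' @param field a `spot_field` or image matrix.
#' @param detect_sigma PSF standard deviation in pixels (`> 0`).
#' @param threshold `"auto"` (median + 6 MAD of the band-passed image) or a
#'   numeric cutoff on the band-passed image.
#' @param max_iters refinement iteration cap.
#' @param min_snr discard refined spots whose fitted peak amplitude falls
#'   below this multiple of the local noise (MAD of the fit window's border
#'   pixels); rejects shot-noise peaks inside bright regions that pass the
#'   global band-pass threshold.
#' @return Data frame with one row per spot: `x`, `y` (0-based sub-pixel
#'   center, x = column), `intensity` (integrated, above background),
#'   `background`, `snr` (peak amplitude over local noise).
#' @export
localize_spots <- function(field, detect_sigma = 1.3, threshold = "auto",
                           max_iters = 50, min_snr = 2) {
  img <- if (inherits(field, "spot_field")) field$image else field
  stopifnot(is.matrix(img), detect_sigma > 0)
  blur <- function(m, s) {
    k <- gauss_kernel(s)
    sep_convolve(m, k)
  }
  dog <- blur(img, detect_sigma) - blur(img, 1.6 * detect_sigma)
  thr <- if (identical(threshold, "auto")) {
    floorv <- 1e-6 * max(abs(img), 1)
    median(dog) + max(6 * mad(dog), floorv)
  } else as.numeric(threshold)

  nr <- nrow(img); nc <- ncol(img)
  cand <- which(dog > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > 1 & cand[, 1] < nr &
               cand[, 2] > 1 & cand[, 2] < nc, , drop = FALSE]
  if (nrow(cand) > 0) {
    ismax <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; cc <- cand[i, 2]
      v <- dog[r, cc]
      nb <- dog[(r - 1):(r + 1), (cc - 1):(cc + 1)]
      v >= max(nb) && sum(nb == v) == 1L
    }, TRUE)
    cand <- cand[ismax, , drop = FALSE]
  }
  if (nrow(cand) == 0L)
    return(data.frame(x = numeric(), y = numeric(), intensity = numeric(),
                      background = numeric()))

  sig <- detect_sigma
  w <- ceiling(4 * sig)
  spots <- lapply(seq_len(nrow(cand)), function(i) {
    y0 <- cand[i, 1] - 1; x0 <- cand[i, 2] - 1      # 0-based
    for (it in seq_len(max_iters)) {
      rows <- max(0, round(y0) - w):min(nr - 1, round(y0) + w)
      cols <- max(0, round(x0) - w):min(nc - 1, round(x0) + w)
      sub <- img[rows + 1, cols + 1, drop = FALSE]
      edge <- c(sub[1, ], sub[nrow(sub), ], sub[, 1], sub[, ncol(sub)])
      bg <- median(edge)
      I <- sub - bg
      gy <- exp(-(rows - y0)^2 / (2 * sig^2))
      gx <- exp(-(cols - x0)^2 / (2 * sig^2))
      M <- outer(gy, gx)
      wI <- M * I
      tot <- sum(wI)
      if (tot <= 0) break
      xn <- sum(t(t(wI) * cols)) / tot
      yn <- sum(wI * rows) / tot
      if (!is.finite(xn) || !is.finite(yn)) break
      shift <- sqrt((xn - x0)^2 + (yn - y0)^2)
      x0 <- min(max(xn, 0), nc - 1); y0 <- min(max(yn, 0), nr - 1)
      if (shift < 1e-3) break
    }
    rows <- max(0, round(y0) - w):min(nr - 1, round(y0) + w)
    cols <- max(0, round(x0) - w):min(nc - 1, round(x0) + w)
    sub <- img[rows + 1, cols + 1, drop = FALSE]
    edge <- c(sub[1, ], sub[nrow(sub), ], sub[, 1], sub[, ncol(sub)])
    bg <- median(edge)
    I <- sub - bg
    M <- outer(exp(-(rows - y0)^2 / (2 * sig^2)),
               exp(-(cols - x0)^2 / (2 * sig^2)))
    A <- sum(M * I) / sum(M * M)                     # LS Gaussian amplitude
    sd_local <- max(mad(edge), .Machine$double.eps)  # local noise floor
    c(x = x0, y = y0, intensity = A * 2 * pi * sig^2, background = bg,
      snr = A / sd_local)
  })
  out <- as.data.frame(do.call(rbind, spots))
  out <- out[is.finite(out$intensity) & out$intensity > 0 &
             out$snr >= min_snr &
             out$x >= 0 & out$x <= nc - 1 & out$y >= 0 & out$y <= nr - 1, ,
             drop = FALSE]
  # merge duplicates within 1 px, keeping the brighter
  if (nrow(out) > 1) {
    o <- order(-out$intensity)
    out <- out[o, ]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      if (i < nrow(out)) {
        j <- (i + 1):nrow(out)
        d2 <- (out$x[j] - out$x[i])^2 + (out$y[j] - out$y[i])^2
        keep[j[d2 < 1]] <- FALSE
      }
    }
    out <- out[keep, ]
  }
  rownames(out) <- NULL
  out
}

gauss_kernel <- function(sigma) {
  w <- ceiling(4 * sigma)
  k <- exp(-(-w:w)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 2-D convolution with replicated edges
sep_convolve <- function(m, k) {
  w <- (length(k) - 1L) / 2L
  pad_apply <- function(mm) {
    n <- nrow(mm)
    padded <- rbind(mm[rep(1L, w), , drop = FALSE], mm,
                    mm[rep(n, w), , drop = FALSE])
    out <- matrix(0, n, ncol(mm))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1L), , drop = FALSE]
    out
  }
  t(pad_apply(t(pad_apply(m))))
}

#' Assign spots to cells, count mRNA, and call transcription sites
#'
#' Each spot is assigned to the cell whose label contains its (rounded)
#' center; spots outside every cell get label 0 and are excluded from
#' counts. A transcription site (TS) is a nuclear spot whose integrated
#' intensity is at least `ts_rule` times the median single-spot intensity
#' of the field. Per-cell counts are returned in the copy-number table
#' layout consumed by [fit_counts()].
#'
#' @param spots data frame from [localize_spots()].
#' @param masks a `segmentation_masks` from [segment()].
#' @param ts_rule TS intensity multiple of the median spot (default 2).
#' @param count_ts_units when `TRUE`, a TS adds
#'   `round(intensity / median spot intensity)` mRNA equivalents to its
#'   cell's count instead of 1.
#' @param min_intensity_frac drop detections dimmer than this fraction of
#'   the median spot intensity before counting (0 disables).
#' @param dose_uM,clone values recorded in the counts table.
#' @return List with `spots` (input annotated with `cell_label`,
#'   `is_nuclear`, `is_ts`), `counts` (data frame `cell_id`, `dose_uM`,
#'   `clone`, `mrna_count`, `ts_count`), `median_spot_intensity`.
#' @export
count_and_classify <- function(spots, masks, ts_rule = 2,
                               count_ts_units = FALSE,
                               min_intensity_frac = 0.4,
                               dose_uM = NA_real_, clone = "img") {
  stopifnot(inherits(masks, "segmentation_masks"))
  # gate out sub-single-molecule detections (noise peaks), the usual
  # intensity-histogram gating of single mRNAs
  if (nrow(spots) > 0 && min_intensity_frac > 0)
    spots <- spots[spots$intensity >=
                     min_intensity_frac * median(spots$intensity), ,
                   drop = FALSE]
  nr <- nrow(masks$cells); nc <- ncol(masks$cells)
  at <- function(m, x, y) m[cbind(pmin(pmax(round(y) + 1, 1), nr),
                                  pmin(pmax(round(x) + 1, 1), nc))]
  spots$cell_label <- if (nrow(spots)) at(masks$cells, spots$x, spots$y)
                      else integer()
  spots$is_nuclear <- if (nrow(spots)) at(masks$nuclei, spots$x, spots$y) > 0
                      else logical()
  med <- if (nrow(spots)) median(spots$intensity) else NA_real_
  spots$is_ts <- spots$is_nuclear & spots$intensity >= ts_rule * med
  labs <- seq_len(max(masks$cells, 0L))
  if (length(labs) == 0L)
    return(list(spots = spots,
                counts = data.frame(cell_id = character(),
                                    dose_uM = numeric(), clone = character(),
                                    mrna_count = integer(),
                                    ts_count = integer()),
                median_spot_intensity = med))
  counts <- data.frame(
    cell_id = sprintf("%s_cell%03d", clone, labs),
    dose_uM = dose_uM, clone = clone,
    mrna_count = vapply(labs, function(l) {
      s <- spots[spots$cell_label == l, , drop = FALSE]
      n_plain <- sum(!s$is_ts)
      n_ts <- if (count_ts_units)
        sum(round(s$intensity[s$is_ts] / med)) else sum(s$is_ts)
      as.integer(n_plain + n_ts)
    }, 1L),
    ts_count = vapply(labs, function(l)
      sum(spots$cell_label == l & spots$is_ts), 1L))
  list(spots = spots, counts = counts, median_spot_intensity = med)
}

#' Link transcription-site detections across frames into intensity traces
#'
#' Greedy nearest-neighbor linking: at each frame, candidate matches
#' between open tracks and detections are taken in order of increasing
#' displacement (ties by earlier track index), accepting those within
#' `max_jump`; tracks unmatched for more than `max_gap` frames are closed
#' and remaining detections open new tracks. Frames without a detection
#' contribute intensity 0 (darkness is evidence for the off state).
#'
#' @param spot_lists list (one element per frame) of data frames with
#'   `x`, `y`, `intensity`; zero-row frames allowed.
#' @param max_jump maximum per-frame displacement in pixels.
#' @param max_gap maximum number of consecutive missed frames.
#' @param frame_interval minutes per frame (propagated to the traces).
#' @return List of `intensity_trace` objects spanning the full recording,
#'   intensity 0 where the track had no detection; each carries its
#'   per-frame positions in `$track`.
#' @export
track_ts <- function(spot_lists, max_jump = 3, max_gap = 2,
                     frame_interval = 15) {
  stopifnot(length(spot_lists) >= 2L)
  nF <- length(spot_lists)
  tracks <- list()   # each: list(x, y, last_frame, frames, xs, ys, ints)
  for (f in seq_len(nF)) {
    det <- spot_lists[[f]]
    if (is.null(det)) det <- data.frame(x = numeric(), y = numeric(),
                                        intensity = numeric())
    open_idx <- which(vapply(tracks, function(tr)
      f - tr$last_frame <= max_gap + 1L, TRUE))
    used_det <- rep(FALSE, nrow(det))
    if (length(open_idx) && nrow(det)) {
      pairs <- expand.grid(ti = open_idx, di = seq_len(nrow(det)))
      pairs$d <- sqrt((vapply(pairs$ti, function(i) tracks[[i]]$x, 1) -
                         det$x[pairs$di])^2 +
                      (vapply(pairs$ti, function(i) tracks[[i]]$y, 1) -
                         det$y[pairs$di])^2)
      pairs <- pairs[pairs$d <= max_jump, , drop = FALSE]
      pairs <- pairs[order(pairs$d, pairs$ti), , drop = FALSE]
      used_tr <- logical(length(tracks))
      for (r in seq_len(nrow(pairs))) {
        ti <- pairs$ti[r]; di <- pairs$di[r]
        if (used_tr[ti] || used_det[di]) next
        used_tr[ti] <- TRUE; used_det[di] <- TRUE
        tracks[[ti]]$x <- det$x[di]; tracks[[ti]]$y <- det$y[di]
        tracks[[ti]]$last_frame <- f
        tracks[[ti]]$frames <- c(tracks[[ti]]$frames, f)
        tracks[[ti]]$xs <- c(tracks[[ti]]$xs, det$x[di])
        tracks[[ti]]$ys <- c(tracks[[ti]]$ys, det$y[di])
        tracks[[ti]]$ints <- c(tracks[[ti]]$ints, det$intensity[di])
      }
    }
    for (di in which(!used_det)) {
      tracks[[length(tracks) + 1L]] <-
        list(x = det$x[di], y = det$y[di], last_frame = f, frames = f,
             xs = det$x[di], ys = det$y[di], ints = det$intensity[di])
    }
  }
  cfg <- trace_config(frame_interval = frame_interval,
                      duration = nF * frame_interval, nascent_dwell = 5,
                      noise_sd = 0, mode = "steady")
  lapply(tracks, function(tr) {
    intensity <- numeric(nF)
    intensity[tr$frames] <- tr$ints
    structure(list(time_min = frame_interval * seq_len(nF),
                   intensity = intensity, true_state = NULL,
                   dwells = NULL, cfg = cfg,
                   track = data.frame(frame = tr$frames, x = tr$xs,
                                      y = tr$ys, intensity = tr$ints)),
              class = "intensity_trace")
  })
}
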