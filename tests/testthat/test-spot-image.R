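test_that("blank images yield no spots and no labels", {
  blank <- render_image(NULL, shape = c(64, 64), background = 5,
                        poisson_noise = FALSE, read_noise_sd = 0)
  expect_equal(nrow(localize_spots(blank)), 0L)
  expect_warning(m <- segment(matrix(5, 64, 64), min_area = 20), "no nuclei")
  expect_true(m$empty)
  expect_equal(max(m$nuclei), 0L)
})

test_that("a noiseless spot is localized to sub-0.05 px with exact photometry", {
  f <- render_image(data.frame(x = 41.7, y = 20.3, amplitude = 50),
                    shape = c(64, 96), psf_sigma = 1.3, background = 10,
                    poisson_noise = FALSE, read_noise_sd = 0)
  s <- localize_spots(f, detect_sigma = 1.3)
  expect_equal(nrow(s), 1L)
  expect_lt(sqrt((s$x - 41.7)^2 + (s$y - 20.3)^2), 0.05)
  expect_lt(abs(s$intensity - 50 * 2 * pi * 1.3^2) / (50 * 2 * pi * 1.3^2),
            0.02)
})

test_that("localization bias is below 0.05 px over random sub-pixel offsets", {
  set.seed(41)
  errs <- sapply(1:20, function(i) {
    x0 <- 20 + runif(1); y0 <- 24 + runif(1)
    f <- render_image(data.frame(x = x0, y = y0, amplitude = 50),
                      shape = c(48, 48), psf_sigma = 1.3, background = 8,
                      poisson_noise = FALSE, read_noise_sd = 0)
    s <- localize_spots(f, detect_sigma = 1.3)
    c(s$x - x0, s$y - y0)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.05)     # bias
  expect_lt(max(abs(errs)), 0.05)               # noiseless worst case
})

test_that("a 50-spot field at SNR 10 is recovered with perfect recall and precision", {
  set.seed(42)
  tr <- sparse_spots(50, c(6, 121), c(6, 121), min_sep = 7, amplitude = 60)
  f <- render_image(tr, shape = c(128, 128), psf_sigma = 1.3,
                    background = 20, poisson_noise = TRUE,
                    read_noise_sd = 2, seed = 9)
  s <- localize_spots(f, detect_sigma = 1.3)
  expect_equal(nrow(s), 50L)                    # precision 1
  d <- vapply(seq_len(nrow(tr)), function(i)
    min(sqrt((s$x - tr$x[i])^2 + (s$y - tr$y[i])^2)), 1)
  expect_true(all(d < 0.5))                     # recall 1 at 0.5 px
})

test_that("nuclei are thresholded, area-filtered, and border-pruned", {
  nuc <- data.frame(cx = c(20, 60, 100, 40, 3), cy = c(20, 40, 90, 100, 60),
                    rx = c(9, 10, 8, 9, 10), ry = c(7, 8, 9, 8, 9),
                    level = 40)
  f <- render_image(NULL, shape = c(128, 128), background = 5, nuclei = nuc,
                    poisson_noise = FALSE, read_noise_sd = 1, seed = 2)
  m <- segment(f, min_area = 30)
  expect_equal(max(m$nuclei), 4L)               # border nucleus removed
  expect_true(all(m$cells[m$nuclei > 0] == m$nuclei[m$nuclei > 0]))
  m_all <- segment(f, min_area = 30, border_policy = "keep")
  expect_equal(max(m_all$nuclei), 5L)
  expect_warning(m_big <- segment(f, min_area = 500), "no nuclei")
  expect_true(m_big$empty)                      # area filter removes all
})

test_that("spots are assigned to cells and bright nuclear spots become TS calls", {
  nuc <- data.frame(cx = 60, cy = 60, rx = 10, ry = 9, level = 30)
  cel <- data.frame(cx = 60, cy = 60, rx = 40, ry = 38, level = 8)
  set.seed(43)
  cyto <- sparse_spots(30, c(25, 95), c(25, 95), min_sep = 6, amplitude = 30)
  keep <- ((cyto$x - 60) / 40)^2 + ((cyto$y - 60) / 38)^2 < 0.9 &
    ((cyto$x - 60) / 11)^2 + ((cyto$y - 60) / 10)^2 > 1.5
  cyto <- cyto[keep, ]
  sp <- rbind(cyto, data.frame(x = 60, y = 60, amplitude = 12 * 30))
  f <- render_image(sp, shape = c(128, 128), background = 5, nuclei = nuc,
                    cells = cel, poisson_noise = FALSE, read_noise_sd = 0.4,
                    seed = 3)
  m <- segment(f, min_area = 50)
  s <- localize_spots(f, detect_sigma = 1.3)
  cc <- count_and_classify(s, m, ts_rule = 2)
  expect_equal(nrow(cc$counts), 1L)
  expect_equal(cc$counts$ts_count, 1L)
  expect_equal(sum(cc$spots$is_ts), 1L)
  expect_equal(sum(!cc$spots$is_ts & cc$spots$cell_label == 1L), nrow(cyto))
  expect_equal(cc$counts$mrna_count, nrow(cyto) + 1L)
  # TS counted in intensity-equivalent units when requested
  cc2 <- count_and_classify(s, m, ts_rule = 2, count_ts_units = TRUE)
  expect_gt(cc2$counts$mrna_count, cc$counts$mrna_count + 5L)
})

test_that("counts tables round-trip through CSV into the telegraph fitter", {
  x <- simulate_counts(normalized_params(1, 1.5, 20), 400, seed = 44)
  tab <- data.frame(cell_id = sprintf("c%03d", seq_along(x)), dose_uM = 50,
                    clone = "rt", mrna_count = x)
  path <- tempfile(fileext = ".csv")
  write_counts_csv(tab, path)
  back <- read_counts_csv(path)
  expect_equal(back$mrna_count, tab$mrna_count)
  fit <- fit_counts(back, bin_width = 5, n_starts = 3)
  expect_true(fit$converged)
})

test_that("tracking links detections, closes gaps, and separates distant spots", {
  mk <- function(x, y, i = 30) data.frame(x = x, y = y, intensity = i)
  none <- mk(numeric(0), numeric(0), numeric(0))
  frames <- lapply(1:10, function(f)
    if (f %in% 5:6) none else mk(50 + 0.1 * f, 50 - 0.1 * f))
  tks <- track_ts(frames, max_jump = 3, max_gap = 2, frame_interval = 15)
  expect_equal(length(tks), 1L)                 # gap closed, one track
  expect_equal(tks[[1]]$intensity[5:6], c(0, 0))
  expect_equal(sum(tks[[1]]$intensity > 0), 8L)
  frames2 <- lapply(1:6, function(f) mk(c(20, 100), c(20, 100)))
  tks2 <- track_ts(frames2, max_jump = 3, max_gap = 2)
  expect_equal(length(tks2), 2L)                # never merged
  expect_true(all(vapply(tks2, function(t) all(t$intensity > 0), TRUE)))
  frames3 <- lapply(1:10, function(f) if (f > 4 && f < 9) none else mk(50, 50))
  tks3 <- track_ts(frames3, max_jump = 3, max_gap = 2)
  expect_equal(length(tks3), 2L)                # gap too long: split
})

test_that("image rendering, localization and counting compose into a valid
           copy-number experiment", {
  set.seed(61)
  truth <- normalized_params(1, 1.5, 25)
  counts_true <- simulate_counts(truth, 1000, seed = 61)
  all_counts <- integer(0)
  idx <- 1L
  grid9 <- expand.grid(cx = c(40, 120, 200), cy = c(40, 120, 200))
  for (fno in seq_len(ceiling(1000 / 9))) {
    k <- min(9L, 1000L - (fno - 1L) * 9L)
    cs <- grid9[seq_len(k), ]
    nuc <- data.frame(cx = cs$cx, cy = cs$cy, rx = 12, ry = 10, level = 60)
    cel <- data.frame(cx = cs$cx, cy = cs$cy, rx = 34, ry = 32, level = 12)
    sp <- do.call(rbind, lapply(seq_len(k), function(j) {
      n <- counts_true[idx + j - 1L]
      if (n == 0) return(NULL)
      pts <- matrix(NA_real_, 0, 2)
      while (nrow(pts) < n) {    # exactly n separated spots inside the cell
        cand <- c(cs$cx[j] + runif(1, -30, 30), cs$cy[j] + runif(1, -28, 28))
        if (((cand[1] - cs$cx[j]) / 34)^2 +
            ((cand[2] - cs$cy[j]) / 32)^2 > 0.92) next
        if (nrow(pts) && min((pts[, 1] - cand[1])^2 +
                             (pts[, 2] - cand[2])^2) < 36) next
        pts <- rbind(pts, cand)
      }
      data.frame(x = pts[, 1], y = pts[, 2], amplitude = 80)
    }))
    if (is.null(sp)) sp <- data.frame(x = numeric(), y = numeric(),
                                      amplitude = numeric())
    fld <- render_image(sp, shape = c(240, 240), psf_sigma = 1.3,
                        background = 10, poisson_noise = TRUE,
                        read_noise_sd = 2, nuclei = nuc, cells = cel,
                        seed = 1000 + fno)
    m <- segment(fld, min_area = 80)
    s <- localize_spots(fld, detect_sigma = 1.3)
    cc <- count_and_classify(s, m, ts_rule = 4)
    all_counts <- c(all_counts, cc$counts$mrna_count)
    idx <- idx + k
  }
  expect_equal(length(all_counts), 1000L)
  expect_lt(abs(mean(all_counts) - mean(counts_true)) / mean(counts_true),
            0.10)
  fit <- fit_counts(all_counts, bin_width = 5, n_starts = 4)
  expect_lt(abs(fit$beta - 1.5) / 1.5, 0.20)
  expect_lt(abs(fit$gamma - 25) / 25, 0.20)
})
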