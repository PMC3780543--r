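test_that("counts without initiation or activation are identically zero", {
  expect_equal(simulate_counts(telegraph_params(1, 1, 0, 1), 50, seed = 1),
               integer(50))
  expect_equal(simulate_counts(telegraph_params(0, 1, 9, 1), 50, seed = 1),
               integer(50))
  expect_error(simulate_counts(telegraph_params(1, 1, 5, 0), 10), "d > 0")
  expect_error(simulate_counts(telegraph_params(1, 1, 5, 1), 0), "positive")
})

test_that("stationary sample mean matches the closed-form mean", {
  p <- normalized_params(1.5, 1.5, 340)
  x <- simulate_counts(p, 5000, seed = 1)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 170), 3 * se)
})

test_that("stationary counts match the analytic PMF by chi-square", {
  sets <- list(c(1, 1.5, 20), c(0.3, 0.5, 8), c(5, 5, 60))
  for (i in seq_along(sets)) {
    p <- do.call(normalized_params, as.list(sets[[i]]))
    x <- simulate_counts(p, 10000, seed = 100 + i)
    pmf <- telegraph_pmf(p, max(x) + 20, tail_warn = FALSE)
    expect_gt(chisq_pvalue(x, pmf), 0.01)
  }
})

test_that("fixed seed gives bit-identical outputs", {
  p <- normalized_params(1, 1.5, 20)
  expect_identical(simulate_counts(p, 200, seed = 9),
                   simulate_counts(p, 200, seed = 9))
  cfg <- trace_cfg_snr5()
  t1 <- simulate_trace(telegraph_params(1/35, 1/36, 2, 1), cfg, seed = 4)
  t2 <- simulate_trace(telegraph_params(1/35, 1/36, 2, 1), cfg, seed = 4)
  expect_identical(t1, t2)
  sp <- data.frame(x = 10, y = 12, amplitude = 40)
  expect_identical(render_image(sp, shape = c(32, 32), seed = 3)$image,
                   render_image(sp, shape = c(32, 32), seed = 3)$image)
})

test_that("trace presets behave as designed", {
  prm <- telegraph_params(1/35, 1/36, 5, 1)
  cfg_on <- trace_config(15, 900, nascent_dwell = 15, noise_sd = 0,
                         mode = "always_on")
  tr <- simulate_trace(prm, cfg_on, seed = 2)
  expect_true(all(tr$intensity > 0))
  expect_true(all(tr$true_state == 1L))
  cfg_p <- trace_config(15, 900, nascent_dwell = 15, noise_sd = 0,
                        mode = "pulse")
  trp <- simulate_trace(prm, cfg_p, seed = 3)
  expect_equal(sum(rle(trp$true_state)$values == 1L), 1L)
  expect_equal(sum(trp$dwells$state == "on"), 1L)
  cfg_i <- trace_config(15, 300, nascent_dwell = 15, noise_sd = 0,
                        mode = "induction")
  tri <- simulate_trace(prm, cfg_i, seed = 4)
  expect_true(tri$dwells$state[1] == "off")
})

test_that("hidden dwell times are exponential with the generative means", {
  cfg <- trace_cfg_snr5()
  trs <- simulate_traces(telegraph_params(1/35, 1/36, 2, 1), cfg, 500,
                         seed = 11)
  # the initial dwell's post-t0 residual is a complete exponential draw
  # (memorylessness), so only the final, boundary-truncated run is censored
  dw <- do.call(rbind, lapply(trs, function(t) {
    d <- t$dwells; d$censored[1] <- FALSE; d
  }))
  for (st in c("on", "off")) {
    target <- if (st == "on") 36 else 35
    f <- fit_dwell_exponential(dw, st, handle_censoring = TRUE)
    expect_lt(abs(f$mean - target), 2 * f$se)
    d <- dw$duration_min[dw$state == st & !dw$censored]
    expect_lt(abs(mean(d) / sd(d) - 1), 0.07)  # exponential signature
  }
})

test_that("induction activates an increasing fraction of cells", {
  cfg <- trace_config(15, 300, nascent_dwell = 15, noise_sd = 0,
                      mode = "induction")
  trs <- simulate_traces(telegraph_params(1/35, 1/36, 2, 1), cfg, 300,
                         seed = 5)
  frac <- rowMeans(sapply(trs, function(t) t$intensity > 0))
  expect_lt(frac[1], frac[2])
  expect_lt(frac[2], frac[4])
  expect_lt(frac[1], 0.5)
})

test_that("dose series emits one group per dose with ordered means", {
  doses <- c(1.56, 3.125, 6.25, 12.5, 25, 50)
  dm <- dose_map(doses, activation_scale = 1.5 / 9.6)
  tab <- simulate_dose_series(normalized_params(1, 1.5, 340), dm, 400,
                              seed = 7)
  expect_setequal(unique(tab$dose_uM), doses)
  expect_equal(nrow(tab), 6 * 400)
  m <- tapply(tab$mrna_count, tab$dose_uM, mean)[as.character(doses)]
  expect_true(all(diff(m) > 0))
  truth <- attr(tab, "truth")
  expect_equal(truth[[6]]$a, 1.5 / 9.6 * 50)
  # silent template: no activation-independent expression
  tab0 <- simulate_dose_series(normalized_params(1, 1.5, 0), dm, 20,
                               seed = 8)
  expect_true(all(tab0$mrna_count == 0))
  expect_error(dose_map(c(2, 1), 1), "increasing")
  expect_error(dose_map(c(1, 2), 0), "activation_scale")
})

test_that("rendered images honor truth spots, background and noise model", {
  blank <- render_image(NULL, shape = c(32, 48), background = 7,
                        poisson_noise = FALSE, read_noise_sd = 0)
  expect_true(all(blank$image == 7))
  one <- render_image(data.frame(x = 20.5, y = 11.2, amplitude = 30),
                      shape = c(32, 48), psf_sigma = 1.5, background = 2,
                      poisson_noise = FALSE, read_noise_sd = 0)
  expect_equal(sum(one$image - 2), 30 * 2 * pi * 1.5^2, tolerance = 1e-3)
  expect_error(render_image(data.frame(x = 99, y = 2, amplitude = 1),
                            shape = c(32, 32)), "outside")
})
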