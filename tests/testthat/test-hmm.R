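test_that("a noiseless two-level square wave is decoded exactly", {
  states <- rep(rep(c(0L, 1L), 5), each = 6)
  y <- states * 5
  fit <- fit_hmm_decode(y, seed = 1)
  expect_equal(fit$n_states, 2L)
  expect_identical(fit$path, states)
  expect_identical(fit$path_midpoint, states)
  expect_lt(fit$model$mu[1], fit$model$mu[2])   # off labeled low
  expect_true(all(fit$posterior >= 0 & fit$posterior <= 1))
})

test_that("featureless traces collapse to a single state at the right label", {
  set.seed(3)
  vehicle <- rnorm(60, 0, 2)                     # baseline + noise only
  f0 <- fit_hmm_decode(vehicle, seed = 1)
  expect_equal(f0$n_states, 1L)
  expect_equal(mean(f0$path), 0)
  expect_equal(mean(fit_hmm_decode(rep(0, 60), seed = 1)$path), 0)
  expect_equal(mean(fit_hmm_decode(rep(40, 60) + rnorm(60), seed = 1)$path), 1)
  expect_error(fit_hmm_decode(c(1, 2, 3)), ">= 10")
})

test_that("decoding is faithful when dwells are long relative to frames", {
  cfg <- trace_cfg_snr5()
  trs <- simulate_traces(telegraph_params(1/300, 1/300, 2, 1), cfg, 150,
                         seed = 7)
  decs <- lapply(trs, fit_hmm_decode, seed = 1)
  mis <- mean(mapply(function(d, tr) mean(d$path != tr$true_state),
                     decs, trs))
  expect_lt(mis, 0.05)
})

test_that("decoded active fraction tracks the generative active fraction", {
  cfg <- trace_cfg_snr5()
  trs <- simulate_traces(telegraph_params(1/35, 1/36, 2, 1), cfg, 150,
                         seed = 11)
  decs <- lapply(trs, fit_hmm_decode, seed = 1)
  occ <- mean(unlist(lapply(decs, function(d) d$path_midpoint)))
  expect_lt(abs(occ - 36 / 71), 0.05)
})

test_that("dwell extraction run-length encodes with boundary censoring", {
  dw <- extract_dwells(c(1, 1, 0, 0, 0, 1), frame_interval = 15)
  expect_equal(dw$state, c("on", "off", "on"))
  expect_equal(dw$duration_min, c(30, 45, 15))
  expect_equal(dw$censored, c(TRUE, FALSE, TRUE))
  allo <- extract_dwells(rep(0L, 60), frame_interval = 15)
  expect_equal(nrow(allo), 1L)
  expect_equal(allo$duration_min, 900)
  expect_true(allo$censored)
  expect_equal(attr(allo, "experiment_duration"), 900)
  set.seed(1)
  path <- rbinom(40, 1, 0.5)
  dws <- extract_dwells(path, frame_interval = 15)
  expect_equal(sum(dws$duration_min), 40 * 15)   # concatenation invariant
  expect_error(extract_dwells(integer(0), 15), "empty")
})

test_that("exponential dwell MLE equals the sample mean and handles censoring", {
  d <- data.frame(state = "on", duration_min = c(10, 20, 30, 15, 25),
                  censored = FALSE)
  f <- fit_dwell_exponential(d, "on")
  expect_equal(f$mean, 20)
  expect_equal(f$se, 20 / sqrt(5))
  # censored likelihood: closed form vs brute-force optimization
  dc <- data.frame(state = "on", duration_min = c(20, 40, 100, 120),
                   censored = c(FALSE, FALSE, TRUE, TRUE))
  fc <- fit_dwell_exponential(dc, "on", handle_censoring = TRUE)
  expect_equal(fc$mean, (20 + 40 + 100 + 120) / 2)
  nll <- function(m) 2 * log(m) + (20 + 40) / m + (100 + 120) / m
  expect_equal(fc$mean, optimize(nll, c(1, 1e4))$minimum, tolerance = 1e-4)
  # heavy censoring: censored-likelihood estimate exceeds the naive mean
  expect_gt(fc$mean, mean(c(20, 40)))
  expect_error(fit_dwell_exponential(d[1:3, ], "on"), "at least 5")
})

test_that("exponential fits are unbiased on exponential data", {
  set.seed(8)
  est <- replicate(20, {
    d <- data.frame(state = "off", duration_min = rexp(40, 1 / 30),
                    censored = FALSE)
    fit_dwell_exponential(d, "off")$mean
  })
  expect_lt(abs(mean(est) - 30), 2 * sd(est) / sqrt(20))
})

test_that("sampling-corrected rates invert the frame-sampled transition matrix", {
  # exact frame-sampled chains (no decoding noise): recovery of 36/35
  set.seed(9)
  paths <- lapply(1:400, function(i) {
    t <- 0; s <- rbinom(1, 1, 36 / 71); sw <- 0; st <- s
    while (t < 900) {
      t <- t + rexp(1, ifelse(s == 1, 1 / 36, 1 / 35)); s <- 1 - s
      sw <- c(sw, t); st <- c(st, s)
    }
    st[findInterval(seq(15, 900, 15), sw)]
  })
  r <- fit_dwell_rates(paths, 15)
  expect_true(r$valid)
  expect_lt(abs(r$on_mean - 36), 3)
  expect_lt(abs(r$off_mean - 35), 3)
  expect_lt(abs(r$active_fraction - 36 / 71), 0.02)
  # degenerate all-off input flagged invalid
  r0 <- fit_dwell_rates(lapply(1:5, function(i) rep(0L, 60)), 15)
  expect_false(r0$valid)
  expect_true(is.na(r0$on_mean))
})
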