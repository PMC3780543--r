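test_that("analytic PMF agrees with the master-equation oracle on a grid", {
  for (alpha in c(0.1, 1, 5))
    for (beta in c(0.5, 1.5, 5))
      for (gamma in c(5, 20, 100)) {
        p <- normalized_params(alpha, beta, gamma)
        n_max <- burstkit:::default_n_max(p) + 50L
        pmf <- telegraph_pmf(p, n_max, tail_warn = FALSE)
        cme <- cme_oracle(p, n_max)
        expect_lt(max(abs(pmf - cme)), 1e-6)
      }
})

test_that("PMF normalizes and reports its truncated tail", {
  p <- normalized_params(1, 1.5, 20)
  pmf <- telegraph_pmf(p)
  expect_true(all(pmf >= 0))
  expect_lt(attr(pmf, "tail_mass"), 1e-6)
  expect_equal(sum(pmf) + attr(pmf, "tail_mass"), 1, tolerance = 1e-10)
  expect_warning(telegraph_pmf(p, n_max = 5), "tail mass")
  cme <- cme_oracle(p)
  expect_equal(sum(cme), 1, tolerance = 1e-8)
})

test_that("PMF moments match the closed-form summaries", {
  for (prm in list(c(1, 1.5, 20), c(0.3, 0.5, 8), c(1.5, 1.5, 340))) {
    p <- normalized_params(prm[1], prm[2], prm[3])
    pmf <- telegraph_pmf(p, tail_warn = FALSE)
    n <- seq_along(pmf) - 1
    s <- telegraph_summary(p)
    expect_equal(sum(n * pmf), s$mean, tolerance = 1e-8)
    expect_equal(sum(n^2 * pmf) - sum(n * pmf)^2, s$mean * s$fano,
                 tolerance = 1e-7)
  }
  s <- telegraph_summary(normalized_params(1.5, 1.5, 340))
  expect_equal(s$mean, 170)
  expect_equal(s$active_fraction, 0.5)
  # 38-min on / 35-min off bursting is active about half the time
  expect_equal(telegraph_summary(normalized_params(1 / 35, 1 / 38, 1)
               )$active_fraction, 38 / 73, tolerance = 1e-12)
  expect_lt(abs(38 / 73 - 0.5), 0.05)
})

test_that("degenerate limits: silent gene and always-on Poisson", {
  p0 <- telegraph_pmf(normalized_params(1, 1, 0), 10)
  expect_equal(as.numeric(p0), c(1, rep(0, 10)))
  expect_equal(cme_oracle(normalized_params(1, 1, 0), 10)[1], 1,
               tolerance = 1e-10)
  pp <- telegraph_pmf(normalized_params(2, 0, 12), 60, tail_warn = FALSE)
  expect_equal(as.numeric(pp), dpois(0:60, 12), tolerance = 1e-12)
  s <- telegraph_summary(normalized_params(2, 0, 12))
  expect_equal(s$active_fraction, 1)
  expect_equal(s$fano, 1)
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(normalized_params(-1, 1, 5), "alpha")
  expect_error(normalized_params(1, -1, 5))
  expect_error(telegraph_params(1, 1, 1, -1))
  expect_error(telegraph_pmf(normalized_params(1, 1, 5), n_max = -2))
  expect_error(telegraph_summary(list()), "cannot interpret")
})
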