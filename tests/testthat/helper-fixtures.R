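# shared fixtures built in code

# chi-square goodness of fit of integer counts against a model PMF,
# pooling bins so every expected count is >= min_expected
chisq_pvalue <- function(counts, pmf, min_expected = 5) {
  n <- length(counts)
  p <- c(pmf, max(0, 1 - sum(pmf)))           # open tail bin
  obs <- tabulate(pmin(counts, length(p) - 1L) + 1L, length(p))
  exp_ <- n * p
  # pool from the right until all expected >= min_expected
  while (length(exp_) > 2 && (exp_[length(exp_)] < min_expected)) {
    k <- length(exp_)
    exp_[k - 1] <- exp_[k - 1] + exp_[k]; exp_ <- exp_[-k]
    obs[k - 1] <- obs[k - 1] + obs[k]; obs <- obs[-k]
  }
  keep <- exp_ >= min_expected
  # pool any remaining sparse interior bins into their neighbor
  if (!all(keep)) {
    obs <- c(sum(obs[!keep]), obs[keep])
    exp_ <- c(sum(exp_[!keep]), exp_[keep])
  }
  stat <- sum((obs - exp_)^2 / exp_)
  stats::pchisq(stat, df = length(exp_) - 1, lower.tail = FALSE)
}

# lay sparse spots with a minimum pairwise separation inside a box
sparse_spots <- function(n, xlim, ylim, min_sep = 6, amplitude = 60) {
  pts <- matrix(NA_real_, 0, 2)
  while (nrow(pts) < n) {
    cand <- c(runif(1, xlim[1], xlim[2]), runif(1, ylim[1], ylim[2]))
    if (nrow(pts) && min((pts[, 1] - cand[1])^2 +
                         (pts[, 2] - cand[2])^2) < min_sep^2) next
    pts <- rbind(pts, cand)
  }
  data.frame(x = pts[, 1], y = pts[, 2], amplitude = amplitude)
}

# standard 15-min / 15-h trace acquisition with on-level-to-noise ratio 5
trace_cfg_snr5 <- function(mode = "steady")
  trace_config(frame_interval = 15, duration = 900, nascent_dwell = 15,
               noise_sd = 6, mode = mode)
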