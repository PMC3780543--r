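#' Rescale a transcription-site trace to the unit interval
#'
#' Robust percentile normalization: the (5th, 95th) percentile window is
#' mapped to \[0, 1\] (values outside are not clipped). Used before HMM
#' fitting so emission parameters live on a common scale.
#'
#' @param x numeric intensity vector.
#' @param probs lower/upper percentiles of the window.
#' @return Rescaled numeric vector.
#' @export
normalize_trace <- function(x, probs = c(0.05, 0.95)) {
  q <- quantile(x, probs, names = FALSE)
  if (diff(q) < .Machine$double.eps^0.5) return(x - q[1])
  (x - q[1]) / diff(q)
}

#' Fit and decode a two-state hidden Markov model on an intensity trace
#'
#' Baum-Welch EM with Gaussian emissions on the percentile-normalized trace,
#' followed by Viterbi decoding into \{off, on\} (states labeled by emission
#' mean, off = lower). Initialization is 2-means clustering with jittered
#' restarts; the restart with the best log-likelihood wins. A
#' single-Gaussian model is fit alongside and preferred by BIC when the
#' trace carries no evidence of two intensity levels; such traces are
#' declared single-state and decoded all-off when their raw mean is at
#' baseline (below three raw standard deviations), all-on otherwise.
#'
#' @param trace an `intensity_trace` (from [simulate_trace()]) or numeric
#'   intensity vector; at least 10 finite frames.
#' @param n_restarts EM restarts (default 5).
#' @param max_iter EM iteration cap (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param seed integer seed controlling initialization.
#' @return An object of class `hmm_fit`: `model` (per-frame transition
#'   matrix `P`, emission `mu`/`sigma`, initial distribution), `path`
#'   (Viterbi, 0 = off, 1 = on per frame), `path_midpoint` (per-frame
#'   classification at the midpoint of the fitted emission means — Viterbi
#'   smoothing suppresses single-frame excursions, which biases downstream
#'   dwell statistics, so dwell-rate estimation uses this path), `posterior`
#'   (frames x 2 matrix), `loglik`, `n_states` (1 if collapsed),
#'   `frame_interval`.
#' @export
fit_hmm_decode <- function(trace, n_restarts = 5, max_iter = 500,
                           tol = 1e-8, seed = 1L) {
  raw <- if (inherits(trace, "intensity_trace")) trace$intensity else trace
  dt <- if (inherits(trace, "intensity_trace"))
    trace$cfg$frame_interval else NA_real_
  if (length(raw) < 10L || any(!is.finite(raw)))
    stop("need >= 10 finite intensity frames")
  nT <- length(raw)
  # frame-to-frame differences estimate the noise floor robustly even when
  # the trace carries slow state structure
  sigma_diff <- mad(diff(raw)) / sqrt(2)
  baseline_on <- mean(raw) > 3 * sigma_diff + .Machine$double.eps

  single_state <- function() {
    st <- as.integer(baseline_on)
    structure(list(
      model = list(P = diag(2), mu = c(0, 1), sigma = c(1, 1) * sd(raw),
                   init = c(1 - st, st)),
      path = rep(st, nT),
      path_midpoint = rep(st, nT),
      posterior = matrix(rep(c(1 - st, st), each = nT), nT, 2,
                         dimnames = list(NULL, c("off", "on"))),
      loglik = sum(dnorm(raw, mean(raw), max(sd(raw), 1e-6), log = TRUE)),
      n_states = 1L, frame_interval = dt), class = "hmm_fit")
  }
  if (sd(raw) < .Machine$double.eps^0.5) return(single_state())

  y <- normalize_trace(raw)
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(kmeans(y, 2L, nstart = 2L), error = function(e) NULL)
    mu0 <- if (is.null(km)) quantile(y, c(0.25, 0.75), names = FALSE)
           else sort(km$centers[, 1])
    if (r > 1) mu0 <- mu0 + rnorm(2, 0, 0.15)
    sd0 <- rep(max(sd(y) / 2, 0.05), 2)
    em <- hmm_em(y, mu0, sd0, max_iter = max_iter, tol = tol)
    if (is.null(best) || em$loglik > best$loglik) best <- em
  }
  # order states by emission mean: state 1 = off (lower)
  o <- order(best$mu)
  P <- best$P[o, o]; mu <- best$mu[o]; sig <- best$sigma[o]
  init <- best$init[o]

  # AIC guard against fitting structure into featureless traces (vehicle
  # controls); AIC rather than BIC because mid-frame switching blends the
  # two levels and short traces would otherwise collapse too readily
  ll1 <- sum(dnorm(y, mean(y), max(sd(y), 1e-6), log = TRUE))
  aic1 <- -2 * ll1 + 2 * 2
  aic2 <- -2 * best$loglik + 2 * 7
  if (aic1 <= aic2) return(single_state())

  dec <- hmm_viterbi(y, P, mu, sig, init)
  post <- hmm_posterior(y, P, mu, sig, init)
  colnames(post) <- c("off", "on")
  structure(list(model = list(P = P, mu = mu, sigma = sig, init = init),
                 path = dec,
                 path_midpoint = as.integer(y > mean(mu)),
                 posterior = post, loglik = best$loglik,
                 n_states = 2L, frame_interval = dt), class = "hmm_fit")
}

# Baum-Welch for a 2-state Gaussian HMM (scaled forward-backward)
hmm_em <- function(y, mu, sigma, max_iter = 500, tol = 1e-8) {
  nT <- length(y)
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  init <- c(0.5, 0.5)
  sigma <- pmax(sigma, 1e-3)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    B <- cbind(dnorm(y, mu[1], sigma[1]), dnorm(y, mu[2], sigma[2]))
    B <- pmax(B, 1e-300)
    # forward
    alpha <- matrix(0, nT, 2); cscale <- numeric(nT)
    a <- init * B[1, ]; cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
    for (t in 2:nT) {
      a <- (alpha[t - 1, ] %*% P) * B[t, ]
      cscale[t] <- sum(a); alpha[t, ] <- a / cscale[t]
    }
    ll <- sum(log(cscale))
    # backward
    beta <- matrix(0, nT, 2); beta[nT, ] <- 1
    for (t in (nT - 1):1)
      beta[t, ] <- (P %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
    g <- alpha * beta
    g <- g / rowSums(g)
    xi <- matrix(0, 2, 2)
    for (t in 1:(nT - 1)) {
      m <- (alpha[t, ] %o% (B[t + 1, ] * beta[t + 1, ])) * P / cscale[t + 1]
      xi <- xi + m
    }
    P <- xi / pmax(rowSums(xi), 1e-300)
    init <- g[1, ]
    for (k in 1:2) {
      wk <- g[, k]
      mu[k] <- sum(wk * y) / sum(wk)
      sigma[k] <- sqrt(sum(wk * (y - mu[k])^2) / sum(wk))
    }
    sigma <- pmax(sigma, 1e-3)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3))
      break
    ll_old <- ll
  }
  list(P = P, mu = mu, sigma = sigma, init = init, loglik = ll, iter = it)
}

hmm_viterbi <- function(y, P, mu, sigma, init) {
  nT <- length(y)
  lB <- cbind(dnorm(y, mu[1], sigma[1], log = TRUE),
              dnorm(y, mu[2], sigma[2], log = TRUE))
  lP <- log(pmax(P, 1e-300))
  v <- matrix(-Inf, nT, 2); ptr <- matrix(1L, nT, 2)
  v[1, ] <- log(pmax(init, 1e-300)) + lB[1, ]
  for (t in 2:nT) for (k in 1:2) {
    cand <- v[t - 1, ] + lP[, k]
    ptr[t, k] <- which.max(cand)
    v[t, k] <- cand[ptr[t, k]] + lB[t, k]
  }
  path <- integer(nT)
  path[nT] <- which.max(v[nT, ])
  for (t in (nT - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  path - 1L   # 0 = off, 1 = on
}

hmm_posterior <- function(y, P, mu, sigma, init) {
  nT <- length(y)
  B <- pmax(cbind(dnorm(y, mu[1], sigma[1]), dnorm(y, mu[2], sigma[2])),
            1e-300)
  alpha <- matrix(0, nT, 2); cscale <- numeric(nT)
  a <- init * B[1, ]; cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
  for (t in 2:nT) {
    a <- (alpha[t - 1, ] %*% P) * B[t, ]
    cscale[t] <- sum(a); alpha[t, ] <- a / cscale[t]
  }
  beta <- matrix(0, nT, 2); beta[nT, ] <- 1
  for (t in (nT - 1):1)
    beta[t, ] <- (P %*% (B[t + 1, ] * beta[t + 1, ])) / cscale[t + 1]
  g <- alpha * beta
  g / rowSums(g)
}

#' Run-length encode a decoded state path into dwell times
#'
#' Consecutive runs of the same state become dwells of length
#' `run length x frame_interval`. The first and last runs touch the
#' recording boundary, so their true durations are only bounded below; they
#' are flagged censored.
#'
#' @param path integer vector of 0/1 states (or an `hmm_fit`).
#' @param frame_interval minutes per frame.
#' @param duration recording length in minutes (default
#'   `length(path) * frame_interval`).
#' @return An object of class `dwell_set`: data frame with `state`
#'   (`"off"`/`"on"`), `duration_min`, `censored`; attributes
#'   `experiment_duration` and `frame_interval`.
#' @export
#' @examples
#' extract_dwells(c(1, 1, 0, 0, 0, 1), frame_interval = 15)
extract_dwells <- function(path, frame_interval, duration = NULL) {
  if (inherits(path, "hmm_fit")) {
    if (missing(frame_interval)) frame_interval <- path$frame_interval
    path <- path$path
  }
  if (length(path) == 0L) stop("empty state path")
  stopifnot(all(path %in% c(0L, 1L)), frame_interval > 0)
  if (is.null(duration)) duration <- length(path) * frame_interval
  r <- rle(as.integer(path))
  k <- length(r$lengths)
  out <- data.frame(state = ifelse(r$values == 1L, "on", "off"),
                    duration_min = r$lengths * frame_interval,
                    censored = seq_len(k) %in% c(1L, k))
  structure(out, experiment_duration = duration,
            frame_interval = frame_interval,
            class = c("dwell_set", "data.frame"))
}

#' Exponential maximum-likelihood fit of dwell times
#'
#' For uncensored dwells the MLE of the exponential mean is the sample mean.
#' With `handle_censoring = TRUE`, censored dwells (known only to exceed
#' their recorded length) contribute survival terms, giving
#' `mean = (sum of all durations) / (number of uncensored dwells)` — the
#' standard censored-exponential MLE. The standard error comes from the
#' observed information, `mean / sqrt(n_uncensored)`.
#'
#' @param dwells a `dwell_set` (or data frame with `state`, `duration_min`,
#'   `censored`), possibly pooled over traces.
#' @param which `"on"` or `"off"`.
#' @param handle_censoring include censored dwells through the survival
#'   likelihood (default `FALSE`: censored dwells are dropped, matching
#'   common practice).
#' @return List with `mean`, `se`, `n`, `n_censored`.
#' @export
fit_dwell_exponential <- function(dwells, which = c("on", "off"),
                                  handle_censoring = FALSE) {
  which <- match.arg(which)
  d <- dwells[dwells$state == which, , drop = FALSE]
  unc <- d$duration_min[!d$censored]
  cen <- d$duration_min[d$censored]
  if (length(unc) < 5L && !handle_censoring)
    stop("need at least 5 uncensored dwells (or handle_censoring = TRUE)")
  if (handle_censoring) {
    if (length(unc) < 1L)
      stop("censored-likelihood fit needs at least one uncensored dwell")
    m <- (sum(unc) + sum(cen)) / length(unc)
  } else {
    m <- mean(unc)
  }
  list(mean = m, se = m / sqrt(length(unc)), n = length(unc) + length(cen),
       n_censored = length(cen))
}

#' Sampling-corrected dwell means from decoded state paths
#'
#' Dwell means read off run lengths of a frame-sampled path are biased
#' upward: runs are quantized to whole frames and state flips that reverse
#' between consecutive frames are invisible, merging adjacent dwells. For a
#' two-state Markov process the bias is removed exactly by estimating the
#' per-frame transition matrix `P` from pooled path transitions and mapping
#' it back to continuous-time rates through the matrix logarithm,
#' `Q = log(lambda) / ((lambda - 1) dt) * (P - I)` with
#' `lambda = 1 - P[1,2] - P[2,1]`; the mean dwells are the inverse rates.
#' Requires `lambda > 0`, i.e. frames fast enough that the chain does not
#' mix completely between observations.
#'
#' @param paths list of 0/1 state vectors (or of `hmm_fit` objects).
#' @param frame_interval minutes per frame.
#' @return List with `on_mean`, `off_mean` (minutes), `active_fraction`
#'   (stationary on probability `a/(a+b)`), `P` (estimated per-frame
#'   transition matrix), `valid` (`FALSE` when `lambda <= 0`, in which case
#'   the means are `NA`).
#' @export
fit_dwell_rates <- function(paths, frame_interval) {
  if (inherits(paths, "hmm_fit")) paths <- list(paths)
  trans <- matrix(0, 2, 2)
  for (p in paths) {
    if (inherits(p, "hmm_fit")) p <- p$path
    if (length(p) < 2L) next
    from <- p[-length(p)] + 1L
    to <- p[-1L] + 1L
    for (k in 1:4)
      trans[k] <- trans[k] + sum(from == ((k - 1) %% 2 + 1) &
                                 to == ((k - 1) %/% 2 + 1))
  }
  rs <- rowSums(trans)
  if (any(rs == 0))
    return(list(on_mean = NA_real_, off_mean = NA_real_,
                active_fraction = mean(unlist(lapply(paths, function(p)
                  if (inherits(p, "hmm_fit")) p$path else p))),
                P = NA, valid = FALSE))
  P <- trans / rs
  lambda <- 1 - P[1, 2] - P[2, 1]
  if (lambda <= 0)
    return(list(on_mean = NA_real_, off_mean = NA_real_,
                active_fraction = P[1, 2] / (P[1, 2] + P[2, 1]),
                P = P, valid = FALSE))
  Q <- log(lambda) / ((lambda - 1) * frame_interval) * (P - diag(2))
  a <- Q[1, 2]; b <- Q[2, 1]
  list(on_mean = 1 / b, off_mean = 1 / a, active_fraction = a / (a + b),
       P = P, valid = TRUE)
}
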