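#' Kinetic parameters of the two-state (telegraph) gene
#'
#' The telegraph model switches a promoter between an inactive state and an
#' active state: activation at rate `a`, inactivation at rate `b`, transcript
#' initiation at rate `c` while active, and first-order mRNA decay at rate
#' `d`. All rates are per minute.
#'
#' @param a activation rate (1/min), `>= 0`.
#' @param b inactivation rate (1/min), `>= 0`.
#' @param c initiation rate while active (1/min), `>= 0`.
#' @param d mRNA decay rate (1/min), `>= 0` (`> 0` for steady-state work).
#' @return An object of class `telegraph_params`.
#' @seealso [normalized_params()] for the decay-normalized parameterization.
#' @export
#' @examples
#' telegraph_params(a = 1/35, b = 1/36, c = 2, d = 0.005)
telegraph_params <- function(a, b, c, d) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), is.numeric(d),
            length(a) == 1L, length(b) == 1L, length(c) == 1L, length(d) == 1L)
  if (any(!is.finite(c(a, b, c, d))) || any(c(a, b, c, d) < 0))
    stop("all rates must be finite and non-negative")
  structure(list(a = a, b = b, c = c, d = d), class = "telegraph_params")
}

#' Decay-normalized telegraph parameters
#'
#' Snapshot (fixed-cell) data identify the kinetic rates only up to the mRNA
#' decay rate `d`, so all distribution fitting works with the unitless ratios
#' `alpha = a/d`, `beta = b/d`, `gamma = c/d`.
#'
#' @param alpha normalized activation rate `a/d`, `> 0`.
#' @param beta normalized inactivation rate `b/d`, `>= 0`.
#' @param gamma normalized initiation rate `c/d`, `>= 0`.
#' @return An object of class `normalized_params`.
#' @export
#' @examples
#' normalized_params(alpha = 1.5, beta = 1.5, gamma = 340)
normalized_params <- function(alpha, beta, gamma) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L, length(gamma) == 1L)
  if (any(!is.finite(c(alpha, beta, gamma))))
    stop("parameters must be finite")
  if (alpha <= 0 || beta < 0 || gamma < 0)
    stop("require alpha > 0, beta >= 0, gamma >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "normalized_params")
}

#' @export
print.normalized_params <- function(x, ...) {
  cat(sprintf("normalized telegraph parameters: a/d = %g, b/d = %g, c/d = %g\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

as_normalized <- function(p) {
  if (inherits(p, "normalized_params")) return(p)
  if (inherits(p, "telegraph_params")) {
    if (p$d <= 0) stop("d > 0 required to normalize by decay rate")
    return(normalized_params(p$a / p$d, p$b / p$d, p$c / p$d))
  }
  if (is.numeric(p) && length(p) == 3L)
    return(normalized_params(p[[1]], p[[2]], p[[3]]))
  stop("cannot interpret parameters; give normalized_params(), ",
       "telegraph_params(), or a numeric vector (alpha, beta, gamma)")
}

# default truncation point: mean + 12 sd + margin, rounded up
default_n_max <- function(p) {
  s <- telegraph_summary(p)
  v <- s$mean * s$fano
  as.integer(ceiling(s$mean + 12 * sqrt(max(v, 1)) + 30))
}

#' Steady-state mRNA copy-number distribution of the telegraph model
#'
#' Evaluates the analytic stationary distribution
#' \deqn{P(n) = \frac{\Gamma(\alpha+n)\,\Gamma(\alpha+\beta)}
#'  {\Gamma(n+1)\,\Gamma(\alpha+\beta+n)\,\Gamma(\alpha)}\,
#'  \gamma^n\, {}_1F_1(\alpha+n;\, \alpha+\beta+n;\, -\gamma)}
#' for `n = 0..n_max`. The confluent hypergeometric factor is computed in log
#' space through the Kummer transformation, whose series has non-negative
#' terms, so the evaluation is stable for `gamma` in the hundreds where the
#' naive alternating series overflows.
#'
#' @param p parameters accepted by [normalized_params()] (or a
#'   `telegraph_params`, normalized internally).
#' @param n_max truncation point; defaults to mean + 12 standard deviations.
#' @param tail_warn warn when the truncated tail mass exceeds `1e-6`.
#' @return Numeric vector of probabilities for counts `0..n_max`, with the
#'   truncated tail mass in attribute `"tail_mass"`.
#' @export
#' @examples
#' p <- telegraph_pmf(normalized_params(1, 1.5, 20))
#' sum(p) + attr(p, "tail_mass")  # == 1 up to numerical error
telegraph_pmf <- function(p, n_max = NULL, tail_warn = TRUE) {
  p <- as_normalized(p)
  if (is.null(n_max)) n_max <- default_n_max(p)
  n_max <- as.integer(n_max)
  if (n_max < 0) stop("n_max must be >= 0")
  pr <- telegraph_pmf_cpp(p$alpha, p$beta, p$gamma, n_max)
  tail_mass <- max(0, 1 - sum(pr))
  if (tail_warn && tail_mass > 1e-6)
    warning(sprintf("truncation at n_max = %d leaves tail mass %.3g > 1e-6",
                    n_max, tail_mass))
  attr(pr, "tail_mass") <- tail_mass
  pr
}

#' Moments of the steady-state telegraph distribution
#'
#' Closed-form stationary summaries: mean mRNA
#' \eqn{\langle N\rangle = \gamma\,\alpha/(\alpha+\beta)}, the active
#' fraction \eqn{\alpha/(\alpha+\beta)} (fraction of time the promoter spends
#' in the on state), and the Fano factor
#' \eqn{1 + \gamma\beta / [(\alpha+\beta)(1+\alpha+\beta)]}.
#'
#' @inheritParams telegraph_pmf
#' @return List with `mean`, `active_fraction`, `fano`.
#' @export
#' @examples
#' telegraph_summary(normalized_params(1.5, 1.5, 340))  # mean 170, f = 0.5
telegraph_summary <- function(p) {
  p <- as_normalized(p)
  ab <- p$alpha + p$beta
  if (ab <= 0) stop("degenerate parameters: alpha + beta must be > 0")
  f <- p$alpha / ab
  list(mean = p$gamma * f,
       active_fraction = f,
       fano = 1 + p$gamma * p$beta / (ab * (1 + ab)))
}

#' Brute-force master-equation stationary distribution
#'
#' Independent numerical oracle for [telegraph_pmf()]: builds the truncated
#' generator of the joint (promoter state, copy number) Markov chain on
#' states \{off, on\} x \{0..n_max\} with unit decay rate, solves for its
#' stationary null vector with a sparse LU factorization, and marginalizes
#' over the promoter state. Shares no code with the analytic evaluation.
#'
#' @inheritParams telegraph_pmf
#' @param n_max truncation; must be large enough that the boundary state
#'   carries `< 1e-8` probability.
#' @return Numeric vector of stationary probabilities for counts `0..n_max`.
#' @export
cme_oracle <- function(p, n_max = NULL) {
  p <- as_normalized(p)
  if (is.null(n_max)) n_max <- default_n_max(p) + 50L
  n_max <- as.integer(n_max)
  ns <- 2L * (n_max + 1L)                    # index = 2 n + s + 1, s in {0,1}
  idx <- function(n, s) 2L * n + s + 1L
  n_all <- 0:n_max
  ii <- c(idx(n_all, 0L),                    # off -> on, rate alpha
          idx(n_all, 1L),                    # on -> off, rate beta
          idx(n_all[n_all < n_max], 1L),     # birth while on, rate gamma
          idx(n_all[n_all > 0L], 0L),        # decay, rate n (d = 1)
          idx(n_all[n_all > 0L], 1L))
  jj <- c(idx(n_all, 1L),
          idx(n_all, 0L),
          idx(n_all[n_all < n_max] + 1L, 1L),
          idx(n_all[n_all > 0L] - 1L, 0L),
          idx(n_all[n_all > 0L] - 1L, 1L))
  xx <- c(rep(p$alpha, n_max + 1L),
          rep(p$beta, n_max + 1L),
          rep(p$gamma, n_max),
          n_all[n_all > 0L],
          n_all[n_all > 0L])
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(ns, ns))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  A <- Matrix::t(Q)
  A[ns, ] <- 1                               # replace one balance eq. by sum-to-1
  rhs <- c(rep(0, ns - 1L), 1)
  pi_full <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                      error = function(e)
                        stop("singular or ill-conditioned truncated generator: ",
                             conditionMessage(e)))
  pn <- pi_full[idx(n_all, 0L)] + pi_full[idx(n_all, 1L)]
  boundary <- pn[n_max + 1L]
  if (boundary > 1e-8)
    warning(sprintf("boundary state mass %.3g > 1e-8; increase n_max", boundary))
  pn
}
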