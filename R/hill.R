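#' Hill dose-response parameters
#'
#' @param A_max saturation response (e.g. mRNA/cell), `>= 0`.
#' @param EC50 half-maximal dose (uM), `> 0`.
#' @param h Hill coefficient, `> 0` (1 = non-cooperative).
#' @return An object of class `hill_params`.
#' @export
hill_params <- function(A_max, EC50, h = 1) {
  stopifnot(length(A_max) == 1L, length(EC50) == 1L, length(h) == 1L)
  if (A_max < 0 || EC50 <= 0 || h <= 0)
    stop("require A_max >= 0, EC50 > 0, h > 0")
  structure(list(A_max = A_max, EC50 = EC50, h = h), class = "hill_params")
}

#' Evaluate the Hill dose-response curve
#'
#' `activity = A_max * dose^h / (EC50^h + dose^h)`; zero at dose 0 and
#' saturating at `A_max`.
#'
#' @param p a [hill_params()] (or list with `A_max`, `EC50`, `h`).
#' @param doses ligand concentrations, `>= 0`.
#' @return Numeric vector of activities.
#' @export
#' @examples
#' hill_curve(hill_params(190, 9.6, 1), c(0, 9.6, 1e6))
hill_curve <- function(p, doses) {
  stopifnot(all(doses >= 0))
  dh <- doses^p$h
  ifelse(doses == 0, 0, p$A_max * dh / (p$EC50^p$h + dh))
}

#' Telegraph-model equivalent of a Hill dose response
#'
#' When only the activation rate depends on dose, `a = k * dose`, the
#' steady-state mean `gamma * a / (a + b)` is exactly a Hill function of
#' dose with `h = 1`, `A_max = gamma` (= c/d) and `EC50 = beta / k` (= b/k).
#' This is the algebraic bridge between the population dose response and
#' the burst kinetics.
#'
#' @param beta normalized inactivation rate `b/d`.
#' @param gamma normalized initiation rate `c/d`.
#' @param activation_scale the dose-to-activation constant `k`.
#' @return A [hill_params()] with `h = 1`.
#' @export
telegraph_hill_equiv <- function(beta, gamma, activation_scale) {
  hill_params(A_max = gamma, EC50 = beta / activation_scale, h = 1)
}

#' Fit the Hill equation to dose-response data
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) for the three-
#' parameter Hill curve, optionally with the Hill coefficient frozen (the
#' two-parameter fit used for non-cooperative responses). Weights are
#' `1/se^2` when standard errors are supplied, else unweighted.
#'
#' @param doses ligand concentrations (`>= 0`); at least 3 distinct positive
#'   doses for a free-`h` fit, 2 when `h` is fixed.
#' @param responses measured activities (same length).
#' @param se optional standard errors of the responses.
#' @param fix_h freeze the Hill coefficient at this value (e.g. 1), or
#'   `NULL` to fit it.
#' @return An object of class `hill_fit`: `params` ([hill_params()]),
#'   `se` (named standard errors), `fitted`, `residuals`, `rss` (weighted),
#'   `fixed_h` flag.
#' @export
#' @examples
#' d <- c(1.56, 3.125, 6.25, 12.5, 25, 50)
#' y <- hill_curve(hill_params(190, 9.6, 1), d)
#' fit_hill(d, y, fix_h = 1)$params
fit_hill <- function(doses, responses, se = NULL, fix_h = NULL) {
  stopifnot(length(doses) == length(responses), all(doses >= 0))
  npos <- length(unique(doses[doses > 0]))
  need <- if (is.null(fix_h)) 3L else 2L
  if (npos < need)
    stop(sprintf("need at least %d distinct positive doses", need))
  if (length(unique(doses)) < 2L) stop("degenerate design: all doses equal")
  w <- if (is.null(se)) rep(1, length(doses)) else {
    stopifnot(length(se) == length(doses), all(se > 0))
    1 / se^2
  }
  dat <- data.frame(dose = doses, y = responses, w = w)
  A0 <- max(responses)
  half_idx <- which.min(abs(responses - A0 / 2))
  E0 <- max(doses[half_idx], min(doses[doses > 0]))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  if (is.null(fix_h)) {
    fit <- minpack.lm::nlsLM(
      y ~ A * dose^h / (E^h + dose^h), data = dat, weights = w,
      start = list(A = A0, E = E0, h = 1),
      lower = c(0, 1e-8, 1e-3), upper = c(Inf, Inf, 20), control = ctrl)
  } else {
    h_fixed <- fix_h
    fit <- minpack.lm::nlsLM(
      y ~ A * dose^h_fixed / (E^h_fixed + dose^h_fixed), data = dat,
      weights = w, start = list(A = A0, E = E0),
      lower = c(0, 1e-8), upper = c(Inf, Inf), control = ctrl)
  }
  cf <- coef(fit)
  sm <- summary(fit)
  ses <- sm$coefficients[, "Std. Error"]
  prm <- hill_params(A_max = cf[["A"]], EC50 = cf[["E"]],
                     h = if (is.null(fix_h)) cf[["h"]] else fix_h)
  r <- dat$y - hill_curve(prm, dat$dose)
  structure(list(params = prm,
                 se = c(A_max = unname(ses["A"]), EC50 = unname(ses["E"]),
                        h = if (is.null(fix_h)) unname(ses["h"]) else NA_real_),
                 fitted = hill_curve(prm, dat$dose),
                 residuals = r, rss = sum(w * r^2),
                 fixed_h = !is.null(fix_h)), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("Hill fit%s: A_max = %.4g (SE %.3g), EC50 = %.4g (SE %.3g), h = %.3g%s\n",
              if (x$fixed_h) " (h fixed)" else "", p$A_max, x$se["A_max"],
              p$EC50, x$se["EC50"], p$h,
              if (x$fixed_h) "" else sprintf(" (SE %.3g)", x$se["h"])))
  invisible(x)
}
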