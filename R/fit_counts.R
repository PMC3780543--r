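#' Binned maximum-likelihood telegraph fit of mRNA copy-number data
#'
#' Fits the steady-state telegraph distribution to per-cell mRNA counts by
#' maximizing the multinomial log-likelihood of histogram bins, with the bin
#' probability summed over the bin (last bin open-ended). With a single
#' group all three normalized parameters (`alpha = a/d`, `beta = b/d`,
#' `gamma = c/d`) are free; with several groups (a dose series) `beta` and
#' `gamma` are shared while each group gets its own activation rate `alpha`
#' — the frequency-modulation hypothesis, under which only the on rate
#' varies with dose.
#'
#' Optimization is bounded quasi-Newton (`L-BFGS-B`) on log-parameters with
#' `n_starts` multi-starts: the first from a method-of-moments guess, the
#' rest Latin-hypercube perturbations of it. Among near-tied optima the
#' smallest `gamma` is preferred. Uncertainties, when requested, come from a
#' parametric bootstrap (counts resampled from the fitted distribution and
#' refit from the fitted optimum).
#'
#' @param table data frame with column `mrna_count` and, for a dose series,
#'   `dose_uM` (output of [simulate_dose_series()] or [read_counts_csv()]);
#'   or a bare numeric vector of counts for a single group.
#' @param bin_width histogram bin width in mRNA (default 100).
#' @param n_starts number of multi-starts (default 8).
#' @param n_boot parametric-bootstrap replicates for confidence intervals
#'   (default 0 = point estimates only).
#' @param seed integer seed for starts and bootstrap.
#' @param maxit iteration cap per start.
#' @return An object of class `telegraph_fit`: per-group `alpha` (named),
#'   shared `beta` and `gamma`, `loglik`, `converged`, `boundary` flags for
#'   estimates at optimizer bounds, group sizes, and optional bootstrap
#'   percentile intervals in `$boot`.
#' @export
#' @examples
#' x <- simulate_counts(normalized_params(1, 1.5, 20), 500, seed = 7)
#' fit_counts(x, bin_width = 5, n_starts = 4)
fit_counts <- function(table, bin_width = 100, n_starts = 8, n_boot = 0,
                       seed = 1L, maxit = 300) {
  if (is.numeric(table) && is.null(dim(table)))
    table <- data.frame(dose_uM = 0, mrna_count = as.integer(table))
  stopifnot(is.data.frame(table), "mrna_count" %in% names(table),
            bin_width >= 1)
  if (!"dose_uM" %in% names(table)) table$dose_uM <- 0
  if (any(table$mrna_count < 0)) stop("counts must be non-negative")
  groups <- split(table$mrna_count, table$dose_uM)
  if (any(vapply(groups, length, 1L) < 10L))
    stop("each group needs at least 10 cells")
  G <- length(groups)
  gnames <- names(groups)

  binfo <- lapply(groups, function(x) {
    bmax <- max(1L, floor(max(x) / bin_width))
    tab <- tabulate(pmin(floor(x / bin_width), bmax) + 1L, bmax + 1L)
    list(tab = tab, n_max = as.integer(bmax * bin_width - 1L),
         grp = floor(0:(bmax * bin_width - 1L) / bin_width) + 1L)
  })

  nll_dose <- function(g, la, lb, lg) {
    bi <- binfo[[g]]
    pmf <- telegraph_pmf_cpp(exp(la), exp(lb), exp(lg), bi$n_max)
    pv <- pmax(c(rowsum(pmf, bi$grp), 1 - sum(pmf)), 1e-300)
    v <- -sum(bi$tab * log(pv))
    if (is.finite(v)) v else 1e12
  }
  nll <- function(theta) {
    tot <- 0
    for (g in seq_len(G))
      tot <- tot + nll_dose(g, theta[g], theta[G + 1L], theta[G + 2L])
    tot
  }
  # forward-difference gradient exploiting per-dose separability: each
  # alpha_g touches only its own dose's likelihood term
  grad <- function(theta) {
    h <- 1e-6
    lb <- theta[G + 1L]; lg <- theta[G + 2L]
    base <- vapply(seq_len(G), function(g)
      nll_dose(g, theta[g], lb, lg), 1)
    gr <- numeric(G + 2L)
    for (g in seq_len(G))
      gr[g] <- (nll_dose(g, theta[g] + h, lb, lg) - base[g]) / h
    gr[G + 1L] <- (sum(vapply(seq_len(G), function(g)
      nll_dose(g, theta[g], lb + h, lg), 1)) - sum(base)) / h
    gr[G + 2L] <- (sum(vapply(seq_len(G), function(g)
      nll_dose(g, theta[g], lb, lg + h), 1)) - sum(base)) / h
    gr
  }

  th0 <- moment_init(groups)
  npar <- G + 2L
  # gamma cannot exceed a modest multiple of the largest observed count
  # (the active-state ceiling); an open upper box would send the optimizer
  # into regions where the hypergeometric series costs O(gamma) per term
  gmax <- max(30 * max(table$mrna_count), 1e3)
  lower <- c(rep(log(1e-3), G), log(1e-3), log(1e-2))
  upper <- c(rep(log(1e3), G), log(1e3), log(gmax))
  set.seed(as.integer(seed))
  starts <- matrix(rep(th0, each = n_starts), n_starts, npar)
  if (n_starts > 1L) {
    u <- lhs::randomLHS(n_starts - 1L, npar)
    starts[-1L, ] <- starts[-1L, ] + 1.2 * (2 * u - 1)
  }
  starts <- pmin(pmax(starts, rep(lower, each = n_starts)),
                 rep(upper, each = n_starts))

  # multi-start at a coarse tolerance, then polish the winner tightly
  fits <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fits[[s]] <- tryCatch(
      optim(starts[s, ], nll, gr = grad, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = maxit, factr = 1e10)),
      error = function(e) list(value = Inf, convergence = 99L))
  }
  vals <- vapply(fits, function(f) f$value, 1)
  if (all(!is.finite(vals)))
    stop("telegraph fit did not converge in any of the restarts")
  near <- which(vals <= min(vals) + 1)
  gammas <- vapply(fits[near], function(f) f$par[G + 2L], 1)
  best0 <- fits[[near[which.min(gammas)]]]
  best <- tryCatch(
    optim(best0$par, nll, gr = grad, method = "L-BFGS-B", lower = lower,
          upper = upper, control = list(maxit = maxit, factr = 1e7)),
    error = function(e) best0)
  if (!identical(best$convergence, 0L) && !identical(best0$convergence, 0L))
    stop("telegraph fit did not converge in any of the restarts")

  est <- exp(best$par)
  boundary <- abs(best$par - lower) < 1e-4 | abs(best$par - upper) < 1e-4
  names(boundary) <- c(paste0("alpha_", gnames), "beta", "gamma")
  out <- structure(list(
    alpha = setNames(est[seq_len(G)], gnames),
    beta = est[G + 1L], gamma = est[G + 2L],
    loglik = -best$value, converged = identical(best$convergence, 0L),
    boundary = boundary, bin_width = bin_width,
    n_per_group = vapply(groups, length, 1L),
    doses = suppressWarnings(as.numeric(gnames))), class = "telegraph_fit")

  if (n_boot > 0) {
    bp <- matrix(NA_real_, n_boot, npar)
    for (r in seq_len(n_boot)) {
      sim <- list()
      for (g in seq_len(G)) {
        p <- normalized_params(out$alpha[g], out$beta, out$gamma)
        pmf <- telegraph_pmf(p, tail_warn = FALSE)
        sim[[gnames[g]]] <- sample.int(length(pmf), out$n_per_group[g],
                                       replace = TRUE, prob = pmf) - 1L
      }
      bfit <- tryCatch(
        optim(best$par, make_nll_for(sim, bin_width), method = "L-BFGS-B",
              lower = lower, upper = upper, control = list(maxit = maxit)),
        error = function(e) NULL)
      if (!is.null(bfit)) bp[r, ] <- exp(bfit$par)
    }
    ci <- t(apply(bp, 2, quantile, c(0.025, 0.975), na.rm = TRUE))
    rownames(ci) <- names(boundary)
    out$boot <- ci
  }
  out
}

# rebuild the negative log-likelihood for a list of count vectors
make_nll_for <- function(groups, bin_width) {
  G <- length(groups)
  binfo <- lapply(groups, function(x) {
    bmax <- max(1L, floor(max(x) / bin_width))
    list(tab = tabulate(pmin(floor(x / bin_width), bmax) + 1L, bmax + 1L),
         n_max = as.integer(bmax * bin_width - 1L),
         grp = floor(0:(bmax * bin_width - 1L) / bin_width) + 1L)
  })
  function(theta) {
    alpha <- exp(theta[seq_len(G)])
    beta <- exp(theta[G + 1L]); gamma <- exp(theta[G + 2L])
    tot <- 0
    for (g in seq_len(G)) {
      bi <- binfo[[g]]
      pmf <- telegraph_pmf_cpp(alpha[g], beta, gamma, bi$n_max)
      pv <- pmax(c(rowsum(pmf, bi$grp), 1 - sum(pmf)), 1e-300)
      tot <- tot - sum(bi$tab * log(pv))
    }
    if (!is.finite(tot)) tot <- 1e12
    tot
  }
}

# method-of-moments starting point on the log scale:
# gamma from the upper tail of the highest-mean group, active fractions from
# group means, beta from the Fano factor of the highest-mean group.
moment_init <- function(groups) {
  G <- length(groups)
  m <- vapply(groups, mean, 1)
  top <- which.max(m)
  x <- groups[[top]]
  gamma0 <- max(quantile(x, 0.995) * 1.15, max(m) * 1.3, 5)
  f <- pmin(pmax(m / gamma0, 0.01), 0.99)
  fano <- max(var(x) / max(m[top], 0.1), 1.1)
  s0 <- gamma0 * (1 - f[top]) / max(fano - 1, 0.1) - 1
  s0 <- min(max(s0, 0.05), 100)
  beta0 <- min(max(s0 * (1 - f[top]), 1e-2), 1e3)
  alpha0 <- pmin(pmax(beta0 * f / (1 - f), 1e-3), 1e4)
  log(c(alpha0, beta0, gamma0))
}

#' @export
print.telegraph_fit <- function(x, ...) {
  cat("Binned maximum-likelihood telegraph fit\n")
  cat(sprintf("  shared b/d = %.4g, c/d = %.4g (bin width %d)\n",
              x$beta, x$gamma, x$bin_width))
  cat("  per-group a/d:\n")
  for (g in names(x$alpha))
    cat(sprintf("    %s: %.4g\n", g, x$alpha[g]))
  cat(sprintf("  log-likelihood %.2f; converged: %s\n", x$loglik,
              x$converged))
  if (any(x$boundary))
    cat("  at bounds:", paste(names(x$boundary)[x$boundary], collapse = ", "),
        "\n")
  invisible(x)
}
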