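#' Concentration vs fraction-bound titration data
#'
#' @param concentrations Protein concentrations in nM (strictly positive).
#' @param fraction_bound Fraction of probe bound, in [0, 1].
#' @return Object of class \code{binding_curve} (a data frame).
#' @export
binding_curve <- function(concentrations, fraction_bound) {
  if (length(concentrations) != length(fraction_bound))
    stop("concentrations and fraction_bound must have equal length")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  if (any(fraction_bound < 0 | fraction_bound > 1))
    stop("fraction_bound must lie in [0, 1]")
  structure(data.frame(concentration_nM = as.numeric(concentrations),
                       fraction_bound = as.numeric(fraction_bound)),
            class = c("binding_curve", "data.frame"))
}

#' Fraction bound from free-DNA band intensities
#'
#' The fraction bound in a gel-shift titration is estimated from the
#' depletion of the free-DNA band: 1 - I_free / I_free,0, clipped to
#' [0, 1].
#'
#' @param free_intensities Free-DNA band intensity per lane.
#' @param zero_protein_intensity Free-DNA intensity in the no-protein
#'   lane (must be positive).
#' @param concentrations Optional protein concentrations (nM) per lane; if
#'   supplied, a \code{binding_curve} is returned, else a numeric vector.
#' @return numeric vector or \code{binding_curve}.
#' @export
fraction_bound_from_intensities <- function(free_intensities,
                                            zero_protein_intensity,
                                            concentrations = NULL) {
  if (zero_protein_intensity <= 0)
    stop("zero-protein reference intensity must be positive")
  fb <- pmin(pmax(1 - free_intensities / zero_protein_intensity, 0), 1)
  if (is.null(concentrations)) fb else binding_curve(concentrations, fb)
}

.hill <- function(p, A, kd, h) A * p^h / (kd^h + p^h)

#' Fit a three-parameter Hill equation to a binding curve
#'
#' Least-squares fit of f([P]) = A [P]^h / (KD^h + [P]^h), estimating the
#' amplitude A, the apparent equilibrium dissociation constant KD (the
#' protein concentration at half-maximal binding, in nM) and the Hill
#' coefficient h. Initialisation is a fixed grid of starting values
#' (A0 = max(f); KD0 at the concentration nearest half of A0, the
#' geometric mid-concentration, the top concentration and twice the top
#' concentration; h0 = 0.5 to 6 in steps of 0.5); the start with the
#' lowest residual sum of squares wins, ties going to the earliest start,
#' so the fit is fully deterministic. Parameters are bounded
#' (0 < A <= 1.05, KD > 0, 0.1 < h <= 6). Levenberg-Marquardt least
#' squares via minpack.lm.
#'
#' @param curve A \code{binding_curve} (or data frame with columns
#'   \code{concentration_nM} and \code{fraction_bound}) with at least 4
#'   points.
#' @return Object of class \code{hill_fit} with components
#'   \code{amplitude}, \code{kd}, \code{hill_h}, \code{rss},
#'   \code{converged}, \code{curve} and the underlying \code{nls} fit.
#' @export
fit_hill <- function(curve) {
  p <- curve$concentration_nM
  f <- curve$fraction_bound
  if (length(p) < 4L) stop("Hill fit needs at least 4 titration points")
  if (length(unique(f)) == 1L)
    stop("fraction_bound values are all equal; nothing to fit")
  if (all(f == 0)) stop("all-zero binding curve; nothing to fit")
  a0 <- max(f)
  kd_half <- p[which.min(abs(f - a0 / 2))]
  # deterministic multi-start: steep sparse titrations trap a single
  # Levenberg-Marquardt run in local optima
  starts <- expand.grid(
    kd0 = unique(c(kd_half, exp(mean(log(range(p)))), max(p), 2 * max(p))),
    h0 = seq(0.5, 6, by = 0.5))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      f ~ A * p^h / (kd^h + p^h),
      start = list(A = a0, kd = starts$kd0[i], h = starts$h0[i]),
      lower = c(A = 1e-6, kd = 1e-6, h = 0.1),
      upper = c(A = 1.05, kd = Inf, h = 6),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss * (1 - 1e-9) - 1e-30)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("Hill fit failed to converge from any start")
  fit <- best$fit
  est <- stats::coef(fit)
  structure(
    list(amplitude = unname(est["A"]), kd = unname(est["kd"]),
         hill_h = unname(est["h"]),
         rss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv,
         curve = curve, nls = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Three-parameter Hill fit\n")
  cat(sprintf("  amplitude A      : %.4f\n", x$amplitude))
  cat(sprintf("  apparent KD (nM) : %.4g\n", x$kd))
  cat(sprintf("  Hill coefficient : %.4g\n", x$hill_h))
  cat(sprintf("  residual SS      : %.3g  (converged: %s)\n",
              x$rss, x$converged))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(amplitude = object$amplitude, kd = object$kd, hill_h = object$hill_h)
}

#' @export
summary.hill_fit <- function(object, ...) {
  s <- summary(object$nls)
  structure(list(fit = object, nls_summary = s), class = "summary.hill_fit")
}

#' @export
print.summary.hill_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter table (from nls):\n")
  print(x$nls_summary$coefficients)
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$curve$concentration_nM
  else if (is.numeric(newdata)) newdata
  else newdata$concentration_nM
  .hill(p, object$amplitude, object$kd, object$hill_h)
}

#' @export
fitted.hill_fit <- function(object, ...) predict(object)

#' @export
residuals.hill_fit <- function(object, ...) {
  object$curve$fraction_bound - fitted(object)
}

#' @export
plot.hill_fit <- function(x, n = 200, ...) {
  p <- x$curve$concentration_nM
  grid <- exp(seq(log(min(p)), log(max(p)), length.out = n))
  plot(p, x$curve$fraction_bound, log = "x",
       xlab = "[protein] (nM)", ylab = "fraction bound",
       ylim = c(0, max(1, x$amplitude)), ...)
  graphics::lines(grid, .hill(grid, x$amplitude, x$kd, x$hill_h))
  graphics::abline(v = x$kd, lty = 2)
  invisible(x)
}

#' Simulate titration curves from a fitted Hill model
#'
#' @param object A \code{hill_fit}.
#' @param nsim Number of simulated curves.
#' @param seed Optional integer seed.
#' @param noise_sigma Additive Gaussian noise standard deviation (default
#'   0.03); values are clipped to [0, 1].
#' @param ... Unused.
#' @return list of \code{binding_curve}s at the fitted concentrations.
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL,
                              noise_sigma = 0.03, ...) {
  run <- function() {
    lapply(seq_len(nsim), function(i) {
      f <- fitted(object) + stats::rnorm(nrow(object$curve), 0, noise_sigma)
      binding_curve(object$curve$concentration_nM, pmin(pmax(f, 0), 1))
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
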