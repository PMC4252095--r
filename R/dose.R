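#' Dose estimation by inverse regression with Merkle confidence limits
#'
#' Core machinery shared by the whole-body, partial-body and Dolphin
#' estimators.  The point dose solves \eqn{\hat Y(d) = Y_0} by bracketed
#' root finding on \eqn{[0, d_{max}]}.  The 95\% limits follow the
#' inverse-regression (Merkle) construction combining the simultaneous
#' calibration-curve band \eqn{\hat Y(d) \pm R\,s(d)} (R from
#' [band_constant()]) with the observed-yield uncertainty
#' \eqn{z\,SE(Y_0)}: by default the lower limit solves
#' \eqn{\hat Y(d) + R\,s(d) = Y_0 - z\,SE(Y_0)} and the upper limit
#' solves \eqn{\hat Y(d) - R\,s(d) = Y_0 + z\,SE(Y_0)}.
#'
#' @param fit a fitted calibration curve ([gt_fit] or [classical_fit]).
#' @param yield observed dicentric yield \eqn{Y_0}.
#' @param yield_se standard error of the observed yield (0 for a point
#'   inversion of the curve alone).
#' @param z normal quantile applied to the yield uncertainty.
#' @param level confidence level of the curve band.
#' @param combine how band and yield uncertainty combine: `"merkle"`
#'   (default, both), `"band"` (curve band only) or `"yield"` (yield
#'   uncertainty only).
#' @param dmax upper end of the search bracket in Gy.
#' @param method tag stored in the result.
#' @return An object of class `dose_estimate`: a list with `dose`,
#'   `conf_int`, `yield`, `yield_se`, `method` and auxiliary fields.
#' @export
dose_from_yield <- function(fit, yield, yield_se = 0, z = 1.96,
                            level = 0.95,
                            combine = c("merkle", "band", "yield"),
                            dmax = 100, method = "inverse-regression") {
  combine <- match.arg(combine)
  stopifnot(yield >= 0, yield_se >= 0)
  yfun <- function(d) .curve_yield(fit, d)
  ymax <- yfun(dmax)
  if (yield > ymax)
    stop("dose not estimable: yield ", signif(yield, 4),
         " exceeds the curve's ceiling ", signif(ymax, 4),
         " at ", dmax, " Gy (saturation)", call. = FALSE)
  solve_on <- function(f, lo = 0, hi = dmax) {
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi)) return(NA_real_)
    if (flo >= 0) return(lo)          # target at or below curve start
    if (fhi < 0) return(NA_real_)     # never reached within bracket
    stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
  }
  d0 <- if (yield == 0) 0 else solve_on(function(d) yfun(d) - yield)
  use_band <- combine %in% c("merkle", "band")
  use_yield <- combine %in% c("merkle", "yield") && yield_se > 0
  R <- if (use_band) band_constant(fit, level) else 0
  sfun <- if (use_band) function(d) .pred_se(fit, d) else function(d) 0
  ylo <- yield - if (use_yield) z * yield_se else 0
  yhi <- yield + if (use_yield) z * yield_se else 0
  dL <- solve_on(function(d) yfun(d) + R * sfun(d) - ylo)
  dU <- solve_on(function(d) yfun(d) - R * sfun(d) - yhi)
  if (is.na(dU))
    warning("upper confidence limit exceeds ", dmax,
            " Gy (yield near curve saturation)")
  structure(list(dose = d0, conf_int = c(lower = dL, upper = dU),
                 yield = yield, yield_se = yield_se, z = z,
                 band_R = R, combine = combine, method = method,
                 curve = if (inherits(fit, "gt_fit")) "gt" else fit$model),
            class = "dose_estimate")
}

#' @export
print.dose_estimate <- function(x, ...) {
  cat(sprintf("Dose estimate (%s, %s curve)\n", x$method, x$curve))
  cat(sprintf("  yield: %.4f (SE %.4f)\n", x$yield, x$yield_se))
  cat(sprintf("  dose: %.2f Gy  95%% CI (%.2f - %.2f) Gy\n",
              x$dose, x$conf_int[1], x$conf_int[2]))
  if (!is.null(x$fraction))
    cat(sprintf("  estimated irradiated fraction: %.2f\n", x$fraction))
  if (!is.null(x$u)) cat(sprintf("  dispersion u = %.2f\n", x$u))
  invisible(x)
}

#' Whole-body dose estimation
#'
#' Inverts a fitted calibration curve at the observed yield of a scored
#' sample.  The yield SE is the empirical \eqn{\sqrt{Var/N}} of the
#' distribution (which reproduces published SE columns), and confidence
#' limits follow the Merkle construction of [dose_from_yield()].
#'
#' @param x a [dicentric_dist] (or count vector) for the blood sample.
#' @param fit a fitted calibration curve.
#' @inheritParams dose_from_yield
#' @return A `dose_estimate`.
#' @examples
#' cal <- read_distribution_table(
#'   system.file("extdata", "calibration_dicentrics.tsv", package = "gtdose"))
#' fit <- gt_fit(cal)
#' s6 <- dicentric_dist(c(1, 16, 54, 42, 21, 9, 4, 2, 1), dose = 6)
#' whole_body_dose(s6, fit)
#' @export
whole_body_dose <- function(x, fit, z = 1.96,
                            combine = c("merkle", "band", "yield"),
                            dmax = 100) {
  s <- summary(.as_dist(x))
  se <- if (is.na(s$SE)) 0 else s$SE
  # with no dicentrics the empirical SE is 0; the upper yield bound then
  # falls back on the exact Poisson 97.5% limit 3.69/N
  if (s$X == 0) se <- stats::qgamma(0.975, 1) / s$N / z
  est <- dose_from_yield(fit, s$Y, se, z = z,
                         combine = match.arg(combine), dmax = dmax,
                         method = "whole-body")
  est$u <- s$u
  est
}

#' Zero-truncated weighted-Poisson fit for the irradiated fraction
#'
#' After a partial-body exposure the scored cells are a mixture of
#' irradiated and unirradiated lymphocytes, so the zero class is inflated
#' and carries no information about the dose to the irradiated fraction.
#' This fits the zero-truncated weighted Poisson by maximum likelihood to
#' the cells with at least one dicentric, and reports the *untruncated*
#' mean yield at the fitted parameters — the expected yield in the
#' irradiated fraction — with a delta-method SE from the inverse observed
#' information of the truncated fit.
#'
#' @param x a [dicentric_dist] or count vector.
#' @return An object of class `ztwp_fit`: `lambda`, `b`, `vcov` (on the
#'   natural scale), `yield`, `yield_se`, `n_cells` used, and a
#'   `boundary` flag set when the likelihood is flat in `b` (weight
#'   parameter at its upper boundary; the yield remains well determined).
#' @examples
#' part <- dicentric_dist(c(201, 8, 34, 28, 19, 7, 1, 0, 1, 0, 1))
#' ztwp_fit(part)
#' @export
ztwp_fit <- function(x) {
  x <- .as_dist(x)
  k <- seq_along(x$counts) - 1
  keep <- k >= 1 & x$counts > 0
  n_pos <- sum(x$counts[keep])
  if (n_pos < 2)
    stop("zero-truncated fit needs at least 2 cells with dicentrics",
         call. = FALSE)
  kk <- k[keep]; nn <- x$counts[keep]
  nll <- function(theta) {
    lam <- exp(theta[1]); b <- exp(theta[2])
    v <- tryCatch(-sum(nn * dztwpois(kk, lam, b, log = TRUE)),
                  error = function(e) 1e12)
    if (!is.finite(v)) 1e12 else v
  }
  mstart <- sum(kk * nn) / n_pos
  opt <- stats::optim(c(log(mstart), 0), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  lam <- exp(opt$par[1]); b <- exp(opt$par[2])
  H <- stats::optimHess(opt$par, nll)
  Vt <- tryCatch(solve(H), error = function(e) NULL)
  boundary <- is.null(Vt) || kappa(H) > 1e10 || b > 1e4
  if (is.null(Vt)) Vt <- .pinv(H)
  J <- diag(c(lam, b))
  V <- J %*% Vt %*% t(J)
  dimnames(V) <- list(c("lambda", "b"), c("lambda", "b"))
  # delta method through the closed-form untruncated mean
  g <- c((wpois_mean(lam * (1 + 1e-6), b) -
            wpois_mean(lam * (1 - 1e-6), b)) / (2e-6 * lam),
         (wpois_mean(lam, b + max(1e-6, 1e-6 * b)) -
            wpois_mean(lam, max(0, b - max(1e-6, 1e-6 * b)))) /
           (2 * max(1e-6, 1e-6 * b)))
  yield_se <- sqrt(max(0, drop(t(g) %*% V %*% g)))
  structure(list(lambda = lam, b = b, vcov = V,
                 yield = wpois_mean(lam, b), yield_se = yield_se,
                 n_cells = n_pos, loglik = -opt$value,
                 convergence = opt$convergence, boundary = boundary),
            class = "ztwp_fit")
}

#' @export
print.ztwp_fit <- function(x, ...) {
  cat("Zero-truncated weighted-Poisson fit (cells with >= 1 dicentric)\n")
  cat(sprintf("  lambda = %.4f  b = %.4g  (%d cells)\n",
              x$lambda, x$b, x$n_cells))
  cat(sprintf("  irradiated-fraction yield = %.4f (SE %.4f)\n",
              x$yield, x$yield_se))
  if (x$boundary)
    cat("  note: weight parameter at boundary (flat likelihood in b)\n")
  invisible(x)
}

#' Partial-body dose estimation via the zero-truncated weighted Poisson
#'
#' Estimates the dose to the irradiated fraction: the irradiated-fraction
#' yield and SE come from [ztwp_fit()], and the GT calibration curve is
#' inverted at that yield with Merkle limits as in [whole_body_dose()].
#' A warning (not a hard gate) is issued when the sample's u statistic is
#' not significantly overdispersed, since underdispersion can mask
#' zero inflation and the u-test must be used with caution.
#'
#' @inheritParams whole_body_dose
#' @return A `dose_estimate`.
#' @export
partial_body_dose <- function(x, fit, z = 1.96,
                              combine = c("merkle", "band", "yield"),
                              dmax = 100) {
  x <- .as_dist(x)
  s <- summary(x)
  if (!is.na(s$u) && s$u < 1.96)
    warning("u = ", round(s$u, 2), " does not indicate overdispersion; ",
            "partial-body analysis may not be appropriate")
  zf <- ztwp_fit(x)
  est <- dose_from_yield(fit, zf$yield, zf$yield_se, z = z,
                         combine = match.arg(combine), dmax = dmax,
                         method = "partial-body (zero-truncated WP)")
  est$u <- s$u
  est$ztwp <- zf
  est
}

#' Partial-body dose estimation by the Dolphin contaminated-Poisson method
#'
#' The classical estimator of the yield in the irradiated fraction: with
#' N scored cells, n0 of them without dicentrics and X dicentrics in
#' total, the irradiated-fraction yield solves
#' \deqn{\frac{Y_F}{1 - e^{-Y_F}} = \frac{X}{N - n_0},}
#' the estimated irradiated (cell) fraction is
#' \eqn{\hat f = (X / Y_F) / N}, and the dose inverts the classical
#' calibration curve at \eqn{Y_F} with Merkle limits.  The yield SE is a
#' ratio-estimator delta method propagated through the inverse of
#' \eqn{h(Y) = Y/(1 - e^{-Y})}.
#'
#' @param x a [dicentric_dist] or count vector.
#' @param fit a [classical_fit] calibration curve (the method is defined
#'   for the classical Poisson framework).
#' @inheritParams dose_from_yield
#' @return A `dose_estimate` with an extra `fraction` element.
#' @examples
#' lin <- classical_curve("linear", alpha = 0.4034, se = c(alpha = 0.0056))
#' part <- dicentric_dist(c(201, 8, 34, 28, 19, 7, 1, 0, 1, 0, 1))
#' dolphin_dose(part, lin)
#' @export
dolphin_dose <- function(x, fit, z = 1.96,
                         combine = c("merkle", "band", "yield"),
                         dmax = 100) {
  x <- .as_dist(x)
  k <- seq_along(x$counts) - 1
  N <- sum(x$counts); n0 <- x$counts[1]; X <- sum(k * x$counts)
  if (N - n0 < 1 || X < 1)
    stop("Dolphin method needs at least one cell with dicentrics",
         call. = FALSE)
  ratio <- X / (N - n0)
  if (ratio <= 1)
    stop("Dolphin method inapplicable: X/(N - n0) = ", signif(ratio, 4),
         " <= 1 (no excess of zero-dicentric cells)", call. = FALSE)
  h <- function(y) y / (1 - exp(-y))
  Yf <- stats::uniroot(function(y) h(y) - ratio, c(1e-10, 100),
                       tol = 1e-12)$root
  # ratio-estimator variance of X/(N - n0) over i.i.d. cells, then the
  # delta method through h^{-1}
  kbar <- X / N; pbar <- (N - n0) / N
  s_kk <- sum(x$counts * (k - kbar)^2) / (N - 1)
  ind <- as.numeric(k > 0)
  s_ii <- sum(x$counts * (ind - pbar)^2) / (N - 1)
  s_ki <- sum(x$counts * (k - kbar) * (ind - pbar)) / (N - 1)
  var_ratio <- (s_kk - 2 * ratio * s_ki + ratio^2 * s_ii) / (N * pbar^2)
  hprime <- (1 - exp(-Yf) - Yf * exp(-Yf)) / (1 - exp(-Yf))^2
  Yf_se <- sqrt(max(0, var_ratio)) / hprime
  est <- dose_from_yield(fit, Yf, Yf_se, z = z, combine = match.arg(combine),
                         dmax = dmax, method = "partial-body (Dolphin)")
  est$fraction <- (X / Yf) / N
  est$u <- summary(x)$u
  est
}
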