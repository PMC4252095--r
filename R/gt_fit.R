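#' Gompertz-type dose-response pieces
#'
#' Under the GT model the weighted-Poisson rate follows a saturating
#' Gompertz curve of the dose,
#' \eqn{\lambda(d) = \beta_0 \exp\{-\beta_1 \exp(-\beta_2 d)\}}, and the
#' weight parameter grows linearly, \eqn{b(d) = \beta_3 d} (no intercept:
#' an unirradiated sample is pure Poisson).  The predicted dicentric yield
#' \eqn{\hat Y(d)} is the closed-form weighted-Poisson mean evaluated at
#' \eqn{(\lambda(d), b(d))}; it is a sigmoid, nondecreasing in dose and
#' bounded, which is what lets the calibration span 0-25 Gy where linear
#' and linear-quadratic curves run away from the saturating data.
#'
#' @param dose dose(s) in Gy.
#' @param fit a [gt_fit] object, or a numeric vector of the four GT
#'   coefficients (beta0, beta1, beta2, beta3).
#' @return Numeric vector: the rate \eqn{\lambda(d)}, weight \eqn{b(d)} or
#'   predicted yield \eqn{\hat Y(d)}.
#' @seealso [gt_fit()], [wpois_mean()]
#' @examples
#' p <- c(8.47, 6.85, 0.232, 1.06)
#' gt_lambda(c(0, 10, 25), p)
#' gt_yield(c(0, 10, 25), p)
#' @export
gt_lambda <- function(dose, fit) {
  p <- .gt_coefs(fit)
  p[1] * exp(-p[2] * exp(-p[3] * dose))
}

#' @rdname gt_lambda
#' @export
gt_b <- function(dose, fit) {
  p <- .gt_coefs(fit)
  p[4] * dose
}

#' @rdname gt_lambda
#' @export
gt_yield <- function(dose, fit) {
  p <- .gt_coefs(fit)
  vapply(dose, function(d) wpois_mean(gt_lambda(d, p), p[4] * d), numeric(1))
}

.gt_coefs <- function(fit) {
  p <- if (inherits(fit, "gt_fit")) fit$coefficients else as.numeric(fit)
  if (length(p) != 4 || any(!is.finite(p)))
    stop("GT coefficients must be 4 finite numbers", call. = FALSE)
  if (p[1] <= 0 || p[3] <= 0 || p[4] < 0)
    stop("invalid GT coefficients: need beta0 > 0, beta2 > 0, beta3 >= 0",
         call. = FALSE)
  unname(p)
}

# cell-level negative log-likelihood on the log-parameter scale
.gt_nll <- function(theta, cal) {
  p <- exp(theta)
  tot <- 0
  for (d in cal) {
    lam <- p[1] * exp(-p[2] * exp(-p[3] * d$dose))
    b <- p[4] * d$dose
    k <- seq_along(d$counts) - 1
    lp <- stats::dpois(k, lam, log = TRUE) + log1p(b * k^2) -
      log1p(b * lam * (1 + lam))
    tot <- tot - sum(d$counts * lp)
  }
  if (!is.finite(tot)) 1e12 else tot
}

.gt_default_starts <- function(cal) {
  ymax <- max(vapply(cal, function(d) summary(d)$Y, numeric(1)), 0.5)
  list(c(1.1 * ymax, 6, 0.2, 1),
       c(1.1 * ymax, 6, 0.3, 1e-3),   # near-Poisson start
       c(1.5 * ymax, 4, 0.1, 2),
       c(2.0 * ymax, 8, 0.15, 0.3),
       c(1.05 * ymax, 5, 0.5, 5))
}

# SVD pseudo-inverse fallback for near-singular information matrices
.pinv <- function(H, tol = 1e-10) {
  s <- svd(H)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(NA_real_, nrow(H), ncol(H)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

.new_gt_fit <- function(coefficients, vcov = NULL, loglik = NA, data = NULL,
                        convergence = NA, starts = NULL, singular = FALSE) {
  names(coefficients) <- c("beta0", "beta1", "beta2", "beta3")
  structure(list(coefficients = coefficients, vcov = vcov, loglik = loglik,
                 data = data, convergence = convergence, starts = starts,
                 singular_hessian = singular,
                 data_fingerprint = if (!is.null(data)) .data_fingerprint(data)),
            class = "gt_fit")
}

#' Fit the Gompertz-type weighted-Poisson dose-response by maximum likelihood
#'
#' Maximizes the cell-level log-likelihood
#' \eqn{\sum_d \sum_k n_{d,k} \log P\{X = k;\, \lambda(d), b(d)\}}
#' over the four GT parameters.  Optimization runs on the log scale (all
#' four parameters positive), with a quasi-Newton optimizer from several
#' dispersed starting points including a near-Poisson start; the best
#' converged optimum is kept.  The covariance matrix is the inverse of the
#' observed information (numerical Hessian at the optimum), mapped back to
#' the natural scale; a pseudo-inverse is used, with a flag, when the
#' Hessian is near-singular.
#'
#' @param data a [calibration_data] object (>= 4 distinct doses with cells).
#' @param starts optional list of starting parameter vectors
#'   (natural scale, length 4); defaults to five dispersed starts derived
#'   from the maximum observed yield.
#' @param tol relative convergence tolerance on the objective.
#' @return An object of class `gt_fit` with components `coefficients`
#'   (beta0..beta3), `vcov`, `loglik`, `data`, `convergence` and `starts`
#'   (a data frame of per-start objective values).  Methods: `print`,
#'   `summary`, `coef`, `vcov`, `logLik`, `predict`, `plot`, `simulate`,
#'   `residuals`.
#' @examples
#' cal <- read_distribution_table(
#'   system.file("extdata", "calibration_dicentrics.tsv", package = "gtdose"))
#' fit <- gt_fit(cal)
#' coef(fit)
#' predict(fit, dose = c(2, 6, 12), se.fit = TRUE)
#' @export
gt_fit <- function(data, starts = NULL, tol = 1e-12) {
  cal <- .as_calibration(data)
  if (length(cal) < 4)
    stop("GT fit is underdetermined: need at least 4 distinct doses",
         call. = FALSE)
  if (is.null(starts)) starts <- .gt_default_starts(cal)
  runs <- lapply(starts, function(s) {
    tryCatch(stats::optim(log(s), .gt_nll, cal = cal, method = "BFGS",
                          control = list(maxit = 2000, reltol = tol)),
             error = function(e) NULL)
  })
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok))
    stop("GT fit failed to converge from every start", call. = FALSE)
  vals <- vapply(runs[ok], `[[`, numeric(1), "value")
  best <- runs[ok][[which.min(vals)]]
  if (best$convergence != 0)
    warning("optimizer reported non-convergence (code ", best$convergence, ")")
  p <- exp(best$par)
  H <- stats::optimHess(best$par, .gt_nll, cal = cal)
  Vt <- tryCatch(solve(H), error = function(e) NULL)
  singular <- is.null(Vt)
  if (singular) {
    warning("singular Hessian: covariance from pseudo-inverse")
    Vt <- .pinv(H)
  }
  J <- diag(p)
  V <- J %*% Vt %*% t(J)
  dimnames(V) <- list(c("beta0", "beta1", "beta2", "beta3"),
                      c("beta0", "beta1", "beta2", "beta3"))
  nll_end <- rep(NA_real_, length(starts))
  nll_end[ok] <- vapply(runs[ok], `[[`, numeric(1), "value")
  start_report <- data.frame(
    t(vapply(starts, as.numeric, numeric(4))),
    nll_start = vapply(starts, function(s) .gt_nll(log(s), cal), numeric(1)),
    nll_end = nll_end)
  names(start_report)[1:4] <- c("beta0", "beta1", "beta2", "beta3")
  .new_gt_fit(p, vcov = V, loglik = -best$value, data = cal,
              convergence = best$convergence, starts = start_report,
              singular = singular)
}

#' @export
coef.gt_fit <- function(object, ...) object$coefficients

#' @export
vcov.gt_fit <- function(object, ...) object$vcov

#' @export
logLik.gt_fit <- function(object, ...) {
  n <- if (!is.null(object$data))
    sum(vapply(object$data, function(d) sum(d$counts), numeric(1))) else NA
  structure(object$loglik, df = 4, nobs = n, class = "logLik")
}

#' @export
print.gt_fit <- function(x, digits = 4, ...) {
  cat("Gompertz-type weighted-Poisson dose-response\n")
  cat("  lambda(d) = beta0 * exp(-beta1 * exp(-beta2 * d)),  b(d) = beta3 * d\n\n")
  print(round(x$coefficients, digits))
  if (!is.na(x$loglik)) cat("log-likelihood:", format(x$loglik), "\n")
  invisible(x)
}

#' @export
summary.gt_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(pmax(diag(object$vcov), 0))
        else rep(NA_real_, 4)
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se)
  structure(list(coefficients = tab, loglik = object$loglik,
                 convergence = object$convergence,
                 singular = object$singular_hessian),
            class = "summary.gt_fit")
}

#' @export
print.summary.gt_fit <- function(x, ...) {
  cat("Gompertz-type weighted-Poisson dose-response (ML on cell-level counts)\n\n")
  stats::printCoefmat(x$coefficients)
  cat("\nlog-likelihood:", format(x$loglik),
      " convergence code:", x$convergence, "\n")
  if (isTRUE(x$singular)) cat("note: covariance from pseudo-inverse\n")
  invisible(x)
}

# delta-method prediction SE shared by gt_fit and classical_fit:
# s(d) = sqrt(g' V g), g the numerical gradient of the yield in the
# coefficients (central differences, step scaled to the coefficient).
.pred_se <- function(fit, dose) {
  V <- stats::vcov(fit)
  if (is.null(V) || any(!is.finite(V)))
    stop("prediction SE needs a parameter covariance matrix", call. = FALSE)
  p <- stats::coef(fit)
  yf <- function(pp, d) .yield_with_coefs(fit, pp, d)
  vapply(dose, function(d) {
    g <- vapply(seq_along(p), function(i) {
      h <- max(1e-7, 1e-6 * abs(p[i]))
      pp <- pm <- p
      pp[i] <- p[i] + h; pm[i] <- p[i] - h
      (yf(pp, d) - yf(pm, d)) / (2 * h)
    }, numeric(1))
    sqrt(max(0, drop(t(g) %*% V %*% g)))
  }, numeric(1))
}

.yield_with_coefs <- function(fit, p, d) {
  if (inherits(fit, "gt_fit")) {
    wpois_mean(max(p[1] * exp(-p[2] * exp(-p[3] * d)), 1e-300),
               max(p[4], 0) * d)
  } else {
    .classical_mu(p, d, fit$model, fit$intercept)
  }
}

# number of fitted parameters -> band constant R = sqrt(chisq_{0.95, p})
.npar <- function(fit) {
  if (inherits(fit, "gt_fit")) 4L else length(stats::coef(fit))
}

#' Band constant for simultaneous calibration-curve limits
#'
#' \eqn{R = \sqrt{\chi^2_{0.95, p}}} with p the number of fitted
#' parameters: the curve band \eqn{\hat Y(d) \pm R\,s(d)} then has joint
#' 95\% coverage (R = 3.0802 for the 4-parameter GT model, 1.96 for a
#' 1-parameter linear curve).
#'
#' @param fit a fitted curve, or an integer number of parameters.
#' @param level band confidence level.
#' @return The band constant R.
#' @export
band_constant <- function(fit, level = 0.95) {
  p <- if (is.numeric(fit)) as.integer(fit) else .npar(fit)
  sqrt(stats::qchisq(level, df = p))
}

#' Predict dicentric yields from a fitted calibration curve
#'
#' @param object a [gt_fit] or [classical_fit] object.
#' @param dose doses (Gy) at which to predict.
#' @param se.fit also return the delta-method prediction SE.
#' @param interval `"none"` or `"band"`: the simultaneous confidence band
#'   \eqn{\hat Y(d) \pm R\,s(d)} with R from [band_constant()].
#' @param level band confidence level.
#' @param ... unused.
#' @return A numeric vector of yields, or a data frame with columns
#'   `dose`, `fit` and (as requested) `se.fit`, `lower`, `upper`.
#' @export
predict.gt_fit <- function(object, dose, se.fit = FALSE,
                           interval = c("none", "band"), level = 0.95, ...) {
  .predict_curve(object, dose, se.fit, match.arg(interval), level)
}

.predict_curve <- function(object, dose, se.fit, interval, level) {
  fit <- .curve_yield(object, dose)
  if (!se.fit && interval == "none") return(fit)
  out <- data.frame(dose = dose, fit = fit)
  if (se.fit || interval == "band") s <- .pred_se(object, dose)
  if (se.fit) out$se.fit <- s
  if (interval == "band") {
    R <- band_constant(object, level)
    out$lower <- fit - R * s
    out$upper <- fit + R * s
  }
  out
}

.curve_yield <- function(fit, dose) {
  if (inherits(fit, "gt_fit") || is.numeric(fit)) gt_yield(dose, fit)
  else vapply(dose, function(d)
    .classical_mu(stats::coef(fit), d, fit$model, fit$intercept), numeric(1))
}

#' @export
residuals.gt_fit <- function(object, ...) {
  if (is.null(object$data)) stop("fit carries no data", call. = FALSE)
  df <- as.data.frame(object$data)
  e <- df$N * gt_yield(df$dose, object)
  (df$X - e) / sqrt(e)
}

#' @export
plot.gt_fit <- function(x, dmax = NULL, ...) {
  df <- if (!is.null(x$data)) as.data.frame(x$data) else NULL
  if (is.null(dmax)) dmax <- if (!is.null(df)) max(df$dose) * 1.05 else 25
  dd <- seq(0, dmax, length.out = 200)
  pr <- .predict_curve(x, dd, se.fit = FALSE, interval = "band", level = 0.95)
  graphics::plot(dd, pr$fit, type = "l", lwd = 2, xlab = "Dose (Gy)",
                 ylab = "Dicentrics per cell",
                 ylim = range(0, pr$upper, if (!is.null(df)) df$Y), ...)
  graphics::lines(dd, pr$lower, lty = 2)
  graphics::lines(dd, pr$upper, lty = 2)
  if (!is.null(df)) graphics::points(df$dose, df$Y, pch = 19)
  invisible(x)
}

#' Simulate calibration datasets from a fitted GT curve
#'
#' @param object a [gt_fit] object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed (expanded to per-dose substreams).
#' @param doses,cells design; default to the fitted data's design.
#' @param ... unused.
#' @return A list of `nsim` [calibration_data] objects (a single object
#'   when `nsim = 1`).
#' @export
simulate.gt_fit <- function(object, nsim = 1, seed = NULL,
                            doses = NULL, cells = NULL, ...) {
  if (is.null(doses) || is.null(cells)) {
    if (is.null(object$data))
      stop("fit carries no data: supply 'doses' and 'cells'", call. = FALSE)
    df <- as.data.frame(object$data)
    if (is.null(doses)) doses <- df$dose
    if (is.null(cells)) cells <- df$N
  }
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  sims <- lapply(seq_len(nsim), function(i)
    simulate_whole_body(object, doses, cells, seed = seed + (i - 1) * 10000L))
  if (nsim == 1) sims[[1]] else sims
}
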