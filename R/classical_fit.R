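#' Classical linear and linear-quadratic Poisson calibration curves
#'
#' Fits the conventional dicentric dose-response
#' \eqn{Y(d) = C + \alpha d} (linear) or
#' \eqn{Y(d) = C + \alpha d + \beta d^2} (linear-quadratic) by maximum
#' likelihood under the usual Poisson assumption for the per-dose
#' dicentric totals, \eqn{X_d \sim Poisson\{N_d Y(d)\}}.
#'
#' When an intercept is requested, rows at zero dose are dropped from the
#' likelihood (an identity-link Poisson likelihood is undefined wherever
#' the fitted mean is non-positive, and a free intercept must be able to
#' go negative to be diagnostic).  If the fitted intercept comes out
#' negative the curve is automatically refitted without it and the event
#' is recorded in the returned object (`$refit_without_intercept`) — the
#' standard procedure when the basal frequency coefficient is not
#' estimable from high-dose calibration data.
#'
#' Without an intercept the linear model has the closed-form ML solution
#' \eqn{\hat\alpha = \sum_d X_d / \sum_d N_d d}; the linear-quadratic
#' coefficients are found numerically.
#'
#' @param data a [calibration_data] object.
#' @param model `"linear"` or `"linear-quadratic"`.
#' @param intercept fit a basal-frequency intercept C?
#' @return An object of class `classical_fit` with `coefficients`
#'   (`C` if kept, `alpha`, `beta` for LQ), `vcov`, `loglik`, `model`,
#'   `intercept`, `refit_without_intercept` and the data.  Shares the
#'   `predict`/`print`/`summary`/`coef`/`vcov`/`logLik` methods of
#'   [gt_fit()].
#' @examples
#' cal <- read_distribution_table(
#'   system.file("extdata", "calibration_dicentrics.tsv", package = "gtdose"))
#' classical_fit(cal, "linear", intercept = FALSE)
#' @export
classical_fit <- function(data, model = c("linear", "linear-quadratic"),
                          intercept = TRUE) {
  model <- match.arg(model)
  cal <- .as_calibration(data)
  df <- as.data.frame(cal)
  npar_min <- if (model == "linear") 2L else 3L
  if (nrow(df) < npar_min)
    stop("need at least ", npar_min, " doses for a ", model, " fit",
         call. = FALSE)
  if (all(df$X == 0)) stop("degenerate fit: no dicentrics observed",
                           call. = FALSE)
  refit <- FALSE
  if (intercept) {
    f <- .classical_ml(df[df$dose > 0, , drop = FALSE], model,
                       intercept = TRUE)
    if (f$coefficients[["C"]] < 0) {
      message("fitted intercept C = ", signif(f$coefficients[["C"]], 3),
              " < 0: refitting without intercept")
      refit <- TRUE
      intercept <- FALSE
    }
  }
  if (!intercept) f <- .classical_ml(df, model, intercept = FALSE)
  structure(c(f, list(model = model, intercept = intercept,
                      refit_without_intercept = refit, data = cal,
                      data_fingerprint = .data_fingerprint(cal))),
            class = "classical_fit")
}

.classical_mu <- function(p, d, model, intercept) {
  mu <- if (intercept) p[["C"]] else 0
  mu <- mu + p[["alpha"]] * d
  if (model == "linear-quadratic") mu <- mu + p[["beta"]] * d^2
  mu
}

.classical_ml <- function(df, model, intercept) {
  nms <- c(if (intercept) "C", "alpha", if (model == "linear-quadratic") "beta")
  # zero-dose rows of a no-intercept curve have mean 0 identically: their
  # log-likelihood term is constant in the parameters and is dropped
  keep <- intercept | df$dose > 0
  nll <- function(p) {
    names(p) <- nms
    mu <- df$N[keep] * vapply(df$dose[keep], function(d)
      .classical_mu(p, d, model, intercept), numeric(1))
    if (any(mu <= 0 & df$X[keep] > 0)) return(1e12)
    use <- mu > 0
    -sum(df$X[keep][use] * log(mu[use]) - mu[use])
  }
  if (!intercept && model == "linear") {
    # closed-form score solution; dose-0 rows contribute only to the total
    alpha <- sum(df$X) / sum(df$N * df$dose)
    info <- sum(df$N * df$dose) / alpha
    co <- c(alpha = alpha)
    V <- matrix(1 / info, 1, 1, dimnames = list("alpha", "alpha"))
    ll <- -nll(co)
  } else {
    start <- stats::setNames(c(if (intercept) 0.01, 0.2,
                               if (model == "linear-quadratic") 0.01), nms)
    opt <- stats::optim(start, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
    opt <- stats::optim(opt$par, nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-13))
    co <- stats::setNames(opt$par, nms)
    H <- stats::optimHess(co, nll)
    V <- tryCatch(solve(H), error = function(e) .pinv(H))
    dimnames(V) <- list(nms, nms)
    ll <- -opt$value
  }
  list(coefficients = co, vcov = V, loglik = ll, convergence = 0L)
}

#' Build a classical curve from published coefficients
#'
#' Wraps externally supplied (e.g. published) linear or linear-quadratic
#' coefficients in a `classical_fit` object so they can be used for
#' prediction, goodness-of-fit and dose estimation.  Standard errors, if
#' given, populate a diagonal covariance (no published covariances).
#'
#' @param model `"linear"` or `"linear-quadratic"`.
#' @param alpha linear coefficient (dicentrics per cell per Gy).
#' @param beta quadratic coefficient (per Gy^2), LQ only.
#' @param C optional basal frequency intercept.
#' @param se optional named vector of standard errors.
#' @param vcov optional full covariance matrix (overrides `se`).
#' @return A `classical_fit` object without data.
#' @examples
#' lin <- classical_curve("linear", alpha = 0.4034, se = c(alpha = 0.0056))
#' predict(lin, dose = c(1, 5, 10))
#' @export
classical_curve <- function(model = c("linear", "linear-quadratic"),
                            alpha, beta = NULL, C = NULL, se = NULL,
                            vcov = NULL) {
  model <- match.arg(model)
  intercept <- !is.null(C)
  if (model == "linear-quadratic" && is.null(beta))
    stop("linear-quadratic curve needs 'beta'", call. = FALSE)
  co <- c(if (intercept) c(C = C), alpha = alpha,
          if (model == "linear-quadratic") c(beta = beta))
  if (is.null(vcov)) {
    vcov <- diag(length(co)) * 0
    if (!is.null(se)) {
      se <- se[names(co)]
      se[is.na(se)] <- 0
      vcov <- diag(se^2, length(co))
    }
    dimnames(vcov) <- list(names(co), names(co))
  }
  structure(list(coefficients = co, vcov = vcov, loglik = NA_real_,
                 convergence = NA_integer_, model = model,
                 intercept = intercept, refit_without_intercept = FALSE,
                 data = NULL),
            class = "classical_fit")
}

#' @export
coef.classical_fit <- function(object, ...) object$coefficients

#' @export
vcov.classical_fit <- function(object, ...) object$vcov

#' @export
logLik.classical_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.classical_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s Poisson dose-response%s\n", x$model,
              if (x$intercept) " (with intercept)" else ""))
  print(round(x$coefficients, digits))
  if (x$refit_without_intercept)
    cat("note: negative fitted intercept; refitted without intercept\n")
  invisible(x)
}

#' @export
summary.classical_fit <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `z value` = object$coefficients / se)
  structure(list(coefficients = tab, model = object$model,
                 loglik = object$loglik,
                 refit = object$refit_without_intercept),
            class = "summary.classical_fit")
}

#' @export
print.summary.classical_fit <- function(x, ...) {
  cat(x$model, "Poisson dose-response (ML on per-dose totals)\n\n")
  stats::printCoefmat(x$coefficients)
  if (!is.na(x$loglik)) cat("\nlog-likelihood:", format(x$loglik), "\n")
  if (isTRUE(x$refit))
    cat("note: negative fitted intercept; refitted without intercept\n")
  invisible(x)
}

#' @rdname predict.gt_fit
#' @export
predict.classical_fit <- function(object, dose, se.fit = FALSE,
                                  interval = c("none", "band"),
                                  level = 0.95, ...) {
  .predict_curve(object, dose, se.fit, match.arg(interval), level)
}

#' @export
residuals.classical_fit <- function(object, ...) {
  if (is.null(object$data)) stop("fit carries no data", call. = FALSE)
  df <- as.data.frame(object$data)
  e <- df$N * .curve_yield(object, df$dose)
  ifelse(e > 0, (df$X - e) / sqrt(e), NA_real_)
}
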