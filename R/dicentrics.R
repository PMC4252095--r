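#' Dicentric cell-count distributions
#'
#' A `dicentric_dist` holds the histogram of dicentrics per cell for one
#' scored sample: `counts[k + 1]` is the number of cells in which exactly
#' `k` dicentrics were observed.  The dose (if known), the irradiated
#' blood fraction (1 for whole-body samples) and a free-text label travel
#' with the counts.
#'
#' @param counts non-negative integer vector of cell counts by number of
#'   dicentrics, starting at zero dicentrics.
#' @param dose dose in Gy, or `NA` when unknown (field samples).
#' @param fraction fraction of irradiated blood in (0, 1]; 1 = whole body.
#' @param label optional sample label.
#' @return An object of class `dicentric_dist`.
#' @examples
#' d10 <- dicentric_dist(c(0, 0, 0, 3, 18, 40, 35, 25, 16, 9, 4), dose = 10)
#' summary(d10)
#' u_test(d10)
#' @export
dicentric_dist <- function(counts, dose = NA_real_, fraction = 1, label = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) < 1 || any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  if (sum(counts) < 1) stop("at least one cell is required", call. = FALSE)
  if (!is.na(fraction) && (fraction <= 0 || fraction > 1))
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  structure(list(counts = counts, dose = as.numeric(dose),
                 fraction = fraction, label = label),
            class = "dicentric_dist")
}

.as_dist <- function(x) {
  if (inherits(x, "dicentric_dist")) return(x)
  if (is.numeric(x)) return(dicentric_dist(x))
  stop("expected a 'dicentric_dist' or a count vector", call. = FALSE)
}

#' @export
print.dicentric_dist <- function(x, ...) {
  s <- summary(x)
  cat("Dicentric distribution",
      if (!is.null(x$label)) paste0("[", x$label, "]"),
      if (!is.na(x$dose)) sprintf("dose = %g Gy", x$dose),
      if (!is.na(x$fraction) && x$fraction < 1)
        sprintf("(%.0f%% irradiated)", 100 * x$fraction), "\n")
  k <- seq_along(x$counts) - 1L
  print(stats::setNames(as.integer(x$counts), k))
  cat(sprintf("N = %d cells, X = %d dicentrics, Y = %.4f, DI = %.3f, u = %.2f\n",
              s$N, s$X, s$Y, s$DI, s$u))
  invisible(x)
}

#' Summary statistics of a dicentric distribution
#'
#' Computes the cell total N, dicentric total X, yield Y = X/N, the sample
#' variance (N - 1 denominator), the standard error of the yield
#' \eqn{\sqrt{Var/N}}, the dispersion index DI = Var/Y and the u-test
#' statistic.  All derived quantities use full-precision intermediates.
#'
#' @param object,x a [dicentric_dist] (or bare count vector).
#' @param ... unused.
#' @return A list of class `summary.dicentric_dist` with elements
#'   `N`, `X`, `Y`, `Var`, `SE`, `DI`, `u`.
#' @export
summary.dicentric_dist <- function(object, ...) {
  x <- .as_dist(object)
  k <- seq_along(x$counts) - 1
  N <- sum(x$counts)
  X <- sum(k * x$counts)
  Y <- X / N
  if (N >= 2) {
    Var <- (sum(k^2 * x$counts) - N * Y^2) / (N - 1)
    SE <- sqrt(Var / N)
  } else Var <- SE <- NA_real_
  DI <- if (is.na(Var) || Y == 0) NA_real_ else Var / Y
  u <- if (X >= 2 && N >= 2 && !is.na(DI))
    (DI - 1) * sqrt((N - 1) / (2 * (1 - 1 / X))) else NA_real_
  structure(list(N = as.integer(N), X = as.integer(X), Y = Y, Var = Var,
                 SE = SE, DI = DI, u = u),
            class = "summary.dicentric_dist")
}

#' @export
print.summary.dicentric_dist <- function(x, ...) {
  cat(sprintf("N = %d  X = %d  Y = %.4f  Var = %.4f  SE = %.4f  DI = %.3f  u = %.2f\n",
              x$N, x$X, x$Y, x$Var, x$SE, x$DI, x$u))
  invisible(x)
}

#' u-test for Poisson dispersion of dicentrics among cells
#'
#' The standardized dispersion statistic
#' \eqn{u = (DI - 1)\sqrt{(N-1) / \{2(1 - 1/X)\}}} (Rao-Chakravarti form,
#' as used in the IAEA cytogenetic dosimetry manual).  Values outside
#' \eqn{\pm 1.96} indicate a significant departure from the Poisson at the
#' 5\% level: negative u means underdispersion, positive u overdispersion
#' (the signature of partial-body exposure).
#'
#' @param x a [dicentric_dist] or count vector.
#' @return The u statistic (numeric scalar).
#' @export
u_test <- function(x) {
  s <- summary(.as_dist(x))
  if (s$X < 2) stop("u statistic undefined for fewer than 2 dicentrics",
                    call. = FALSE)
  s$u
}

#' Expected cell distribution under the Poisson assumption
#'
#' Expected number of cells with k dicentrics, `N * dpois(k, Y)`, using
#' the observed sample yield; the reference against which underdispersion
#' is judged.  Values are unrounded; round half-up for display.
#'
#' @param x a [dicentric_dist] or count vector.
#' @param kmax highest count class to report (default: observed classes).
#' @return Numeric vector of expected cell counts for k = 0..kmax.
#' @export
poisson_expected <- function(x, kmax = NULL) {
  x <- .as_dist(x)
  s <- summary(x)
  if (is.null(kmax)) kmax <- length(x$counts) - 1L
  s$N * stats::dpois(0:kmax, s$Y)
}

#' Convert a polycentric chromosome to dicentric equivalents
#'
#' A chromosome with n centromeres is scored as n - 1 dicentric
#' equivalents (a tricentric counts as 2, a monocentric as 0).
#'
#' @param n_centromeres integer vector, number of centromeres (>= 1).
#' @return Integer vector of dicentric equivalents.
#' @export
polycentrics_to_dicentrics <- function(n_centromeres) {
  if (any(n_centromeres < 1) || any(n_centromeres != round(n_centromeres)))
    stop("'n_centromeres' must be integers >= 1", call. = FALSE)
  as.integer(n_centromeres) - 1L
}
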