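#' Goodness of fit of a calibration curve by per-dose Pearson chi-square
#'
#' For each calibration dose the statistic
#' \eqn{\chi^2_d = (X_d - N_d \hat Y(d))^2 / \{N_d \hat Y(d)\}} compares
#' the observed dicentric total with the curve's expectation; doses where
#' the expected yield is exactly zero (a no-intercept classical curve at
#' dose 0) are excluded.  The total over included doses is the summary
#' measure used to compare calibration models.
#'
#' @param data a [calibration_data] object.
#' @param fit a [gt_fit] or [classical_fit] object.
#' @return A data frame with columns `dose`, `observed`, `expected`,
#'   `chisq` (NA where excluded), with the total in
#'   `attr(, "total")`.
#' @examples
#' cal <- read_distribution_table(
#'   system.file("extdata", "calibration_dicentrics.tsv", package = "gtdose"))
#' gof <- chi2_goodness(cal, gt_fit(cal))
#' attr(gof, "total")
#' @export
chi2_goodness <- function(data, fit) {
  df <- as.data.frame(.as_calibration(data))
  e <- df$N * .curve_yield(fit, df$dose)
  chisq <- ifelse(e > 0, (df$X - e)^2 / e, NA_real_)
  out <- data.frame(dose = df$dose, observed = df$X, expected = e,
                    chisq = chisq)
  attr(out, "total") <- sum(chisq, na.rm = TRUE)
  out
}
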