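# Published reference tables and independent oracles used across tests.

fixture <- function(name) system.file("extdata", name, package = "gtdose")

load_calibration <- function() {
  read_distribution_table(fixture("calibration_dicentrics.tsv"))
}
load_samples <- function() {
  read_distribution_table(fixture("exposure_samples.tsv"))
}
load_caffeine <- function() {
  read_distribution_table(fixture("caffeine_timecourse.tsv"))
}

# Published summary columns (Y, Var, SE, DI, u) as printed, stored as
# strings so each cell is compared at its own printed precision.
printed_calibration_stats <- data.frame(
  dose = c(0, 0.1, 0.5, 1, 3, 5, 7, 10, 15, 20, 25),
  Y = c("0.001", "0.006", "0.039", "0.120", "0.786", "2.547", "4.027",
        "6.100", "8.340", "9.570", "10.650"),
  Var = c("0.001", "0.005", "0.037", "0.118", "0.641", "1.578", "2.697",
          "2.493", "6.792", "7.985", "10.008"),
  SE = c("0.001", "0.002", "0.004", "0.011", "0.036", "0.103", "0.134",
         "0.129", "0.261", "0.283", "0.316"),
  DI = c("1.00", "0.99", "0.96", "0.98", "0.82", "0.62", "0.67", "0.41",
         "0.81", "0.83", "0.94"),
  u = c(NA, "-0.17", "-1.23", "-0.43", "-2.91", "-3.29", "-2.85", "-5.11",
        "-1.31", "-1.17", "-0.42"),
  stringsAsFactors = FALSE)

printed_sample_stats <- data.frame(
  label = c("2Gy-100", "6Gy-30", "6Gy-70", "6Gy-100", "12Gy-30", "12Gy-70",
            "12Gy-100", "17Gy-100"),
  Y = c("0.311", "0.273", "0.983", "2.833", "0.412", "1.04", "5.793", "9.14"),
  SE = c("0.024", "0.051", "0.094", "0.11", "0.101", "0.2", "0.165", "0.249"),
  DI = c("0.88", "3.75", "2.67", "0.65", "6.15", "5.77", "0.7", "0.68"),
  u = c("-1.83", "38.97", "20.45", "-3.06", "57.71", "41.28", "-2.57",
        "-2.25"),
  stringsAsFactors = FALSE)

printed_caffeine_stats <- data.frame(
  label = c("48h", "51h", "54h", "57h", "60h", "72h"),
  Y = c("7.167", "7.493", "7.053", "6.100", "5.733", "4.167"),
  Var = c("4.502", "4.963", "3.554", "2.493", "3.687", "2.985"),
  SE = c("0.173", "0.182", "0.154", "0.129", "0.157", "0.141"),
  DI = c("0.63", "0.66", "0.50", "0.41", "0.64", "0.72"),
  u = c("-3.21", "-2.92", "-4.28", "-5.11", "-3.08", "-2.45"),
  stringsAsFactors = FALSE)

# Published GT coefficients and SEs
printed_gt <- c(beta0 = 8.4716, beta1 = 6.8462, beta2 = 0.2318,
                beta3 = 1.0623)
printed_gt_se <- c(0.2097, 0.1204, 0.0051, 0.1764)

# Published per-dose goodness-of-fit chi-square values
printed_chisq <- data.frame(
  dose = c(0, 0.1, 0.5, 1, 3, 5, 7, 10, 15, 20, 25),
  lq = c(NA, 29.4, 118.1, 72.6, 2.3, 96.6, 178.4, 100.3, 43.6, 3.7, 97.2),
  linear = c(NA, 60.2, 262.6, 199.2, 74.5, 20.8, 76.7, 63.9, 86.4, 27.8, 3.1),
  gt = c(16.1, 6.5, 6.2, 22.8, 10.5, 2.3, 1.2, 0, 1.7, 0.6, 2.1))

# Published Poisson-expected bracket counts for the calibration rows
# (count classes 0..14; the >= 15 tail is spread over footnote classes)
printed_poisson_expected <- list(
  `0` = c(1998, 2), `0.1` = c(1988, 12), `0.5` = c(1924, 75, 1),
  `1` = c(887, 106, 6), `3` = c(228, 179, 70, 18, 4, 1),
  `5` = c(12, 30, 38, 32, 21, 10, 4, 2, 1),
  `7` = c(3, 11, 22, 29, 29, 24, 16, 9, 5, 2, 1),
  `10` = c(1, 4, 11, 19, 25, 26, 23, 17, 12, 7, 4, 2, 1),
  `15` = c(0, 0, 1, 2, 5, 8, 11, 13, 14, 13, 11, 8, 6, 4, 2),
  `20` = c(0, 0, 0, 1, 2, 5, 7, 10, 12, 13, 12, 11, 9, 6, 4),
  `25` = c(0, 0, 0, 1, 3, 5, 7, 10, 12, 12, 12, 11, 9, 7, 5))

# compare a computed value against a printed (rounded) one at the printed
# number of decimals
expect_printed <- function(value, printed) {
  if (is.na(printed)) return(invisible(TRUE))
  dec <- nchar(sub("^-?[0-9]*\\.?", "", printed))
  expect_true(abs(value - as.numeric(printed)) <= 0.5 * 10^(-dec) + 1e-9,
              label = sprintf("computed %.6f vs printed %s", value, printed))
}

# brute-force series oracles for the weighted Poisson (independent of the
# package's closed forms)
oracle_norm <- function(lambda, b, kmax = 500) {
  sum(exp(-lambda + (0:kmax) * log(lambda) - lfactorial(0:kmax)) *
        (1 + b * (0:kmax)^2))
}
oracle_moments <- function(lambda, b, kmax = 500) {
  k <- 0:kmax
  w <- exp(-lambda + k * log(lambda) - lfactorial(k)) * (1 + b * k^2)
  p <- w / sum(w)
  m <- sum(k * p)
  c(mean = m, var = sum((k - m)^2 * p))
}
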