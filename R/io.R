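#' Calibration datasets
#'
#' A `calibration_data` object is a list of [dicentric_dist] samples with
#' known doses, as used to fit a dose-response curve.
#'
#' @param dists list of [dicentric_dist] objects, each with a known dose.
#' @return An object of class `calibration_data`.
#' @export
calibration_data <- function(dists) {
  if (inherits(dists, "dicentric_dist")) dists <- list(dists)
  stopifnot(is.list(dists), length(dists) >= 1)
  dists <- lapply(dists, .as_dist)
  doses <- vapply(dists, function(d) d$dose, numeric(1))
  if (any(is.na(doses)))
    stop("all calibration samples need a known dose", call. = FALSE)
  if (anyDuplicated(doses))
    stop("calibration doses must be distinct", call. = FALSE)
  structure(dists[order(doses)], class = "calibration_data")
}

.as_calibration <- function(x) {
  if (inherits(x, "calibration_data")) return(x)
  if (inherits(x, "dicentric_dist")) return(calibration_data(list(x)))
  if (is.list(x)) return(calibration_data(x))
  stop("expected a 'calibration_data' object", call. = FALSE)
}

#' @export
print.calibration_data <- function(x, ...) {
  cat("Calibration dataset:", length(x), "samples\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.calibration_data <- function(x, ...) {
  do.call(rbind, lapply(x, function(d) {
    s <- summary(d)
    data.frame(dose = d$dose, fraction = d$fraction, N = s$N, X = s$X,
               Y = s$Y, Var = s$Var, SE = s$SE, DI = s$DI, u = s$u)
  }))
}

#' Read and write dicentric distribution tables
#'
#' The canonical interchange format is a rectangular TSV (UTF-8, `.`
#' decimal) with one row per sample and columns `dose` (Gy), an optional
#' `fraction` (irradiated blood fraction, defaulting to 1), an optional
#' `label`, `cells` (total scored) and count-class columns `c0`, `c1`, ...
#' giving the number of cells with 0, 1, ... dicentrics.  Row sums of the
#' count classes must equal `cells`; ragged tails are zero-padded on
#' write.
#'
#' @param path file path.
#' @param sep field separator; `"\t"` (canonical) or `","`.
#' @return `read_distribution_table` returns a [calibration_data] object
#'   when every row has a known dose and distinct doses, otherwise a plain
#'   list of [dicentric_dist].  `write_distribution_table` returns `path`
#'   invisibly.
#' @examples
#' tab <- system.file("extdata", "calibration_dicentrics.tsv", package = "gtdose")
#' cal <- read_distribution_table(tab)
#' as.data.frame(cal)
#' @export
read_distribution_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, fill = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nm <- names(df)
  ccols <- grep("^c[0-9]+$", nm, value = TRUE)
  if (!("cells" %in% nm) || !("dose" %in% nm) || length(ccols) == 0)
    stop("malformed header: need 'dose', 'cells' and count columns c0..cK",
         call. = FALSE)
  ks <- as.integer(sub("^c", "", ccols))
  ccols <- ccols[order(ks)]
  if (!identical(sort(ks), seq_len(length(ks)) - 1L))
    stop("count columns must be consecutive c0..cK", call. = FALSE)
  dists <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    counts <- as.numeric(df[i, ccols])
    counts[is.na(counts)] <- 0    # ragged tails pad with zeros
    if (any(counts < 0))
      stop(sprintf("row %d: negative counts", i), call. = FALSE)
    if (sum(counts) != df$cells[i])
      stop(sprintf("row %d: count classes sum to %d but cells = %d",
                   i, sum(counts), df$cells[i]), call. = FALSE)
    dists[[i]] <- dicentric_dist(
      counts,
      dose = df$dose[i],
      fraction = if ("fraction" %in% nm) df$fraction[i] else 1,
      label = if ("label" %in% nm) df$label[i] else NULL)
  }
  doses <- vapply(dists, `[[`, numeric(1), "dose")
  whole <- vapply(dists, function(d) isTRUE(d$fraction == 1), logical(1))
  if (!any(is.na(doses)) && !anyDuplicated(doses) && all(whole))
    calibration_data(dists) else dists
}

#' @rdname read_distribution_table
#' @param x a [calibration_data] object or list of [dicentric_dist].
#' @export
write_distribution_table <- function(x, path, sep = "\t") {
  if (inherits(x, "dicentric_dist")) x <- list(x)
  kmax <- max(vapply(x, function(d) length(d$counts), integer(1)))
  rows <- lapply(x, function(d) {
    counts <- c(d$counts, rep(0, kmax - length(d$counts)))
    cbind(data.frame(dose = d$dose, fraction = d$fraction,
                     cells = sum(d$counts)),
          as.data.frame(as.list(stats::setNames(counts,
                                                paste0("c", 0:(kmax - 1))))))
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write fitted-curve coefficient files
#'
#' Fitted calibration curves are serialized as flat JSON holding the model
#' kind, coefficients, standard errors, covariance matrix, log-likelihood,
#' convergence report and a fingerprint of the data they were fitted to.
#' `read_curve_json` reconstitutes an object usable by [predict] and the
#' dose-estimation functions.
#'
#' @param fit a [gt_fit] or [classical_fit] object.
#' @param path file path for the JSON coefficient file.
#' @return `read_curve_json` returns the reconstituted fit object.
#' @export
write_curve_json <- function(fit, path) {
  stopifnot(inherits(fit, c("gt_fit", "classical_fit")))
  out <- list(
    model_kind = if (inherits(fit, "gt_fit")) "gt" else fit$model,
    coefficients = as.list(stats::coef(fit)),
    se = as.list(sqrt(pmax(diag(stats::vcov(fit)), 0))),
    covariance = stats::vcov(fit),
    loglik = as.numeric(fit$loglik %||% NA),
    convergence = fit$convergence %||% NA,
    intercept = isTRUE(fit$intercept),
    data_fingerprint = fit$data_fingerprint %||% NULL)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_curve_json
#' @export
read_curve_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- unlist(j$coefficients)
  V <- if (!is.null(j$covariance)) as.matrix(j$covariance) else NULL
  if (!is.null(V)) dimnames(V) <- list(names(co), names(co))
  if (identical(j$model_kind, "gt")) {
    .new_gt_fit(coefficients = co, vcov = V, loglik = j$loglik,
                convergence = j$convergence)
  } else {
    classical_curve(model = j$model_kind,
                    C = if (isTRUE(j$intercept)) co[["C"]] else NULL,
                    alpha = co[["alpha"]],
                    beta = if ("beta" %in% names(co)) co[["beta"]] else NULL,
                    vcov = V)
  }
}

.data_fingerprint <- function(cal) {
  df <- as.data.frame(cal)
  list(doses = df$dose, cells = df$N, dicentrics = df$X)
}
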