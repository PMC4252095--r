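#' Simulate whole-body dicentric distributions from a GT model
#'
#' Draws cell-level dicentric counts from the weighted Poisson at
#' \eqn{(\lambda(d), b(d))} for each design dose.  A single global seed is
#' expanded to per-dose substreams keyed by position in the dose list, so
#' appending doses to a design never reshuffles the draws of the existing
#' ones.
#'
#' @param fit a [gt_fit] object or numeric GT coefficient vector.
#' @param doses doses in Gy.
#' @param cells number of cells to score at each dose (recycled).
#' @param seed integer seed.
#' @return A [calibration_data] object of simulated samples.
#' @examples
#' sim <- simulate_whole_body(c(8.47, 6.85, 0.232, 1.06),
#'                            doses = c(1, 5, 10), cells = 200, seed = 1)
#' as.data.frame(sim)
#' @export
simulate_whole_body <- function(fit, doses, cells, seed = NULL) {
  p <- .gt_coefs(fit)
  if (length(doses) < 1 || any(doses < 0))
    stop("'doses' must be non-negative", call. = FALSE)
  cells <- rep_len(cells, length(doses))
  if (any(cells < 1)) stop("'cells' must be positive", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  dists <- lapply(seq_along(doses), function(i) {
    k <- .sim_cells(p, doses[i], cells[i], fraction = 1,
                    seed = .substream(seed, i))
    dicentric_dist(k, dose = doses[i], fraction = 1)
  })
  calibration_data(dists)
}

#' Simulate a partial-body exposure
#'
#' Each scored cell is irradiated with probability `fraction` — in which
#' case its dicentric count is drawn from the weighted Poisson at the
#' design dose — and otherwise contributes zero dicentrics, producing the
#' zero-inflated mixture characteristic of partial-body exposure.
#'
#' @inheritParams simulate_whole_body
#' @param dose exposure dose in Gy.
#' @param fraction irradiated blood fraction in (0, 1].
#' @return A [dicentric_dist].
#' @examples
#' pb <- simulate_partial_body(c(8.47, 6.85, 0.232, 1.06),
#'                             dose = 12, cells = 250, fraction = 0.3,
#'                             seed = 1)
#' u_test(pb)   # strongly positive: zero-inflated overdispersion
#' @export
simulate_partial_body <- function(fit, dose, cells, fraction, seed = NULL) {
  p <- .gt_coefs(fit)
  if (fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  k <- .sim_cells(p, dose, cells, fraction, seed = .substream(seed, 1L))
  dicentric_dist(k, dose = dose, fraction = fraction)
}

# per-dose substream: deterministic function of (seed, index), kept below
# 2^31 so it is a valid integer seed
.substream <- function(seed, i) as.integer((seed + 104729 * i) %% .Machine$integer.max)

# returns a histogram vector counts[k+1]
.sim_cells <- function(p, dose, n, fraction, seed) {
  set.seed(seed)
  irr <- if (fraction < 1) stats::runif(n) < fraction else rep(TRUE, n)
  k <- integer(n)
  if (any(irr)) {
    lam <- gt_lambda(dose, p); b <- p[4] * dose
    k[irr] <- rwpois(sum(irr), lam, b)
  }
  tabulate(k + 1L, nbins = max(k) + 1L)
}
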