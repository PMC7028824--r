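#' One-step probability matrix of the non-spatial two-state chain
#'
#' The 2x2 column-stochastic matrix over a step of length `tau` for the
#' state vector `y = (r, p)` (fraction not in / in cancer state). The
#' growth entry is `1 - exp(-integral of lambda over [t, t + tau])`, which
#' for constant `lambda` is `1 - exp(-lambda * tau)`; the reverse
#' transition has probability 0 (irreversibility).
#'
#' @param rate hazard: a single non-negative number, or a function of time
#'   for a time-varying hazard.
#' @param tau positive step length.
#' @param t left endpoint of the step (only used for time-varying `rate`).
#' @export
macro_matrix <- function(rate, tau, t = 0) {
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  q <- -expm1(-integrate_rate(rate, t, t + tau))
  matrix(c(1 - q, q, 0, 1), nrow = 2L,
         dimnames = list(c("non_cancer", "cancer"), NULL))
}

integrate_rate <- function(rate, from, to) {
  if (is.function(rate)) {
    val <- stats::integrate(function(s) check_rate(rate(s)), from, to,
                            rel.tol = 1e-10)$value
    return(val)
  }
  check_rate(rate)
  rate * (to - from)
}

check_rate <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("hazard must be finite and non-negative", call. = FALSE)
  r
}

#' Evolve the non-spatial chain
#'
#' Applies the one-step matrix repeatedly, `y_{(k+1)tau} = P_tau y_{k tau}`,
#' and returns the cancer fraction `p(k tau)` for `k = 1, ..., steps`. With
#' `p(0) = 0` and constant hazard this reproduces the closed form
#' `p(k tau) = 1 - exp(-lambda * k * tau)` to machine precision.
#'
#' @inheritParams macro_matrix
#' @param steps number of steps.
#' @param y0 initial state `(r, p)`, non-negative, summing to 1.
#' @export
macro_evolve <- function(rate, tau, steps, y0 = c(1, 0)) {
  if (length(y0) != 2L || any(y0 < 0) || abs(sum(y0) - 1) > 1e-12)
    stop("`y0` must be a length-2 non-negative vector summing to 1",
         call. = FALSE)
  steps <- as.integer(steps)
  stopifnot(steps >= 1L)
  y <- as.numeric(y0)
  p <- numeric(steps)
  constant <- !is.function(rate)
  if (constant) P <- macro_matrix(rate, tau)
  for (k in seq_len(steps)) {
    if (!constant) P <- macro_matrix(rate, tau, t = (k - 1) * tau)
    y <- as.numeric(P %*% y)
    p[k] <- y[2L]
  }
  p
}

#' Closed-form cancer fraction of the non-spatial chain
#'
#' `p(t) = 1 - exp(-integral_0^t lambda(s) ds)` with `p(0) = 0`; strictly
#' increasing for positive hazard and tending to 1 (full cancer) as
#' `t -> Inf`. Vectorised over `t`.
#'
#' @inheritParams macro_matrix
#' @param t non-negative time(s).
#' @export
analytic_fraction <- function(rate, t) {
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  if (is.function(rate))
    return(vapply(t, function(ti) -expm1(-integrate_rate(rate, 0, ti)),
                  numeric(1L)))
  -expm1(-check_rate(rate) * t)
}

#' Fraction of nodes in cancer state
#'
#' @param state an [initial_state()]-style list, or a bare binary vector.
#' @export
cancer_fraction <- function(state) {
  S <- if (is.list(state)) state$S else state
  if (length(S) == 0L) stop("empty node set", call. = FALSE)
  mean(S != 0)
}

#' Root-mean-square distance between two fraction curves
#'
#' `sqrt(mean((p_n - p)^2))` over the compared points; 0 iff the curves
#' coincide at every point, `|delta|` for a constant offset `delta`.
#'
#' @param p_n,p numeric vectors of equal length.
#' @export
rms_curves <- function(p_n, p) {
  if (length(p_n) != length(p) || length(p) == 0L)
    stop("curves must be non-empty and of equal length", call. = FALSE)
  sqrt(mean((p_n - p)^2))
}

#' Validate a uniform-rate lattice run against the analytic chain
#'
#' Compares the lattice fraction `p_n(k tau)` of a trajectory produced in
#' uniform-rate validation mode (`rate_model(..., mode = "uniform")`, run
#' to all-cancer with a fixed step) against the analytic fraction
#' `p(k tau) = 1 - exp(-lambda * k * tau)` on the sampler's own step grid,
#' and reports `RMS = sqrt(sum_k (p_n - p)^2 / n_t)` where `n_t` is the
#' first step index at which all nodes are cancerous.
#'
#' @param traj a fixed-step `trajectory` run to all-cancer.
#' @param lambda the constant hazard used in the run.
#' @return object of class `validation_report`: `n`, `lambda`, `tau`,
#'   `n_t`, `rms`, and the per-step comparison `table`.
#' @export
rms_vs_analytic <- function(traj, lambda) {
  stopifnot(inherits(traj, "trajectory"))
  check_rate(lambda)
  if (traj$sampler != "fixed_tau")
    stop("validation requires the fixed-step sampler", call. = FALSE)
  counts <- traj$step_counts
  if (length(counts) == 0L || max(counts) < traj$n)
    stop("trajectory must be run to all-cancer (stop_fraction = 1)",
         call. = FALSE)
  taus <- diff(c(0, traj$step_times))
  tau <- taus[1L]
  if (any(abs(taus - tau) > 1e-9 * tau))
    stop("validation requires a constant step length", call. = FALSE)
  n_t <- which(counts == traj$n)[1L]
  k <- seq_len(n_t)
  p_n <- counts[k] / traj$n
  p <- analytic_fraction(lambda, traj$step_times[k])
  structure(list(n = traj$n, lambda = lambda, tau = tau, n_t = n_t,
                 rms = rms_curves(p_n, p),
                 table = data.frame(k = k, t = traj$step_times[k],
                                    p_n = p_n, p = p)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "validation_report: n=%d, lambda=%g, tau=%g, n_t=%d, RMS=%.4e\n",
    x$n, x$lambda, x$tau, x$n_t, x$rms))
  invisible(x)
}
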