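#' Tumor mass from volume fraction
#'
#' `m_T = rho * f * V_R`: the occupied volume fraction `f` of a reference
#' volume `V_R`, at tissue density `rho`, expressed as mass.
#'
#' @param f volume fraction in `[0, 1]`.
#' @param rho density (kg/m^3), positive.
#' @param V_R reference volume (m^3), positive.
#' @export
mass_from_fraction <- function(f, rho, V_R) {
  if (any(f < 0) || any(f > 1))
    stop("`f` must be in [0, 1]", call. = FALSE)
  if (rho <= 0 || V_R <= 0)
    stop("`rho` and `V_R` must be positive", call. = FALSE)
  rho * f * V_R
}

#' @rdname mass_from_fraction
#' @param m mass (kg), in `[0, rho * V_R]`.
#' @export
fraction_from_mass <- function(m, rho, V_R) {
  if (rho <= 0 || V_R <= 0)
    stop("`rho` and `V_R` must be positive", call. = FALSE)
  f <- m / (rho * V_R)
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("mass outside [0, rho * V_R]", call. = FALSE)
  pmin(pmax(f, 0), 1)
}

#' Edge length of the bounding cube of a volume
#' @param V volume, positive.
#' @export
box_edge_from_volume <- function(V) {
  if (any(V <= 0)) stop("`V` must be positive", call. = FALSE)
  V^(1 / 3)
}

#' Gompertz growth law
#'
#' The classical S-shaped tumor mass curve
#' `m(t) = m_inf * exp(-b * exp(-c * t))`: increasing, inflected, tending
#' to the asymptotic mass `m_inf`.
#'
#' @param t time(s) (days).
#' @param m_inf asymptotic mass, positive.
#' @param b displacement parameter, non-negative (`b = 0` gives the
#'   constant `m_inf`).
#' @param c growth-rate parameter (per day), positive.
#' @export
gompertz_mass <- function(t, m_inf, b, c) {
  if (m_inf <= 0 || c <= 0 || b < 0)
    stop("require m_inf > 0, c > 0, b >= 0", call. = FALSE)
  m_inf * exp(-b * exp(-c * t))
}

#' Observed growth curve container
#'
#' @param time strictly increasing times (days).
#' @param mass non-negative masses (kg), bounded by `rho * V_R`.
#' @param rho tissue density (kg/m^3).
#' @param V_R reference (end) volume (m^3).
#' @return data.frame of class `growth_curve` with attributes `rho`, `V_R`.
#' @export
growth_curve <- function(time, mass, rho = 1000, V_R = max(mass) / rho) {
  if (length(time) != length(mass) || length(time) < 2L)
    stop("need matching time/mass vectors of length >= 2", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(mass < 0) || any(mass > rho * V_R * (1 + 1e-9)))
    stop("masses must lie in [0, rho * V_R]", call. = FALSE)
  structure(data.frame(time = time, mass = mass),
            rho = rho, V_R = V_R, class = c("growth_curve", "data.frame"))
}

#' Synthetic Gompertz growth curve
#'
#' Generates a [growth_curve()] from the Gompertz law, for exercising the
#' calibration pipeline without external data.
#'
#' @inheritParams gompertz_mass
#' @param times sampling times (days).
#' @param rho density used for the mass/fraction conversion.
#' @export
gompertz_curve <- function(times, m_inf, b, c, rho = 1000) {
  growth_curve(times, gompertz_mass(times, m_inf, b, c),
               rho = rho, V_R = m_inf / rho)
}

#' Time at which a growth curve reaches half its final mass
#'
#' Linear interpolation of the first crossing of `m_ref / 2`; `m_ref`
#' defaults to the curve's largest mass.
#'
#' @param curve a [growth_curve()] or data.frame with `time`, `mass`.
#' @param m_ref reference (final) mass.
#' @export
time_to_half_mass <- function(curve, m_ref = NULL) {
  if (is.null(m_ref)) m_ref <- max(curve$mass)
  target <- m_ref / 2
  above <- which(curve$mass >= target)
  if (length(above) == 0L) return(NA_real_)
  k <- above[1L]
  if (k == 1L) return(curve$time[1L])
  t0 <- curve$time[k - 1L]; t1 <- curve$time[k]
  m0 <- curve$mass[k - 1L]; m1 <- curve$mass[k]
  if (m1 == m0) return(t1)
  t0 + (target - m0) / (m1 - m0) * (t1 - t0)
}

#' Fit the base rate to an observed growth curve by bisection
#'
#' The objective is the signed difference between the simulated and
#' observed time-to-half-mass, a scalar summary that is monotone
#' decreasing in `lambda` (larger base rates speed growth). Each
#' evaluation averages the simulated `T` over `replicates` runs from a
#' central seed; the bracket is halved until its width drops to `tol`.
#'
#' Because every hazard in the neighbour-only model is proportional to
#' `lambda`, the first-passage time scales exactly as `1 / lambda`, so the
#' objective has a unique root and the fitted value recovers the
#' generating rate of a self-simulated curve up to Monte Carlo noise.
#'
#' @param observed a [growth_curve()].
#' @param lattice lattice for the simulation runs; for physical units
#'   build it over the bounding box of the reference volume
#'   (`extent = c(0, box_edge_from_volume(V_R))`), so the fitted `lambda`
#'   carries units of 1/(length * time).
#' @param bracket `c(lo, hi)` initial bracket for `lambda`.
#' @param tol bracket-width tolerance (same units as `lambda`).
#' @param replicates simulation replicates per objective evaluation.
#' @param seed RNG seed; per-evaluation streams derive from
#'   `(seed, iteration, replicate)`.
#' @inheritParams simulate_growth
#' @return object of class `calibration_result`: `lambda` (bracket
#'   midpoint at termination), `bracket` history, `iterations`, `misfit`
#'   (objective at the fitted value), `replicates`.
#' @export
fit_lambda <- function(observed, lattice, bracket, tol,
                       replicates = 5L, seed = 1L,
                       tau_control = tau_rule(), max_steps = 1e6L) {
  stopifnot(inherits(lattice, "skin_lattice"))
  lo <- bracket[1L]; hi <- bracket[2L]
  if (!(lo > 0) || !(hi > lo)) stop("invalid bracket", call. = FALSE)
  if (!(tol > 0) || tol >= hi - lo)
    stop("`tol` must be positive and smaller than the bracket width",
         call. = FALSE)
  T_obs <- time_to_half_mass(observed)
  if (is.na(T_obs))
    stop("observed curve never reaches half its final mass", call. = FALSE)

  objective <- function(lam, iter) {
    Ts <- vapply(seq_len(replicates), function(r) {
      set.seed((seed * 1009L + iter * 97L + r) %% .Machine$integer.max)
      model <- rate_model(lambda = lam)
      traj <- simulate_growth(lattice, model, seeds = "center",
                              stop_fraction = 0.5,
                              tau_control = tau_control,
                              max_steps = max_steps)
      time_to_fraction(traj, 0.5)
    }, numeric(1L))
    mean(Ts) - T_obs
  }

  g_lo <- objective(lo, 0L)
  g_hi <- objective(hi, 0L)
  if (!(g_lo > 0 && g_hi < 0))
    stop(sprintf(paste("calibration error: objective does not change sign",
                       "over the bracket (g(%g)=%.4g, g(%g)=%.4g);",
                       "widen the bracket"),
                 lo, g_lo, hi, g_hi), call. = FALSE)

  history <- list(c(lo, hi))
  iter <- 0L
  g_mid <- NA_real_
  while (hi - lo > tol) {
    iter <- iter + 1L
    mid <- (lo + hi) / 2
    g_mid <- objective(mid, iter)
    if (g_mid > 0) lo <- mid else hi <- mid
    history[[length(history) + 1L]] <- c(lo, hi)
  }
  structure(list(lambda = (lo + hi) / 2,
                 bracket = do.call(rbind, history),
                 iterations = iter, misfit = g_mid,
                 replicates = replicates, T_obs = T_obs),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: lambda=%.6g after %d bisections (misfit %.4g)\n",
    x$lambda, x$iterations, x$misfit))
  invisible(x)
}
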