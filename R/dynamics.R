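#' Transition-rate model
#'
#' Bundles the parameters of the per-node hazard
#' `lambda_i = lambda * sum_j S_j / d(x_i, x_j) + alpha * R_i`,
#' where the sum runs over the nearest neighbours of node `i` and `R_i` is
#' the lifetime UV-burden factor returned by [uv_exposure()].
#'
#' @param lambda base contamination rate (per unit time, per reciprocal
#'   unit distance); must be positive.
#' @param alpha UV sensitivity (per unit time), non-negative. Ignored when
#'   `uv_mode = "none"`.
#' @param beta UV attenuation with depth (per unit depth), non-negative.
#'   Only used when `uv_mode = "attenuated"`.
#' @param uv_mode `"none"`, `"surface"` (exposure 1 on the top layer only),
#'   or `"attenuated"` (`R_i = exp(-beta * zhat_i)` with depth
#'   `zhat_i = z_top - z_i`).
#' @param depth_axis which coordinate axis plays depth; default the last
#'   axis. The exposed surface sits at that coordinate's maximum.
#' @param mode `"neighbour"` for the spatial rate law above; `"uniform"` is
#'   the validation mode in which every susceptible node carries hazard
#'   `lambda` regardless of its neighbours (used to benchmark the lattice
#'   against the analytic non-spatial chain).
#' @return object of class `rate_model`.
#' @export
rate_model <- function(lambda, alpha = 0, beta = 0,
                       uv_mode = c("none", "surface", "attenuated"),
                       depth_axis = NULL,
                       mode = c("neighbour", "uniform")) {
  uv_mode <- match.arg(uv_mode)
  mode <- match.arg(mode)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0)
    stop("`lambda` must be a single positive number", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be non-negative", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("`beta` must be non-negative", call. = FALSE)
  if (!is.null(depth_axis)) depth_axis <- as.integer(depth_axis)
  structure(list(lambda = lambda, alpha = alpha, beta = beta,
                 uv_mode = uv_mode, depth_axis = depth_axis, mode = mode),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model: lambda=%g, alpha=%g, beta=%g, uv=%s, mode=%s\n",
              x$lambda, x$alpha, x$beta, x$uv_mode, x$mode))
  invisible(x)
}

model_depth_axis <- function(lattice, model) {
  dz <- model$depth_axis
  if (is.null(dz)) dz <- lattice$dim
  if (dz < 1L || dz > lattice$dim)
    stop("`depth_axis` outside lattice dimensionality", call. = FALSE)
  dz
}

#' Per-node lifetime UV exposure
#'
#' The phenomenological UV transmission factor `R_i`:
#' mode `"none"` gives 0 everywhere; `"surface"` gives 1 exactly on the top
#' layer (depth 0) and 0 below; `"attenuated"` gives the Beer--Lambert-like
#' decay `exp(-beta * zhat_i)` with depth `zhat_i = z_top - z_i`.
#'
#' @inheritParams neighbours
#' @param model a [rate_model()].
#' @return numeric vector of length `lattice$n`, in `[0, 1]`.
#' @export
uv_exposure <- function(lattice, model) {
  stopifnot(inherits(lattice, "skin_lattice"),
            inherits(model, "rate_model"))
  if (model$uv_mode == "none") return(numeric(lattice$n))
  dz <- model_depth_axis(lattice, model)
  zhat <- lattice$extent[2L, dz] - lattice$coords[, dz]
  if (model$uv_mode == "surface")
    as.numeric(zhat < lattice$spacing[dz] / 2)
  else
    exp(-model$beta * zhat)
}

#' Initial state
#'
#' @inheritParams neighbours
#' @param seeds integer node ids initially in cancer state, or `"center"`
#'   for the node nearest the domain centre (ties to the lowest id).
#' @return list with binary flags `S` (0 susceptible, 1 cancerous) and the
#'   current time `t = 0`.
#' @export
initial_state <- function(lattice, seeds = integer(0)) {
  seeds <- resolve_seeds(lattice, seeds)
  S <- integer(lattice$n)
  S[seeds] <- 1L
  list(S = S, t = 0)
}

resolve_seeds <- function(lattice, seeds) {
  if (is.character(seeds)) {
    if (!identical(unname(seeds), "center") &&
        !identical(unname(seeds), "centre"))
      stop("character `seeds` must be \"center\"", call. = FALSE)
    return(centre_node(lattice))
  }
  seeds <- as.integer(seeds)
  if (anyNA(seeds) || any(seeds < 1L) || any(seeds > lattice$n))
    stop("seed node ids out of range", call. = FALSE)
  unique(seeds)
}

#' Transition hazard of a single node
#'
#' Evaluates `lambda_i` for node `i` from the current state: the
#' distance-weighted count of cancerous neighbours times `lambda`, plus the
#' UV term `alpha * R_i`. A node already in cancer state returns 0 (total
#' function; the samplers never consult it).
#'
#' @param state an [initial_state()]-style list.
#' @inheritParams uv_exposure
#' @param uv per-node exposure from [uv_exposure()].
#' @param i node identifier.
#' @export
node_rate <- function(state, lattice, model, uv, i) {
  i <- check_node(lattice, i)
  if (state$S[i] == 1L) return(0)
  if (model$mode == "uniform") return(model$lambda)
  nb <- neighbours(lattice, i)
  w <- sum(state$S[nb] / neighbour_distances(lattice, i))
  model$lambda * w + if (model$uv_mode == "none") 0 else model$alpha * uv[i]
}

#' Probability of transition over a finite step
#'
#' `1 - exp(-rate * tau)`, the exact flip probability of an exponential
#' clock with constant hazard `rate` over an interval of length `tau`.
#' Vectorised over `rate`.
#'
#' @param rate non-negative hazard(s).
#' @param tau positive step length.
#' @export
transition_probability <- function(rate, tau) {
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("`tau` must be positive", call. = FALSE)
  if (any(rate < 0)) stop("`rate` must be non-negative", call. = FALSE)
  -expm1(-rate * tau)
}

#' One fixed-tau step (reference implementation)
#'
#' Advances the state by one step of length `tau`: every susceptible node
#' flips independently with probability `1 - exp(-lambda_i * tau)`, hazards
#' evaluated from the state at the start of the step (tau-leaping
#' semantics). This R implementation mirrors the compiled engine used by
#' [simulate_growth()] and is intended for inspection and testing.
#'
#' @inheritParams node_rate
#' @param tau positive step length.
#' @return list with the updated `state` and the integer vector `flipped`.
#' @export
step_fixed_tau <- function(state, lattice, model, uv, tau) {
  stopifnot(tau > 0)
  S <- state$S
  sus <- which(S == 0L)
  if (length(sus)) {
    if (model$mode == "uniform") {
      rates <- rep.int(model$lambda, length(sus))
    } else {
      deg <- diff(lattice$nbr_ptr)
      contrib <- S[lattice$nbr_idx] / lattice$nbr_dist
      W <- as.numeric(rowsum(contrib, rep.int(seq_len(lattice$n), deg),
                             reorder = TRUE))
      uvterm <- if (model$uv_mode == "none") 0 else model$alpha * uv
      rates <- (model$lambda * W + uvterm)[sus]
    }
    p <- transition_probability(rates, tau)
    flipped <- sus[runif(length(sus)) < p]
    S[flipped] <- 1L
  } else {
    flipped <- integer(0)
  }
  list(state = list(S = S, t = state$t + tau), flipped = flipped)
}

#' Simulate cancer progression on the lattice
#'
#' Runs the irreversible two-state process until a target fraction (or
#' count) of nodes is in cancer state. The default sampler is the
#' fixed-step (tau-leaping) scheme: hazards are frozen at the start of each
#' step, the step length is `min(tau_max, c / max_i lambda_i)` (or a fixed
#' `tau` when supplied), and flipped nodes are stamped with the end-of-step
#' time. `sampler = "event_driven"` uses the statistically exact Gillespie
#' scheme instead ([simulate_event_driven()]).
#'
#' @inheritParams uv_exposure
#' @param seeds initial cancerous nodes (ids or `"center"`); may be empty
#'   when a UV mode supplies spontaneous initiation.
#' @param stop_fraction target fraction in `(0, 1]`; the run stops the
#'   first time the cancer count reaches `ceiling(stop_fraction * n)`.
#' @param stop_count alternative stop condition as an absolute node count
#'   (overrides `stop_fraction`).
#' @param tau_control list from [tau_rule()].
#' @param max_steps step budget before the run is declared stagnant.
#' @param sampler `"fixed_tau"` or `"event_driven"`.
#' @return object of class `trajectory`: event `times` and `nodes`
#'   (end-of-step stamped), per-step `step_times` / `step_counts`, the
#'   initial count `n0`, total node count `n`, and the sampler tag.
#' @export
simulate_growth <- function(lattice, model, seeds = integer(0),
                            stop_fraction = 0.5, stop_count = NULL,
                            tau_control = tau_rule(),
                            max_steps = 1e6L,
                            sampler = c("fixed_tau", "event_driven")) {
  sampler <- match.arg(sampler)
  stopifnot(inherits(lattice, "skin_lattice"),
            inherits(model, "rate_model"))
  if (is.null(stop_count)) {
    if (stop_fraction <= 0 || stop_fraction > 1)
      stop("`stop_fraction` must be in (0, 1]", call. = FALSE)
    stop_count <- as.integer(ceiling(stop_fraction * lattice$n - 1e-9))
  }
  stop_count <- as.integer(stop_count)
  if (stop_count < 1L || stop_count > lattice$n)
    stop("`stop_count` out of range", call. = FALSE)

  seeds <- resolve_seeds_maybe_empty(lattice, seeds)
  if (length(seeds) == 0L && model$uv_mode == "none" &&
      model$mode == "neighbour")
    warning(paste("no initial seeds and no UV initiation:",
                  "the state can never change"), call. = FALSE)

  if (sampler == "event_driven")
    return(simulate_event_driven(lattice, model, seeds,
                                 stop_count = stop_count,
                                 max_events = max_steps))

  S0 <- integer(lattice$n)
  S0[seeds] <- 1L
  uv <- uv_exposure(lattice, model)
  uv_rate <- if (model$uv_mode == "none") numeric(lattice$n) else
    model$alpha * uv

  tc <- tau_control
  res <- cpp_simulate_fixed(lattice$nbr_ptr, lattice$nbr_idx,
                            1 / lattice$nbr_dist, uv_rate, model$lambda, S0,
                            stop_count, tc$c,
                            if (is.finite(tc$tau_max)) tc$tau_max else
                              .Machine$double.xmax,
                            if (is.null(tc$tau)) 0 else tc$tau,
                            as.integer(max_steps),
                            model$mode == "uniform")
  if (res$status == 2L)
    stop_stagnation("total hazard is zero before the stop condition")
  if (res$status == 3L)
    stop_stagnation(sprintf(
      "stop condition not reached within the %d-step budget", max_steps))

  new_trajectory(times = res$times, nodes = res$nodes,
                 step_times = res$step_times, step_counts = res$step_counts,
                 n = lattice$n, n0 = length(seeds), t_end = res$t_end,
                 sampler = "fixed_tau", tau = tc$tau,
                 stop_count = stop_count)
}

resolve_seeds_maybe_empty <- function(lattice, seeds) {
  if (length(seeds) == 0L) return(integer(0))
  resolve_seeds(lattice, seeds)
}

stop_stagnation <- function(msg) {
  stop(errorCondition(paste0("stagnation: ", msg),
                      class = c("skinmarkov_stagnation", "error")))
}

#' Time-step selection rule
#'
#' The adaptive default `tau = c / max_i lambda_i` keeps the largest
#' per-step flip probability near `1 - exp(-c)`; the per-step probability
#' itself is exact for frozen hazards, so `c` only controls the
#' rate-freezing error. A fixed `tau` overrides the adaptive rule.
#'
#' @param c dimensionless target for `tau * max rate` (default 0.05).
#' @param tau_max upper bound on the adaptive step.
#' @param tau fixed step length, or `NULL` for adaptive.
#' @export
tau_rule <- function(c = 0.05, tau_max = Inf, tau = NULL) {
  if (!is.null(tau) && tau <= 0) stop("fixed `tau` must be positive",
                                      call. = FALSE)
  if (c <= 0) stop("`c` must be positive", call. = FALSE)
  list(c = c, tau_max = tau_max, tau = tau)
}

new_trajectory <- function(times, nodes, step_times, step_counts, n, n0,
                           t_end, sampler, tau, stop_count) {
  structure(list(times = as.numeric(times), nodes = as.integer(nodes),
                 step_times = as.numeric(step_times),
                 step_counts = as.integer(step_counts),
                 n = n, n0 = n0, t_end = t_end, sampler = sampler,
                 tau = tau, stop_count = stop_count),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory (%s): %d/%d nodes cancerous at t=%.4g (%d events)\n",
    x$sampler, x$n0 + length(x$times), x$n, x$t_end, length(x$times)))
  invisible(x)
}

#' Event-driven (Gillespie) sampler
#'
#' Statistically exact continuous-time sampling of the lattice process:
#' hazards are constant between transitions, so the waiting time to the
#' next event is exponential with the total susceptible hazard and the
#' transitioning node is chosen with probability proportional to its
#' hazard. Serves as the oracle against which the fixed-step sampler is
#' checked in distribution.
#'
#' @inheritParams simulate_growth
#' @param max_events event budget.
#' @export
simulate_event_driven <- function(lattice, model, seeds = integer(0),
                                  stop_fraction = 0.5, stop_count = NULL,
                                  max_events = 1e6L) {
  stopifnot(inherits(lattice, "skin_lattice"),
            inherits(model, "rate_model"))
  if (is.null(stop_count))
    stop_count <- as.integer(ceiling(stop_fraction * lattice$n - 1e-9))
  seeds <- resolve_seeds_maybe_empty(lattice, seeds)

  n <- lattice$n
  S <- integer(n)
  S[seeds] <- 1L
  uv <- uv_exposure(lattice, model)
  uvterm <- if (model$uv_mode == "none") numeric(n) else model$alpha * uv

  W <- numeric(n)
  for (i in seeds) {
    nb <- neighbours(lattice, i)
    W[nb] <- W[nb] + 1 / neighbour_distances(lattice, i)
  }
  rate <- if (model$mode == "uniform") rep.int(model$lambda, n) else
    model$lambda * W + uvterm
  rate[S == 1L] <- 0

  t <- 0
  count <- length(seeds)
  ev_t <- numeric(0)
  ev_n <- integer(0)
  while (count < stop_count) {
    total <- sum(rate)
    if (total <= 0)
      stop_stagnation("total hazard is zero before the stop condition")
    if (length(ev_t) >= max_events)
      stop_stagnation("event budget exhausted")
    t <- t + rexp(1L, total)
    i <- sample.int(n, 1L, prob = rate)
    S[i] <- 1L
    rate[i] <- 0
    count <- count + 1L
    ev_t <- c(ev_t, t)
    ev_n <- c(ev_n, i)
    nb <- neighbours(lattice, i)
    dd <- neighbour_distances(lattice, i)
    sus <- S[nb] == 0L
    if (model$mode == "neighbour" && any(sus)) {
      j <- nb[sus]
      rate[j] <- rate[j] + model$lambda / dd[sus]
    }
  }
  new_trajectory(times = ev_t, nodes = ev_n, step_times = ev_t,
                 step_counts = length(seeds) + seq_along(ev_t),
                 n = n, n0 = length(seeds), t_end = t,
                 sampler = "event_driven", tau = NULL,
                 stop_count = stop_count)
}

#' Time at which a trajectory first reaches a fraction
#'
#' The minimal recorded time with cancer fraction at least `f`; the start
#' time (0) if the initial state already satisfies it, `NA` if the
#' trajectory never reached it.
#'
#' @param traj a `trajectory`.
#' @param f target fraction in `(0, 1]`.
#' @export
time_to_fraction <- function(traj, f) {
  stopifnot(inherits(traj, "trajectory"))
  if (f <= 0 || f > 1) stop("`f` must be in (0, 1]", call. = FALSE)
  target <- as.integer(ceiling(f * traj$n - 1e-9))
  if (traj$n0 >= target) return(0)
  k <- target - traj$n0
  if (k > length(traj$times)) return(NA_real_)
  traj$times[k]
}

#' Fraction curve of a trajectory
#'
#' @param traj a `trajectory`.
#' @return data.frame with columns `time`, `count`, `fraction`, starting at
#'   the initial state; the fraction is a non-decreasing step function.
#' @export
fraction_curve <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  cnt <- traj$n0 + seq_along(traj$times)
  data.frame(time = c(0, traj$times),
             count = c(traj$n0, cnt),
             fraction = c(traj$n0, cnt) / traj$n)
}
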